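# Junction typing against hand-constructed alignment geometry; the toy
# construct has LB at [0,25) and RB at [4975,5000), bridge sites at 180/4819.

test_that("read pairs classify into the four taxa", {
  cm <- toy_construct()
  p_inv <- mk_pair(r1 = mk_seg("chr2", 100, 150), r2 = mk_seg("chr2", 400, 150, "-"))
  expect_equal(classify_read_pair(p_inv), "INVALID_GENOME_ONLY")
  p_td <- mk_pair(r1 = mk_seg("tDNA", 100, 150), r2 = mk_seg("tDNA", 400, 150, "-"))
  expect_equal(classify_read_pair(p_td), "INVALID_TDNA_ONLY")
  r2 <- rbind(mk_seg("tDNA", 0, 70, "+", 0, mate = "R2"),
              mk_seg("chr1", 5000, 80, "+", 70, mate = "R2"))
  expect_equal(classify_read_pair(mk_pair(r2 = r2)), "SPLIT")
  p_dc <- mk_pair(r1 = mk_seg("chr1", 100, 150), r2 = mk_seg("tDNA", 50, 150, "-"))
  expect_equal(classify_read_pair(p_dc), "DISCORDANT")
  expect_error(classify_read_pair(mk_pair()), "no aligned segments")
})

test_that("split validity needs >= 20 bp exclusive coverage per segment", {
  mk_split <- function(x) {
    r1 <- rbind(mk_seg("chr1", 1000, x, "+", 0),
                mk_seg("tDNA", 30, 150 - x, "+", x))
    mk_pair(r1 = r1)
  }
  cls <- vapply(1:50, function(x) classify_read_pair(mk_split(x)), character(1))
  expect_equal(cls == "SPLIT", 1:50 >= 20)
  # overlapping segments count only exclusive coverage
  r1 <- rbind(mk_seg("chr1", 1000, 80, "+", 0),          # read [0,80)
              mk_seg("tDNA", 30, 85, "+", 65))           # read [65,150), overlap 15
  expect_equal(classify_read_pair(mk_pair(r1 = r1)), "SPLIT")  # 65 and 70 exclusive
  r1b <- rbind(mk_seg("chr1", 1000, 131, "+", 0),        # read [0,131)
               mk_seg("tDNA", 30, 50, "+", 100))         # read [100,150): 19 bp exclusive
  expect_false(classify_read_pair(mk_pair(r1 = r1b)) == "SPLIT")
})

test_that("mates fragmenting into 3+ segments contribute no split evidence", {
  r1 <- rbind(mk_seg("chr1", 1000, 60, "+", 0),
              mk_seg("tDNA", 30, 50, "+", 60),
              mk_seg("chr2", 4000, 40, "+", 110))
  expect_false(classify_read_pair(mk_pair(r1 = r1, r2 = mk_seg("chr1", 1500, 150))) == "SPLIT")
  r1two <- r1[1:2, ]
  expect_equal(classify_read_pair(mk_pair(r1 = r1two)), "SPLIT")
})

test_that("split junctions type by geometry: the canonical eight cases", {
  cm <- toy_construct()
  lab <- function(p) {
    e <- junction_from_split(p, cm)
    c(paste(e$ref_side, e$border, e$direction, sep = "&"), e$breakpoint)
  }
  # genome [4900,5000)+ then tDNA near LB, + -> ideal left junction
  p <- mk_pair(r1 = rbind(mk_seg("chr1", 4900, 100, "+", 0),
                          mk_seg("tDNA", 0, 50, "+", 100)))
  expect_equal(lab(p), c("Left&LB&Forward", "5000"))
  # same geometry, tDNA segment on the minus strand -> Reverse
  p2 <- mk_pair(r1 = rbind(mk_seg("chr1", 4900, 100, "+", 0),
                           mk_seg("tDNA", 0, 50, "-", 100)))
  expect_equal(lab(p2), c("Left&LB&Reverse", "5000"))
  # tDNA (near RB) then genome [5000,5080)+ -> ideal right junction
  p3 <- mk_pair(r1 = rbind(mk_seg("tDNA", 4930, 70, "+", 0),
                           mk_seg("chr1", 5000, 80, "+", 70)))
  expect_equal(lab(p3), c("Right&RB&Forward", "5001"))
  # genome on minus strand with tDNA following = genome precedes in fragment
  # orientation -> Right
  p4 <- mk_pair(r1 = rbind(mk_seg("chr1", 5000, 80, "-", 0),
                           mk_seg("tDNA", 4930, 70, "-", 80)))
  expect_equal(lab(p4), c("Right&RB&Forward", "5001"))
})

test_that("borders equidistant from both repeats are discarded with a counter", {
  # repeat edges chosen so an exact midpoint exists (tie at 2500)
  withr::with_seed(8, s <- tagtis:::.rand_seq(5000, 0.45))
  cm <- construct_model("tie", s, c(0, 25), c(4976, 5000), 180, 4820)
  p <- mk_pair(r1 = rbind(mk_seg("chr1", 4900, 100, "+", 0),
                          mk_seg("tDNA", 2500, 50, "+", 100)))
  expect_null(junction_from_split(p, cm))
  ev <- extract_evidence(list(p), cm)
  expect_equal(nrow(ev), 0L)
  expect_equal(unname(attr(ev, "class_counts")["AMBIGUOUS_BORDER"]), 1L)
})

test_that("discordant junctions infer side from the genome mate and direction from strand parity", {
  cm <- toy_construct()
  # genome mate + (faces right), tDNA mate on - near LB -> Left&LB&Forward
  p <- mk_pair(r1 = mk_seg("chr1", 4800, 150, "+", 0),
               r2 = mk_seg("tDNA", 31, 150, "-", 0))
  e <- junction_from_discordant(p, cm)
  expect_equal(paste(e$ref_side, e$border, e$direction, sep = "&"), "Left&LB&Forward")
  expect_equal(e$breakpoint, 4950)      # outer bound: junction lies at or beyond
  expect_equal(e$kind, "discordant")
  # genome mate -, tDNA mate + near RB -> Right&RB&Forward
  p2 <- mk_pair(r1 = mk_seg("chr1", 5100, 150, "-", 0),
                r2 = mk_seg("tDNA", 4819, 150, "+", 0))
  e2 <- junction_from_discordant(p2, cm)
  expect_equal(paste(e2$ref_side, e2$border, e2$direction, sep = "&"), "Right&RB&Forward")
  expect_equal(e2$breakpoint, 5101)
})

test_that("the insertion-type vocabulary is the stable 8-label set", {
  v <- enumerate_insertion_types()
  expect_length(v, 8L)
  expect_equal(v[1], "Left&LB&Forward")
  expect_equal(anyDuplicated(v), 0L)
  expect_true(all(grepl("^(Left|Right)&(LB|RB)&(Forward|Reverse)$", v)))
})

test_that("deduplication keeps one record per Tn5 fragment signature", {
  cm <- toy_construct()
  mkev <- function(id, cut, nmm = 0) {
    p <- mk_pair(r1 = rbind(mk_seg("chr1", cut, 100 + (4900 - cut), "+", 0, nmm = nmm),
                            mk_seg("tDNA", 0, 50, "+", 100 + (4900 - cut))),
                 id = id)
    junction_from_split(p, cm)
  }
  same1 <- mkev("b", 4900); same2 <- mkev("a", 4900, nmm = 1)
  diff1 <- mkev("c", 4853); diff2 <- mkev("d", 4887)
  dd <- dedupe_evidence(rbind(same1, same2, diff1, diff2))
  expect_equal(nrow(dd), 3L)
  expect_true("b" %in% dd$read_id)      # fewest mismatches wins among dups
  expect_false("a" %in% dd$read_id)
  expect_equal(nrow(dedupe_evidence(tagtis:::.empty_evidence())), 0L)
})

test_that("clustering applies support thresholds and modal breakpoints", {
  cm <- toy_construct()
  mksp <- function(id, cut, bp_shift = 0L) {
    glen <- 100L
    p <- mk_pair(r1 = rbind(mk_seg("chr1", cut, 5000 + bp_shift - cut, "+", 0),
                            mk_seg("tDNA", 0, 50, "+", 5000 + bp_shift - cut)),
                 id = id)
    junction_from_split(p, cm)
  }
  ev5 <- do.call(rbind, lapply(1:5, function(i) mksp(paste0("s", i), 4900 - i * 7)))
  calls <- cluster_calls(ev5, sample = "S")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$split_supportN, 5L)
  expect_equal(calls$breakpoint, 5000)
  expect_equal(calls$discort_supportN, 0L)
  # one split + three discordant within range -> kept under the one-split rule
  mkdc <- function(id, pos) {
    p <- mk_pair(r1 = mk_seg("chr1", pos, 150, "+", 0),
                 r2 = mk_seg("tDNA", 31, 150, "-", 0), id = id)
    junction_from_discordant(p, cm)
  }
  ev13 <- rbind(mksp("s1", 4880), mkdc("d1", 4500), mkdc("d2", 4600), mkdc("d3", 4700))
  c13 <- cluster_calls(ev13, sample = "S")
  expect_equal(nrow(c13), 1L)
  expect_false(c13$imprecise)
  expect_equal(c13$split_supportN, 1L)
  expect_equal(c13$discort_supportN, 3L)
  # a lone split is filtered under the defaults
  expect_equal(nrow(cluster_calls(mksp("solo", 4880), sample = "S")), 0L)
  # discordant-only evidence groups into an imprecise support-only cluster
  cdo <- cluster_calls(rbind(mkdc("d1", 4500), mkdc("d2", 4600)), sample = "S")
  expect_equal(nrow(cdo), 1L)
  expect_true(cdo$imprecise)
  expect_equal(cdo$breakpoint, 4750)    # outermost Left estimate
})

test_that("breakpoint mode is reported with smallest-tie preference", {
  cm <- toy_construct()
  mksp <- function(id, cut, bp) {
    p <- mk_pair(r1 = rbind(mk_seg("chr1", cut, bp - cut, "+", 0),
                            mk_seg("tDNA", 0, 50, "+", bp - cut)), id = id)
    junction_from_split(p, cm)
  }
  ev <- rbind(mksp("a", 4900, 5000), mksp("b", 4890, 5000),
              mksp("c", 4880, 5002), mksp("d", 4870, 5002), mksp("e", 4860, 5001))
  calls <- cluster_calls(ev, sample = "S")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$breakpoint, 5000)  # 5000 and 5002 tie at 2 -> smallest
  expect_equal(calls$split_supportN, 5L)
})

test_that("control subtraction removes nearby control sites only", {
  calls <- mk_call(777)
  out <- subtract_control(calls, mk_call(780), radius = 10)
  expect_equal(nrow(out), 0L)
  expect_equal(nrow(attr(out, "removed")), 1L)
  expect_equal(nrow(subtract_control(calls, NULL)), 1L)
  expect_equal(nrow(subtract_control(calls, mk_call(900))), 1L)
  expect_equal(nrow(subtract_control(calls, mk_call(777, chrom = "chr9"))), 1L)
})

test_that("full-TIS pairing computes target deletions and leaves halves unpaired", {
  mk2 <- function(bp, side)
    mk_call(bp, chrom = "chr1", side = side,
            border = if (side == "Left") "LB" else "RB")
  calls <- rbind(mk2(5000, "Left"), mk2(5001, "Right"))
  class(calls) <- c("tis_calls", "data.frame")
  ft <- pair_full_tis(calls)
  expect_equal(nrow(ft$full), 1L)
  expect_equal(ft$full$target_deletion_bp, 0)
  expect_equal(ft$full$pattern, "Left&LB&Forward + Right&RB&Forward")
  calls2 <- rbind(mk2(5000, "Left"), mk2(5031, "Right"))
  class(calls2) <- c("tis_calls", "data.frame")
  expect_equal(pair_full_tis(calls2)$full$target_deletion_bp, 30)
  lone <- mk2(5000, "Left")
  res <- pair_full_tis(lone)
  expect_equal(nrow(res$full), 0L)
  expect_equal(nrow(res$unpaired), 1L)
  far <- rbind(mk2(5000, "Left"), mk2(9000, "Right"))
  class(far) <- c("tis_calls", "data.frame")
  expect_equal(nrow(pair_full_tis(far)$full), 0L)
})

test_that("multi-mapped calls are flagged with their alternate sites, never dropped", {
  cm <- toy_construct()
  mksp <- function(id, cut) {
    # each read's alternate loci shift with its own segment start, the way
    # equally-scoring hits on identical repeat copies do
    co <- data.frame(contig = c("chr2", "chr3", "chr4"),
                     ref_start = c(1000L, 2000L, 3000L) - (4900L - cut),
                     strand = "+", stringsAsFactors = FALSE)
    g <- mk_seg("chr1", cut, 5000 - cut, "+", 0, cohits = co)
    p <- mk_pair(r1 = rbind(g, mk_seg("tDNA", 0, 50, "+", 5000 - cut)), id = id)
    junction_from_split(p, cm)
  }
  ev <- rbind(mksp("a", 4900), mksp("b", 4890))
  calls <- resolve_multimap(cluster_calls(ev, sample = "S"))
  expect_equal(nrow(calls), 1L)
  expect_true(calls$ambiguous)
  expect_equal(nrow(calls$ambiguous_sites[[1]]), 3L)
  # alternate breakpoints follow the junction-end arithmetic
  expect_setequal(calls$ambiguous_sites[[1]]$breakpoint, c(1100, 2100, 3100))
  noco <- cluster_calls(rbind(
    junction_from_split(mk_pair(r1 = rbind(mk_seg("chr1", 4900, 100, "+", 0),
                                           mk_seg("tDNA", 0, 50, "+", 100)), id = "x"), cm),
    junction_from_split(mk_pair(r1 = rbind(mk_seg("chr1", 4890, 110, "+", 0),
                                           mk_seg("tDNA", 0, 50, "+", 110)), id = "y"), cm)),
    sample = "S")
  noco <- resolve_multimap(noco)
  expect_false(noco$ambiguous)
})

test_that("support counts are invariant to duplicating every input pair", {
  cm <- toy_construct()
  mksp <- function(id, cut) {
    p <- mk_pair(r1 = rbind(mk_seg("chr1", cut, 5000 - cut, "+", 0),
                            mk_seg("tDNA", 0, 50, "+", 5000 - cut)), id = id)
    junction_from_split(p, cm)
  }
  ev <- rbind(mksp("a", 4900), mksp("b", 4890), mksp("c", 4880))
  dup <- rbind(ev, transform(ev, read_id = paste0(read_id, "_copy")))
  c1 <- cluster_calls(dedupe_evidence(ev), sample = "S")
  c2 <- cluster_calls(dedupe_evidence(dup), sample = "S")
  expect_equal(c1$split_supportN, c2$split_supportN)
  expect_equal(c1$breakpoint, c2$breakpoint)
})
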