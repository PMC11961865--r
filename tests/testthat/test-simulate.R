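test_that("simulated genomes are seed-deterministic and honor gc", {
  g1 <- simulate_genome(2, c(20000, 20000), 0.4, seed = 1)
  g2 <- simulate_genome(2, c(20000, 20000), 0.4, seed = 1)
  expect_identical(as.character(g1), as.character(g2))
  expect_equal(names(g1), c("chr1", "chr2"))
  gc1 <- simulate_genome(1, 5000, gc = 1, seed = 2)
  expect_true(grepl("^[GC]+$", as.character(gc1[[1]])))
  expect_error(simulate_genome(0, 1000), "n_contigs")
  expect_error(simulate_genome(1, -5), "positive")
})

test_that("an ideal forward insertion yields the canonical label pair, both detectable", {
  cm <- toy_construct()
  g <- toy_genome(len = 30000)
  ev <- insertion_event("e1", "chr1", 15000, units = "F")
  im <- implant_insertions(g, cm, list(ev), seed = 5)
  tr <- im$truth
  expect_equal(tr$left_label, "Left&LB&Forward")
  expect_equal(tr$right_label, "Right&RB&Forward")
  expect_true(tr$detectable_left && tr$detectable_right)
  expect_equal(tr$left_breakpoint, 15000)
  expect_equal(tr$right_breakpoint, 15001)
  # modified contig grows by the payload
  expect_equal(Biostrings::width(im$genome)[1], 30000 + nchar(cm$tdna_seq))
})

test_that("truncating away a bridge site makes that junction undetectable", {
  cm <- toy_construct()
  g <- toy_genome(len = 30000)
  ev <- insertion_event("e1", "chr1", 15000, units = "F", lb_truncation = 200L)
  im <- implant_insertions(g, cm, list(ev), seed = 6)
  expect_false(im$truth$detectable_left)
  expect_true(im$truth$detectable_right)
})

test_that("a head-to-head concatemer exposes LB at both outer junctions", {
  cm <- toy_construct()
  g <- toy_genome(len = 30000)
  ev <- insertion_event("e1", "chr1", 15000, units = c("F", "R"))
  im <- implant_insertions(g, cm, list(ev), seed = 7)
  expect_equal(im$truth$left_label, "Left&LB&Forward")
  expect_equal(im$truth$right_label, "Right&LB&Reverse")
})

test_that("deletions and event bounds are validated", {
  cm <- toy_construct()
  g <- toy_genome(len = 30000)
  expect_error(implant_insertions(g, cm, list(insertion_event("e", "chr1", 500)), seed = 1),
               "contig end")
  evs <- list(insertion_event("a", "chr1", 15000), insertion_event("b", "chr1", 16000))
  expect_error(implant_insertions(g, cm, evs, seed = 1), "2 kb")
  expect_error(implant_insertions(g, cm, list(insertion_event("e", "chrZ", 5000)), seed = 1),
               "not in genome")
})

test_that("libraries are byte-deterministic and keep fragment bookkeeping", {
  sc1 <- simulate_scenario(seed = 21, n_events = 1, archetypes = "ideal_F",
                           params = library_params(n_capturable = 10, seed = 21))
  sc2 <- simulate_scenario(seed = 21, n_events = 1, archetypes = "ideal_F",
                           params = library_params(n_capturable = 10, seed = 21))
  expect_identical(sc1$lib$r1, sc2$lib$r1)
  expect_identical(sc1$lib$r2, sc2$lib$r2)
  n_det <- sum(sc1$implant$junctions$detectable)
  n_dup <- sum(grepl(":d$", names(sc1$lib$r1)))
  expect_equal(length(sc1$lib$r1), 10 * n_det + 50 + n_dup)
})

test_that("every junction amplicon R2 starts at the bridge site reading toward the border", {
  cm <- toy_construct()
  sc <- simulate_scenario(seed = 22, n_events = 1, archetypes = "ideal_F",
                          construct = cm,
                          params = library_params(n_capturable = 8, n_background = 0,
                                                  seed = 22))
  td <- cm$tdna_seq
  left_r2 <- sc$lib$r2[grepl(":L:", names(sc$lib$r2)) & !grepl(":d$", names(sc$lib$r2))]
  # LB bridge at 0-based 180 reads toward LB: R2 = revcomp of template ending
  # at the bridge site
  expect_gt(length(left_r2), 0)
  want_l <- tagtis:::revcomp(substr(td, 166, 181))
  for (r in left_r2) expect_equal(substr(r, 1, 16), want_l)
  right_r2 <- sc$lib$r2[grepl(":R:", names(sc$lib$r2)) & !grepl(":d$", names(sc$lib$r2))]
  want_r <- substr(td, cm$rb_bridge + 1, cm$rb_bridge + 16)
  for (r in right_r2) expect_equal(substr(r, 1, 16), want_r)
})

test_that("a zero-insertion library contains no construct-derived reads", {
  sc <- simulate_scenario(seed = 23, n_events = 0,
                          params = library_params(seed = 23))
  expect_equal(nrow(sc$implant$truth), 0)
  expect_false(any(sc$control_lib$segments$contig == "tDNA"))
  idx <- build_index(sc$merged_ref)
  pairs <- align_read_pairs(sc$control_lib$r1, sc$control_lib$r2, idx)
  cls <- vapply(pairs, classify_read_pair, character(1))
  expect_true(all(cls == "INVALID_GENOME_ONLY"))
})

test_that("FASTQ files round-trip", {
  reads <- c(a = "ACGTACGT", b = "GGGTTTCC")
  f <- tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  expect_equal(read_fastq(f), reads)
  expect_equal(length(readLines(f)), 8L)
})
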