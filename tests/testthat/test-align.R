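test_that("index size and parameter bounds behave as documented", {
  ref <- simulate_genome(1, 1000, seed = 31)
  idx <- build_index(ref, k = 21)
  expect_equal(length(idx$tab$key), 1000 - 21 + 1)
  expect_error(build_index(ref, k = 4), "k must be odd")
  expect_error(build_index(ref, k = 22), "k must be odd")
  expect_warning(build_index(Biostrings::DNAStringSet(c(chrA = strrep("ACGT", 500),
                                                        tiny = "ACGT"))),
                 "shorter than k")
})

test_that("a unique substring aligns full-length with zero mismatches", {
  ref <- simulate_genome(1, 20000, seed = 32)
  idx <- build_index(ref)
  s <- as.character(ref[[1]])
  rd <- substr(s, 5001, 5150)
  seg <- align_read(rd, idx)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$ref_start, 5000L)
  expect_equal(seg$ref_end, 5150L)
  expect_equal(seg$strand, "+")
  expect_equal(seg$read_start, 0L)
  expect_equal(seg$read_end, 150L)
  expect_equal(seg$n_mismatch, 0L)
})

test_that("minus-strand alignments report original-read offsets", {
  ref <- simulate_genome(1, 20000, seed = 33)
  idx <- build_index(ref)
  s <- as.character(ref[[1]])
  rd <- tagtis:::revcomp(substr(s, 7001, 7150))
  seg <- align_read(rd, idx)
  expect_equal(seg$strand, "-")
  expect_equal(seg$ref_start, 7000L)
  expect_equal(seg$ref_end, 7150L)
  expect_equal(c(seg$read_start, seg$read_end), c(0L, 150L))
})

test_that("a chimeric genome+tDNA read splits at the exact junction offset", {
  # oracle: the read is built from two known substrings, so the expected
  # segments are fixed by construction
  g <- toy_genome(len = 20000, seed = 34)
  cm <- toy_construct()
  merged <- build_merged_reference(g, cm)
  idx <- build_index(merged)
  s <- as.character(g[[1]])
  # choose a junction without chance microhomology, so the boundary is
  # unambiguous: the genome base preceding the window must differ from the
  # last tDNA base of the chimera
  gs <- 9001L
  while (substr(s, gs - 1L, gs - 1L) == substr(cm$tdna_seq, 170, 170)) gs <- gs + 997L
  rd <- paste0(substr(cm$tdna_seq, 101, 170),  # 70 bp of tDNA
               substr(s, gs, gs + 79L))        # 80 bp of chr1
  seg <- align_read(rd, idx)
  seg <- seg[order(seg$read_start), ]
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$contig, c("tDNA", "chr1"))
  expect_equal(seg$read_start, c(0L, 70L))
  expect_equal(seg$read_end, c(70L, 150L))
  expect_equal(seg$ref_start, c(100L, gs - 1L))
  expect_equal(seg$n_mismatch, c(0L, 0L))
})

test_that("scattered substitutions are crossed; a random read finds nothing", {
  ref <- simulate_genome(1, 20000, seed = 35)
  idx <- build_index(ref)
  s <- as.character(ref[[1]])
  rd <- substr(s, 3001, 3150)
  ch <- strsplit(rd, "")[[1]]
  for (i in c(40, 80, 120)) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  seg <- align_read(paste(ch, collapse = ""), idx)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$read_start, 0L)
  expect_equal(seg$read_end, 150L)
  expect_equal(seg$n_mismatch, 3L)
  withr::with_seed(36, rnd <- tagtis:::.rand_seq(150, 0.5))
  expect_equal(nrow(align_read(rnd, idx)), 0L)
})

test_that("repeated loci tie deterministically and are recorded as cohits", {
  block <- tagtis:::.rand_seq  # deterministic block via seed
  withr::with_seed(37, b <- block(400, 0.5))
  withr::with_seed(38, spacer <- block(3000, 0.5))
  ref <- Biostrings::DNAStringSet(c(
    chr1 = paste0(spacer, b, spacer, b, spacer)))
  idx <- build_index(ref)
  rd <- substr(b, 101, 250)
  seg <- align_read(rd, idx)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$ref_start, 3000L + 100L)   # lexicographically smallest locus
  co <- seg$cohits[[1]]
  expect_equal(nrow(co), 1L)
  expect_equal(co$ref_start, 3000L + 400L + 3000L + 100L)
})

test_that("on an error-free library the aligner reproduces the truth segments", {
  sc <- simulate_scenario(seed = 39, n_events = 1, archetypes = "ideal_R",
                          params = library_params(n_capturable = 10,
                                                  n_background = 20, seed = 39))
  idx <- build_index(sc$merged_ref)
  truth <- sc$lib$segments
  key <- function(df) {
    df <- df[order(df$read_id, df$mate, df$read_start), ]
    paste(df$read_id, df$mate, df$contig, df$ref_start, df$ref_end, df$strand,
          df$read_start, df$read_end, sep = "|")
  }
  got <- list()
  for (id in unique(truth$read_id)) {
    for (m in c("R1", "R2")) {
      rd <- if (m == "R1") sc$lib$r1[[id]] else sc$lib$r2[[id]]
      seg <- align_read(rd, idx)
      if (nrow(seg)) { seg$read_id <- id; seg$mate <- m }
      got[[paste(id, m)]] <- seg[, c("read_id", "mate", "contig", "ref_start",
                                     "ref_end", "strand", "read_start", "read_end")]
    }
  }
  got <- do.call(rbind, got)
  expect_setequal(key(got), key(truth))
})
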