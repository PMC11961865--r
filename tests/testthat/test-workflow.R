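# Deep enough that every junction is essentially guaranteed split support:
# a fragment crosses the junction with p ~ 0.18, so 60 fragments leave a
# junction split-less with p ~ 7e-6.
small_params <- function(seed) library_params(n_capturable = 60L, n_background = 20L,
                                              seed = seed)

test_that("run_simulate writes a complete, reproducible fixture directory", {
  d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
  cfg <- list(outdir = d1, seed = 91L, n_events = 1L, archetypes = "ideal_F",
              contig_len = 30000L, params = small_params(91L))
  run_simulate(cfg)
  files <- c("genome.fasta", "genome_modified.fasta", "S1_R1.fastq", "S1_R2.fastq",
             "WT_R1.fastq", "WT_R2.fastq", "S1.truth.sam", "truth.tsv",
             "construct.yaml")
  expect_true(all(file.exists(file.path(d1, files))))
  cfg$outdir <- d2
  run_simulate(cfg)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  # zero-event fixture: truth table is header-only
  d3 <- file.path(tempdir(), "fix3")
  run_simulate(list(outdir = d3, seed = 92L, n_events = 0L,
                    contig_len = 30000L, params = small_params(92L)))
  expect_equal(length(readLines(file.path(d3, "truth.tsv"))), 1L)
})

test_that("run_call produces the full output manifest and is deterministic", {
  fix <- file.path(tempdir(), "fixc")
  run_simulate(list(outdir = fix, seed = 93L, n_events = 1L, archetypes = "ideal_F",
                    contig_len = 30000L, params = small_params(93L)))
  out1 <- file.path(tempdir(), "out1"); out2 <- file.path(tempdir(), "out2")
  cfg <- list(sample = "S1",
              fastq1 = file.path(fix, "S1_R1.fastq"),
              fastq2 = file.path(fix, "S1_R2.fastq"),
              genome = file.path(fix, "genome.fasta"),
              construct = file.path(fix, "construct.yaml"),
              outdir = out1)
  run_call(cfg)
  manifest <- c("S1.tDNA.summary", "supported_reads.fasta", "realignment.tsv",
                "flanks.fasta", "full_tis.tsv", "run.log")
  expect_true(all(file.exists(file.path(out1, manifest))))
  cfg$outdir <- out2
  run_call(cfg)
  for (f in manifest)
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)),
                     label = f)
  # the summary recovers the implanted junctions
  smry <- read_summary(file.path(out1, "S1.tDNA.summary"))
  truth <- utils::read.table(file.path(fix, "truth.tsv"), sep = "\t", header = TRUE)
  expect_true(truth$left_breakpoint %in% smry$breakpoint)
  expect_true(truth$right_breakpoint %in% smry$breakpoint)
  # run.log read-class counts sum to the number of input pairs
  log <- readLines(file.path(out1, "run.log"))
  npairs <- as.integer(sub("read pairs: ", "", grep("^read pairs", log, value = TRUE)))
  cls <- as.integer(sub(".*: ", "", grep("^class ", log, value = TRUE)))
  expect_equal(sum(cls) - cls[length(cls)], npairs)  # ambiguous-border is a sub-count
})

test_that("a wild-type library yields an empty summary with success", {
  fix <- file.path(tempdir(), "fixwt")
  run_simulate(list(outdir = fix, seed = 94L, n_events = 0L,
                    contig_len = 30000L, params = small_params(94L)))
  out <- file.path(tempdir(), "outwt")
  run_call(list(sample = "WT",
                fastq1 = file.path(fix, "WT_R1.fastq"),
                fastq2 = file.path(fix, "WT_R2.fastq"),
                genome = file.path(fix, "genome.fasta"),
                construct = file.path(fix, "construct.yaml"),
                outdir = out))
  expect_equal(length(readLines(file.path(out, "WT.tDNA.summary"))), 1L)
})

test_that("run_call accepts pre-computed alignments and control subtraction", {
  fix <- file.path(tempdir(), "fixsam")
  run_simulate(list(outdir = fix, seed = 95L, n_events = 1L, archetypes = "ideal_R",
                    contig_len = 30000L, params = small_params(95L)))
  out <- file.path(tempdir(), "outsam")
  run_call(list(sample = "S1",
                alignments = file.path(fix, "S1.truth.sam"),
                genome = file.path(fix, "genome.fasta"),
                construct = file.path(fix, "construct.yaml"),
                outdir = out))
  smry <- read_summary(file.path(out, "S1.tDNA.summary"))
  truth <- utils::read.table(file.path(fix, "truth.tsv"), sep = "\t", header = TRUE)
  expect_true(all(c(truth$left_breakpoint, truth$right_breakpoint) %in% smry$breakpoint))
  # control subtraction via a summary file: subtracting the sample's own calls
  # empties the summary
  out2 <- file.path(tempdir(), "outsam2")
  run_call(list(sample = "S1",
                alignments = file.path(fix, "S1.truth.sam"),
                genome = file.path(fix, "genome.fasta"),
                construct = file.path(fix, "construct.yaml"),
                control_calls = file.path(out, "S1.tDNA.summary"),
                outdir = out2))
  expect_equal(length(readLines(file.path(out2, "S1.tDNA.summary"))), 1L)
})

test_that("invalid run configs fail with clear messages", {
  expect_error(run_call(list(sample = "x")), "missing field")
  expect_error(run_call(list(sample = "x", genome = "g", construct = "c",
                             outdir = tempfile())),
               "fastq1")
  expect_error(run_simulate(list(seed = 1)), "outdir")
})
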