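# End-to-end orchestration: scenario simulation (a complete self-test fixture
# with ground truth) and the align/parse -> classify -> call -> report run.

# Event archetypes used by the scenario sampler. The first four are
# single-unit insertions; the concatemer archetypes expose the insertion
# types that only arise when a truncated outer unit is reached through a
# bridge site in a deeper unit.
.ARCHETYPES <- c("ideal_F", "ideal_R", "trunc_F", "trunc_R",
                 "concat_FR", "concat_RF",
                 "lbrev_leading", "rbfwd_leading",
                 "rbrev_trailing", "lbfwd_trailing")

#' Names of the insertion-event archetypes used by the scenario sampler
#'
#' Single-unit insertions (ideal and border-truncated, both orientations),
#' head-to-head / tail-to-tail concatemers, and concatemers with a heavily
#' truncated outer unit; together their junctions realize all eight
#' insertion-type labels.
#'
#' @return character vector of archetype names.
#' @export
event_archetypes <- function() .ARCHETYPES

.make_event <- function(archetype, event_id, contig, position, construct) {
  U <- nchar(construct$tdna_seq)
  deletion <- sample(0:50, 1L)
  fl <- sample(0:20, 1L); fr <- sample(0:20, 1L)
  small <- function() sample(1:150, 1L)
  heavy <- U - 250L   # leaves a ~250 bp border fragment as the outer unit
  a <- switch(archetype,
    ideal_F = list(units = "F"),
    ideal_R = list(units = "R"),
    trunc_F = list(units = "F", lb_truncation = small(), rb_truncation = small()),
    trunc_R = list(units = "R", lb_truncation = small(), rb_truncation = small()),
    concat_FR = list(units = c("F", "R")),
    concat_RF = list(units = c("R", "F")),
    lbrev_leading = list(units = c("R", "F"), rb_truncation = heavy),
    rbfwd_leading = list(units = c("F", "F"), lb_truncation = heavy),
    rbrev_trailing = list(units = c("F", "R"), lb_truncation = heavy),
    lbfwd_trailing = list(units = c("F", "F"), rb_truncation = heavy),
    stop("unknown archetype: ", archetype))
  do.call(insertion_event, c(list(event_id = event_id, contig = contig,
                                  position = position, deletion = deletion,
                                  filler_left = fl, filler_right = fr), a))
}

#' Simulate a complete test scenario
#'
#' Builds a random genome and toy construct, samples insertion events from the
#' archetype catalogue, implants them, and simulates a sample library plus a
#' wild-type control library — everything the caller needs, with ground truth.
#'
#' @param seed scenario seed (drives genome, events and libraries).
#' @param n_contigs,contig_len,gc genome shape.
#' @param n_events number of insertions (default drawn from 1-3).
#' @param archetypes optional archetype names, one per event (recycled with
#'   random draws); see the catalogue in the package source.
#' @param params a [library_params()] for the sample library.
#' @param control_params a [library_params()] for the control (background
#'   only).
#' @param construct optional [construct_model()] (default [simulate_construct()]).
#' @param sample_name sample identifier.
#' @return list: `construct`, `genome` (original), `merged_ref`, `implant`
#'   (with `truth`), `lib` (sample library), `control_lib`.
#' @export
simulate_scenario <- function(seed = 1L, n_contigs = 2L, contig_len = 100000L,
                              gc = 0.36, n_events = NULL, archetypes = NULL,
                              params = library_params(seed = seed),
                              control_params = library_params(n_background = 40L,
                                                              seed = seed + 1000L),
                              construct = NULL, sample_name = "S1") {
  if (is.null(construct)) construct <- simulate_construct(seed = 997L)
  genome <- simulate_genome(n_contigs, contig_len, gc = gc, seed = seed)
  withr::with_seed(seed + 500L, {
    if (is.null(n_events)) n_events <- sample(1:3, 1L)
    if (n_events > 0L) {
      if (is.null(archetypes)) archetypes <- character(0)
      if (length(archetypes) < n_events)
        archetypes <- c(archetypes,
                        sample(.ARCHETYPES, n_events - length(archetypes), replace = TRUE))
      # spread events over contigs, well separated
      slots <- expand.grid(contig = paste0("chr", seq_len(n_contigs)),
                           frac = c(0.2, 0.5, 0.8), stringsAsFactors = FALSE)
      slots <- slots[sample.int(nrow(slots), n_events), , drop = FALSE]
      jit <- max(1L, min(5000L, contig_len %/% 20L))
      events <- lapply(seq_len(n_events), function(i) {
        pos <- as.integer(contig_len * slots$frac[i] + sample(-jit:jit, 1L))
        .make_event(archetypes[i], sprintf("ev%d", i), slots$contig[i], pos, construct)
      })
    } else events <- list()
  })
  implant <- implant_insertions(genome, construct, events, seed = seed + 77L,
                                detect_range = params$fragment_max - 30L)
  merged <- build_merged_reference(genome, construct)
  lib <- simulate_ttloc_library(implant$genome, construct, implant, params,
                                sample_name = sample_name)
  ctrl_implant <- list(genome = genome,
                       truth = implant$truth[0, ],
                       junctions = implant$junctions[0, ],
                       piece_map = data.table::rbindlist(lapply(names(genome), function(cn)
                         data.table::data.table(contig = cn, mod_start = 0L,
                                                mod_end = Biostrings::width(genome)[match(cn, names(genome))],
                                                src = cn, src_lo = 0L, src_dir = 1L))))
  control <- simulate_ttloc_library(genome, construct, ctrl_implant, control_params,
                                    sample_name = "WT")
  list(construct = construct, genome = genome, merged_ref = merged,
       implant = implant, lib = lib, control_lib = control,
       events = events, seed = seed)
}

#' Run the caller end-to-end and write all report files
#'
#' Executes align/parse -> classify -> junction extraction -> dedupe ->
#' cluster -> control subtraction -> multimap flagging -> full-TIS pairing,
#' then writes `<sample>.tDNA.summary`, `supported_reads.fasta`,
#' `realignment.tsv`, `flanks.fasta`, `full_tis.tsv` and `run.log` into the
#' output directory. Zero calls is still a success.
#'
#' @param config list (or YAML path) with fields: `sample`; either
#'   `fastq1`/`fastq2` or `alignments` (SAM/BAM against the merged reference);
#'   `genome` (FASTA path or sequences); `construct` (config path or
#'   [construct_model()]); optional `control_calls` (summary path or
#'   `tis_calls`); optional thresholds `min_non_overlap`, `tol`, `min_split`,
#'   `min_discordant_with_one_split`, `max_fragment`, `subtract_radius`,
#'   `pair_window`, `flank`; `outdir`.
#' @return the output directory, invisibly; the calls table is attached as
#'   attribute `calls`.
#' @export
run_call <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(min_non_overlap = 20L, tol = 5L, min_split = 2L,
                   min_discordant_with_one_split = 3L, max_fragment = 900L,
                   subtract_radius = 10L, pair_window = 100L, flank = 2000L)
  cfg <- modifyList(defaults, config)
  for (f in c("sample", "genome", "construct", "outdir"))
    if (is.null(cfg[[f]])) stop("run config missing field: ", f, call. = FALSE)
  if (is.null(cfg$alignments) && (is.null(cfg$fastq1) || is.null(cfg$fastq2)))
    stop("run config needs fastq1+fastq2 or alignments", call. = FALSE)
  construct <- if (inherits(cfg$construct, "construct_model")) cfg$construct else
    load_construct(cfg$construct)
  genome <- as_dna(cfg$genome)
  merged <- build_merged_reference(genome, construct)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  reads <- NULL
  if (!is.null(cfg$alignments)) {
    pairs <- read_alignment_file(cfg$alignments, merged_ref = merged)
    reads <- attr(pairs, "reads")
    index <- NULL
  } else {
    if (is.null(cfg$fastq1) || is.null(cfg$fastq2))
      stop("run config needs fastq1+fastq2 or alignments", call. = FALSE)
    r1 <- if (is.character(cfg$fastq1) && length(cfg$fastq1) == 1L) read_fastq(cfg$fastq1) else cfg$fastq1
    r2 <- if (is.character(cfg$fastq2) && length(cfg$fastq2) == 1L) read_fastq(cfg$fastq2) else cfg$fastq2
    reads <- c(setNames(r1, paste0(names(r1), "/1")), setNames(r2, paste0(names(r2), "/2")))
    index <- build_index(merged)
    pairs <- align_read_pairs(r1, r2, index)
  }
  control_calls <- NULL
  if (!is.null(cfg$control_calls)) {
    control_calls <- if (is.character(cfg$control_calls)) read_summary(cfg$control_calls) else cfg$control_calls
  }
  calls <- call_tis(pairs, construct, sample = cfg$sample,
                    control_calls = control_calls,
                    min_non_overlap = cfg$min_non_overlap, tol = cfg$tol,
                    min_split = cfg$min_split,
                    min_discordant_with_one_split = cfg$min_discordant_with_one_split,
                    max_fragment = cfg$max_fragment,
                    subtract_radius = cfg$subtract_radius)
  paired <- pair_full_tis(calls, window = cfg$pair_window)

  summary_path <- file.path(cfg$outdir, paste0(cfg$sample, ".tDNA.summary"))
  write_summary(calls, summary_path)
  if (is.null(index)) index <- build_index(merged)
  if (is.null(reads)) reads <- setNames(character(0), character(0))
  write_supported_reads(calls, reads, index,
                        file.path(cfg$outdir, "supported_reads.fasta"),
                        file.path(cfg$outdir, "realignment.tsv"))
  flanks <- Biostrings::DNAStringSet()
  if (nrow(calls)) for (i in seq_len(nrow(calls)))
    flanks <- c(flanks, extract_flanks(calls[i, ], genome, flank = cfg$flank))
  write_fasta(flanks, file.path(cfg$outdir, "flanks.fasta"))
  utils::write.table(paired$full, file.path(cfg$outdir, "full_tis.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  counts <- attr(calls, "class_counts")
  removed <- attr(calls, "removed")
  log <- c(sprintf("sample: %s", cfg$sample),
           sprintf("read pairs: %d", length(pairs)),
           sprintf("class %s: %d", names(counts), counts),
           sprintf("calls: %d (imprecise: %d, multi-mapped: %d)", nrow(calls),
                   sum(calls$imprecise), sum(calls$ambiguous)),
           sprintf("full TIS pairs: %d; unpaired calls: %d",
                   nrow(paired$full), nrow(paired$unpaired)),
           if (!is.null(removed) && nrow(removed))
             sprintf("control-subtracted: %s:%s (%s)", removed$chrom,
                     removed$breakpoint, removed$ref_side)
           else "control-subtracted: none")
  writeLines(log, file.path(cfg$outdir, "run.log"))
  attr(cfg$outdir, "calls") <- calls
  attr(cfg$outdir, "full_tis") <- paired$full
  invisible(cfg$outdir)
}

#' Simulate a scenario and write it out as a fixture directory
#'
#' Writes genome FASTA, modified FASTA, read FASTQs, truth SAM (against the
#' merged reference), truth TSV and the construct config — a complete
#' self-test fixture, byte-identical for a fixed seed.
#'
#' @param config list (or YAML path): `seed`, `outdir`, and any argument of
#'   [simulate_scenario()] (`n_contigs`, `contig_len`, `n_events`, ...).
#' @return the output directory, invisibly; the scenario is attached as
#'   attribute `scenario`.
#' @export
run_simulate <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$outdir)) stop("simulate config missing field: outdir", call. = FALSE)
  outdir <- config$outdir
  args <- config[setdiff(names(config), "outdir")]
  sc <- do.call(simulate_scenario, args)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sc$genome, file.path(outdir, "genome.fasta"))
  write_fasta(sc$implant$genome, file.path(outdir, "genome_modified.fasta"))
  write_fastq(sc$lib$r1, file.path(outdir, paste0(sc$lib$sample, "_R1.fastq")))
  write_fastq(sc$lib$r2, file.path(outdir, paste0(sc$lib$sample, "_R2.fastq")))
  write_fastq(sc$control_lib$r1, file.path(outdir, "WT_R1.fastq"))
  write_fastq(sc$control_lib$r2, file.path(outdir, "WT_R2.fastq"))
  write_truth_sam(sc$lib$segments, reads = list(R1 = sc$lib$r1, R2 = sc$lib$r2),
                  merged_ref = sc$merged_ref,
                  path = file.path(outdir, paste0(sc$lib$sample, ".truth.sam")))
  utils::write.table(sc$implant$truth, file.path(outdir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_construct(sc$construct, file.path(outdir, "construct.yaml"))
  attr(outdir, "scenario") <- sc
  invisible(outdir)
}
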