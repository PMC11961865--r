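# Shared fixtures and independent oracles, built in code at test time.

toy_construct <- function() simulate_construct(seed = 11L)

toy_genome <- function(len = 30000L, n = 1L, seed = 12L)
  simulate_genome(n, len, gc = 0.4, seed = seed)

# Hand-built segment row in the read-pair record format.
mk_seg <- function(contig, ref_start, len, strand = "+", read_start = 0L,
                   read_id = "r", mate = "R1", nmm = 0L, cohits = NULL) {
  data.frame(read_id = read_id, mate = mate, contig = contig,
             ref_start = as.integer(ref_start),
             ref_end = as.integer(ref_start + len), strand = strand,
             read_start = as.integer(read_start),
             read_end = as.integer(read_start + len),
             n_mismatch = as.integer(nmm), is_supplementary = FALSE,
             stringsAsFactors = FALSE, cohits = I(list(cohits)))
}

empty_seg <- function() mk_seg("x", 0, 1)[0, ]

# Minimal hand-built call row.
mk_call <- function(bp, chrom = "chr3", side = "Left", border = "LB",
                    direction = "Forward", sample = "S", split = 3L, disc = 0L) {
  cl <- data.frame(sample = sample, chrom = chrom, breakpoint = bp,
                   ref_side = side, border = border, direction = direction,
                   split_supportN = split, discort_supportN = disc,
                   imprecise = FALSE, ambiguous = FALSE, stringsAsFactors = FALSE,
                   ambiguous_sites = I(list(NULL)), read_ids = I(list(character(0))))
  class(cl) <- c("tis_calls", "data.frame")
  cl
}

mk_pair <- function(r1 = empty_seg(), r2 = empty_seg(), id = "r") {
  if (nrow(r1)) { r1$read_id <- id; r1$mate <- "R1" }
  if (nrow(r2)) { r2$read_id <- id; r2$mate <- "R2" }
  list(read_id = id, r1 = r1, r2 = r2)
}

# Build the 16 junction reads of the exhaustive geometry sweep:
# genome side x border region x orientation, each also as its whole-read
# reverse complement (read-layout/strand swap). Returns reads plus the
# geometry each was built from.
junction_sweep_reads <- function(construct, genome) {
  g <- as.character(genome[[1]])
  td <- construct$tdna_seq
  U <- nchar(td)
  g_left <- substr(g, 10001, 10070)    # genome ends at breakpoint 10070
  g_right <- substr(g, 20001, 20080)   # genome starts at breakpoint 20001
  t_lb <- substr(td, 1, 80)            # LB-proximal construct piece
  t_rb <- substr(td, U - 79, U)        # RB-proximal piece
  reads <- list(); want <- character(0)
  for (side in c("Left", "Right")) for (border in c("LB", "RB"))
    for (dir in c("Forward", "Reverse")) {
      tpiece <- if (border == "LB") t_lb else t_rb
      if (dir == "Reverse") tpiece <- tagtis:::revcomp(tpiece)
      rd <- if (side == "Left") paste0(g_left, tpiece) else paste0(tpiece, g_right)
      lab <- paste(side, border, dir, sep = "&")
      reads[[paste0(lab, "|fwd")]] <- rd
      reads[[paste0(lab, "|rc")]] <- tagtis:::revcomp(rd)
      want <- c(want, lab, lab)
    }
  list(reads = unlist(reads), expected = setNames(want, names(reads)))
}

# Classify every sweep read through the real aligner + classifier.
sweep_labels <- function(construct, genome) {
  merged <- build_merged_reference(genome, construct)
  idx <- build_index(merged)
  sw <- junction_sweep_reads(construct, genome)
  got <- vapply(names(sw$reads), function(nm) {
    segs <- align_read(sw$reads[[nm]], idx)
    segs$read_id <- nm; segs$mate <- "R1"
    p <- mk_pair(r1 = segs, id = nm)
    stopifnot(classify_read_pair(p) == "SPLIT")
    e <- junction_from_split(p, construct)
    paste(e$ref_side, e$border, e$direction, sep = "&")
  }, character(1))
  list(got = got, expected = sw$expected)
}

# Run the full caller on a simulated scenario, via the internal aligner or
# via the truth-SAM path.
run_pipeline <- function(sc, via = c("align", "sam"), control = TRUE, ...) {
  via <- match.arg(via)
  if (via == "align") {
    idx <- build_index(sc$merged_ref)
    pairs <- align_read_pairs(sc$lib$r1, sc$lib$r2, idx)
    cpairs <- align_read_pairs(sc$control_lib$r1, sc$control_lib$r2, idx)
  } else {
    sam <- tempfile(fileext = ".sam")
    write_truth_sam(sc$lib$segments, reads = list(R1 = sc$lib$r1, R2 = sc$lib$r2),
                    merged_ref = sc$merged_ref, path = sam)
    pairs <- read_alignment_file(sam, merged_ref = sc$merged_ref)
    csam <- tempfile(fileext = ".sam")
    write_truth_sam(sc$control_lib$segments,
                    reads = list(R1 = sc$control_lib$r1, R2 = sc$control_lib$r2),
                    merged_ref = sc$merged_ref, path = csam)
    cpairs <- read_alignment_file(csam, merged_ref = sc$merged_ref)
  }
  control_calls <- if (control) call_tis(cpairs, sc$construct, sample = "WT", ...) else NULL
  call_tis(pairs, sc$construct, sample = sc$lib$sample,
           control_calls = control_calls, ...)
}

# Compare calls against scenario truth. Returns per-junction recovery table.
score_scenario <- function(sc, calls, tol = 0L) {
  jx <- sc$implant$junctions
  det <- jx[jx$detectable, , drop = FALSE]
  precise <- calls[!calls$imprecise, , drop = FALSE]
  lab <- paste(precise$ref_side, precise$border, precise$direction, sep = "&")
  hit <- vapply(seq_len(nrow(det)), function(i) {
    any(precise$chrom == det$contig[i] & lab == det$label[i] &
          abs(precise$breakpoint - det$breakpoint[i]) <= tol)
  }, logical(1))
  fp <- vapply(seq_len(nrow(precise)), function(j) {
    !any(det$contig == precise$chrom[j] & det$label == lab[j] &
           abs(det$breakpoint - precise$breakpoint[j]) <= tol)
  }, logical(1))
  list(n_detectable = nrow(det), n_recovered = sum(hit),
       n_calls = nrow(precise), n_false = sum(fp),
       n_imprecise = sum(calls$imprecise))
}

# Independent per-base oracle for GSH prediction: a base is safe iff its
# distance to every feature of class c exceeds buffer_c.
gsh_oracle <- function(chrom_len, tracks, buffers, min_length) {
  safe <- rep(TRUE, chrom_len)
  for (cls in names(tracks)) {
    tr <- tracks[[cls]]; b <- buffers[[cls]]
    for (k in seq_len(nrow(tr))) {
      lo <- max(0L, tr$start[k] - b); hi <- min(chrom_len, tr$end[k] + b)
      if (hi > lo) safe[(lo + 1L):hi] <- FALSE
    }
  }
  r <- rle(safe)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_length
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

# Independent per-base oracle for the gene-context annotation precedence.
annotate_oracle <- function(p, genes) {
  # genes: data.frame(id, start, end, strand, exons = list of (start,end) 1-based)
  in_exon <- FALSE; in_gene <- FALSE
  for (k in seq_len(nrow(genes))) {
    if (p >= genes$start[k] && p <= genes$end[k]) {
      in_gene <- TRUE
      for (ex in genes$exons[[k]])
        if (p >= ex[1] && p <= ex[2]) in_exon <- TRUE
    }
  }
  if (in_exon) return("exon")
  if (in_gene) return("intron")
  dup <- Inf; ddn <- Inf
  for (k in seq_len(nrow(genes))) {
    tss <- if (genes$strand[k] == "+") genes$start[k] else genes$end[k]
    e3 <- if (genes$strand[k] == "+") genes$end[k] else genes$start[k]
    d1 <- if (genes$strand[k] == "+") tss - p else p - tss
    d2 <- if (genes$strand[k] == "+") p - e3 else e3 - p
    if (d1 >= 1) dup <- min(dup, d1)
    if (d2 >= 1) ddn <- min(ddn, d2)
  }
  if (dup <= 1000) return("promoter(<=1kb)")
  if (dup <= 2000) return("promoter(1-2kb)")
  if (dup <= 3000) return("promoter(2-3kb)")
  if (ddn <= 300) return("downstream(<=300bp)")
  "distal(>3kb)"
}

# GRanges gene model from the oracle's gene table.
genes_to_granges <- function(genes, chrom = "chr1") {
  rows <- list()
  for (k in seq_len(nrow(genes))) {
    rows[[length(rows) + 1L]] <- data.frame(
      start = genes$start[k], end = genes$end[k], strand = genes$strand[k],
      type = "gene", ID = genes$id[k])
    for (ex in genes$exons[[k]])
      rows[[length(rows) + 1L]] <- data.frame(
        start = ex[1], end = ex[2], strand = genes$strand[k],
        type = "exon", ID = NA_character_)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$type <- df$type
  gr$ID <- df$ID
  gr
}
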