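# The four reporting artifacts: summary table, supported-read FASTA +
# re-alignment TSV, 2 kb flanks, and PCR primer-window recommendations.

#' Write the TIS summary table
#'
#' Tab-separated with the fixed column order `Sample, Ref:Breakpoint, RefSide,
#' tDNA, Direction, Split_supportN, Discort_supportN`, sorted by
#' (chrom, breakpoint, label). The conventional filename is
#' `<sample>.tDNA.summary`.
#'
#' @param calls `tis_calls`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_summary <- function(calls, path) {
  if (!nrow(calls)) {
    writeLines(paste(c("Sample", "Ref:Breakpoint", "RefSide", "tDNA", "Direction",
                       "Split_supportN", "Discort_supportN"), collapse = "\t"), path)
    return(invisible(path))
  }
  df <- data.frame(
    Sample = calls$sample,
    `Ref:Breakpoint` = paste0(calls$chrom, ":", format(calls$breakpoint, scientific = FALSE, trim = TRUE)),
    RefSide = calls$ref_side,
    tDNA = calls$border,
    Direction = calls$direction,
    Split_supportN = calls$split_supportN,
    Discort_supportN = calls$discort_supportN,
    check.names = FALSE, stringsAsFactors = FALSE)
  df <- df[order(calls$chrom, calls$breakpoint,
                 paste(calls$ref_side, calls$border, calls$direction)), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a summary table back into a calls-like data.frame
#' @param path summary file written by [write_summary()].
#' @return data.frame with the scalar call fields.
#' @export
read_summary <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  if (!nrow(df)) return(.empty_calls())
  loc <- strsplit(df[["Ref:Breakpoint"]], ":", fixed = TRUE)
  out <- data.frame(
    sample = df$Sample,
    chrom = vapply(loc, `[`, character(1), 1L),
    breakpoint = as.numeric(vapply(loc, `[`, character(1), 2L)),
    ref_side = df$RefSide, border = df$tDNA, direction = df$Direction,
    split_supportN = as.integer(df$Split_supportN),
    discort_supportN = as.integer(df$Discort_supportN),
    stringsAsFactors = FALSE)
  out
}

#' Write supported reads as FASTA plus a re-alignment report
#'
#' FASTA headers are `readID|sample|chrom:pos|label|kind`. The companion TSV
#' re-aligns every supported read against the merged reference with the
#' built-in aligner and reports one row per aligned segment (blast-tabular
#' style), for manual checking of each call.
#'
#' @param calls `tis_calls`.
#' @param reads named character vector resolving supporting read ids (mate
#'   sequences may be given as `id` or `id/1`, `id/2`).
#' @param index [build_index()] over the merged reference.
#' @param fasta_path,tsv_path output paths.
#' @return invisible list of the two paths.
#' @export
write_supported_reads <- function(calls, reads, index, fasta_path, tsv_path) {
  fa <- character(0); rows <- list()
  if (nrow(calls)) for (i in seq_len(nrow(calls))) {
    label <- paste(calls$ref_side[i], calls$border[i], calls$direction[i], sep = "&")
    for (id in sort(unlist(calls$read_ids[i]))) {
      mates <- reads[names(reads) %in% c(id, paste0(id, "/1"), paste0(id, "/2"))]
      if (!length(mates)) { warning("supporting read not found: ", id); next }
      for (k in seq_along(mates)) {
        hdr <- paste(names(mates)[k], calls$sample[i],
                     paste0(calls$chrom[i], ":", calls$breakpoint[i]), label,
                     if (calls$split_supportN[i] > 0L) "split" else "discordant",
                     sep = "|")
        fa <- c(fa, paste0(">", hdr), mates[[k]])
        seg <- align_read(mates[[k]], index)
        if (nrow(seg)) rows[[length(rows) + 1L]] <- data.frame(
          read = names(mates)[k], contig = seg$contig,
          ref_start = seg$ref_start + 1L, ref_end = seg$ref_end,
          strand = seg$strand, mismatches = seg$n_mismatch,
          read_start = seg$read_start + 1L, read_end = seg$read_end,
          stringsAsFactors = FALSE)
      }
    }
  }
  writeLines(fa, fasta_path)
  tsv <- if (length(rows)) do.call(rbind, rows) else data.frame(
    read = character(0), contig = character(0), ref_start = integer(0),
    ref_end = integer(0), strand = character(0), mismatches = integer(0),
    read_start = integer(0), read_end = integer(0))
  utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta_path, tsv = tsv_path))
}

#' Extract 2 kb flanking sequences around a breakpoint
#'
#' The upstream record covers the `flank` bases before the breakpoint
#' (1-based positions `breakpoint-flank .. breakpoint-1`), the downstream
#' record the `flank` bases from the breakpoint on. Records clipped at a
#' contig end carry a `(truncated)` header suffix.
#'
#' @param call one-row `tis_calls` (or list with `chrom`, `breakpoint`).
#' @param genome genome sequences.
#' @param flank flank length (bp, positive).
#' @return `DNAStringSet` of 2 records.
#' @export
extract_flanks <- function(call, genome, flank = 2000L) {
  if (flank <= 0L) stop("flank must be positive", call. = FALSE)
  genome <- as_dna(genome)
  chrom <- as.character(call$chrom); bp <- as.integer(call$breakpoint)
  if (!chrom %in% names(genome)) stop("contig not in genome: ", chrom, call. = FALSE)
  L <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (bp < 1L || bp > L) stop("breakpoint outside contig", call. = FALSE)
  up0 <- max(1L, bp - flank); up1 <- bp - 1L
  dn0 <- bp; dn1 <- min(L, bp + flank - 1L)
  s <- as.character(genome[[chrom]])
  up <- if (up1 >= up0) substr(s, up0, up1) else ""
  dn <- substr(s, dn0, dn1)
  nm_up <- sprintf("%s:%d-%d|upstream%s", chrom, up0, up1,
                   if (up0 > bp - flank || up1 < up0) " (truncated)" else "")
  nm_dn <- sprintf("%s:%d-%d|downstream%s", chrom, dn0, dn1,
                   if (dn1 < bp + flank - 1L) " (truncated)" else "")
  Biostrings::DNAStringSet(setNames(c(up, dn), c(nm_up, nm_dn)))
}

#' Recommend PCR validation primer windows
#'
#' For each call, one site-specific genomic primer window paired with the
#' common LB/RB primer: Left calls get a sense primer in
#' `[breakpoint-700, breakpoint-300]`, Right calls an antisense primer in
#' `[breakpoint+300, breakpoint+700]` (1-based), so the expected product size
#' falls in the 350-700 bp range used for Sanger validation. Windows running
#' off a contig end are shrunk with a warning.
#'
#' @param call one-row `tis_calls`.
#' @param contig_length length of the call's contig (bp).
#' @return one-row data.frame: `chrom, window_start, window_end,
#'   genome_primer_sense, common_primer`.
#' @export
recommend_primers <- function(call, contig_length) {
  bp <- as.integer(call$breakpoint)
  if (call$ref_side == "Left") {
    w <- c(bp - 700L, bp - 300L); sense <- "sense"
  } else {
    w <- c(bp + 300L, bp + 700L); sense <- "antisense"
  }
  w0 <- pmax(1L, pmin(w, contig_length))
  if (!identical(w0, w)) warning("primer window shrunk at contig end")
  data.frame(chrom = call$chrom, window_start = w0[1], window_end = w0[2],
             genome_primer_sense = sense,
             common_primer = paste0(call$border, "-common"),
             stringsAsFactors = FALSE)
}
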