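# SAM interop: the simulator writes oracle alignments as plain SAM; external
# alignments (e.g. bwa-mem + samblaster output) are read back through
# Rsamtools/GenomicAlignments. Read-offset convention: read_start/read_end are
# 0-based half-open offsets on the ORIGINAL read; for minus-strand records the
# stored SEQ is the reverse complement, so soft-clip lengths are flipped.

#' Write truth alignments as SAM
#'
#' One record per alignment segment (primary + supplementary), against the
#' merged reference. Unaligned leftovers of a read appear as soft clips.
#'
#' @param segments segment table as produced by the simulator: columns
#'   `read_id, mate, contig, ref_start, ref_end, strand, read_start, read_end,
#'   read_len, n_mismatch, is_supplementary`.
#' @param reads list with named character vectors `R1` and `R2`.
#' @param merged_ref the merged reference (`DNAStringSet`), for `@SQ` lines.
#' @param path output SAM path.
#' @export
write_truth_sam <- function(segments, reads, merged_ref, path) {
  merged_ref <- as_dna(merged_ref)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(merged_ref), Biostrings::width(merged_ref)))
  lines <- character(0)
  if (nrow(segments)) {
    seg <- segments
    # primary record of the mate's partner, for RNEXT/PNEXT
    prim <- seg[!seg$is_supplementary, ]
    key <- paste(prim$read_id, prim$mate)
    prim_contig <- setNames(prim$contig, key)
    prim_pos <- setNames(prim$ref_start + 1L, key)
    prim_strand <- setNames(prim$strand, key)
    recs <- character(nrow(seg))
    for (i in seq_len(nrow(seg))) {
      s <- seg[i, ]
      sq <- if (s$mate == "R1") reads$R1[[s$read_id]] else reads$R2[[s$read_id]]
      L <- nchar(sq)
      flag <- 1L + if (s$mate == "R1") 64L else 128L
      if (s$strand == "-") flag <- flag + 16L
      mkey <- paste(s$read_id, if (s$mate == "R1") "R2" else "R1")
      has_mate <- mkey %in% key
      if (has_mate && prim_strand[[mkey]] == "-") flag <- flag + 32L
      if (s$is_supplementary) flag <- flag + 2048L
      mlen <- s$read_end - s$read_start
      if (s$strand == "+") { cl <- s$read_start; cr <- L - s$read_end }
      else { cl <- L - s$read_end; cr <- s$read_start }
      cigar <- paste0(if (cl > 0L) paste0(cl, "S") else "", mlen, "M",
                      if (cr > 0L) paste0(cr, "S") else "")
      oseq <- if (s$strand == "-") revcomp(sq) else sq
      rnext <- if (!has_mate) "*" else if (prim_contig[[mkey]] == s$contig) "=" else prim_contig[[mkey]]
      pnext <- if (!has_mate) 0L else prim_pos[[mkey]]
      recs[i] <- paste(s$read_id, flag, s$contig, s$ref_start + 1L, 60L, cigar,
                       rnext, pnext, 0L, oseq, strrep("I", L),
                       paste0("NM:i:", s$n_mismatch), sep = "\t")
    }
    lines <- recs
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read alignments from SAM/BAM into read-pair records
#'
#' Reconstructs per-segment alignments from primary + supplementary records
#' (secondary alignments and unmapped records are ignored). Soft/hard clips
#' define read offsets; offsets are flipped to original-read coordinates for
#' minus-strand records. Records on contigs absent from the supplied reference
#' are skipped with a counted warning, as are reads with only one mate present.
#'
#' @param path SAM or BAM file. A `.sam` file is converted with
#'   [Rsamtools::asBam()] first.
#' @param merged_ref optional reference (`DNAStringSet`) used to validate
#'   contig names.
#' @return a list of read-pair records, each
#'   `list(read_id, r1 = <segment data.frame>, r2 = ...)`; attribute
#'   `skipped` counts ignored records.
#' @export
read_alignment_file <- function(path, merged_ref = NULL) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, dest, overwrite = TRUE,
                                             indexDestination = FALSE))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = "NM")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  skipped <- c(unmapped = 0L, secondary = 0L, bad_contig = 0L, unpaired = 0L)
  if (n == 0L)
    return(structure(list(), skipped = skipped))
  flag <- x$flag
  keep <- bitwAnd(flag, 4L) == 0L
  skipped["unmapped"] <- sum(!keep)
  sec <- bitwAnd(flag, 256L) != 0L
  skipped["secondary"] <- sum(sec & keep)
  keep <- keep & !sec
  contig <- as.character(x$rname)
  if (!is.null(merged_ref)) {
    ok <- contig %in% names(as_dna(merged_ref))
    nbad <- sum(keep & !ok)
    if (nbad) warning(nbad, " record(s) on contigs absent from the reference, skipped")
    skipped["bad_contig"] <- nbad
    keep <- keep & ok
  }
  idx <- which(keep)
  if (!length(idx)) return(structure(list(), skipped = skipped))
  cig <- x$cigar[idx]
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  qwidth <- mapply(function(o, l) sum(l[o %in% c("M", "I", "=", "X", "S", "H")]), ops, lens)
  clip_l <- mapply(function(o, l) { k <- which(!o %in% c("S", "H")); if (!length(k)) 0L else sum(l[seq_len(k[1] - 1L)]) }, ops, lens)
  qaln <- mapply(function(o, l) sum(l[o %in% c("M", "I", "=", "X")]), ops, lens)
  rwidth <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  minus <- bitwAnd(x$flag[idx], 16L) != 0L
  read_start <- ifelse(minus, qwidth - (clip_l + qaln), clip_l)
  read_end <- ifelse(minus, qwidth - clip_l, clip_l + qaln)
  nm <- x$tag$NM[idx]
  nm[vapply(nm, is.null, logical(1))] <- NA_integer_
  nm <- as.integer(unlist(lapply(nm, function(v) if (length(v)) v[1] else NA_integer_)))
  seg <- data.frame(
    read_id = x$qname[idx],
    mate = ifelse(bitwAnd(x$flag[idx], 64L) != 0L, "R1", "R2"),
    contig = contig[idx],
    ref_start = x$pos[idx] - 1L,
    ref_end = x$pos[idx] - 1L + rwidth,
    strand = ifelse(minus, "-", "+"),
    read_start = as.integer(read_start),
    read_end = as.integer(read_end),
    n_mismatch = ifelse(is.na(nm), 0L, nm),
    is_supplementary = bitwAnd(x$flag[idx], 2048L) != 0L,
    stringsAsFactors = FALSE)
  seg$cohits <- rep(list(NULL), nrow(seg))
  pairs <- .pair_segments(seg)
  one_mated <- vapply(pairs, function(p) nrow(p$r1) == 0L || nrow(p$r2) == 0L, logical(1))
  skipped["unpaired"] <- sum(one_mated)
  # recover original-orientation read sequences from primary records
  pi <- which(!seg$is_supplementary)
  sq <- as.character(x$seq[idx][pi])
  flip <- seg$strand[pi] == "-"
  sq[flip] <- revcomp(sq[flip])
  reads <- setNames(sq, paste0(seg$read_id[pi], ifelse(seg$mate[pi] == "R1", "/1", "/2")))
  structure(pairs[!one_mated], skipped = skipped, reads = reads[!duplicated(names(reads))])
}

# Group a segment table into read-pair records.
.pair_segments <- function(seg) {
  empty <- seg[0, , drop = FALSE]
  sp <- split(seq_len(nrow(seg)), seg$read_id)
  lapply(names(sp), function(id) {
    s <- seg[sp[[id]], , drop = FALSE]
    list(read_id = id,
         r1 = if (any(s$mate == "R1")) s[s$mate == "R1", , drop = FALSE] else empty,
         r2 = if (any(s$mate == "R2")) s[s$mate == "R2", , drop = FALSE] else empty)
  })
}
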