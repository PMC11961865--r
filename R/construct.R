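#' @import data.table
#' @importFrom utils head tail modifyList
#' @importFrom stats runif setNames
#' @importFrom methods is
NULL

# Internal coordinates are 0-based half-open everywhere; user-facing
# breakpoints are reported 1-based ("chr4B:408235032" style).

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a plain character sequence
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Describe a T-DNA construct
#'
#' A construct model holds the T-DNA sequence between (and including) the left
#' and right border repeats, written 5'->3' as the upper/forward strand with the
#' LB repeat at low coordinates, plus the two bridge-primer sites used for
#' library enrichment. Each bridge site is the template position at which read 2
#' of an amplicon starts, and it reads toward its border repeat: the LB bridge
#' reads toward decreasing coordinates, the RB bridge toward increasing
#' coordinates. By convention the border repeats themselves are part of the
#' sequence, so junction reads can align across a repeat.
#'
#' @param name construct name.
#' @param tdna_seq character scalar, the LB-to-RB forward-strand sequence.
#' @param lb_repeat,rb_repeat integer length-2 vectors, 0-based half-open
#'   intervals of the border repeats on `tdna_seq`.
#' @param lb_bridge,rb_bridge integer scalar bridge-site positions (0-based) or
#'   character primer sequences to be located by exact match (see
#'   [load_construct()]).
#' @return an object of class `construct_model`.
#' @export
construct_model <- function(name, tdna_seq, lb_repeat, rb_repeat,
                            lb_bridge, rb_bridge) {
  tdna_seq <- toupper(as.character(tdna_seq))
  L <- nchar(tdna_seq)
  lb_repeat <- as.integer(lb_repeat)
  rb_repeat <- as.integer(rb_repeat)
  chk <- function(iv, what) {
    if (length(iv) != 2L || iv[1] < 0L || iv[2] <= iv[1] || iv[2] > L)
      stop(sprintf("invalid interval for %s", what), call. = FALSE)
  }
  chk(lb_repeat, "lb_repeat"); chk(rb_repeat, "rb_repeat")
  if (is.character(lb_bridge)) lb_bridge <- .locate_bridge(tdna_seq, lb_bridge, "LB")
  if (is.character(rb_bridge)) rb_bridge <- .locate_bridge(tdna_seq, rb_bridge, "RB")
  lb_bridge <- as.integer(lb_bridge); rb_bridge <- as.integer(rb_bridge)
  if (rb_repeat[1] < lb_repeat[2]) {
    # plasmid map drawn the other way round: normalize so LB comes first.
    # Features keep their identity; only coordinates flip with the strand.
    tdna_seq <- revcomp(tdna_seq)
    flip <- function(iv) c(L - iv[2], L - iv[1])
    lb_repeat <- flip(lb_repeat); rb_repeat <- flip(rb_repeat)
    lb_bridge <- L - 1L - lb_bridge; rb_bridge <- L - 1L - rb_bridge
  }
  if (rb_repeat[1] < lb_repeat[2])
    stop("lb_repeat and rb_repeat overlap", call. = FALSE)
  if (lb_bridge < lb_repeat[2] || lb_bridge >= rb_repeat[1])
    stop("lb_bridge site must lie between the border repeats, interior of the LB repeat",
         call. = FALSE)
  if (rb_bridge <= lb_bridge || rb_bridge >= rb_repeat[1])
    stop("rb_bridge site must lie between the bridge sites' ordering and interior of the RB repeat",
         call. = FALSE)
  structure(list(name = as.character(name), tdna_seq = tdna_seq,
                 lb_repeat = lb_repeat, rb_repeat = rb_repeat,
                 lb_bridge = lb_bridge, rb_bridge = rb_bridge),
            class = "construct_model")
}

# Locate a bridge primer by exact substring match. The LB primer reads toward
# the LB repeat, i.e. it anneals to the forward strand and its sequence is the
# reverse complement of the template; the RB primer matches the template as-is.
.locate_bridge <- function(tdna_seq, primer, border) {
  primer <- toupper(primer)
  query <- if (border == "LB") revcomp(primer) else primer
  hits <- gregexpr(query, tdna_seq, fixed = TRUE)[[1]]
  if (identical(as.integer(hits), -1L))
    stop(sprintf("%s bridge primer sequence not found in construct", border), call. = FALSE)
  if (length(hits) > 1L)
    stop(sprintf("ambiguous bridge site: %s bridge primer found %d times", border, length(hits)),
         call. = FALSE)
  start0 <- as.integer(hits) - 1L
  if (border == "LB") start0 + nchar(primer) - 1L else start0  # 5'-most template base of R2
}

#' @export
print.construct_model <- function(x, ...) {
  cat(sprintf("T-DNA construct '%s': %d bp\n", x$name, nchar(x$tdna_seq)))
  cat(sprintf("  LB repeat [%d,%d)  bridge site %d (reads -)\n",
              x$lb_repeat[1], x$lb_repeat[2], x$lb_bridge))
  cat(sprintf("  RB repeat [%d,%d)  bridge site %d (reads +)\n",
              x$rb_repeat[1], x$rb_repeat[2], x$rb_bridge))
  invisible(x)
}

#' Load a construct description from a config file
#'
#' The config is a YAML mapping with fields `name`, `sequence` (or
#' `sequence_file` pointing at a single-record FASTA), `lb_repeat`, `rb_repeat`
#' (0-based half-open `[start, end]` pairs) and `lb_bridge` / `rb_bridge`
#' (either a 0-based position or a primer sequence located by exact match;
#' a primer occurring more than once is rejected).
#'
#' @param config path to a YAML file, or an already-parsed list.
#' @return a [construct_model()].
#' @export
load_construct <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  need <- c("name", "lb_repeat", "rb_repeat", "lb_bridge", "rb_bridge")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("construct config missing field(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  seq <- if (!is.null(cfg$sequence)) cfg$sequence else {
    if (is.null(cfg$sequence_file))
      stop("construct config needs 'sequence' or 'sequence_file'", call. = FALSE)
    ss <- Biostrings::readDNAStringSet(cfg$sequence_file)
    if (length(ss) != 1L) stop("sequence_file must contain exactly one record", call. = FALSE)
    as.character(ss[[1]])
  }
  bridge <- function(x) if (is.character(x)) x else as.integer(x)
  construct_model(cfg$name, seq, unlist(cfg$lb_repeat), unlist(cfg$rb_repeat),
                  bridge(cfg$lb_bridge), bridge(cfg$rb_bridge))
}

#' Write a construct description to YAML
#' @param construct a [construct_model()].
#' @param path output file.
#' @export
write_construct <- function(construct, path) {
  yaml::write_yaml(list(
    name = construct$name, sequence = construct$tdna_seq,
    lb_repeat = as.integer(construct$lb_repeat),
    rb_repeat = as.integer(construct$rb_repeat),
    lb_bridge = as.integer(construct$lb_bridge),
    rb_bridge = as.integer(construct$rb_bridge)), path)
  invisible(path)
}

#' Build the merged alignment reference (genome + "tDNA" contig)
#'
#' All alignment and calling operations work against the plant genome with the
#' construct appended as one extra contig titled `"tDNA"`. The name is
#' reserved: a genome already containing it is rejected.
#'
#' @param genome a `DNAStringSet`, a named character vector, or a FASTA path.
#' @param construct a [construct_model()].
#' @return a named `DNAStringSet` with the `tDNA` contig last.
#' @export
build_merged_reference <- function(genome, construct) {
  genome <- as_dna(genome)
  if (length(genome) == 0L) stop("no contigs in genome", call. = FALSE)
  if (anyDuplicated(names(genome))) stop("genome contig names must be unique", call. = FALSE)
  if ("tDNA" %in% names(genome))
    stop("genome already contains a contig named 'tDNA' (reserved)", call. = FALSE)
  out <- c(genome, Biostrings::DNAStringSet(setNames(construct$tdna_seq, "tDNA")))
  out
}

#' Coerce sequences to a DNAStringSet
#' @param x `DNAStringSet`, named character vector, or FASTA path.
#' @return `DNAStringSet`
#' @keywords internal
as_dna <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && is.null(names(x)) && file.exists(x))
    return(Biostrings::readDNAStringSet(x))
  if (is.character(x)) {
    if (is.null(names(x))) stop("character sequences must be named", call. = FALSE)
    return(Biostrings::DNAStringSet(x))
  }
  stop("cannot interpret sequences of class ", class(x)[1], call. = FALSE)
}

#' Write sequences as wrapped FASTA
#' @param seqs `DNAStringSet` or named character vector.
#' @param path output path.
#' @param width line wrap (default 60, the conventional width).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  Biostrings::writeXStringSet(as_dna(seqs), path, width = width)
  invisible(path)
}
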