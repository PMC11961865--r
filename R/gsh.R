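# Genomic safe harbor prediction: the complement of buffered annotation
# intervals, per the published distance criteria (10 kb from centromeres and
# genes, 20 kb from lncRNAs and tRNAs, 30 kb from miRNAs).

#' GSH prediction parameters
#'
#' Buffers are exclusive edge distances in bp: a base is a candidate iff its
#' distance to the nearest feature of every class exceeds that class's buffer.
#' `min_length` drops complement slivers below a reportable size (the source
#' criteria state no minimum; 1 kb is this package's default, config-exposed).
#'
#' @param gene,lncRNA,miRNA,tRNA,centromere per-class buffers (bp).
#' @param min_length minimum reported interval length (bp).
#' @param ... buffers for additional track classes.
#' @return list of class `gsh_params`.
#' @export
gsh_params <- function(gene = 10000L, lncRNA = 20000L, miRNA = 30000L,
                       tRNA = 20000L, centromere = 10000L,
                       min_length = 1000L, ...) {
  buffers <- c(list(gene = gene, lncRNA = lncRNA, miRNA = miRNA,
                    tRNA = tRNA, centromere = centromere), list(...))
  if (any(unlist(buffers) < 0L)) stop("buffers must be >= 0", call. = FALSE)
  structure(list(buffers = lapply(buffers, as.integer),
                 min_length = as.integer(min_length)), class = "gsh_params")
}

# Coerce one track to a data.frame(chrom, start, end) in 0-based half-open
# coordinates. BED files import as 1-based GRanges via rtracklayer.
.as_track <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- rtracklayer::import(x, format = "BED")
  if (methods::is(x, "GRanges"))
    return(data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                      start = GenomicRanges::start(x) - 1L,
                      end = GenomicRanges::end(x), stringsAsFactors = FALSE))
  if (is.data.frame(x)) {
    names(x)[1:3] <- c("chrom", "start", "end")
    return(x[, c("chrom", "start", "end")])
  }
  stop("cannot interpret track of class ", class(x)[1], call. = FALSE)
}

#' Predict genomic safe harbors
#'
#' Every track interval is expanded by its class buffer on both sides
#' (clamped at chromosome ends); the union of all expanded intervals is
#' subtracted from each chromosome; complement intervals of at least
#' `min_length` bp are reported.
#'
#' @param chrom_sizes named integer vector of chromosome lengths, or a
#'   two-column file (`chrom<TAB>length`).
#' @param tracks named list of tracks (BED path, `GRanges`, or
#'   `data.frame(chrom, start, end)`, 0-based half-open); names must match
#'   buffer classes in `params`.
#' @param params a [gsh_params()].
#' @return data.frame `chrom, start, end, length` (0-based half-open), sorted;
#'   attributes `count` and `total_bp` summarize it.
#' @export
predict_gsh <- function(chrom_sizes, tracks, params = gsh_params()) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L && file.exists(chrom_sizes)) {
    cs <- utils::read.table(chrom_sizes, sep = "\t", header = FALSE,
                            col.names = c("chrom", "len"), stringsAsFactors = FALSE)
    chrom_sizes <- setNames(cs$len, cs$chrom)
  }
  buf_list <- list()
  for (cls in names(tracks)) {
    b <- params$buffers[[cls]]
    if (is.null(b)) stop("no buffer defined for track class: ", cls, call. = FALSE)
    tr <- .as_track(tracks[[cls]])
    bad <- setdiff(unique(tr$chrom), names(chrom_sizes))
    if (length(bad))
      stop("track '", cls, "' names unknown chromosome: ", bad[1], call. = FALSE)
    if (any(tr$start < 0L) || any(tr$end > chrom_sizes[tr$chrom]))
      stop("track '", cls, "' has intervals outside chromosome bounds", call. = FALSE)
    tr$start <- pmax(0L, tr$start - b)
    tr$end <- pmin(unname(chrom_sizes[tr$chrom]), tr$end + b)
    buf_list[[cls]] <- tr
  }
  excl <- if (length(buf_list)) do.call(rbind, buf_list) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  out <- lapply(sort(names(chrom_sizes)), function(cn) {
    full <- IRanges::IRanges(start = 1L, end = chrom_sizes[[cn]])
    e <- excl[excl$chrom == cn, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = e$start + 1L, end = e$end))
    gsh <- IRanges::setdiff(full, ir)
    gsh <- gsh[IRanges::width(gsh) >= params$min_length]
    if (!length(gsh)) return(NULL)
    data.frame(chrom = cn, start = IRanges::start(gsh) - 1L,
               end = IRanges::end(gsh), length = IRanges::width(gsh),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(chrom = character(0), start = integer(0),
                                      end = integer(0), length = integer(0))
  rownames(out) <- NULL
  attr(out, "count") <- nrow(out)
  attr(out, "total_bp") <- sum(out$length)
  out
}

#' Write GSH intervals as BED plus a summary TSV
#' @param gsh result of [predict_gsh()].
#' @param bed_path,summary_path output files.
#' @export
write_gsh <- function(gsh, bed_path, summary_path) {
  utils::write.table(gsh[, c("chrom", "start", "end")], bed_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(n_gsh = attr(gsh, "count"),
                                total_bp = attr(gsh, "total_bp")),
                     summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(bed_path)
}
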