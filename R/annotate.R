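# Gene-context annotation of integration sites against GFF3 gene models.

#' Annotate TIS positions against gene models
#'
#' Each site gets exactly one category under the precedence
#' exon > intron > promoter bins > downstream <= 300 bp > distal:
#' `exon` when inside an annotated exon; `intron` when inside a gene body but
#' no exon; promoter bins `promoter(<=1kb)`, `promoter(1-2kb)`,
#' `promoter(2-3kb)` by distance upstream of the nearest transcription start
#' site on the gene's strand; `downstream(<=300bp)` within 300 bp past a gene
#' 3' end; otherwise `distal(>3kb)`. A position 301 bp - 3 kb downstream of
#' one gene but within a promoter bin of another is therefore assigned to the
#' promoter bin; residual cases are distal. The nearest gene is the one whose
#' TSS is closest (ties -> smaller gene id); for exon/intron it is the
#' containing gene and the reported distance is 0.
#'
#' @param calls `tis_calls` (or data.frame with `chrom`, `breakpoint`).
#' @param genes GFF3 path or `GRanges` with `type` (`gene`, `exon`) and gene
#'   identifiers (`ID` for genes, `Parent` or `gene_id` for exons).
#' @return data.frame: `chrom, breakpoint, category, nearest_gene, distance`.
#' @export
annotate_tis <- function(calls, genes) {
  gr <- if (is.character(genes)) rtracklayer::import(genes) else genes
  g <- gr[gr$type == "gene"]
  ex <- gr[gr$type == "exon"]
  gene_id <- if (!is.null(g$ID)) as.character(g$ID) else as.character(seq_along(g))
  gstrand <- as.character(GenomicRanges::strand(g))
  if (any(gstrand == "*")) {
    warning(sum(gstrand == "*"), " strandless gene(s) treated as +")
    gstrand[gstrand == "*"] <- "+"
  }
  gchr <- as.character(GenomicRanges::seqnames(g))
  gs <- GenomicRanges::start(g); ge <- GenomicRanges::end(g)
  tss <- ifelse(gstrand == "+", gs, ge)
  end3 <- ifelse(gstrand == "+", ge, gs)
  exchr <- as.character(GenomicRanges::seqnames(ex))
  exs <- GenomicRanges::start(ex); exe <- GenomicRanges::end(ex)
  out <- lapply(seq_len(nrow(calls)), function(i) {
    chrom <- calls$chrom[i]; p <- as.integer(calls$breakpoint[i])
    in_gene <- which(gchr == chrom & gs <= p & ge >= p)
    in_exon <- any(exchr == chrom & exs <= p & exe >= p)
    # upstream-of-TSS distances on each gene's strand (>= 1 when upstream)
    same <- which(gchr == chrom)
    dup <- ifelse(gstrand[same] == "+", tss[same] - p, p - tss[same])
    dup[dup < 1L] <- NA
    ddn <- ifelse(gstrand[same] == "+", p - end3[same], end3[same] - p)
    ddn[ddn < 1L] <- NA
    if (length(in_gene)) {
      gidx <- in_gene[order(gene_id[in_gene])][1]
      cat <- if (in_exon) "exon" else "intron"
      return(data.frame(chrom = chrom, breakpoint = p, category = cat,
                        nearest_gene = gene_id[gidx], distance = 0L,
                        stringsAsFactors = FALSE))
    }
    dmin <- suppressWarnings(min(dup, na.rm = TRUE))
    if (is.finite(dmin) && dmin <= 3000L) {
      cat <- if (dmin <= 1000L) "promoter(<=1kb)" else
        if (dmin <= 2000L) "promoter(1-2kb)" else "promoter(2-3kb)"
      k <- which(dup == dmin); k <- k[order(gene_id[same][k])][1]
      return(data.frame(chrom = chrom, breakpoint = p, category = cat,
                        nearest_gene = gene_id[same][k], distance = dmin,
                        stringsAsFactors = FALSE))
    }
    dmin_dn <- suppressWarnings(min(ddn, na.rm = TRUE))
    if (is.finite(dmin_dn) && dmin_dn <= 300L) {
      k <- which(ddn == dmin_dn); k <- k[order(gene_id[same][k])][1]
      return(data.frame(chrom = chrom, breakpoint = p, category = "downstream(<=300bp)",
                        nearest_gene = gene_id[same][k], distance = dmin_dn,
                        stringsAsFactors = FALSE))
    }
    near <- if (length(same)) {
      dall <- abs(tss[same] - p)
      k <- which(dall == min(dall)); k <- k[order(gene_id[same][k])][1]
      gene_id[same][k]
    } else NA_character_
    dist <- if (length(same)) min(abs(tss[same] - p)) else NA_integer_
    data.frame(chrom = chrom, breakpoint = p, category = "distal(>3kb)",
               nearest_gene = near, distance = dist, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' The annotation category vocabulary
#' @return character vector of the seven categories in precedence order.
#' @export
annotation_categories <- function() {
  c("exon", "intron", "promoter(<=1kb)", "promoter(1-2kb)", "promoter(2-3kb)",
    "downstream(<=300bp)", "distal(>3kb)")
}
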