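# A small seed-and-extend aligner adequate for simulated or small references.
# Ungapped extension only (mismatches allowed, no indels); chimeric reads get
# at most two segments, mirroring the split-read extraction cap of the
# published pipeline. Real datasets are expected to come through the SAM path
# (bwa-mem); this aligner exists so the package is testable end-to-end.

.BASE_MAP <- local({
  m <- rep(NA_integer_, 128L)
  m[utf8ToInt("A")] <- 0L; m[utf8ToInt("C")] <- 1L
  m[utf8ToInt("G")] <- 2L; m[utf8ToInt("T")] <- 3L
  m
})

# 2-bit rolling k-mer encoding (exact in doubles for k <= 25); windows
# containing non-ACGT are NA.
.encode_kmers <- function(base_codes, k) {
  n <- length(base_codes) - k + 1L
  if (n <= 0L) return(numeric(0))
  kc <- numeric(n); bad <- logical(n)
  for (j in 0:(k - 1L)) {
    seg <- base_codes[(1L + j):(n + j)]
    nas <- is.na(seg)
    if (any(nas)) { bad <- bad | nas; seg[nas] <- 0L }
    kc <- kc + seg * 4^(k - 1L - j)
  }
  kc[bad] <- NA_real_
  kc
}

#' Build a k-mer seed index over a reference
#'
#' Exact k-mer -> position lookup over the forward strand (reads are queried
#' in both orientations). A secondary 13-mer table is kept for the
#' second-segment pass so that remainders as short as 20 bp are alignable.
#'
#' @param ref merged reference (`DNAStringSet`, named character, FASTA path).
#' @param k seed length; odd, between 11 and 25.
#' @return an object of class `seed_index`.
#' @export
build_index <- function(ref, k = 21L) {
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 11L || k > 25L)
    stop("k must be odd and within [11, 25]", call. = FALSE)
  ref <- as_dna(ref)
  seqs <- setNames(as.character(ref), names(ref))
  short <- nchar(seqs) < k
  if (any(short))
    warning("skipping contig(s) shorter than k: ",
            paste(names(seqs)[short], collapse = ", "))
  codes <- lapply(seqs, utf8ToInt)
  bases <- lapply(codes, function(u) .BASE_MAP[u])
  tab_for <- function(kk) {
    code <- numeric(0); contig <- integer(0); pos <- integer(0)
    for (ci in seq_along(seqs)) {
      if (nchar(seqs[[ci]]) < kk) next
      kc <- .encode_kmers(bases[[ci]], kk)
      keep <- which(!is.na(kc))
      code <- c(code, kc[keep])
      contig <- c(contig, rep.int(ci, length(keep)))
      pos <- c(pos, keep - 1L)
    }
    o <- order(code, contig, pos)
    list(key = code[o], contig = contig[o], pos = pos[o])
  }
  structure(list(k = k, k2 = 13L, seqs = seqs, lens = nchar(seqs),
                 contig_names = names(seqs), codes = codes, bases = bases,
                 tab = tab_for(k), tab2 = tab_for(13L)),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("seed_index: %d contig(s), %d bp, k = %d (%d seed positions)\n",
              length(x$seqs), sum(x$lens), x$k, length(x$tab$key)))
  invisible(x)
}

# All table hits for a vector of query k-mer codes (NA -> no hit).
# Returns parallel vectors qidx (into q) and tidx (into the table).
.seed_hits <- function(tab, q) {
  q[is.na(q)] <- -1
  lo <- findInterval(q - 0.5, tab$key) + 1L
  hi <- findInterval(q, tab$key)
  n <- pmax(0L, hi - lo + 1L)
  list(qidx = rep.int(seq_along(q), n), tidx = sequence(n, from = lo))
}

# Ungapped x-drop extension along one diagonal. m is the match vector over
# the valid window; anchor is a 0-based offset within it known to match.
# Scoring +1 match / -6 mismatch, drop 30, trimmed back to the first
# maximum-scoring prefix: recovery past a true junction would need a 7-base
# chance-match run, so segment boundaries stay put for breakpoint work while
# isolated sequencing errors are still crossed.
.xdrop_extend <- function(m, anchor, mismatch = -6L, xdrop = 30L) {
  n <- length(m)
  v <- ifelse(m, 1L, mismatch)
  right <- anchor
  if (anchor < n) {
    cs <- cumsum(v[(anchor + 1L):n])
    cm <- cummax(cs)
    stop_at <- which(cs < cm - xdrop)
    lim <- if (length(stop_at)) stop_at[1] else length(cs)
    best <- which.max(cs[seq_len(lim)])
    if (cs[best] > 0L) right <- anchor + best
  }
  left <- anchor
  if (anchor > 0L) {
    cs <- cumsum(v[anchor:1])
    cm <- cummax(cs)
    stop_at <- which(cs < cm - xdrop)
    lim <- if (length(stop_at)) stop_at[1] else length(cs)
    best <- which.max(cs[seq_len(lim)])
    if (cs[best] > 0L) left <- anchor - best
  }
  c(left, right)   # 0-based half-open on the query
}

# Extend one (contig, diagonal) candidate; returns NULL or the segment in
# forward-query coordinates.
.extend_on_diag <- function(qv, sv, diag, anchor) {
  Lq <- length(qv); Lc <- length(sv)
  p0 <- max(0L, -diag); p1 <- min(Lq, Lc - diag)   # valid query offsets
  if (p1 - p0 <= 0L) return(NULL)
  m <- qv[(p0 + 1L):p1] == sv[(p0 + diag + 1L):(p1 + diag)]
  a <- anchor - p0
  if (a < 0L || a >= length(m) || !m[a + 1L]) {
    a <- which(m)[1]
    if (is.na(a)) return(NULL)
    a <- a - 1L
  }
  ext <- .xdrop_extend(m, a)
  q0 <- p0 + ext[1]; q1 <- p0 + ext[2]
  if (q1 <= q0) return(NULL)
  nmm <- sum(!m[(ext[1] + 1L):ext[2]])
  list(q0 = q0, q1 = q1, ref0 = q0 + diag, ref1 = q1 + diag,
       nmm = nmm, score = (q1 - q0 - nmm) - 6L * nmm)
}

# One segment search for a (sub)sequence. Returns a one-row segment
# data.frame in subquery coordinates (plus cohits) or NULL.
.seed_segment <- function(sq, index, use_k2 = FALSE, max_mismatch_frac = 0.05) {
  tab <- if (use_k2) index$tab2 else index$tab
  kk <- if (use_k2) index$k2 else index$k
  L <- nchar(sq)
  if (L < kk) return(NULL)
  n <- L - kk + 1L
  uf <- utf8ToInt(toupper(sq))
  bf <- .BASE_MAP[uf]
  br <- rev(3L - bf)                      # reverse complement in 2-bit space
  q <- c(.encode_kmers(bf, kk), .encode_kmers(br, kk))
  hits <- .seed_hits(tab, q)
  if (!length(hits$qidx)) return(NULL)
  strand2 <- hits$qidx > n                # TRUE = reverse-complement query
  qpos <- (hits$qidx - 1L) %% n
  contig <- tab$contig[hits$tidx]
  diag <- tab$pos[hits$tidx] - qpos
  gid <- (contig * 2 + strand2) * 2^33 + (diag + 2^31)
  o <- order(gid, qpos)
  r <- rle(gid[o])
  votes <- r$lengths
  vmax <- max(votes)
  first <- cumsum(c(1L, votes[-length(votes)]))
  top <- which(votes == vmax)
  results <- vector("list", length(top))
  tcontig <- integer(length(top)); tstrand <- character(length(top))
  bf2 <- bf; bf2[is.na(bf2)] <- -1L
  br2 <- br; br2[is.na(br2)] <- -1L
  # comparisons run in 2-bit space; N (coded -1 / -2) never matches
  for (i in seq_along(top)) {
    j <- o[first[top[i]]]
    tstrand[i] <- if (strand2[j]) "-" else "+"
    tcontig[i] <- contig[j]
    sv <- index$bases[[contig[j]]]
    sv2 <- sv; sv2[is.na(sv2)] <- -2L
    results[[i]] <- .extend_on_diag(if (strand2[j]) br2 else bf2, sv2, diag[j], qpos[j])
  }
  scores <- vapply(results, function(r) if (is.null(r)) -Inf else r$score, numeric(1))
  if (!any(is.finite(scores))) return(NULL)
  smax <- max(scores)
  ties <- which(scores == smax)
  cn <- index$contig_names[tcontig[ties]]
  ord <- ties[order(cn, vapply(results[ties], `[[`, numeric(1), "ref0"), tstrand[ties])]
  pick <- ord[1]
  res <- results[[pick]]
  len <- res$q1 - res$q0
  if (len < kk || res$nmm > max_mismatch_frac * len) return(NULL)
  st <- tstrand[pick]
  if (st == "+") { rs <- res$q0; re <- res$q1 } else { rs <- L - res$q1; re <- L - res$q0 }
  cohits <- NULL
  if (length(ord) > 1L) {
    cohits <- do.call(rbind, lapply(ord[-1], function(i) data.frame(
      contig = index$contig_names[tcontig[i]], ref_start = results[[i]]$ref0,
      strand = tstrand[i], stringsAsFactors = FALSE)))
  }
  data.frame(contig = index$contig_names[tcontig[pick]],
             ref_start = res$ref0, ref_end = res$ref1,
             strand = st, read_start = rs, read_end = re,
             n_mismatch = res$nmm, stringsAsFactors = FALSE,
             cohits = I(list(cohits)))
}

#' Align one read against a seed index
#'
#' Greedy chimeric alignment: the best seeded ungapped extension forms the
#' primary segment; if >= 20 bp of the read remains unaligned at either end, a
#' second alignment of the remainder is attempted (at most two segments per
#' read). Equally-best loci are recorded as `cohits`; the primary is the
#' lexicographically smallest (contig, position) for determinism.
#'
#' @param read character scalar read sequence.
#' @param index a [build_index()] result.
#' @param max_mismatch_frac maximum mismatch fraction per segment.
#' @param min_remainder minimum unaligned tail length for the second pass
#'   (default 20 bp, the split-validity floor).
#' @return a segment `data.frame` (possibly 0 rows): columns `contig,
#'   ref_start, ref_end, strand, read_start, read_end, n_mismatch,
#'   is_supplementary, cohits`.
#' @export
align_read <- function(read, index, max_mismatch_frac = 0.05, min_remainder = 20L) {
  empty <- data.frame(contig = character(0), ref_start = integer(0),
                      ref_end = integer(0), strand = character(0),
                      read_start = integer(0), read_end = integer(0),
                      n_mismatch = integer(0), is_supplementary = logical(0),
                      cohits = I(list()))
  read <- toupper(read)
  prim <- .seed_segment(read, index, use_k2 = FALSE, max_mismatch_frac = max_mismatch_frac)
  if (is.null(prim)) return(empty)
  L <- nchar(read)
  segs <- prim
  # remainder pass: try both unaligned ends, keep the longer successful one
  rem <- list()
  if (prim$read_start >= min_remainder) rem$pre <- c(0L, prim$read_start)
  if (L - prim$read_end >= min_remainder) rem$suf <- c(prim$read_end, L)
  best2 <- NULL
  for (r in rem) {
    sub <- substr(read, r[1] + 1L, r[2])
    s2 <- .seed_segment(sub, index, use_k2 = TRUE, max_mismatch_frac = max_mismatch_frac)
    if (is.null(s2)) next
    # segments below the split-validity floor carry no evidence; emitting them
    # would only flip pair classes relative to the SAM extraction path
    if (s2$read_end - s2$read_start < min_remainder) next
    s2$read_start <- s2$read_start + r[1]
    s2$read_end <- s2$read_end + r[1]
    if (is.null(best2) || (s2$read_end - s2$read_start) > (best2$read_end - best2$read_start))
      best2 <- s2
  }
  if (!is.null(best2)) segs <- rbind(prim, best2)
  segs$is_supplementary <- c(FALSE, rep(TRUE, nrow(segs) - 1L))
  segs
}

#' Align a set of reads into read-pair records
#'
#' @param r1,r2 named character vectors of mate sequences (same names).
#' @param index a [build_index()] result.
#' @param ... passed to [align_read()].
#' @return list of read-pair records (`list(read_id, r1, r2)` segment tables),
#'   ordered by read id.
#' @export
align_read_pairs <- function(r1, r2, index, ...) {
  ids <- sort(intersect(names(r1), names(r2)))
  lapply(ids, function(id) {
    a1 <- align_read(r1[[id]], index, ...)
    a2 <- align_read(r2[[id]], index, ...)
    add_id <- function(df, mate) {
      if (nrow(df)) { df$read_id <- id; df$mate <- mate }
      df
    }
    list(read_id = id, r1 = add_id(a1, "R1"), r2 = add_id(a2, "R2"))
  })
}

#' Convert a truth segment table into read-pair records
#' @param segments segment table (simulator output).
#' @return list of read-pair records.
#' @export
pairs_from_segments <- function(segments) {
  if (!nrow(segments)) return(list())
  segments$cohits <- rep(list(NULL), nrow(segments))
  .pair_segments(segments)
}
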