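# Read-pair classification, junction typing, deduplication, clustering and
# full-TIS pairing. Conventions (all user-facing coordinates 1-based):
#  - "Left"  = genome lies to the LEFT of the junction; breakpoint is the last
#    genome base before the insertion.
#  - "Right" = genome lies to the RIGHT; breakpoint is the first genome base
#    after the insertion (so a full TIS reads deletion = right - left - 1).
#  - Direction "Forward" = the integrated T-DNA forward strand (LB->RB upper
#    strand) is co-linear with the genome forward strand.

.TDNA_NAME <- "tDNA"

#' The eight insertion-type labels
#'
#' RefSide & border & Direction, in stable order: Left before Right, LB before
#' RB, Forward before Reverse.
#'
#' @return character vector of length 8.
#' @export
enumerate_insertion_types <- function() {
  as.vector(t(outer(c("Left", "Right"), as.vector(t(outer(
    c("LB", "RB"), c("Forward", "Reverse"), paste, sep = "&"))), paste, sep = "&")))
}

# Split-validity per mate: exactly 2 segments, one on the genome and one on
# the tDNA contig, each covering >= min_non_overlap bp of the read exclusive
# of their overlap (the published extraction used minNonOverlap 20 and a
# 2-segment cap).
.split_mate <- function(segs, min_non_overlap = 20L) {
  if (nrow(segs) != 2L) return(NULL)
  on_t <- segs$contig == .TDNA_NAME
  if (sum(on_t) != 1L) return(NULL)
  ov <- max(0L, min(segs$read_end) - max(segs$read_start))
  excl <- (segs$read_end - segs$read_start) - ov
  if (any(excl < min_non_overlap)) return(NULL)
  list(genome = segs[!on_t, , drop = FALSE], tdna = segs[on_t, , drop = FALSE])
}

#' Classify a read pair
#'
#' `SPLIT` if either mate splits validly between a genome contig and the tDNA
#' contig; otherwise `DISCORDANT` if one mate maps only to the genome and the
#' other only to the tDNA contig; otherwise `INVALID_GENOME_ONLY` /
#' `INVALID_TDNA_ONLY` by where the aligned bases lie (majority rule for the
#' rare mixed leftovers that fail split validity).
#'
#' @param pair read-pair record `list(read_id, r1, r2)`.
#' @param min_non_overlap minimum per-segment exclusive coverage for a valid
#'   split (bp).
#' @return one of `"SPLIT"`, `"DISCORDANT"`, `"INVALID_GENOME_ONLY"`,
#'   `"INVALID_TDNA_ONLY"`.
#' @export
classify_read_pair <- function(pair, min_non_overlap = 20L) {
  segs <- rbind(pair$r1[, c("contig", "read_start", "read_end")],
                pair$r2[, c("contig", "read_start", "read_end")])
  if (!nrow(segs)) stop("read pair has no aligned segments", call. = FALSE)
  for (m in list(pair$r1, pair$r2)) {
    if (nrow(m) && !is.null(.split_mate(m, min_non_overlap))) return("SPLIT")
  }
  t1 <- pair$r1$contig == .TDNA_NAME; t2 <- pair$r2$contig == .TDNA_NAME
  if (nrow(pair$r1) && nrow(pair$r2)) {
    if ((all(t1) && all(!t2)) || (all(!t1) && all(t2))) return("DISCORDANT")
  }
  tdna_bp <- sum((segs$read_end - segs$read_start)[segs$contig == .TDNA_NAME])
  genome_bp <- sum((segs$read_end - segs$read_start)[segs$contig != .TDNA_NAME])
  if (tdna_bp > genome_bp) "INVALID_TDNA_ONLY" else "INVALID_GENOME_ONLY"
}

# Tn5 fragment signature: the outermost genome coordinate of the pair on the
# junction's far side (the cut site), plus chrom and side. Distinct cut sites
# are independent molecules; identical signatures are PCR duplicates.
.fragment_sig <- function(pair, chrom, ref_side) {
  segs <- rbind(pair$r1, pair$r2)
  g <- segs[segs$contig == chrom, , drop = FALSE]
  pos <- if (ref_side == "Left") min(g$ref_start) else max(g$ref_end)
  paste(chrom, pos, ref_side, sep = ":")
}

# Map a read offset on a tdna segment to a 1-based tDNA coordinate.
.tdna_coord <- function(t, read_pos) {
  if (t$strand == "+") t$ref_start + (read_pos - t$read_start) + 1L
  else t$ref_end - (read_pos - t$read_start)
}

#' Junction evidence from a split read pair
#'
#' Typing follows the junction geometry: with the genome segment on reference
#' interval \[g1,g2) and strand s, the junction adjoins the segment's
#' high-coordinate end (RefSide = Left, breakpoint = g2) when s = + and the
#' tDNA part follows the genome part in read order, or when s = - and it
#' precedes it; otherwise RefSide = Right with breakpoint = g1+1. Direction is
#' Forward iff genome and tDNA segment strands agree. The border is whichever
#' repeat lies nearer the junction-adjacent tDNA coordinate; evidence
#' equidistant from both repeats is discarded (returns NULL).
#'
#' @param pair a SPLIT-classified read-pair record.
#' @param construct the [construct_model()].
#' @param min_non_overlap split-validity floor (bp).
#' @return one-row evidence data.frame, or NULL for an ambiguous border.
#' @export
junction_from_split <- function(pair, construct, min_non_overlap = 20L) {
  sp <- NULL
  for (m in list(pair$r1, pair$r2)) {
    if (nrow(m)) sp <- .split_mate(m, min_non_overlap)
    if (!is.null(sp)) break
  }
  if (is.null(sp)) stop("read pair is not a valid split", call. = FALSE)
  g <- sp$genome; t <- sp$tdna
  tdna_after <- t$read_start >= g$read_start
  if ((g$strand == "+") == tdna_after) {
    ref_side <- "Left"; breakpoint <- g$ref_end
  } else {
    ref_side <- "Right"; breakpoint <- g$ref_start + 1L
  }
  direction <- if (g$strand == t$strand) "Forward" else "Reverse"
  jpos <- if (tdna_after) t$read_start else t$read_end - 1L
  tdna_pos <- .tdna_coord(t, jpos)
  border <- .nearer_border(construct, tdna_pos - 1L)
  if (is.na(border)) return(NULL)
  cos <- .cosites(g, ref_side)
  data.frame(read_id = pair$read_id, chrom = g$contig, breakpoint = breakpoint,
             ref_side = ref_side, border = border, direction = direction,
             tdna_pos = tdna_pos, kind = "split",
             fragment_sig = .fragment_sig(pair, g$contig, ref_side),
             n_mismatch = g$n_mismatch + t$n_mismatch,
             stringsAsFactors = FALSE, cosites = I(list(cos)))
}

# Alternative (chrom, breakpoint) sites implied by equally-scoring loci of the
# genome segment. If a cohit is on the opposite strand the junction adjoins
# the opposite end of the segment.
.cosites <- function(g, ref_side) {
  co <- g$cohits[[1]]
  if (is.null(co) || !nrow(co)) return(NULL)
  co <- co[co$contig != .TDNA_NAME, , drop = FALSE]
  if (!nrow(co)) return(NULL)
  len <- g$ref_end - g$ref_start
  high_end <- (ref_side == "Left")
  alt_high <- ifelse(co$strand == g$strand, high_end, !high_end)
  data.frame(chrom = co$contig,
             breakpoint = ifelse(alt_high, co$ref_start + len, co$ref_start + 1L),
             stringsAsFactors = FALSE)
}

#' Junction evidence from a discordant read pair
#'
#' The genome mate's strand gives RefSide (mates face each other, so a genome
#' mate on + reads toward a junction on its right: RefSide = Left) and an
#' outer-bound breakpoint estimate; Direction is Forward iff the mate strands
#' differ (the mates sit on opposite strands of one fragment); the border is
#' the repeat nearer the tDNA mate. Border and Direction assume the mate-
#' adjacent T-DNA is also junction-adjacent, which concatemers can violate —
#' discordant typing is treated as corroborative, not definitive.
#'
#' @param pair a DISCORDANT-classified read-pair record.
#' @param construct the [construct_model()].
#' @return one-row evidence data.frame, or NULL for an ambiguous border.
#' @export
junction_from_discordant <- function(pair, construct) {
  m1_t <- nrow(pair$r1) && all(pair$r1$contig == .TDNA_NAME)
  g <- if (m1_t) pair$r2 else pair$r1
  t <- if (m1_t) pair$r1 else pair$r2
  g <- g[which.max(g$read_end - g$read_start), , drop = FALSE]
  t <- t[which.max(t$read_end - t$read_start), , drop = FALSE]
  if (g$strand == "+") {
    ref_side <- "Left"; breakpoint <- g$ref_end
  } else {
    ref_side <- "Right"; breakpoint <- g$ref_start + 1L
  }
  direction <- if (g$strand != t$strand) "Forward" else "Reverse"
  mid <- (t$ref_start + t$ref_end - 1L) %/% 2L
  border <- .nearer_border(construct, mid)
  if (is.na(border)) return(NULL)
  cos <- .cosites(g, ref_side)
  data.frame(read_id = pair$read_id, chrom = g$contig, breakpoint = breakpoint,
             ref_side = ref_side, border = border, direction = direction,
             tdna_pos = mid + 1L, kind = "discordant",
             fragment_sig = .fragment_sig(pair, g$contig, ref_side),
             n_mismatch = g$n_mismatch + t$n_mismatch,
             stringsAsFactors = FALSE, cosites = I(list(cos)))
}

#' Extract junction evidence from read-pair alignments
#'
#' Classifies every pair and converts SPLIT and DISCORDANT pairs into
#' junction evidence. Attribute `class_counts` carries the read-taxonomy
#' tally (including evidence discarded for an ambiguous border).
#'
#' @param pairs list of read-pair records.
#' @param construct the [construct_model()].
#' @param min_non_overlap split-validity floor (bp).
#' @return evidence data.frame (one row per informative pair), sorted by
#'   read id.
#' @export
extract_evidence <- function(pairs, construct, min_non_overlap = 20L) {
  counts <- c(INVALID_GENOME_ONLY = 0L, INVALID_TDNA_ONLY = 0L,
              SPLIT = 0L, DISCORDANT = 0L, UNALIGNED = 0L, AMBIGUOUS_BORDER = 0L)
  ev <- list()
  for (p in pairs) {
    if (!nrow(p$r1) && !nrow(p$r2)) {
      counts["UNALIGNED"] <- counts["UNALIGNED"] + 1L
      next
    }
    cls <- classify_read_pair(p, min_non_overlap)
    counts[cls] <- counts[cls] + 1L
    e <- switch(cls,
                SPLIT = junction_from_split(p, construct, min_non_overlap),
                DISCORDANT = junction_from_discordant(p, construct),
                NULL)
    if (cls %in% c("SPLIT", "DISCORDANT") && is.null(e))
      counts["AMBIGUOUS_BORDER"] <- counts["AMBIGUOUS_BORDER"] + 1L
    if (!is.null(e)) ev[[length(ev) + 1L]] <- e
  }
  out <- if (length(ev)) do.call(rbind, ev) else .empty_evidence()
  out <- out[order(out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class_counts = counts)
}

.empty_evidence <- function() {
  data.frame(read_id = character(0), chrom = character(0), breakpoint = integer(0),
             ref_side = character(0), border = character(0), direction = character(0),
             tdna_pos = integer(0), kind = character(0), fragment_sig = character(0),
             n_mismatch = integer(0), cosites = I(list()))
}

#' Collapse PCR duplicates to non-redundant evidence
#'
#' One record is retained per distinct fragment signature (distinct Tn5 cut
#' sites are independent molecules); among duplicates the record with fewest
#' mismatches wins, then the lexicographically smallest read id.
#'
#' @param evidence evidence data.frame.
#' @return deduplicated evidence data.frame.
#' @export
dedupe_evidence <- function(evidence) {
  if (!nrow(evidence)) return(evidence)
  pref <- order(evidence$fragment_sig,
                match(evidence$kind, c("split", "discordant")),
                evidence$n_mismatch, evidence$read_id)
  ev <- evidence[pref, , drop = FALSE]
  ev <- ev[!duplicated(ev$fragment_sig), , drop = FALSE]
  ev <- ev[order(ev$read_id), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Cluster junction evidence into TIS calls
#'
#' Split evidence is grouped by (chrom, RefSide, border, Direction) and
#' clustered around modal breakpoints within `tol`; the reported breakpoint is
#' the mode (ties -> smallest). Discordant evidence attaches to the nearest
#' cluster on the same (chrom, RefSide) within `max_fragment` bp, preferring
#' clusters that also match its inferred border/direction; leftovers form
#' support-only clusters that are reported but flagged imprecise. Clusters are
#' kept iff `split_supportN >= min_split`, or `split_supportN >= 1` with
#' `discort_supportN >= min_discordant_with_one_split`.
#'
#' @param evidence deduplicated evidence.
#' @param sample sample name.
#' @param tol breakpoint clustering tolerance (bp).
#' @param min_split minimum split support.
#' @param min_discordant_with_one_split discordant support required when only
#'   one split read supports a site.
#' @param max_fragment maximum library fragment length (bp), the attachment
#'   radius for discordant evidence.
#' @return a `tis_calls` data.frame.
#' @export
cluster_calls <- function(evidence, sample = "sample", tol = 5L, min_split = 2L,
                          min_discordant_with_one_split = 3L,
                          max_fragment = 900L) {
  sp <- evidence[evidence$kind == "split", , drop = FALSE]
  dc <- evidence[evidence$kind == "discordant", , drop = FALSE]
  clusters <- list()
  if (nrow(sp)) {
    grp <- split(seq_len(nrow(sp)),
                 paste(sp$chrom, sp$ref_side, sp$border, sp$direction, sep = "\r"))
    for (g in grp[order(names(grp))]) {
      rest <- g
      while (length(rest)) {
        tab <- table(sp$breakpoint[rest])
        mode_bp <- as.integer(names(tab)[tab == max(tab)])[1]  # ties -> smallest
        memb <- rest[abs(sp$breakpoint[rest] - mode_bp) <= tol]
        rest <- setdiff(rest, memb)
        r <- sp[memb[1], ]
        clusters[[length(clusters) + 1L]] <- list(
          chrom = r$chrom, breakpoint = mode_bp, ref_side = r$ref_side,
          border = r$border, direction = r$direction,
          split_ids = sp$read_id[memb], disc_ids = character(0),
          cosites = do.call(rbind, sp$cosites[memb]), imprecise = FALSE)
      }
    }
  }
  if (nrow(dc)) {
    leftover <- integer(0)
    for (i in seq_len(nrow(dc))) {
      d <- dc[i, ]
      comp <- which(vapply(clusters, function(cl) {
        !cl$imprecise && cl$chrom == d$chrom && cl$ref_side == d$ref_side &&
          abs(cl$breakpoint - d$breakpoint) <= max_fragment
      }, logical(1)))
      if (!length(comp)) { leftover <- c(leftover, i); next }
      typed <- comp[vapply(comp, function(j)
        clusters[[j]]$border == d$border && clusters[[j]]$direction == d$direction,
        logical(1))]
      cand <- if (length(typed)) typed else comp
      dist <- vapply(cand, function(j) abs(clusters[[j]]$breakpoint - d$breakpoint), numeric(1))
      j <- cand[order(dist, vapply(cand, function(j) clusters[[j]]$breakpoint, numeric(1)))][1]
      clusters[[j]]$disc_ids <- c(clusters[[j]]$disc_ids, d$read_id)
      clusters[[j]]$cosites <- rbind(clusters[[j]]$cosites, d$cosites[[1]])
    }
    # support-only clusters from unattached discordant evidence
    if (length(leftover)) {
      dl <- dc[leftover, , drop = FALSE]
      grp <- split(seq_len(nrow(dl)),
                   paste(dl$chrom, dl$ref_side, dl$border, dl$direction, sep = "\r"))
      for (g in grp[order(names(grp))]) {
        g <- g[order(dl$breakpoint[g])]
        runs <- cumsum(c(1L, diff(dl$breakpoint[g]) > max_fragment))
        for (r in split(g, runs)) {
          bp <- if (dl$ref_side[r[1]] == "Left") max(dl$breakpoint[r]) else min(dl$breakpoint[r])
          clusters[[length(clusters) + 1L]] <- list(
            chrom = dl$chrom[r[1]], breakpoint = bp, ref_side = dl$ref_side[r[1]],
            border = dl$border[r[1]], direction = dl$direction[r[1]],
            split_ids = character(0), disc_ids = dl$read_id[r],
            cosites = do.call(rbind, dl$cosites[r]), imprecise = TRUE)
        }
      }
    }
  }
  keep <- vapply(clusters, function(cl) {
    ns <- length(cl$split_ids); nd <- length(cl$disc_ids)
    cl$imprecise || ns >= min_split ||
      (ns >= 1L && nd >= min_discordant_with_one_split)
  }, logical(1))
  clusters <- clusters[keep]
  calls <- if (length(clusters)) data.frame(
    sample = sample,
    chrom = vapply(clusters, `[[`, character(1), "chrom"),
    breakpoint = vapply(clusters, `[[`, numeric(1), "breakpoint"),
    ref_side = vapply(clusters, `[[`, character(1), "ref_side"),
    border = vapply(clusters, `[[`, character(1), "border"),
    direction = vapply(clusters, `[[`, character(1), "direction"),
    split_supportN = vapply(clusters, function(cl) length(cl$split_ids), integer(1)),
    discort_supportN = vapply(clusters, function(cl) length(cl$disc_ids), integer(1)),
    imprecise = vapply(clusters, `[[`, logical(1), "imprecise"),
    ambiguous = FALSE,
    stringsAsFactors = FALSE,
    ambiguous_sites = I(lapply(clusters, function(cl) {
      co <- cl$cosites
      if (is.null(co) || !nrow(co)) NULL else unique(co)
    })),
    read_ids = I(lapply(clusters, function(cl) c(cl$split_ids, cl$disc_ids)))
  ) else .empty_calls(sample)
  calls <- calls[order(calls$chrom, calls$breakpoint, calls$ref_side,
                       calls$border, calls$direction), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("tis_calls", "data.frame")
  calls
}

.empty_calls <- function(sample = character(0)) {
  out <- data.frame(sample = character(0), chrom = character(0), breakpoint = numeric(0),
                    ref_side = character(0), border = character(0), direction = character(0),
                    split_supportN = integer(0), discort_supportN = integer(0),
                    imprecise = logical(0), ambiguous = logical(0),
                    stringsAsFactors = FALSE,
                    ambiguous_sites = I(list()), read_ids = I(list()))
  class(out) <- c("tis_calls", "data.frame")
  out
}

#' @export
print.tis_calls <- function(x, ...) {
  cat(sprintf("%d TIS call(s)\n", nrow(x)))
  if (nrow(x)) {
    df <- data.frame(sample = x$sample,
                     site = paste0(x$chrom, ":", x$breakpoint),
                     type = paste(x$ref_side, x$border, x$direction, sep = "&"),
                     split = x$split_supportN, discordant = x$discort_supportN,
                     flags = paste0(ifelse(x$imprecise, "imprecise ", ""),
                                    ifelse(x$ambiguous, "multi-mapped", "")))
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Subtract control-sample calls
#'
#' Removes any call whose (chrom, breakpoint) lies within `radius` of a
#' control call of any type; removed calls are returned in attribute
#' `removed`. The control must have been processed by the identical pipeline.
#'
#' @param calls,control_calls `tis_calls` tables.
#' @param radius bp.
#' @return filtered `tis_calls`.
#' @export
subtract_control <- function(calls, control_calls, radius = 10L) {
  if (!nrow(calls) || is.null(control_calls) || !nrow(control_calls)) {
    attr(calls, "removed") <- .empty_calls()
    return(calls)
  }
  hit <- vapply(seq_len(nrow(calls)), function(i) {
    any(control_calls$chrom == calls$chrom[i] &
          abs(control_calls$breakpoint - calls$breakpoint[i]) <= radius)
  }, logical(1))
  out <- calls[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- calls[hit, , drop = FALSE]
  class(out) <- c("tis_calls", "data.frame")
  out
}

#' Flag multi-mapping calls
#'
#' Calls whose evidence carried equally-scoring alternative loci keep their
#' deterministic primary site, are flagged ambiguous, and list all candidate
#' sites for downstream PCR disambiguation. No call is dropped.
#'
#' @param calls `tis_calls`.
#' @return `tis_calls` with `ambiguous` flags set.
#' @export
resolve_multimap <- function(calls) {
  if (!nrow(calls)) return(calls)
  calls$ambiguous <- vapply(calls$ambiguous_sites, function(s)
    !is.null(s) && nrow(s) > 0L, logical(1))
  calls
}

#' Pair left and right calls into full TISs
#'
#' Greedy nearest pairing of each Left call with a Right call on the same
#' chromosome satisfying `right - left - 1 <= window` and
#' `right >= left - window`; `target_deletion_bp = right - left - 1` (negative
#' for duplicated/filled junction overlap). Leftovers are the half-TIS case.
#'
#' @param calls `tis_calls` for one sample.
#' @param window pairing window (bp).
#' @return list with `full` (data.frame of paired TISs) and `unpaired`
#'   (`tis_calls`).
#' @export
pair_full_tis <- function(calls, window = 100L) {
  lefts <- which(calls$ref_side == "Left")
  rights <- which(calls$ref_side == "Right")
  cand <- list()
  for (i in lefts) for (j in rights) {
    if (calls$chrom[i] != calls$chrom[j]) next
    gap <- calls$breakpoint[j] - calls$breakpoint[i] - 1L
    if (gap > window || calls$breakpoint[j] < calls$breakpoint[i] - window) next
    cand[[length(cand) + 1L]] <- c(i = i, j = j, d = abs(gap))
  }
  full <- list(); used <- integer(0)
  if (length(cand)) {
    cd <- do.call(rbind, cand)
    cd <- cd[order(cd[, "d"], cd[, "i"]), , drop = FALSE]
    for (r in seq_len(nrow(cd))) {
      i <- cd[r, "i"]; j <- cd[r, "j"]
      if (i %in% used || j %in% used) next
      used <- c(used, i, j)
      full[[length(full) + 1L]] <- data.frame(
        sample = calls$sample[i], chrom = calls$chrom[i],
        left_breakpoint = calls$breakpoint[i], right_breakpoint = calls$breakpoint[j],
        target_deletion_bp = calls$breakpoint[j] - calls$breakpoint[i] - 1L,
        pattern = paste(paste(calls$ref_side[i], calls$border[i], calls$direction[i], sep = "&"),
                        paste(calls$ref_side[j], calls$border[j], calls$direction[j], sep = "&"),
                        sep = " + "),
        left_split_supportN = calls$split_supportN[i],
        right_split_supportN = calls$split_supportN[j],
        stringsAsFactors = FALSE)
    }
  }
  full <- if (length(full)) do.call(rbind, full) else data.frame(
    sample = character(0), chrom = character(0), left_breakpoint = numeric(0),
    right_breakpoint = numeric(0), target_deletion_bp = numeric(0),
    pattern = character(0), left_split_supportN = integer(0),
    right_split_supportN = integer(0), stringsAsFactors = FALSE)
  full <- full[order(full$chrom, full$left_breakpoint), , drop = FALSE]
  rownames(full) <- NULL
  unpaired <- calls[setdiff(seq_len(nrow(calls)), used), , drop = FALSE]
  rownames(unpaired) <- NULL
  class(unpaired) <- c("tis_calls", "data.frame")
  list(full = full, unpaired = unpaired)
}

#' Run the full evidence-to-calls pipeline on aligned pairs
#'
#' classify -> junction extraction -> dedupe -> cluster -> control subtraction
#' -> multimap flagging. The read-class tally is kept in attribute
#' `class_counts`.
#'
#' @param pairs read-pair records.
#' @param construct the [construct_model()].
#' @param sample sample name.
#' @param control_calls optional `tis_calls` from the wild-type control.
#' @param min_non_overlap,tol,min_split,min_discordant_with_one_split,max_fragment,subtract_radius
#'   thresholds, see the individual stage functions.
#' @return `tis_calls` with attributes `class_counts` and `removed`.
#' @export
call_tis <- function(pairs, construct, sample = "sample", control_calls = NULL,
                     min_non_overlap = 20L, tol = 5L, min_split = 2L,
                     min_discordant_with_one_split = 3L, max_fragment = 900L,
                     subtract_radius = 10L) {
  ev <- extract_evidence(pairs, construct, min_non_overlap)
  counts <- attr(ev, "class_counts")
  ev <- dedupe_evidence(ev)
  calls <- cluster_calls(ev, sample = sample, tol = tol, min_split = min_split,
                         min_discordant_with_one_split = min_discordant_with_one_split,
                         max_fragment = max_fragment)
  calls <- subtract_control(calls, control_calls, radius = subtract_radius)
  removed <- attr(calls, "removed")
  calls <- resolve_multimap(calls)
  attr(calls, "class_counts") <- counts
  attr(calls, "removed") <- removed
  calls
}
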