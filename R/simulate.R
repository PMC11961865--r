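.BASES <- c("A", "C", "G", "T")

.rand_seq <- function(n, gc = 0.4) {
  if (n <= 0L) return("")
  paste(sample(.BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)), collapse = "")
}

#' Simulate a random genome
#'
#' @param n_contigs number of contigs (named chr1..chrN).
#' @param lengths integer vector of contig lengths (recycled to `n_contigs`).
#' @param gc GC fraction.
#' @param seed RNG seed; output is byte-identical for a fixed seed.
#' @return a `DNAStringSet`.
#' @export
simulate_genome <- function(n_contigs, lengths, gc = 0.4, seed = 1L) {
  if (n_contigs < 1L) stop("n_contigs must be >= 1", call. = FALSE)
  lengths <- rep_len(as.integer(lengths), n_contigs)
  if (any(lengths <= 0L)) stop("contig lengths must be positive", call. = FALSE)
  withr::with_seed(seed, {
    seqs <- vapply(lengths, .rand_seq, character(1), gc = gc)
  })
  Biostrings::DNAStringSet(setNames(seqs, paste0("chr", seq_len(n_contigs))))
}

#' Simulate a toy T-DNA construct
#'
#' Random construct sequence with 25 bp border repeats at both ends and bridge
#' sites a fixed distance inside each repeat (the field convention puts bridge
#' primers 150-200 bp away from the border repeats).
#'
#' @param seed RNG seed.
#' @param len construct length in bp.
#' @param repeat_len border repeat length.
#' @param bridge_offset distance of each bridge site from its contig end.
#' @return a [construct_model()].
#' @export
simulate_construct <- function(seed = 1L, len = 5000L, repeat_len = 25L,
                               bridge_offset = 180L) {
  withr::with_seed(seed, seq <- .rand_seq(len, gc = 0.45))
  construct_model("simTDNA", seq,
                  lb_repeat = c(0L, repeat_len),
                  rb_repeat = c(len - repeat_len, len),
                  lb_bridge = bridge_offset,
                  rb_bridge = len - 1L - bridge_offset)
}

#' Describe one T-DNA insertion event
#'
#' @param event_id identifier.
#' @param contig target contig name.
#' @param position 0-based insertion point (start of the deleted target
#'   interval).
#' @param deletion length of the deleted target interval (bp, >= 0).
#' @param units character vector of unit orientations, `"F"` (forward) or
#'   `"R"` (reverse-complemented); more than one unit makes a concatemer.
#' @param lb_truncation,rb_truncation bp trimmed from the LB-type / RB-type
#'   outer end of the payload. The trim applies to the outer unit whose
#'   genome-adjacent end exposes that border; if both outer ends expose the
#'   same border the LB value applies to the left outer end.
#' @param filler_left,filler_right random filler lengths at each junction.
#' @return a list of class `insertion_event`.
#' @export
insertion_event <- function(event_id, contig, position, deletion = 0L,
                            units = "F", lb_truncation = 0L, rb_truncation = 0L,
                            filler_left = 0L, filler_right = 0L) {
  stopifnot(all(units %in% c("F", "R")), deletion >= 0L,
            lb_truncation >= 0L, rb_truncation >= 0L,
            filler_left >= 0L, filler_right >= 0L)
  structure(list(event_id = as.character(event_id), contig = as.character(contig),
                 position = as.integer(position), deletion = as.integer(deletion),
                 units = units,
                 lb_truncation = as.integer(lb_truncation),
                 rb_truncation = as.integer(rb_truncation),
                 filler_left = as.integer(filler_left),
                 filler_right = as.integer(filler_right)),
            class = "insertion_event")
}

# Which border repeat is nearer to a 0-based construct coordinate?
.nearer_border <- function(construct, pos) {
  dist_iv <- function(p, iv) if (p >= iv[1] && p < iv[2]) 0L else min(abs(p - iv[1]), abs(p - (iv[2] - 1L)))
  dl <- dist_iv(pos, construct$lb_repeat)
  dr <- dist_iv(pos, construct$rb_repeat)
  if (dl == dr) return(NA_character_)
  if (dl < dr) "LB" else "RB"
}

# Per-event geometry: oriented unit intervals after outer-end trimming,
# payload sequence, bridge sites in payload coordinates, junction-adjacent
# construct coordinates. Unit i occupies construct interval [a[i], b[i]).
.event_geometry <- function(construct, units, trim_lead, trim_trail) {
  U <- nchar(construct$tdna_seq)
  K <- length(units)
  a <- rep(0L, K); b <- rep(U, K)
  if (units[1] == "F") a[1] <- a[1] + trim_lead else b[1] <- b[1] - trim_lead
  if (units[K] == "F") b[K] <- b[K] - trim_trail else a[K] <- a[K] + trim_trail
  if (any(a >= b)) stop("truncation removes an entire T-DNA unit", call. = FALSE)
  piece_len <- b - a
  offs <- cumsum(c(0L, piece_len))[seq_len(K)]
  payload <- paste(vapply(seq_len(K), function(i) {
    s <- substr(construct$tdna_seq, a[i] + 1L, b[i])
    if (units[i] == "R") revcomp(s) else s
  }, character(1)), collapse = "")
  # surviving bridge sites in payload coordinates with payload reading direction
  bridges <- list()
  for (i in seq_len(K)) {
    for (br in list(c(construct$lb_bridge, -1L), c(construct$rb_bridge, +1L))) {
      p <- br[1]; d <- br[2]
      if (p >= a[i] && p < b[i]) {
        if (units[i] == "F") {
          bridges[[length(bridges) + 1L]] <- c(pos = offs[i] + (p - a[i]), dir = d)
        } else {
          bridges[[length(bridges) + 1L]] <- c(pos = offs[i] + (b[i] - 1L - p), dir = -d)
        }
      }
    }
  }
  bridges <- if (length(bridges)) do.call(rbind, bridges) else
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("pos", "dir")))
  list(a = a, b = b, offs = offs, payload = payload, payload_len = nchar(payload),
       bridges = bridges,
       c_left = if (units[1] == "F") a[1] else b[1] - 1L,
       c_right = if (units[K] == "F") b[K] - 1L else a[K],
       dir_left = if (units[1] == "F") "Forward" else "Reverse",
       dir_right = if (units[K] == "F") "Forward" else "Reverse")
}

#' Implant insertion events into a genome
#'
#' Each event replaces its deleted target interval with
#' `filler_left + payload + filler_right`. Truth coordinates refer to the
#' original genome, 1-based: the left breakpoint is the last retained genome
#' base before the insertion, the right breakpoint the first retained base
#' after it. Labels use the same RefSide&border&Direction vocabulary as the
#' caller. A junction is flagged detectable when some surviving bridge site
#' reads toward it within `detect_range` bp (for a single intact unit this
#' reduces to "the bridge site of the adjacent border was not truncated away").
#'
#' Junctions are implanted without terminal microhomology: when a drawn filler
#' or payload boundary base coincides with the reference continuation base, the
#' filler base is redrawn (or the deletion/truncation extended by 1 bp) so that
#' every truth breakpoint is uniquely aligned. Real junctions can carry
#' microhomology, in which case the breakpoint itself is ambiguous for any
#' caller; the simulator deliberately excludes that ambiguity from truth.
#'
#' @param genome `DNAStringSet` / named character / FASTA path.
#' @param construct a [construct_model()].
#' @param events list of [insertion_event()]s; events on one contig must be
#'   >= 2 kb apart and >= 2 kb from contig ends.
#' @param seed RNG seed (fillers, guard redraws).
#' @param detect_range maximum bridge-to-junction distance still considered
#'   capturable (default 870 bp = default maximum fragment length minus a
#'   30 bp genome anchor).
#' @return list with `genome` (modified `DNAStringSet`), `truth` (one row per
#'   event), `junctions` (one row per junction with simulation metadata) and
#'   `piece_map` (modified-to-source coordinate map used for truth alignments).
#' @export
implant_insertions <- function(genome, construct, events, seed = 1L,
                               detect_range = 870L) {
  genome <- as_dna(genome)
  gseq <- setNames(as.character(genome), names(genome))
  if (length(events) && !all(vapply(events, inherits, logical(1), "insertion_event")))
    stop("events must be insertion_event objects", call. = FALSE)
  base_at <- function(s, i0) substr(s, i0 + 1L, i0 + 1L)  # 0-based lookup
  comp1 <- function(x) unname(.complement[x])

  withr::with_seed(seed, {
    ev_contig <- vapply(events, `[[`, character(1), "contig")
    bad <- setdiff(unique(ev_contig), names(gseq))
    if (length(bad)) stop("event contig not in genome: ", bad[1], call. = FALSE)
    truth <- list(); jx <- list(); maps <- list()
    for (cn in names(gseq)) {
      S <- gseq[[cn]]; Lc <- nchar(S)
      evs <- events[ev_contig == cn]
      if (length(evs)) {
        pos <- vapply(evs, `[[`, integer(1), "position")
        evs <- evs[order(pos)]; pos <- sort(pos)
        ends <- pos + vapply(evs, `[[`, integer(1), "deletion")
        if (any(pos < 2000L) || any(ends > Lc - 2000L))
          stop("event too close to a contig end", call. = FALSE)
        if (length(pos) > 1L && any(pos[-1] - ends[-length(ends)] < 2000L))
          stop("events closer than 2 kb", call. = FALSE)
      }
      cursor <- 0L; mod_len <- 0L; chunks <- character(0); pieces <- list()
      add_piece <- function(len, src, src_lo, src_dir) {
        if (len > 0L)
          pieces[[length(pieces) + 1L]] <<- data.table::data.table(
            contig = cn, mod_start = mod_len, mod_end = mod_len + len,
            src = src, src_lo = src_lo, src_dir = src_dir)
      }
      for (ev in evs) {
        del_start <- ev$position; del_end <- ev$position + ev$deletion
        units <- ev$units; K <- length(units)
        trim_lead <- if (units[1] == "F") ev$lb_truncation else ev$rb_truncation
        trim_trail <- if (units[K] == "F") ev$rb_truncation else ev$lb_truncation
        fl <- strsplit(.rand_seq(ev$filler_left, 0.5), "")[[1]]
        fr <- strsplit(.rand_seq(ev$filler_right, 0.5), "")[[1]]
        geo <- .event_geometry(construct, units, trim_lead, trim_trail)

        # --- microhomology guards (see Details) -------------------------------
        for (iter in 1:12) {   # left junction, inserted side
          first_ins <- if (length(fl)) fl[1] else substr(geo$payload, 1, 1)
          if (first_ins != base_at(S, del_start)) break
          if (length(fl)) { fl[1] <- sample(setdiff(.BASES, base_at(S, del_start)), 1L); break }
          del_start <- del_start - 1L
        }
        if (length(fl) == 0L) {          # left junction, construct-side continuation
          for (iter in 1:12) {
            cont <- if (units[1] == "F") {
              if (geo$a[1] > 0L) base_at(construct$tdna_seq, geo$a[1] - 1L) else NA
            } else {
              if (geo$b[1] < nchar(construct$tdna_seq)) comp1(base_at(construct$tdna_seq, geo$b[1])) else NA
            }
            if (is.na(cont) || cont != base_at(S, del_start - 1L)) break
            trim_lead <- trim_lead + 1L
            geo <- .event_geometry(construct, units, trim_lead, trim_trail)
          }
        }
        for (iter in 1:12) {   # right junction, inserted side
          last_ins <- if (length(fr)) fr[length(fr)] else
            substr(geo$payload, geo$payload_len, geo$payload_len)
          if (last_ins != base_at(S, del_end - 1L)) break
          if (length(fr)) { fr[length(fr)] <- sample(setdiff(.BASES, base_at(S, del_end - 1L)), 1L); break }
          del_end <- del_end + 1L
        }
        if (length(fr) == 0L) {          # right junction, construct-side continuation
          for (iter in 1:12) {
            cont <- if (units[K] == "F") {
              if (geo$b[K] < nchar(construct$tdna_seq)) base_at(construct$tdna_seq, geo$b[K]) else NA
            } else {
              if (geo$a[K] > 0L) comp1(base_at(construct$tdna_seq, geo$a[K] - 1L)) else NA
            }
            if (is.na(cont) || cont != base_at(S, del_end)) break
            trim_trail <- trim_trail + 1L
            geo <- .event_geometry(construct, units, trim_lead, trim_trail)
          }
        }

        # --- stitch -----------------------------------------------------------
        chunks <- c(chunks, substr(S, cursor + 1L, del_start))
        add_piece(del_start - cursor, cn, cursor, +1L)
        mod_len <- mod_len + (del_start - cursor)
        j_left_mod <- mod_len
        chunks <- c(chunks, paste(fl, collapse = ""))
        add_piece(length(fl), NA_character_, NA_integer_, NA_integer_)
        mod_len <- mod_len + length(fl)
        payload_start_mod <- mod_len
        for (i in seq_len(K)) {
          len_i <- geo$b[i] - geo$a[i]
          add_piece(len_i, "tDNA", geo$a[i], if (units[i] == "F") +1L else -1L)
          mod_len <- mod_len + len_i
        }
        chunks <- c(chunks, geo$payload)
        chunks <- c(chunks, paste(fr, collapse = ""))
        add_piece(length(fr), NA_character_, NA_integer_, NA_integer_)
        mod_len <- mod_len + length(fr)
        j_right_mod <- mod_len
        cursor <- del_end

        # --- truth ------------------------------------------------------------
        left_bp <- del_start            # 1-based last genome base kept on the left
        right_bp <- del_end + 1L        # 1-based first genome base kept on the right
        lab_left <- paste("Left", .nearer_border(construct, geo$c_left), geo$dir_left, sep = "&")
        lab_right <- paste("Right", .nearer_border(construct, geo$c_right), geo$dir_right, sep = "&")
        bl <- geo$bridges[geo$bridges[, "dir"] == -1L, , drop = FALSE]
        br <- geo$bridges[geo$bridges[, "dir"] == +1L, , drop = FALSE]
        jd_left <- if (nrow(bl)) min(bl[, "pos"]) + length(fl) + 1L else NA_integer_
        jd_right <- if (nrow(br)) (geo$payload_len - max(br[, "pos"])) + length(fr) else NA_integer_
        det_left <- !is.na(jd_left) && jd_left <= detect_range
        det_right <- !is.na(jd_right) && jd_right <= detect_range
        truth[[length(truth) + 1L]] <- data.frame(
          event_id = ev$event_id, contig = cn,
          left_breakpoint = left_bp, right_breakpoint = right_bp,
          left_label = lab_left, right_label = lab_right,
          detectable_left = det_left, detectable_right = det_right,
          target_deletion_bp = del_end - del_start,
          stringsAsFactors = FALSE)
        jx[[length(jx) + 1L]] <- data.frame(
          event_id = ev$event_id, contig = cn,
          side = c("Left", "Right"),
          label = c(lab_left, lab_right),
          breakpoint = c(left_bp, right_bp),
          junction_mod = c(j_left_mod, j_right_mod),
          bridge_mod = c(if (det_left) payload_start_mod + min(bl[, "pos"]) else NA_integer_,
                         if (det_right) payload_start_mod + max(br[, "pos"]) else NA_integer_),
          jdist = c(jd_left, jd_right),
          detectable = c(det_left, det_right),
          stringsAsFactors = FALSE)
      }
      chunks <- c(chunks, substr(S, cursor + 1L, Lc))
      add_piece(Lc - cursor, cn, cursor, +1L)
      mod_len <- mod_len + (Lc - cursor)
      gseq[[cn]] <- paste(chunks, collapse = "")
      maps[[cn]] <- if (length(pieces)) data.table::rbindlist(pieces) else
        data.table::data.table(contig = cn, mod_start = 0L, mod_end = Lc,
                               src = cn, src_lo = 0L, src_dir = +1L)
    }
  })
  truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
    event_id = character(0), contig = character(0),
    left_breakpoint = integer(0), right_breakpoint = integer(0),
    left_label = character(0), right_label = character(0),
    detectable_left = logical(0), detectable_right = logical(0),
    target_deletion_bp = integer(0))
  jx <- if (length(jx)) do.call(rbind, jx) else data.frame(
    event_id = character(0), contig = character(0), side = character(0),
    label = character(0), breakpoint = integer(0), junction_mod = integer(0),
    bridge_mod = integer(0), jdist = integer(0), detectable = logical(0))
  list(genome = Biostrings::DNAStringSet(gseq), truth = truth,
       junctions = jx, piece_map = data.table::rbindlist(maps))
}

#' Library simulation parameters
#'
#' Defaults reflect the assay as published: PE150 reads, amplicons (bridge
#' site to Tn5 cut) uniform on 150-900 bp, 8 capturable fragments per
#' junction, PCR duplicates re-emitted at rate 0.1, error-free bases.
#'
#' @param fragment_min,fragment_max amplicon length range (bp).
#' @param read_len read length (bp).
#' @param n_capturable capturable fragments emitted per detectable junction.
#' @param substitution_rate per-base substitution error probability (< 0.1).
#' @param duplicate_rate probability that a fragment is re-emitted as a PCR
#'   duplicate (same cut site, new read id).
#' @param n_background read pairs drawn uniformly from the sample genome
#'   (nonspecific amplification; they may fall inside integrated T-DNA).
#' @param me_prefix prepend the 19 bp Tn5 mosaic-end remnant to read 1
#'   (untrimmed-input emulation).
#' @param seed RNG seed.
#' @return a list of class `library_params`.
#' @export
library_params <- function(fragment_min = 150L, fragment_max = 900L,
                           read_len = 150L, n_capturable = 8L,
                           substitution_rate = 0, duplicate_rate = 0.1,
                           n_background = 50L, me_prefix = FALSE, seed = 1L) {
  if (read_len > fragment_max) stop("read_len must be <= fragment_max", call. = FALSE)
  if (substitution_rate < 0 || substitution_rate >= 0.1)
    stop("substitution_rate must be in [0, 0.1)", call. = FALSE)
  structure(list(fragment_min = as.integer(fragment_min),
                 fragment_max = as.integer(fragment_max),
                 read_len = as.integer(read_len),
                 n_capturable = as.integer(n_capturable),
                 substitution_rate = substitution_rate,
                 duplicate_rate = duplicate_rate,
                 n_background = as.integer(n_background),
                 me_prefix = isTRUE(me_prefix), seed = as.integer(seed)),
            class = "library_params")
}

.ME_SEQ <- "AGATGTGTATAAGAGACAG"   # 19 bp Tn5 mosaic end

# Substitute bases at rate p; returns list(seq, err_pos (0-based)).
.mutate_read <- function(seq, p) {
  if (p <= 0) return(list(seq = seq, err = integer(0)))
  n <- nchar(seq)
  hit <- which(runif(n) < p)
  if (!length(hit)) return(list(seq = seq, err = integer(0)))
  ch <- strsplit(seq, "")[[1]]
  for (i in hit) ch[i] <- sample(setdiff(.BASES, ch[i]), 1L)
  list(seq = paste(ch, collapse = ""), err = hit - 1L)
}

#' Simulate a tagmentation / bridge-PCR integration-site library
#'
#' For every detectable junction, emits `n_capturable` amplicons spanning from
#' the nearest inward-reading bridge site to a random Tn5 cut site beyond the
#' junction on the genome side. Read 2 starts at the bridge site and reads
#' toward the border (and across the junction when the fragment geometry allows
#' it); read 1 starts at the Tn5 cut and reads inward from the genome side.
#' Background pairs are drawn uniformly from the sample genome. Short fragments
#' yield junction-spanning (split) reads; longer ones yield pairs that straddle
#' the junction without crossing it (discordant evidence).
#'
#' @param genome_mod the modified (post-insertion) sample genome.
#' @param construct the [construct_model()].
#' @param implant result of [implant_insertions()] (supplies junction metadata
#'   and the modified-to-source coordinate map used for truth alignments).
#' @param params a [library_params()].
#' @param sample_name sample identifier used in read names and outputs.
#' @param dir if non-NULL, write `<sample>_R1.fastq`, `<sample>_R2.fastq`, a
#'   truth SAM against the merged reference, and a truth TSV into `dir`.
#' @param merged_ref merged reference (for the truth SAM header); required when
#'   `dir` is given.
#' @return list with `r1`, `r2` (named character read vectors), `segments`
#'   (truth alignment table, one row per aligned segment) and file paths when
#'   written.
#' @export
simulate_ttloc_library <- function(genome_mod, construct, implant, params,
                                   sample_name = "S1", dir = NULL,
                                   merged_ref = NULL) {
  genome_mod <- as_dna(genome_mod)
  mseq <- setNames(as.character(genome_mod), names(genome_mod))
  jx <- implant$junctions
  map <- implant$piece_map
  rl <- params$read_len
  r1 <- character(0); r2 <- character(0); meta <- list()
  add_pair <- function(id, contig, s1, e1, strand1, s2, e2, strand2, is_dup = FALSE) {
    # reads are substrings of the modified genome; strand "-" means the read is
    # the reverse complement of mod[s, e)
    S <- mseq[[contig]]
    sq1 <- substr(S, s1 + 1L, e1); if (strand1 == "-") sq1 <- revcomp(sq1)
    sq2 <- substr(S, s2 + 1L, e2); if (strand2 == "-") sq2 <- revcomp(sq2)
    m1 <- .mutate_read(sq1, params$substitution_rate)
    m2 <- .mutate_read(sq2, params$substitution_rate)
    r1[[id]] <<- m1$seq; r2[[id]] <<- m2$seq
    meta[[length(meta) + 1L]] <<- list(id = id, contig = contig,
      s1 = s1, e1 = e1, st1 = strand1, err1 = m1$err,
      s2 = s2, e2 = e2, st2 = strand2, err2 = m2$err, dup = is_dup)
  }
  withr::with_seed(params$seed, {
    det <- jx[jx$detectable, , drop = FALSE]
    for (j in seq_len(nrow(det))) {
      row <- det[j, ]
      Lc <- nchar(mseq[[row$contig]])
      for (i in seq_len(params$n_capturable)) {
        frag <- NA
        for (try in 1:100) {
          f <- params$fragment_min + sample.int(params$fragment_max - params$fragment_min + 1L, 1L) - 1L
          if (f <= row$jdist) next
          if (row$side == "Left" && row$bridge_mod - f + 1L < 0L) next
          if (row$side == "Right" && row$bridge_mod + f > Lc) next
          frag <- f; break
        }
        if (is.na(frag)) next
        id <- sprintf("%s:%s:%s:%d", sample_name, row$event_id,
                      substr(row$side, 1, 1), i)
        emit <- function(id2, dup) {
          if (row$side == "Left") {
            cut0 <- row$bridge_mod - frag + 1L
            add_pair(id2, row$contig, cut0, cut0 + rl, "+",
                     row$bridge_mod - rl + 1L, row$bridge_mod + 1L, "-", dup)
          } else {
            cut1 <- row$bridge_mod + frag - 1L
            add_pair(id2, row$contig, cut1 - rl + 1L, cut1 + 1L, "-",
                     row$bridge_mod, row$bridge_mod + rl, "+", dup)
          }
        }
        emit(id, FALSE)
        if (runif(1) < params$duplicate_rate) emit(paste0(id, ":d"), TRUE)
      }
    }
    if (params$n_background > 0L) {
      lens <- nchar(mseq)
      for (i in seq_len(params$n_background)) {
        cn <- sample(names(mseq), 1L, prob = lens)
        Lc <- lens[[cn]]
        frag <- params$fragment_min +
          sample.int(params$fragment_max - params$fragment_min + 1L, 1L) - 1L
        s <- sample.int(Lc - frag + 1L, 1L) - 1L
        id <- sprintf("%s:bg:%d", sample_name, i)
        if (runif(1) < 0.5) {
          add_pair(id, cn, s, s + rl, "+", s + frag - rl, s + frag, "-")
        } else {
          add_pair(id, cn, s + frag - rl, s + frag, "-", s, s + rl, "+")
        }
      }
    }
    if (params$me_prefix) {
      r1 <- setNames(paste0(.ME_SEQ, r1), names(r1))
    }
  })
  segs <- .truth_segments(meta, map, me_shift = if (params$me_prefix) nchar(.ME_SEQ) else 0L)
  out <- list(r1 = r1, r2 = r2, segments = segs, sample = sample_name)
  if (!is.null(dir)) {
    if (is.null(merged_ref)) stop("merged_ref required to write the truth SAM", call. = FALSE)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    f1 <- file.path(dir, paste0(sample_name, "_R1.fastq"))
    f2 <- file.path(dir, paste0(sample_name, "_R2.fastq"))
    write_fastq(r1, f1); write_fastq(r2, f2)
    fs <- file.path(dir, paste0(sample_name, ".truth.sam"))
    write_truth_sam(segs, reads = list(R1 = r1, R2 = r2),
                    merged_ref = merged_ref, path = fs)
    ft <- file.path(dir, paste0(sample_name, ".truth.tsv"))
    utils::write.table(implant$truth, ft, sep = "\t", quote = FALSE, row.names = FALSE)
    out$files <- c(r1 = f1, r2 = f2, sam = fs, truth = ft)
  }
  out
}

# Project each simulated read through the modified-to-source piece map into
# truth alignment segments on the merged reference. Segments shorter than
# 20 bp are not emitted (below the split-validity floor on every path); at
# most the two longest segments per read are kept, mirroring the extraction
# cap of the published pipeline.
.truth_segments <- function(meta, map, min_emit = 20L, max_segments = 2L,
                            me_shift = 0L) {
  map_df <- as.data.frame(map)
  map_by_contig <- split(map_df, map_df$contig)
  rows <- list()
  for (m in meta) {
    cmap <- map_by_contig[[m$contig]]
    for (mate in c("R1", "R2")) {
      if (mate == "R1") { s <- m$s1; e <- m$e1; st <- m$st1; err <- m$err1 }
      else { s <- m$s2; e <- m$e2; st <- m$st2; err <- m$err2 }
      L <- e - s + (if (mate == "R1") me_shift else 0L)
      shift <- if (mate == "R1") me_shift else 0L
      pm <- cmap[cmap$mod_end > s & cmap$mod_start < e & !is.na(cmap$src), , drop = FALSE]
      if (!nrow(pm)) next
      segs <- list()
      for (k in seq_len(nrow(pm))) {
        os <- max(s, pm$mod_start[k]); oe <- min(e, pm$mod_end[k])
        len <- oe - os
        if (len < min_emit) next
        if (st == "+") { q0 <- os - s; q1 <- oe - s } else { q0 <- e - oe; q1 <- e - os }
        if (pm$src_dir[k] == 1L) {
          ref0 <- pm$src_lo[k] + (os - pm$mod_start[k]); ref1 <- ref0 + len
          seg_strand <- st
        } else {
          ref0 <- pm$src_lo[k] + (pm$mod_end[k] - oe); ref1 <- ref0 + len
          seg_strand <- if (st == "+") "-" else "+"
        }
        q0 <- q0 + shift; q1 <- q1 + shift   # ME prefix offsets R1 query coords
        nm <- sum(err + 1L > q0 - shift & err + 1L <= q1 - shift)
        segs[[length(segs) + 1L]] <- data.frame(
          read_id = m$id, mate = mate, contig = pm$src[k],
          ref_start = ref0, ref_end = ref1, strand = seg_strand,
          read_start = q0, read_end = q1, read_len = L,
          n_mismatch = nm, stringsAsFactors = FALSE)
      }
      if (!length(segs)) next
      segs <- do.call(rbind, segs)
      segs <- segs[order(-(segs$read_end - segs$read_start)), , drop = FALSE]
      segs <- head(segs, max_segments)
      segs$is_supplementary <- c(FALSE, rep(TRUE, nrow(segs) - 1L))
      rows[[length(rows) + 1L]] <- segs
    }
  }
  if (!length(rows)) return(data.frame(
    read_id = character(0), mate = character(0), contig = character(0),
    ref_start = integer(0), ref_end = integer(0), strand = character(0),
    read_start = integer(0), read_end = integer(0), read_len = integer(0),
    n_mismatch = integer(0), is_supplementary = logical(0)))
  do.call(rbind, rows)
}

#' Write reads as FASTQ
#' @param reads named character vector.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  if (!length(reads)) { writeLines(character(0), path); return(invisible(path)) }
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  writeLines(as.vector(rbind(paste0("@", names(reads)), unname(reads), "+", qual)), path)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#' @param path FASTQ file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(ss), sub("\\s.*", "", names(ss)))
}
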