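# ---------------------------------------------------------------------------
# Flank extraction, anchor mapping and classification.
#
# For every IS occurrence the adjacent sequence windows (QIFs, query IS
# flanks) are extracted, mapped onto the other genome, anchor pairs are
# resolved, and the reference anchor flanks (RAFs) are interrogated for IS
# content.  Every occurrence ends in exactly one classification.

#' Classification vocabulary
#'
#' `DLIS`: IS present at this locus only in the genome where it was found.
#' `SLIS`: same (or related) IS at the homologous locus in both genomes.
#' `VERIFY_*`: candidate needing manual verification (related IS inside a
#' flank, consecutive ISs, or flanks matching multiple loci).
#' `DISCARD_*`: no anchor, anchors below coverage cutoffs, or flanks
#' anchoring to inconsistent loci.
#' @export
CLASSIFICATIONS <- c("DLIS", "SLIS", "VERIFY_RELATED_IS_IN_FLANK",
                     "VERIFY_CONSECUTIVE_IS", "VERIFY_UNSPECIFIC_MULTIHIT",
                     "DISCARD_NO_ANCHOR", "DISCARD_LOW_COVERAGE",
                     "DISCARD_CONTEXT_MISMATCH")

#' Extract query IS flanks (QIFs)
#'
#' With shift `S` and flank length `L = cfg$surroundingLen`, the left flank
#' of an occurrence `[start, end)` is `[start - S - L, start - S)` and the
#' right flank `[end + S, end + S + L)`, truncated at record boundaries.
#' Flanks shorter than `cfg$minLength` are marked absent; single-flank QIFs
#' arise at record ends (draft contigs).
#'
#' @param occurrences Occurrence table from [scan_is()].
#' @param asm The assembly the occurrences were found in.
#' @param cfg A [dlis_config()].
#' @return A QIF `data.frame` with flank intervals, sequences,
#'   `both_present` and `shift_applied`.
#' @export
extract_qifs <- function(occurrences, asm, cfg = dlis_config()) {
  L <- cfg$surroundingLen; S <- cfg$shift
  n <- nrow(occurrences)
  qif <- data.frame(occ_id = occurrences$occ_id,
                    record_id = occurrences$record_id,
                    is_name = occurrences$is_name,
                    left_start = NA_integer_, left_end = NA_integer_,
                    right_start = NA_integer_, right_end = NA_integer_,
                    left_seq = "", right_seq = "",
                    both_present = FALSE, related = "none",
                    shift_applied = S, stringsAsFactors = FALSE)
  if (!n) return(qif)
  for (i in seq_len(n)) {
    rec <- asm$records[[occurrences$record_id[i]]]
    len <- rec$length
    ls <- max(0L, occurrences$start[i] - S - L)
    le <- max(0L, occurrences$start[i] - S)
    rs <- min(len, occurrences$end[i] + S)
    re <- min(len, occurrences$end[i] + S + L)
    if (le - ls >= cfg$minLength) {
      qif$left_start[i] <- ls; qif$left_end[i] <- le
      qif$left_seq[i] <- substr(rec$sequence, ls + 1L, le)
    }
    if (re - rs >= cfg$minLength) {
      qif$right_start[i] <- rs; qif$right_end[i] <- re
      qif$right_seq[i] <- substr(rec$sequence, rs + 1L, re)
    }
  }
  qif$both_present <- nzchar(qif$left_seq) & nzchar(qif$right_seq)
  qif
}

# Relatedness of an IS library entry to the IS of an occurrence; "unknown"
# family/group labels never match.
relatedness <- function(occ_name, occ_family, occ_group,
                        ent_name, ent_family, ent_group) {
  if (ent_name == occ_name) return("same_is")
  if (!identical(occ_group, "unknown") && identical(ent_group, occ_group))
    return("same_group")
  if (!identical(occ_family, "unknown") &&
      identical(ent_family, occ_family)) return("same_family")
  "none"
}

related_rank <- c(none = 0L, same_family = 1L, same_group = 2L,
                  same_is = 3L)

#' Flag QIFs containing a related IS
#'
#' Flank sequences are searched against the IS library; a hit whose entry
#' shares the occurrence's name, group or family sets
#' `related` to the most specific matching level.  Unrelated IS hits leave
#' the flag at `"none"` (consecutive insertions of different ISs stay
#' resolvable).
#'
#' @param qifs QIF table from [extract_qifs()].
#' @param occurrences Matching occurrence table.
#' @param library An `is_library`.
#' @param cfg A [dlis_config()].
#' @return The QIF table with the `related` column filled in.
#' @export
flag_related_is <- function(qifs, occurrences, library,
                            cfg = dlis_config()) {
  queries <- character(0)
  for (i in seq_len(nrow(qifs))) {
    if (nzchar(qifs$left_seq[i]))
      queries[paste0("L_", qifs$occ_id[i])] <- qifs$left_seq[i]
    if (nzchar(qifs$right_seq[i]))
      queries[paste0("R_", qifs$occ_id[i])] <- qifs$right_seq[i]
  }
  if (!length(queries)) return(qifs)
  hits <- search_sequences(queries, setNames(library$sequence,
                                             library$name),
                           cfg, culling = 1L)
  if (!nrow(hits)) return(qifs)
  hit_occ <- as.integer(sub("^[LR]_", "", hits$query_id))
  for (i in seq_len(nrow(qifs))) {
    h <- hits[hit_occ == qifs$occ_id[i], , drop = FALSE]
    if (!nrow(h)) next
    oi <- match(qifs$occ_id[i], occurrences$occ_id)
    lev <- vapply(seq_len(nrow(h)), function(j) {
      ei <- match(h$subject_id[j], library$name)
      relatedness(occurrences$is_name[oi], occurrences$family[oi],
                  occurrences$group[oi], library$name[ei],
                  library$family[ei], library$group[ei])
    }, character(1))
    qifs$related[i] <- names(which.max(related_rank[lev]))
  }
  qifs
}

#' Map merged (concatenated) QIFs onto the reference genome
#'
#' Concatenated two-flank QIFs are searched against the reference; a QIF
#' with exactly one hit of query coverage above `cfg$min_anchor_qcov` maps
#' to a contiguous reference locus, i.e. the reference carries no IS there:
#' a direct DLIS candidate.  Direct-repeat offsets up to `cfg$dr_max` do
#' not defeat the coverage test.  All other QIFs fall through to per-side
#' anchor mapping.
#'
#' @param qifs QIF table (only `both_present` rows are used).
#' @param reference Reference [assembly()].
#' @param cfg A [dlis_config()].
#' @return A list keyed by `occ_id` (as character) with elements
#'   `record_id, s_start, s_end, s_strand, point`, for resolved QIFs only.
#' @export
map_merged <- function(qifs, reference, cfg = dlis_config()) {
  idx <- which(qifs$both_present)
  if (!length(idx)) return(list())
  queries <- setNames(paste0(qifs$left_seq[idx], qifs$right_seq[idx]),
                      paste0("M_", qifs$occ_id[idx]))
  hits <- search_sequences(queries, assembly_seqs(reference), cfg)
  out <- list()
  for (i in idx) {
    h <- hits[hits$query_id == paste0("M_", qifs$occ_id[i]) &
                hits$qcovhsp > cfg$min_anchor_qcov &
                hits$aln_length >= cfg$minAlnLength, , drop = FALSE]
    if (nrow(h) != 1L) next
    left_len <- qifs$left_end[i] - qifs$left_start[i]
    off <- min(max(left_len - h$q_start, 0L), h$q_end - h$q_start)
    point <- if (h$s_strand > 0) h$s_start + off else h$s_end - off
    out[[as.character(qifs$occ_id[i])]] <-
      list(record_id = h$subject_id, s_start = h$s_start, s_end = h$s_end,
           s_strand = h$s_strand, point = as.integer(point))
  }
  out
}

#' Map per-side QIF anchors onto the reference genome
#'
#' Each flank is searched independently; hits must have query coverage
#' above `cfg$min_anchor_qcov` and alignment length at least
#' `cfg$minAlnLength`.  Two-flank QIFs need a unique consistent pair of
#' anchors on one reference record (same strand, correct order); the pair
#' gap is scored against the two expected values `2*shift` (no IS in the
#' reference) and `2*shift + IS length` (IS present), and a unique minimum
#' wins.  Single-flank QIFs need exactly one passing hit.
#'
#' @param qifs QIF table from [extract_qifs()].
#' @param reference Reference [assembly()].
#' @param occurrences Matching occurrence table.
#' @param library The IS library (for expected IS lengths).
#' @param cfg A [dlis_config()].
#' @return A list keyed by `occ_id` (character) with `status` one of
#'   `paired, single, unspecific, no_anchor, low_coverage,
#'   context_mismatch` plus anchor coordinates where resolved.
#' @export
map_side_anchors <- function(qifs, reference, occurrences, library,
                             cfg = dlis_config()) {
  queries <- character(0)
  for (i in seq_len(nrow(qifs))) {
    if (nzchar(qifs$left_seq[i]))
      queries[paste0("L_", qifs$occ_id[i])] <- qifs$left_seq[i]
    if (nzchar(qifs$right_seq[i]))
      queries[paste0("R_", qifs$occ_id[i])] <- qifs$right_seq[i]
  }
  hits <- if (length(queries))
    search_sequences(queries, assembly_seqs(reference), cfg)
  else empty_hits()
  pass <- hits[hits$qcovhsp > cfg$min_anchor_qcov &
                 hits$aln_length >= cfg$minAlnLength, , drop = FALSE]
  base_gap <- 2L * cfg$shift
  out <- list()
  for (i in seq_len(nrow(qifs))) {
    oid <- qifs$occ_id[i]
    key <- as.character(oid)
    has_l <- nzchar(qifs$left_seq[i]); has_r <- nzchar(qifs$right_seq[i])
    if (!has_l && !has_r) {
      out[[key]] <- list(status = "no_anchor"); next
    }
    raw_l <- hits[hits$query_id == paste0("L_", oid), , drop = FALSE]
    raw_r <- hits[hits$query_id == paste0("R_", oid), , drop = FALSE]
    ok_l <- pass[pass$query_id == paste0("L_", oid), , drop = FALSE]
    ok_r <- pass[pass$query_id == paste0("R_", oid), , drop = FALSE]
    oi <- match(oid, occurrences$occ_id)
    is_len <- nchar(library$sequence)[match(occurrences$is_name[oi],
                                            library$name)]
    if (is.na(is_len)) is_len <- occurrences$end[oi] - occurrences$start[oi]
    max_is <- max(nchar(library$sequence))
    if (has_l && has_r) {
      if (!nrow(raw_l) || !nrow(raw_r)) {
        out[[key]] <- list(status = "no_anchor"); next
      }
      if (!nrow(ok_l) || !nrow(ok_r)) {
        out[[key]] <- list(status = "low_coverage"); next
      }
      cand <- list(); scores <- numeric(0)
      for (a in seq_len(nrow(ok_l))) for (b in seq_len(nrow(ok_r))) {
        l <- ok_l[a, ]; r <- ok_r[b, ]
        if (l$subject_id != r$subject_id || l$s_strand != r$s_strand) next
        gap <- if (l$s_strand > 0) r$s_start - l$s_end
               else l$s_start - r$s_end
        # the reference locus may be anywhere from contiguous (novel query
        # sequence between the flanks, gap ~ 0) up to IS-present at the
        # shifted distance (gap ~ 2*shift + IS length)
        if (gap < -cfg$dr_max - 10L || gap > base_gap + max_is + 100L) next
        cand[[length(cand) + 1L]] <- list(l = l, r = r, gap = gap)
        scores <- c(scores, min(abs(gap - base_gap),
                                abs(gap - (base_gap + is_len))))
      }
      if (!length(cand)) {
        out[[key]] <- list(status = "context_mismatch"); next
      }
      best <- which(scores == min(scores))
      if (length(best) > 1L) {
        out[[key]] <- list(status = "unspecific"); next
      }
      p <- cand[[best]]
      inner_l <- if (p$l$s_strand > 0) p$l$s_end else p$l$s_start
      point <- if (p$l$s_strand > 0) inner_l + cfg$shift
               else inner_l - cfg$shift
      out[[key]] <- list(status = "paired",
                         record_id = p$l$subject_id,
                         s_start = min(p$l$s_start, p$r$s_start),
                         s_end = max(p$l$s_end, p$r$s_end),
                         s_strand = p$l$s_strand, gap = p$gap,
                         inner_left = if (p$l$s_strand > 0) p$l$s_end
                                      else p$r$s_end,
                         inner_right = if (p$l$s_strand > 0) p$r$s_start
                                       else p$l$s_start,
                         point = as.integer(point))
    } else {
      side <- if (has_l) "left" else "right"
      raw1 <- if (has_l) raw_l else raw_r
      ok1 <- if (has_l) ok_l else ok_r
      if (!nrow(raw1)) { out[[key]] <- list(status = "no_anchor"); next }
      if (!nrow(ok1)) { out[[key]] <- list(status = "low_coverage"); next }
      if (nrow(ok1) > 1L) { out[[key]] <- list(status = "unspecific"); next }
      h <- ok1[1, ]
      # direction in which the IS is expected from the anchor
      dir_right <- (side == "left") == (h$s_strand > 0)
      edge <- if (dir_right) h$s_end else h$s_start
      point <- if (dir_right) edge + cfg$shift else edge - cfg$shift
      out[[key]] <- list(status = "single", record_id = h$subject_id,
                         s_start = h$s_start, s_end = h$s_end,
                         s_strand = h$s_strand, side = side,
                         dir_right = dir_right, edge = edge,
                         point = as.integer(point))
    }
  }
  out
}

#' Interrogate reference anchor flanks (RAFs) for IS content
#'
#' For paired anchors the region between the two inner anchor edges is
#' searched against the IS library; for single anchors a window of length
#' `shift + max IS length + surroundingLen` on the side where the IS would
#' sit.  A related IS (same name, group or family) at the anchored position
#' means the insertion is present in both genomes (`SLIS`); otherwise the
#' occurrence is differentially located (`DLIS`).
#'
#' @param anchors Anchor list from [map_side_anchors()] (entries with
#'   status `paired` or `single`).
#' @param reference Reference [assembly()].
#' @param library An `is_library`.
#' @param occurrences Matching occurrence table.
#' @param cfg A [dlis_config()].
#' @return Named character vector (`occ_id` -> `"DLIS"`/`"SLIS"`).
#' @export
interrogate_raf <- function(anchors, reference, library, occurrences,
                            cfg = dlis_config()) {
  max_is <- max(nchar(library$sequence))
  regions <- character(0); meta <- list()
  for (key in names(anchors)) {
    a <- anchors[[key]]
    if (!a$status %in% c("paired", "single")) next
    rec <- reference$records[[a$record_id]]
    if (a$status == "paired") {
      lo <- max(0L, a$inner_left - cfg$dr_max)
      hi <- min(rec$length, a$inner_right + cfg$dr_max)
      expect_off <- cfg$shift + (a$inner_left - lo)
    } else {
      if (a$dir_right) {
        lo <- a$edge
        hi <- min(rec$length, a$edge + cfg$shift + max_is +
                    cfg$surroundingLen)
        expect_off <- cfg$shift
      } else {
        hi <- a$edge
        lo <- max(0L, a$edge - cfg$shift - max_is - cfg$surroundingLen)
        expect_off <- cfg$shift  # distance from hi, measured from the end
      }
    }
    if (hi - lo < 50L) { meta[[key]] <- NULL; next }
    regions[paste0("RAF_", key)] <- substr(rec$sequence, lo + 1L, hi)
    meta[[key]] <- list(lo = lo, hi = hi, a = a, expect_off = expect_off)
  }
  out <- setNames(rep("DLIS", length(anchors)), names(anchors))
  resolved <- vapply(anchors, function(a)
    a$status %in% c("paired", "single"), logical(1))
  out <- out[resolved]
  if (!length(regions)) return(out)
  hits <- search_sequences(regions, setNames(library$sequence,
                                             library$name),
                           cfg, culling = 1L)
  for (key in names(meta)) {
    if (is.null(meta[[key]])) next
    h <- hits[hits$query_id == paste0("RAF_", key), , drop = FALSE]
    if (!nrow(h)) next
    info <- meta[[key]]
    oi <- match(as.integer(key), occurrences$occ_id)
    width <- info$hi - info$lo
    for (j in seq_len(nrow(h))) {
      ei <- match(h$subject_id[j], library$name)
      lev <- relatedness(occurrences$is_name[oi], occurrences$family[oi],
                         occurrences$group[oi], library$name[ei],
                         library$family[ei], library$group[ei])
      if (lev == "none") next
      ent_len <- nchar(library$sequence[ei])
      # partial ISs at region (scaffold) edges count as present
      at_edge <- h$q_start[j] <= cfg$scaffoldDiff ||
        h$q_end[j] >= width - cfg$scaffoldDiff
      if (h$aln_length[j] < cfg$is_len_fraction * ent_len && !at_edge) next
      positioned <- if (info$a$status == "paired") TRUE
      else if (info$a$dir_right)
        abs(h$q_start[j] - info$expect_off) <= cfg$raf_edge_tol
      else
        abs((width - h$q_end[j]) - info$expect_off) <= cfg$raf_edge_tol
      if (positioned) { out[key] <- "SLIS"; break }
    }
  }
  out
}

#' Classify every IS occurrence of one comparison direction
#'
#' Runs the full flank-analysis chain (QIF extraction, related-IS flag,
#' merged mapping, per-side anchor mapping, RAF interrogation) and assigns
#' exactly one classification per occurrence.  Verify-precedence when
#' several conditions hold: related IS in flank, then consecutive IS, then
#' unspecific multi-hit.
#'
#' @param occurrences Occurrence table (with `consecutive` flags set).
#' @param query Assembly the occurrences belong to.
#' @param reference Assembly searched for homologous loci.
#' @param library An `is_library`.
#' @param cfg A [dlis_config()].
#' @return A `data.frame` with one row per occurrence: coordinates,
#'   classification, anchor locus and hit quality.
#' @export
classify_occurrences <- function(occurrences, query, reference, library,
                                 cfg = dlis_config()) {
  n <- nrow(occurrences)
  rows <- data.frame(occ_id = occurrences$occ_id,
                     is_name = occurrences$is_name,
                     family = occurrences$family,
                     is_record = occurrences$record_id,
                     is_start = occurrences$start,
                     is_end = occurrences$end,
                     partial = occurrences$partial,
                     consecutive = occurrences$consecutive,
                     related = rep("none", n),
                     classification = rep("DISCARD_NO_ANCHOR", n),
                     hit_quality = rep("partial", n),
                     anchor_record = rep(NA_character_, n),
                     anchor_start = rep(NA_integer_, n),
                     anchor_end = rep(NA_integer_, n),
                     anchor_point = rep(NA_integer_, n),
                     anchor_strand = rep(NA_integer_, n),
                     left_flank_start = rep(NA_integer_, n),
                     left_flank_end = rep(NA_integer_, n),
                     right_flank_start = rep(NA_integer_, n),
                     right_flank_end = rep(NA_integer_, n),
                     stringsAsFactors = FALSE)
  if (!n) return(rows)
  qifs <- extract_qifs(occurrences, query, cfg)
  qifs <- flag_related_is(qifs, occurrences, library, cfg)
  rows$related <- qifs$related
  rows$left_flank_start <- qifs$left_start
  rows$left_flank_end <- qifs$left_end
  rows$right_flank_start <- qifs$right_start
  rows$right_flank_end <- qifs$right_end

  merged <- map_merged(qifs, reference, cfg)
  unresolved <- qifs[!(qifs$occ_id %in% as.integer(names(merged))), ,
                     drop = FALSE]
  anchors <- map_side_anchors(unresolved, reference, occurrences, library,
                              cfg)
  raf <- interrogate_raf(anchors, reference, library, occurrences, cfg)

  for (i in seq_len(n)) {
    key <- as.character(occurrences$occ_id[i])
    if (key %in% names(merged)) {
      m <- merged[[key]]
      rows$classification[i] <- "DLIS"
      rows$hit_quality[i] <- "full"
      rows$anchor_record[i] <- m$record_id
      rows$anchor_start[i] <- m$s_start
      rows$anchor_end[i] <- m$s_end
      rows$anchor_point[i] <- m$point
      rows$anchor_strand[i] <- m$s_strand
    } else if (key %in% names(anchors)) {
      a <- anchors[[key]]
      cls <- switch(a$status,
                    paired = raf[[key]],
                    single = raf[[key]],
                    unspecific = "VERIFY_UNSPECIFIC_MULTIHIT",
                    no_anchor = "DISCARD_NO_ANCHOR",
                    low_coverage = "DISCARD_LOW_COVERAGE",
                    context_mismatch = "DISCARD_CONTEXT_MISMATCH")
      rows$classification[i] <- cls
      rows$hit_quality[i] <- if (identical(a$status, "paired")) "full"
                             else "partial"
      if (a$status %in% c("paired", "single")) {
        rows$anchor_record[i] <- a$record_id
        rows$anchor_start[i] <- a$s_start
        rows$anchor_end[i] <- a$s_end
        rows$anchor_point[i] <- a$point
        rows$anchor_strand[i] <- a$s_strand
      }
    }
    # verify-demotion, most actionable cause first
    cls <- rows$classification[i]
    if (cls %in% c("DLIS", "SLIS", "VERIFY_UNSPECIFIC_MULTIHIT")) {
      if (rows$related[i] != "none")
        rows$classification[i] <- "VERIFY_RELATED_IS_IN_FLANK"
      else if (rows$consecutive[i])
        rows$classification[i] <- "VERIFY_CONSECUTIVE_IS"
    }
  }
  rows
}
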