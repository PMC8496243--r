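# ---------------------------------------------------------------------------
# IS occurrence detection: identical-scaffold removal, IS scanning,
# IS-only-scaffold removal and consecutive-IS tagging.

union_width <- function(starts, ends) {
  if (!length(starts)) return(0L)
  sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(start = starts + 1L, end = ends))))
}

#' Remove query scaffolds identical to a reference scaffold
#'
#' A query record is removed when some reference record produces an HSP
#' covering more than `cfg$identical_qcov` percent of the query and the
#' union of all HSPs against that reference record leaves fewer than
#' `cfg$identical_max_unaligned` query nucleotides unaligned.
#'
#' @param query,reference [assembly()] objects.
#' @param cfg A [dlis_config()].
#' @return A list with `retained` (an assembly, or `NULL` when every record
#'   was removed), `removed` (a `data.frame` of removed query records and
#'   the matching reference record) and `hits` (the raw genome-vs-genome
#'   hits, reusable by callers).
#' @export
filter_identical_scaffolds <- function(query, reference,
                                       cfg = dlis_config()) {
  stopifnot(inherits(query, "assembly"), inherits(reference, "assembly"))
  hits <- search_sequences(assembly_seqs(query), assembly_seqs(reference),
                           cfg)
  removed_id <- character(0); matched_ref <- character(0)
  for (qid in names(query$records)) {
    qlen <- query$records[[qid]]$length
    h <- hits[hits$query_id == qid, , drop = FALSE]
    for (sid in unique(h$subject_id)) {
      hs <- h[h$subject_id == sid, , drop = FALSE]
      best_qcov <- max(hs$qcovhsp)
      unaligned <- qlen - union_width(hs$q_start, hs$q_end)
      if (best_qcov > cfg$identical_qcov &&
          unaligned < cfg$identical_max_unaligned) {
        removed_id <- c(removed_id, qid)
        matched_ref <- c(matched_ref, sid)
        break
      }
    }
  }
  retained <- setdiff(names(query$records), removed_id)
  list(retained = if (length(retained))
         assembly(query$records[retained], label = query$label) else NULL,
       removed = data.frame(record_id = removed_id,
                            reference_record = matched_ref,
                            stringsAsFactors = FALSE),
       hits = hits)
}

#' Scan a genome for IS occurrences
#'
#' Searches every record against the IS library (culling limit 1, so one
#' retained hit per genomic region) and converts the retained hits into IS
#' occurrences.  Hits shorter than `cfg$is_len_fraction` of the library IS
#' length are discarded unless they lie within `cfg$scaffoldDiff` of a
#' scaffold end, where partial ISs are expected on draft assemblies.
#' Occurrence intervals are the hit footprint on the genome.
#'
#' @param asm An [assembly()].
#' @param library An `is_library`.
#' @param cfg A [dlis_config()].
#' @return A `data.frame` of occurrences: `occ_id, record_id, start, end,
#'   is_name, family, group, partial, identity_pct, evalue, aln_length,
#'   consecutive`.
#' @export
scan_is <- function(asm, library, cfg = dlis_config()) {
  stopifnot(inherits(asm, "assembly"), inherits(library, "is_library"))
  hits <- search_sequences(assembly_seqs(asm),
                           setNames(library$sequence, library$name),
                           cfg, culling = 1L)
  occ <- empty_occurrences()
  if (!nrow(hits)) return(occ)
  rec_len <- vapply(asm$records, function(r) r$length,
                    integer(1))[hits$query_id]
  lib_len <- nchar(library$sequence)[match(hits$subject_id, library$name)]
  at_start <- hits$q_start <= cfg$scaffoldDiff
  at_end <- hits$q_end >= rec_len - cfg$scaffoldDiff
  keep <- hits$aln_length >= cfg$is_len_fraction * lib_len |
    at_start | at_end
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits)) return(occ)
  at_start <- at_start[keep]; at_end <- at_end[keep]
  lib_idx <- match(hits$subject_id, library$name)
  occ <- data.frame(occ_id = seq_len(nrow(hits)),
                    record_id = hits$query_id,
                    start = hits$q_start, end = hits$q_end,
                    is_name = hits$subject_id,
                    family = library$family[lib_idx],
                    group = library$group[lib_idx],
                    partial = at_start | at_end,
                    identity_pct = hits$identity_pct,
                    evalue = hits$evalue,
                    aln_length = hits$aln_length,
                    consecutive = FALSE,
                    stringsAsFactors = FALSE)
  occ <- occ[order(occ$record_id, occ$start), , drop = FALSE]
  occ$occ_id <- seq_len(nrow(occ))
  rownames(occ) <- NULL
  occ
}

empty_occurrences <- function() {
  data.frame(occ_id = integer(), record_id = character(), start = integer(),
             end = integer(), is_name = character(), family = character(),
             group = character(), partial = logical(),
             identity_pct = numeric(), evalue = numeric(),
             aln_length = integer(), consecutive = logical(),
             stringsAsFactors = FALSE)
}

#' Drop scaffolds that consist mostly of IS sequence
#'
#' A record is dropped when fewer than `cfg$ISdiff` of its nucleotides lie
#' outside the union of its IS hits; small draft contigs made of IS
#' sequence carry no usable flanks.
#'
#' @param asm An [assembly()].
#' @param occurrences Occurrence table from [scan_is()] on `asm`.
#' @param cfg A [dlis_config()].
#' @return A list with `retained` (assembly or `NULL`) and `dropped`
#'   (character vector of record ids).
#' @export
drop_is_only_scaffolds <- function(asm, occurrences, cfg = dlis_config()) {
  dropped <- character(0)
  for (rid in names(asm$records)) {
    o <- occurrences[occurrences$record_id == rid, , drop = FALSE]
    if (!nrow(o)) next
    non_is <- asm$records[[rid]]$length - union_width(o$start, o$end)
    if (non_is < cfg$ISdiff) dropped <- c(dropped, rid)
  }
  retained <- setdiff(names(asm$records), dropped)
  list(retained = if (length(retained))
         assembly(asm$records[retained], label = asm$label) else NULL,
       dropped = dropped)
}

#' Tag consecutive IS occurrences
#'
#' Adjacent occurrences on the same record separated by at most
#' `cfg$consecutive_gap` nucleotides are tagged as a consecutive pair;
#' their flanks overlap another IS, which is a known false-positive mode
#' resolved by manual verification.
#'
#' @param occurrences Occurrence table from [scan_is()].
#' @param cfg A [dlis_config()].
#' @return A list with `pairs` (a `data.frame` of tagged pairs) and
#'   `occurrences` (the input table with the `consecutive` flag set).
#' @export
tag_consecutive <- function(occurrences, cfg = dlis_config()) {
  pairs <- data.frame(record_id = character(), occ_id_1 = integer(),
                      is_name_1 = character(), start_1 = integer(),
                      end_1 = integer(), occ_id_2 = integer(),
                      is_name_2 = character(), start_2 = integer(),
                      end_2 = integer(), gap = integer(),
                      stringsAsFactors = FALSE)
  occ <- occurrences[order(occurrences$record_id, occurrences$start), ,
                     drop = FALSE]
  for (rid in unique(occ$record_id)) {
    o <- occ[occ$record_id == rid, , drop = FALSE]
    if (nrow(o) < 2) next
    gap <- o$start[-1] - o$end[-nrow(o)]
    tagged <- which(gap <= cfg$consecutive_gap)
    for (i in tagged) {
      pairs <- rbind(pairs, data.frame(
        record_id = rid, occ_id_1 = o$occ_id[i], is_name_1 = o$is_name[i],
        start_1 = o$start[i], end_1 = o$end[i], occ_id_2 = o$occ_id[i + 1],
        is_name_2 = o$is_name[i + 1], start_2 = o$start[i + 1],
        end_2 = o$end[i + 1], gap = gap[i], stringsAsFactors = FALSE))
    }
  }
  occurrences$consecutive <- occurrences$occ_id %in%
    c(pairs$occ_id_1, pairs$occ_id_2)
  list(pairs = pairs, occurrences = occurrences)
}
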