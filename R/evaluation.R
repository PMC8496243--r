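# ---------------------------------------------------------------------------
# Scoring a comparison against a simulator truth table, and parameter
# sweeps.

#' Score a comparison result against a simulation truth table
#'
#' A reported site is a true positive when its IS interval on the query
#' genome overlaps `[p - tolerance, p + is_length + tsd + tolerance]` for a
#' truth insertion at (modified-genome) position `p`, matched one-to-one
#' greedily by midpoint distance.  Scores are computed for two calling
#' modes: `DLIS` (high-confidence calls only) and `DLIS+VERIFY` (the
#' pooled verify-manually categories added, the high-sensitivity set).
#'
#' @param result A `comparison_result` whose query genome was produced by
#'   [simulate_insertions()], or a plain `data.frame` of result rows with
#'   columns `found_in`, `classification`, `is_record`, `is_start`,
#'   `is_end` (0-based half-open).
#' @param truth Truth table from [simulate_insertions()].
#' @param tolerance Matching tolerance in nt (default 50).
#' @param fragment_map Optional `fragment_map` attribute from
#'   [fragment_assembly()], used to project contig coordinates back onto
#'   the unfragmented genome.
#' @return An object of class `eval_report`: `data.frame` with one row per
#'   mode (`tp`, `fp`, `fn`, `sensitivity`, `precision`).
#' @export
score_against_truth <- function(result, truth, tolerance = 50L,
                                fragment_map = NULL) {
  rows <- if (inherits(result, "comparison_result")) result$dlis_records
          else result
  rows <- rows[rows$found_in == "query", , drop = FALSE]
  if (!is.null(fragment_map)) {
    m <- match(rows$is_record, fragment_map$record_id)
    ok <- !is.na(m)
    rows$is_record[ok] <- fragment_map$source_record[m[ok]]
    rows$is_start[ok] <- rows$is_start[ok] + fragment_map$offset[m[ok]]
    rows$is_end[ok] <- rows$is_end[ok] + fragment_map$offset[m[ok]]
  }
  modes <- list(DLIS = "DLIS",
                `DLIS+VERIFY` = c("DLIS", "VERIFY_RELATED_IS_IN_FLANK",
                                  "VERIFY_CONSECUTIVE_IS",
                                  "VERIFY_UNSPECIFIC_MULTIHIT"))
  out <- NULL
  matches <- list()
  for (mode in names(modes)) {
    rep_rows <- rows[rows$classification %in% modes[[mode]], , drop = FALSE]
    sc <- match_reports(rep_rows, truth, tolerance)
    out <- rbind(out, data.frame(mode = mode, tp = sc$tp, fp = sc$fp,
                                 fn = sc$fn,
                                 sensitivity = sc$tp / (sc$tp + sc$fn),
                                 precision = if (sc$tp + sc$fp > 0)
                                   sc$tp / (sc$tp + sc$fp) else NA_real_,
                                 stringsAsFactors = FALSE))
    matches[[mode]] <- sc$pairs
  }
  rownames(out) <- NULL
  structure(list(scores = out, matches = matches, tolerance = tolerance),
            class = "eval_report")
}

match_reports <- function(rep_rows, truth, tolerance) {
  nr <- nrow(rep_rows); nt <- nrow(truth)
  if (!nr) return(list(tp = 0L, fp = 0L, fn = nt, pairs = NULL))
  t_lo <- truth$position_modified - tolerance
  t_hi <- truth$position_modified + truth$is_length + truth$tsd_length +
    tolerance
  t_mid <- (t_lo + t_hi) / 2
  r_mid <- (rep_rows$is_start + rep_rows$is_end) / 2
  cand <- NULL
  for (i in seq_len(nr)) {
    j <- which(truth$record_id == rep_rows$is_record[i] &
                 rep_rows$is_end[i] > t_lo & rep_rows$is_start[i] < t_hi)
    if (length(j))
      cand <- rbind(cand, data.frame(r = i, t = j,
                                     d = abs(r_mid[i] - t_mid[j])))
  }
  used_r <- logical(nr); used_t <- logical(nt); tp <- 0L
  pairs <- NULL
  if (!is.null(cand)) {
    cand <- cand[order(cand$d, cand$t), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      i <- cand$r[k]; j <- cand$t[k]
      if (used_r[i] || used_t[j]) next
      used_r[i] <- TRUE; used_t[j] <- TRUE; tp <- tp + 1L
      pairs <- rbind(pairs, data.frame(report = i, truth = j,
                                       distance = cand$d[k]))
    }
  }
  list(tp = tp, fp = nr - tp, fn = nt - tp, pairs = pairs)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> tolerance", x$tolerance, "nt\n")
  print(x$scores, row.names = FALSE)
  invisible(x)
}

#' Sweep one configuration parameter
#'
#' Reruns the full comparison and scoring for each value of one
#' configuration parameter (the published protocol sweeps
#' `surroundingLen` from 100 to 2000 in steps of 100).
#'
#' @param base_cfg A [dlis_config()] providing all other parameters.
#' @param param Name of the parameter to sweep.
#' @param grid Vector of values.
#' @param query,reference,library Comparison inputs.
#' @param truth Simulation truth table for scoring.
#' @param tolerance Matching tolerance (nt).
#' @return A `data.frame`: one row per grid value and scoring mode.
#' @export
sweep_parameter <- function(base_cfg, param, grid, query, reference,
                            library, truth, tolerance = 50L) {
  stopifnot(length(grid) > 0, param %in% names(base_cfg))
  out <- NULL
  for (v in grid) {
    args <- unclass(base_cfg)
    args[[param]] <- v
    if (param == "surroundingLen") args$consecutive_gap <- NULL
    cfg <- do.call(dlis_config, args)
    res <- run_comparison(query, reference, library, cfg)
    sc <- score_against_truth(res, truth, tolerance)$scores
    sc <- cbind(data.frame(value = v), sc)
    names(sc)[1] <- param
    out <- rbind(out, sc)
  }
  rownames(out) <- NULL
  out
}
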