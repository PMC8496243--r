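# ---------------------------------------------------------------------------
# Run configuration: one object carries every tunable of the pipeline.

#' Pipeline configuration
#'
#' Returns the configuration object used by every stage of the comparison.
#' Defaults follow the published parameter optimisation of the method:
#'
#' * `surroundingLen` (500 nt): flank length extracted on each side of a
#'   detected IS (QIF length).
#' * `shift` (0 nt): shift mode; enlarges the masked IS region so flanks are
#'   taken `shift` nt away from the IS, rescuing IS-adjacent repeats.
#' * `evalue_cutoff` (1e-10): E-value cutoff for every homology search.
#' * `identical_qcov` (99 %) and `identical_max_unaligned` (20 nt): a query
#'   scaffold is removed as identical to a reference scaffold when some HSP
#'   covers more than `identical_qcov` percent of it and fewer than
#'   `identical_max_unaligned` nucleotides are left out of the union of all
#'   HSPs.
#' * `min_anchor_qcov` (90 %): minimum query coverage for a QIF (or merged
#'   QIF) hit to count as an anchor.
#' * `is_len_fraction` (1/3): IS hits shorter than this fraction of the
#'   library IS length are discarded, except at scaffold ends.
#' * `minLength` (50 nt): minimum flank length to be used at all.
#' * `minAlnLength` (50 nt): minimum alignment length for an anchor hit.
#' * `ISdiff` (50 nt): scaffolds with fewer than `ISdiff` non-IS
#'   nucleotides are dropped.
#' * `scaffoldDiff` (20 nt): distance to a scaffold end within which an IS
#'   hit counts as terminal (partial).
#' * `consecutive_gap` (`2 * surroundingLen`): maximum distance between two
#'   IS occurrences for them to be tagged as consecutive.
#' * `dr_max` (14 nt): largest direct-repeat/target-site duplication
#'   allowed for in anchor-gap arithmetic.
#' * `raf_edge_tol` (50 nt): how close to the anchored position an IS found
#'   in a reference anchor flank must start to call the same-location case.
#' * `backend`: `"external"` (BLAST+ blastn) or `"builtin"` (bundled
#'   seed-and-extend engine).
#'
#' @param surroundingLen Flank length in nt.
#' @param shift Shift-mode displacement in nt.
#' @param evalue_cutoff E-value cutoff.
#' @param identical_qcov Identical-scaffold HSP coverage threshold (%).
#' @param identical_max_unaligned Identical-scaffold unaligned-nt threshold.
#' @param min_anchor_qcov Anchor query-coverage threshold (%).
#' @param is_len_fraction Minimum hit length as a fraction of IS length.
#' @param minLength Minimum flank length (nt).
#' @param minAlnLength Minimum anchor alignment length (nt).
#' @param ISdiff Minimum non-IS nucleotides for a scaffold to be kept.
#' @param scaffoldDiff Scaffold-end tolerance (nt).
#' @param consecutive_gap Consecutive-IS gap (nt); default
#'   `2 * surroundingLen`.
#' @param dr_max Maximum direct-repeat length (nt).
#' @param raf_edge_tol RAF edge tolerance (nt).
#' @param backend Search backend, `"external"` or `"builtin"`.
#' @param word_size Optional word size passed to the search engine.
#' @param seed Optional RNG seed used by sampling helpers.
#' @return An object of class `dlis_config`.
#' @export
dlis_config <- function(surroundingLen = 500L, shift = 0L,
                        evalue_cutoff = 1e-10, identical_qcov = 99,
                        identical_max_unaligned = 20L, min_anchor_qcov = 90,
                        is_len_fraction = 1 / 3, minLength = 50L,
                        minAlnLength = 50L, ISdiff = 50L, scaffoldDiff = 20L,
                        consecutive_gap = NULL, dr_max = 14L,
                        raf_edge_tol = 50L,
                        backend = c("external", "builtin"),
                        word_size = NULL, seed = NULL) {
  backend <- match.arg(backend)
  if (is.null(consecutive_gap)) consecutive_gap <- 2L * surroundingLen
  cfg <- list(surroundingLen = as.integer(surroundingLen),
              shift = as.integer(shift),
              evalue_cutoff = evalue_cutoff,
              identical_qcov = identical_qcov,
              identical_max_unaligned = as.integer(identical_max_unaligned),
              min_anchor_qcov = min_anchor_qcov,
              is_len_fraction = is_len_fraction,
              minLength = as.integer(minLength),
              minAlnLength = as.integer(minAlnLength),
              ISdiff = as.integer(ISdiff),
              scaffoldDiff = as.integer(scaffoldDiff),
              consecutive_gap = as.integer(consecutive_gap),
              dr_max = as.integer(dr_max),
              raf_edge_tol = as.integer(raf_edge_tol),
              backend = backend,
              word_size = word_size,
              seed = seed)
  stopifnot(cfg$surroundingLen > 0L, cfg$shift >= 0L, cfg$evalue_cutoff > 0,
            cfg$identical_qcov > 0, cfg$identical_qcov <= 100,
            cfg$identical_max_unaligned >= 0L,
            cfg$min_anchor_qcov > 0, cfg$min_anchor_qcov <= 100,
            cfg$is_len_fraction > 0, cfg$is_len_fraction <= 1,
            cfg$minLength >= 0L, cfg$minAlnLength >= 0L, cfg$ISdiff >= 0L,
            cfg$scaffoldDiff >= 0L, cfg$consecutive_gap >= 0L,
            cfg$dr_max >= 0L, cfg$raf_edge_tol >= 0L)
  structure(cfg, class = "dlis_config")
}

#' @export
print.dlis_config <- function(x, ...) {
  cat("<dlis_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-24s %s\n", k,
                if (is.null(v)) "NULL" else format(v, digits = 6)))
  }
  invisible(x)
}

# Evaluate a seed expression reproducibly without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
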