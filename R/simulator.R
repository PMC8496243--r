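# ---------------------------------------------------------------------------
# IS insertion simulator, synthetic genome generator and draft fragmentation.

#' Simulation specification
#'
#' @param n_insertions Number of IS copies to insert (>= 1).
#' @param tsd_length Target-site duplication length in nt (default 0).
#' @param min_spacing Minimum distance between insertion points and to
#'   record ends (default 0 = unconstrained, matching unrestricted random
#'   placement).
#' @param orientation_policy `"random"` or `"forward"`.
#' @param seed RNG seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_insertions, tsd_length = 0L, min_spacing = 0L,
                            orientation_policy = c("random", "forward"),
                            seed = NULL) {
  orientation_policy <- match.arg(orientation_policy)
  stopifnot(n_insertions >= 1L, tsd_length >= 0L, min_spacing >= 0L)
  structure(list(n_insertions = as.integer(n_insertions),
                 tsd_length = as.integer(tsd_length),
                 min_spacing = as.integer(min_spacing),
                 orientation_policy = orientation_policy,
                 seed = seed),
            class = "simulation_spec")
}

# Sample n points in [lo, hi) with pairwise distance >= gap, uniformly via
# the spacing transform (order statistics of a shrunk interval).
sample_spaced_points <- function(n, lo, hi, gap) {
  span <- (hi - lo) - (n - 1) * gap
  if (span <= 0)
    stop("infeasible spacing: cannot place ", n, " points with spacing ",
         gap, " in [", lo, ", ", hi, ")", call. = FALSE)
  u <- sort(runif(n, 0, span))
  as.integer(floor(lo + u + (seq_len(n) - 1) * gap))
}

#' Insert IS copies at random genomic locations
#'
#' Plants `spec$n_insertions` copies of one IS at randomly chosen positions
#' of a genome.  At each sampled point `p` the inserted sequence is the IS
#' (reverse-complemented for minus orientation) followed by a duplication
#' of the `tsd_length` nucleotides immediately left of `p`, producing the
#' biological TSD-IS-TSD pattern around the insertion point.  All
#' downstream feature coordinates are shifted by the cumulative inserted
#' length, and a `mobile_element` feature is added per insertion.
#'
#' @param genome An [assembly()].
#' @param is_entry One row of an `is_library` (or a list with `name` and
#'   `sequence`).
#' @param spec A [simulation_spec()].
#' @return A list with `assembly` (modified genome) and `truth`, a
#'   `data.frame` with one row per insertion: `record_id`, `position`
#'   (0-based, original genome), `position_modified` (0-based, modified
#'   genome), `is_name`, `is_length`, `tsd_length`, `orientation`.
#' @export
simulate_insertions <- function(genome, is_entry, spec) {
  stopifnot(inherits(genome, "assembly"), inherits(spec, "simulation_spec"))
  is_seq <- toupper(is_entry$sequence)
  is_name <- is_entry$name
  is_len <- nchar(is_seq)
  tsd <- spec$tsd_length
  with_seed(spec$seed, {
    lens <- vapply(genome$records, function(r) r$length, integer(1))
    edge <- max(spec$min_spacing, tsd, 1L)
    avail <- pmax(lens - 2L * edge, 0L)
    if (all(avail == 0))
      stop("infeasible spacing: records too short", call. = FALSE)
    rec_of <- sample(names(genome$records), spec$n_insertions,
                     replace = TRUE, prob = avail)
    orient <- if (spec$orientation_policy == "forward")
      rep("+", spec$n_insertions)
    else sample(c("+", "-"), spec$n_insertions, replace = TRUE)
    truth <- NULL
    new_records <- genome$records
    oi <- 0L
    for (rid in names(genome$records)) {
      n_here <- sum(rec_of == rid)
      if (!n_here) next
      len <- lens[[rid]]
      pts <- sample_spaced_points(n_here, edge, len - edge,
                                  spec$min_spacing)
      ors <- orient[oi + seq_len(n_here)]
      oi <- oi + n_here
      rec <- genome$records[[rid]]
      pieces <- character(0)
      prev <- 0L
      shift_at <- integer(n_here)
      for (j in seq_len(n_here)) {
        p <- pts[j]
        ins <- if (ors[j] == "+") is_seq else revcomp(is_seq)
        dup <- if (tsd > 0) substr(rec$sequence, p - tsd + 1L, p) else ""
        pieces <- c(pieces, substr(rec$sequence, prev + 1L, p), ins, dup)
        prev <- p
        shift_at[j] <- (j - 1L) * (is_len + tsd)
      }
      pieces <- c(pieces, substr(rec$sequence, prev + 1L, len))
      new_seq <- paste(pieces, collapse = "")
      # shift features past each insertion point
      fts <- rec$features
      if (nrow(fts)) {
        for (j in seq_len(n_here)) {
          d <- is_len + tsd
          fts$start <- ifelse(fts$start >= pts[j] + shift_at[j],
                              fts$start + d, fts$start)
          fts$end <- ifelse(fts$end > pts[j] + shift_at[j],
                            fts$end + d, fts$end)
        }
      }
      pos_mod <- pts + shift_at
      for (j in seq_len(n_here)) {
        q <- list(c(mobile_element_type =
                      paste0("insertion sequence:", is_name),
                    note = "simulated insertion"))
        fts <- rbind(fts, data.frame(kind = "mobile_element",
                                     start = pos_mod[j],
                                     end = pos_mod[j] + is_len,
                                     strand = if (ors[j] == "+") 1L else -1L,
                                     qualifiers = I(q),
                                     stringsAsFactors = FALSE))
      }
      fts <- fts[order(fts$start), , drop = FALSE]
      new_records[[rid]] <- genome_record(rid, new_seq, fts,
                                          rec$description, rec$topology)
      truth <- rbind(truth, data.frame(record_id = rid, position = pts,
                                       position_modified = pos_mod,
                                       is_name = is_name,
                                       is_length = is_len,
                                       tsd_length = tsd,
                                       orientation = ors,
                                       stringsAsFactors = FALSE))
    }
    truth <- truth[order(truth$record_id, truth$position), , drop = FALSE]
    rownames(truth) <- NULL
    list(assembly = assembly(new_records, label = genome$label),
         truth = truth)
  })
}

#' Generate a synthetic bacterial-like genome
#'
#' I.i.d. nucleotide sequence at a given GC content with optional planted
#' background IS copies (substituted in place, so the record length is
#' exactly `length`) and evenly spaced dummy CDS features for annotation
#' tests.  Deterministic for a fixed seed.
#'
#' @param length Record length in nt.
#' @param gc GC fraction (default 0.5).
#' @param n_background_is Number of pre-existing IS copies to plant.
#' @param library `is_library` supplying background IS sequences (cycled).
#' @param seed RNG seed.
#' @param record_id Record identifier.
#' @param cds_every Spacing of dummy CDS features (default 3000 nt;
#'   `0` disables them).
#' @param cds_len Dummy CDS length (default 900 nt).
#' @return An [assembly()] with one record.
#' @export
make_synthetic_genome <- function(length, gc = 0.5, n_background_is = 0L,
                                  library = NULL, seed = 1L,
                                  record_id = "synchr1", cds_every = 3000L,
                                  cds_len = 900L) {
  stopifnot(length > 0)
  with_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    seq <- paste(bases, collapse = "")
    feats <- empty_features()
    if (n_background_is > 0) {
      stopifnot(!is.null(library))
      picks <- rep(seq_len(nrow(library)),
                   length.out = n_background_is)
      slots <- sample_spaced_points(n_background_is, 2000L, length - 2000L,
                                    max(nchar(library$sequence)) + 2000L)
      for (j in seq_len(n_background_is)) {
        is_seq <- library$sequence[picks[j]]
        substr(seq, slots[j] + 1L, slots[j] + nchar(is_seq)) <- is_seq
        q <- list(c(mobile_element_type =
                      paste0("insertion sequence:",
                             library$name[picks[j]])))
        feats <- rbind(feats, data.frame(kind = "mobile_element",
                                         start = slots[j],
                                         end = slots[j] + nchar(is_seq),
                                         strand = 1L, qualifiers = I(q),
                                         stringsAsFactors = FALSE))
      }
    }
    if (cds_every > 0 && length > cds_len + 600L) {
      starts <- seq(500L, length - cds_len - 1L, by = cds_every)
      for (k in seq_along(starts)) {
        q <- list(c(locus_tag = sprintf("SYN_%04d", k),
                    product = "hypothetical protein"))
        feats <- rbind(feats, data.frame(kind = "CDS", start = starts[k],
                                         end = starts[k] + cds_len,
                                         strand = if (k %% 2) 1L else -1L,
                                         qualifiers = I(q),
                                         stringsAsFactors = FALSE))
      }
    }
    feats <- feats[order(feats$start), , drop = FALSE]
    assembly(list(genome_record(record_id, seq, feats,
                                "synthetic chromosome")))
  })
}

#' Generate a synthetic IS library
#'
#' Random IS-like nucleotide sequences with 25 nt terminal inverted
#' repeats, named `ISSyn1..n`; entries are assigned round-robin to three
#' synthetic families so relatedness logic is exercised.
#'
#' @param n Number of entries.
#' @param length IS length(s), recycled.
#' @param seed RNG seed.
#' @param family Optional family label(s), recycled; default
#'   `synfamA/B/C` round robin.
#' @return An `is_library`.
#' @export
synthetic_is_library <- function(n = 1L, length = 1200L, seed = 42L,
                                 family = NULL) {
  length <- rep_len(length, n)
  if (is.null(family))
    family <- rep_len(c("synfamA", "synfamB", "synfamC"), n)
  else family <- rep_len(family, n)
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      core <- paste(sample(c("A", "C", "G", "T"), length[i] - 50L,
                           replace = TRUE), collapse = "")
      ir <- paste(sample(c("A", "C", "G", "T"), 25L, replace = TRUE),
                  collapse = "")
      paste0(ir, core, revcomp(ir))
    }, character(1))
    is_library(paste0("ISSyn", seq_len(n), "_", family, "_grp",
                      seq_len(n)),
               seqs)
  })
}

#' Fragment an assembly into a draft
#'
#' Splits records at the given breakpoints, emulating draft assemblies
#' whose contigs break inside repeated elements.  Features crossing a
#' breakpoint are dropped; the returned assembly carries a
#' `fragment_map` attribute mapping each contig back to its source record
#' and offset.
#'
#' @param asm An [assembly()].
#' @param breakpoints Named list: record id -> integer vector of cut
#'   positions (0-based). Records not listed are kept whole.
#' @return A draft [assembly()] with attribute `fragment_map`.
#' @export
fragment_assembly <- function(asm, breakpoints) {
  stopifnot(inherits(asm, "assembly"))
  records <- list()
  map <- data.frame(record_id = character(), source_record = character(),
                    offset = integer(), length = integer(),
                    stringsAsFactors = FALSE)
  for (rid in names(asm$records)) {
    rec <- asm$records[[rid]]
    bps <- sort(unique(breakpoints[[rid]]))
    bps <- bps[bps > 0L & bps < rec$length]
    bounds <- c(0L, bps, rec$length)
    for (i in seq_len(length(bounds) - 1L)) {
      lo <- bounds[i]; hi <- bounds[i + 1L]
      cid <- if (length(bps)) sprintf("%s_ctg%03d", rid, i) else rid
      fts <- rec$features
      if (nrow(fts)) {
        keep <- fts$start >= lo & fts$end <= hi
        fts <- fts[keep, , drop = FALSE]
        fts$start <- fts$start - lo
        fts$end <- fts$end - lo
      }
      records[[cid]] <- genome_record(cid, substr(rec$sequence, lo + 1L,
                                                  hi),
                                      fts, rec$description)
      map <- rbind(map, data.frame(record_id = cid, source_record = rid,
                                   offset = lo, length = hi - lo,
                                   stringsAsFactors = FALSE))
    }
  }
  out <- assembly(records, label = asm$label)
  attr(out, "fragment_map") <- map
  out
}

#' Breakpoints at planted IS midpoints
#'
#' Convenience helper producing the `at_is_boundaries` fragmentation mode:
#' one cut inside each simulated IS at its midpoint, so every planted IS
#' ends up split across two contig ends, as real draft assemblies exhibit.
#'
#' @param truth Truth table from [simulate_insertions()].
#' @return Named list of breakpoint vectors for [fragment_assembly()].
#' @export
is_midpoint_breakpoints <- function(truth) {
  mids <- truth$position_modified + truth$is_length %/% 2L
  split(mids, truth$record_id)
}
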