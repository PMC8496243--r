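# ---------------------------------------------------------------------------
# Whole-comparison driver: both directions, consolidation, annotation,
# output tables.

seq_md5 <- function(asmseqs) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(c(names(asmseqs), asmseqs), tf)
  unname(tools::md5sum(tf))
}

direction_pass <- function(qasm, rasm, occ_all, library, cfg,
                           filter_identical = TRUE) {
  stats <- list(removed_identical = 0L, dropped_is_only = 0L,
                occurrences = 0L)
  if (filter_identical) {
    fi <- filter_identical_scaffolds(qasm, rasm, cfg)
    stats$removed_identical <- nrow(fi$removed)
    retained <- fi$retained
  } else retained <- qasm
  empty <- classify_occurrences(empty_occurrences(), qasm, rasm, library,
                                cfg)
  if (is.null(retained))
    return(list(rows = empty, pairs = tag_consecutive(empty_occurrences(),
                                                      cfg)$pairs,
                stats = stats))
  occ <- occ_all[occ_all$record_id %in% names(retained$records), ,
                 drop = FALSE]
  dr <- drop_is_only_scaffolds(retained, occ, cfg)
  stats$dropped_is_only <- length(dr$dropped)
  if (is.null(dr$retained))
    return(list(rows = empty, pairs = tag_consecutive(empty_occurrences(),
                                                      cfg)$pairs,
                stats = stats))
  occ <- occ[occ$record_id %in% names(dr$retained$records), , drop = FALSE]
  tc <- tag_consecutive(occ, cfg)
  stats$occurrences <- nrow(tc$occurrences)
  rows <- classify_occurrences(tc$occurrences, dr$retained, rasm, library,
                               cfg)
  list(rows = rows, pairs = tc$pairs, stats = stats)
}

# Single-linkage clustering of reference-side loci; among duplicated rows
# (same classification/family/reference record, locus within 50 nt) the
# forward-direction, full-quality, lowest-coordinate row is kept.
consolidate_rows <- function(rows, gap = 50L) {
  if (!nrow(rows)) return(list(rows = rows, merged = 0L))
  key_rec <- ifelse(rows$found_in == "query", rows$anchor_record,
                    rows$is_record)
  key_pos <- ifelse(rows$found_in == "query", rows$anchor_point,
                    rows$is_start)
  eligible <- !is.na(key_rec) & !is.na(key_pos) &
    rows$classification %in% c("DLIS", "SLIS", "VERIFY_RELATED_IS_IN_FLANK",
                               "VERIFY_CONSECUTIVE_IS")
  drop <- logical(nrow(rows))
  groups <- split(which(eligible),
                  paste(rows$classification[eligible],
                        rows$family[eligible], key_rec[eligible]))
  for (g in groups) {
    if (length(g) < 2) next
    g <- g[order(key_pos[g])]
    cl_id <- cumsum(c(1L, diff(key_pos[g]) > gap))
    for (cl in split(g, cl_id)) {
      if (length(cl) < 2) next
      pref <- order(rows$found_in[cl] != "query",
                    rows$hit_quality[cl] != "full", key_pos[cl])
      drop[cl[pref[-1]]] <- TRUE
    }
  }
  list(rows = rows[!drop, , drop = FALSE], merged = sum(drop))
}

nearest_cds <- function(features, point, side, max_dist = 5000L) {
  if (!nrow(features)) return("")
  cds <- features[features$kind == "CDS", , drop = FALSE]
  if (!nrow(cds)) return("")
  overlapping <- cds$start < point & cds$end > point
  if (side == "left") {
    ok <- overlapping | (cds$end <= point & point - cds$end <= max_dist)
    if (!any(ok)) return("")
    pick <- which(ok)[which.max(cds$end[ok])]
  } else {
    ok <- overlapping | (cds$start >= point & cds$start - point <= max_dist)
    if (!any(ok)) return("")
    pick <- which(ok)[which.min(cds$start[ok])]
  }
  q <- cds$qualifiers[[pick]]
  paste0(if ("locus_tag" %in% names(q)) q[["locus_tag"]] else "",
         "|",
         if ("product" %in% names(q)) q[["product"]] else "")
}

#' Attach CDS context annotation to result rows
#'
#' For each side of each reported site the nearest CDS (overlapping, or
#' with its closest end within 5 kb) is attached with locus tag and
#' product; assemblies without features yield empty strings.
#'
#' @param rows Result row `data.frame` (from [run_comparison()] internals).
#' @param query,reference The compared assemblies.
#' @return `rows` with `query_left_cds`, `query_right_cds`, `ref_left_cds`,
#'   `ref_right_cds` columns.
#' @export
annotate_context <- function(rows, query, reference) {
  n <- nrow(rows)
  rows$query_left_cds <- rows$query_right_cds <- rep("", n)
  rows$ref_left_cds <- rows$ref_right_cds <- rep("", n)
  for (i in seq_len(n)) {
    if (rows$found_in[i] == "query") {
      q_rec <- query$records[[rows$is_record[i]]]
      q_lo <- rows$is_start[i]; q_hi <- rows$is_end[i]
      r_rec <- if (!is.na(rows$anchor_record[i]))
        reference$records[[rows$anchor_record[i]]] else NULL
      r_lo <- r_hi <- rows$anchor_point[i]
    } else {
      q_rec <- if (!is.na(rows$anchor_record[i]))
        query$records[[rows$anchor_record[i]]] else NULL
      q_lo <- q_hi <- rows$anchor_point[i]
      r_rec <- reference$records[[rows$is_record[i]]]
      r_lo <- rows$is_start[i]; r_hi <- rows$is_end[i]
    }
    if (!is.null(q_rec) && !is.na(q_lo)) {
      rows$query_left_cds[i] <- nearest_cds(q_rec$features, q_lo, "left")
      rows$query_right_cds[i] <- nearest_cds(q_rec$features, q_hi, "right")
    }
    if (!is.null(r_rec) && !is.na(r_lo)) {
      rows$ref_left_cds[i] <- nearest_cds(r_rec$features, r_lo, "left")
      rows$ref_right_cds[i] <- nearest_cds(r_rec$features, r_hi, "right")
    }
  }
  rows
}

#' Run a full pairwise DLIS comparison
#'
#' Executes the complete workflow: identical-scaffold removal, IS
#' scanning, IS-only-scaffold removal, consecutive-IS tagging, flank
#' extraction and mapping, RAF interrogation and classification — first
#' with `(query, reference)`, then with the genomes exchanged so that ISs
#' only present in the reference are reported too.  Results are
#' consolidated (duplicate same-location calls discovered from both
#' directions, and split partial-IS calls anchoring to the same locus, are
#' merged) and annotated with flanking CDS context.
#'
#' @param query,reference [assembly()] objects.
#' @param library An `is_library`.
#' @param cfg A [dlis_config()].
#' @param filter_identical Remove identical scaffolds first (default
#'   `TRUE`; disable to classify occurrences on identical replicons).
#' @return An object of class `comparison_result`: list with
#'   `dlis_records` (consolidated row table; `found_in` is `"query"` or
#'   `"reference"`), `query_is`/`reference_is` (per-genome IS occurrence
#'   tables), `consecutive` (tagged pairs), `stats`, `config`,
#'   `provenance`.
#' @export
run_comparison <- function(query, reference, library, cfg = dlis_config(),
                           filter_identical = TRUE) {
  stopifnot(inherits(query, "assembly"), inherits(reference, "assembly"),
            inherits(library, "is_library"))
  query$label <- "query"; reference$label <- "reference"
  occ_q <- scan_is(query, library, cfg)
  occ_r <- scan_is(reference, library, cfg)
  fwd <- direction_pass(query, reference, occ_q, library, cfg,
                        filter_identical)
  rev <- direction_pass(reference, query, occ_r, library, cfg,
                        filter_identical)
  rows_f <- fwd$rows; rows_r <- rev$rows
  if (nrow(rows_f)) rows_f$found_in <- "query"
  if (nrow(rows_r)) rows_r$found_in <- "reference"
  if (!nrow(rows_f)) rows_f$found_in <- character(0)
  if (!nrow(rows_r)) rows_r$found_in <- character(0)
  rows <- rbind(rows_f, rows_r)
  cons <- consolidate_rows(rows)
  rows <- cons$rows
  if (nrow(rows))
    rows <- rows[order(rows$found_in, rows$is_record, rows$is_start), ,
                 drop = FALSE]
  rownames(rows) <- NULL
  rows <- annotate_context(rows, query, reference)
  categories <- setNames(integer(length(CLASSIFICATIONS)), CLASSIFICATIONS)
  tab <- table(rows$classification)
  categories[names(tab)] <- as.integer(tab)
  stats <- list(categories = categories,
                occurrences_query = fwd$stats$occurrences,
                occurrences_reference = rev$stats$occurrences,
                removed_identical_query = fwd$stats$removed_identical,
                removed_identical_reference = rev$stats$removed_identical,
                dropped_is_only_query = fwd$stats$dropped_is_only,
                dropped_is_only_reference = rev$stats$dropped_is_only,
                duplicates_merged = cons$merged,
                discarded_qifs = sum(categories[startsWith(
                  names(categories), "DISCARD")]))
  provenance <- list(backend = cfg$backend,
                     engine = engine_version(cfg),
                     query_md5 = seq_md5(assembly_seqs(query)),
                     reference_md5 = seq_md5(assembly_seqs(reference)),
                     library_md5 = seq_md5(setNames(library$sequence,
                                                    library$name)))
  structure(list(dlis_records = rows, query_is = occ_q,
                 reference_is = occ_r,
                 consecutive = rbind(fwd$pairs, rev$pairs),
                 stats = stats, config = cfg, provenance = provenance),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>\n")
  cat("  occurrences: query", x$stats$occurrences_query,
      "/ reference", x$stats$occurrences_reference, "\n")
  ct <- x$stats$categories
  for (k in names(ct)) if (ct[k] > 0) cat(sprintf("  %-28s %d\n", k, ct[k]))
  invisible(x)
}

flank_loc_string <- function(ls, le, rs, re) {
  fmt <- function(a, b) if (is.na(a)) "" else paste0(a + 1L, "..", b)
  paste0(fmt(ls, le), ";", fmt(rs, re))
}

#' Write the comparison output tables
#'
#' Emits `FinalResults.csv` (consolidated classified rows, 1-based closed
#' coordinates), `QueryISs.csv`, `RefISs.csv`, `ConsecutiveIS.csv`,
#' `stats.txt` and a machine-readable `stats.json`.
#'
#' @param result A `comparison_result`.
#' @param outdir Output directory (created if needed).
#' @return Character vector of the written file paths, invisibly.
#' @export
write_outputs <- function(result, outdir) {
  stopifnot(inherits(result, "comparison_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- result$dlis_records
  n <- nrow(rows)
  fr <- data.frame(is_id = rows$is_name,
                   is_start = rows$is_start + 1L,
                   is_end = rows$is_end,
                   query_id = character(n), query_flank_loc = character(n),
                   ref_id = character(n), ref_flank_loc = character(n),
                   found_in = rows$found_in,
                   classification = rows$classification,
                   hit_quality = rows$hit_quality,
                   query_left_cds = rows$query_left_cds,
                   query_right_cds = rows$query_right_cds,
                   ref_left_cds = rows$ref_left_cds,
                   ref_right_cds = rows$ref_right_cds,
                   stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    own_loc <- flank_loc_string(rows$left_flank_start[i],
                                rows$left_flank_end[i],
                                rows$right_flank_start[i],
                                rows$right_flank_end[i])
    other_loc <- if (is.na(rows$anchor_start[i])) "" else
      paste0(rows$anchor_start[i] + 1L, "..", rows$anchor_end[i])
    if (rows$found_in[i] == "query") {
      fr$query_id[i] <- rows$is_record[i]
      fr$query_flank_loc[i] <- own_loc
      fr$ref_id[i] <- if (is.na(rows$anchor_record[i])) "" else
        rows$anchor_record[i]
      fr$ref_flank_loc[i] <- other_loc
    } else {
      fr$ref_id[i] <- rows$is_record[i]
      fr$ref_flank_loc[i] <- own_loc
      fr$query_id[i] <- if (is.na(rows$anchor_record[i])) "" else
        rows$anchor_record[i]
      fr$query_flank_loc[i] <- other_loc
    }
  }
  paths <- c(FinalResults = file.path(outdir, "FinalResults.csv"),
             QueryISs = file.path(outdir, "QueryISs.csv"),
             RefISs = file.path(outdir, "RefISs.csv"),
             ConsecutiveIS = file.path(outdir, "ConsecutiveIS.csv"),
             stats_txt = file.path(outdir, "stats.txt"),
             stats_json = file.path(outdir, "stats.json"))
  write.csv(fr, paths["FinalResults"], row.names = FALSE)
  occ_csv <- function(occ) data.frame(record_id = occ$record_id,
                                      start = occ$start + 1L,
                                      end = occ$end,
                                      is_name = occ$is_name,
                                      family = occ$family,
                                      partial = occ$partial,
                                      identity = occ$identity_pct,
                                      evalue = occ$evalue,
                                      stringsAsFactors = FALSE)
  write.csv(occ_csv(result$query_is), paths["QueryISs"], row.names = FALSE)
  write.csv(occ_csv(result$reference_is), paths["RefISs"],
            row.names = FALSE)
  cons <- result$consecutive
  if (nrow(cons)) {
    cons$start_1 <- cons$start_1 + 1L
    cons$start_2 <- cons$start_2 + 1L
  }
  write.csv(cons[, setdiff(names(cons), c("occ_id_1", "occ_id_2")),
                 drop = FALSE],
            paths["ConsecutiveIS"], row.names = FALSE)
  st <- result$stats
  lines <- c(paste0("category\t", names(st$categories), "\t",
                    st$categories),
             paste0("occurrences_query\t", st$occurrences_query),
             paste0("occurrences_reference\t", st$occurrences_reference),
             paste0("removed_identical_query\t",
                    st$removed_identical_query),
             paste0("removed_identical_reference\t",
                    st$removed_identical_reference),
             paste0("dropped_is_only_query\t", st$dropped_is_only_query),
             paste0("dropped_is_only_reference\t",
                    st$dropped_is_only_reference),
             paste0("duplicates_merged\t", st$duplicates_merged),
             paste0("discarded_qifs\t", st$discarded_qifs))
  writeLines(lines, paths["stats_txt"])
  jsonlite::write_json(c(list(categories = as.list(st$categories)),
                         st[setdiff(names(st), "categories")]),
                       paths["stats_json"], auto_unbox = TRUE)
  invisible(paths)
}
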