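# ---------------------------------------------------------------------------
# Graphic genome-context report: one panel per reported DLIS/VERIFY row,
# query track above, reference track below, CDS arrows labelled by product
# or locus tag.

draw_arrow <- function(x0, x1, y, h, strand, col, label = "") {
  head <- min(0.25 * abs(x1 - x0),
              0.015 * diff(graphics::par("usr")[1:2]))
  if (strand >= 0) {
    xs <- c(x0, x1 - head, x1, x1 - head, x0)
    ys <- c(y - h, y - h, y, y + h, y + h)
  } else {
    xs <- c(x1, x0 + head, x0, x0 + head, x1)
    ys <- c(y - h, y - h, y, y + h, y + h)
  }
  graphics::polygon(xs, ys, col = col, border = "grey30")
  if (nzchar(label))
    graphics::text((x0 + x1) / 2, y + 2.2 * h, label, cex = 0.55,
                   srt = 0, adj = c(0.5, 0))
}

draw_track <- function(rec, lo, hi, y, title, highlight = NULL,
                       flanks = NULL) {
  graphics::segments(lo, y, hi, y, lwd = 2, col = "grey40")
  graphics::text(lo, y + 0.16, sprintf("%s  [%s..%s]", title,
                                       format(lo + 1), format(hi)),
                 adj = c(0, 0), cex = 0.7, font = 2)
  if (!is.null(rec) && nrow(rec$features)) {
    fts <- rec$features
    vis <- fts$kind == "CDS" & fts$end > lo & fts$start < hi
    for (i in which(vis)) {
      q <- fts$qualifiers[[i]]
      lab <- if ("product" %in% names(q) && nzchar(q[["product"]]))
        q[["product"]]
      else if ("locus_tag" %in% names(q)) q[["locus_tag"]] else ""
      draw_arrow(max(fts$start[i], lo), min(fts$end[i], hi), y, 0.035,
                 fts$strand[i], "lightsteelblue", substr(lab, 1, 24))
    }
  }
  if (!is.null(flanks)) {
    for (f in flanks) {
      if (any(is.na(f))) next
      graphics::rect(f[1], y - 0.05, f[2], y + 0.05, col = "grey75",
                     border = "grey30")
    }
  }
  if (!is.null(highlight) && !any(is.na(highlight))) {
    graphics::rect(highlight[1], y - 0.06, highlight[2], y + 0.06,
                   col = "firebrick", border = "black")
  }
}

#' Render the graphic genome-context report
#'
#' Writes a PDF with one panel per reported `DLIS`/`VERIFY` row: the query
#' genome track (IS highlighted, flanks boxed, CDS arrows labelled) above
#' the corresponding reference anchor region.  With zero reportable rows a
#' single page stating so is produced.
#'
#' @param result A `comparison_result`.
#' @param query,reference The compared assemblies.
#' @param path Output PDF path.
#' @param window_pad Extra window on each side of the IS/anchor beyond the
#'   flank length (default 2000 nt).
#' @return `path`, invisibly.
#' @export
render_report <- function(result, query, reference, path,
                          window_pad = 2000L) {
  stopifnot(inherits(result, "comparison_result"))
  rows <- result$dlis_records
  rows <- rows[rows$classification %in%
                 c("DLIS", "VERIFY_RELATED_IS_IN_FLANK",
                   "VERIFY_CONSECUTIVE_IS", "VERIFY_UNSPECIFIC_MULTIHIT"), ,
               drop = FALSE]
  L <- result$config$surroundingLen
  grDevices::pdf(path, width = 10, height = 5)
  on.exit(grDevices::dev.off())
  if (!nrow(rows)) {
    graphics::plot.new()
    graphics::text(0.5, 0.5, "no DLIS detected", cex = 1.5)
    return(invisible(path))
  }
  for (i in seq_len(nrow(rows))) {
    own_asm <- if (rows$found_in[i] == "query") query else reference
    oth_asm <- if (rows$found_in[i] == "query") reference else query
    own_rec <- own_asm$records[[rows$is_record[i]]]
    pad <- L + window_pad
    lo1 <- max(0L, rows$is_start[i] - pad)
    hi1 <- min(own_rec$length, rows$is_end[i] + pad)
    graphics::par(mar = c(2, 1, 2, 1))
    graphics::plot(NA, xlim = c(lo1, hi1), ylim = c(0, 1), axes = FALSE,
                   xlab = "", ylab = "",
                   main = sprintf("%s  %s  (%s, %s)", rows$is_name[i],
                                  rows$classification[i],
                                  rows$found_in[i], rows$hit_quality[i]))
    graphics::axis(1, cex.axis = 0.6)
    draw_track(own_rec, lo1, hi1, 0.72,
               paste0(rows$is_record[i], " (", rows$found_in[i], ")"),
               highlight = c(rows$is_start[i], rows$is_end[i]),
               flanks = list(c(rows$left_flank_start[i],
                               rows$left_flank_end[i]),
                             c(rows$right_flank_start[i],
                               rows$right_flank_end[i])))
    if (!is.na(rows$anchor_record[i])) {
      oth_rec <- oth_asm$records[[rows$anchor_record[i]]]
      lo2 <- max(0L, rows$anchor_start[i] - pad)
      hi2 <- min(oth_rec$length, rows$anchor_end[i] + pad)
      # rescale the second track into the same device coordinates
      graphics::par(new = TRUE)
      graphics::plot(NA, xlim = c(lo2, hi2), ylim = c(0, 1), axes = FALSE,
                     xlab = "", ylab = "")
      draw_track(oth_rec, lo2, hi2, 0.28,
                 paste0(rows$anchor_record[i], " (anchor)"),
                 highlight = NULL,
                 flanks = list(c(rows$anchor_start[i],
                                 rows$anchor_end[i])))
      if (!is.na(rows$anchor_point[i]))
        graphics::points(rows$anchor_point[i], 0.28, pch = 25,
                         bg = "firebrick", cex = 1.1)
    }
  }
  invisible(path)
}
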