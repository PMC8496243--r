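# ---------------------------------------------------------------------------
# Local nucleotide homology search behind one contract.
#
# The external backend invokes NCBI BLAST+ blastn (tabular output); the
# built-in backend is a deterministic k-mer seed + ungapped X-drop extension
# engine with a monotone score -> E-value mapping.  Hit coordinates are
# normalised to 0-based half-open intervals with s_start < s_end and the
# subject strand recorded separately.

hit_columns <- c("query_id", "subject_id", "q_start", "q_end", "s_start",
                 "s_end", "s_strand", "identity_pct", "aln_length",
                 "mismatches", "gapopen", "evalue", "bitscore", "qcovhsp",
                 "q_len", "s_len")

empty_hits <- function() {
  df <- data.frame(query_id = character(), subject_id = character(),
                   q_start = integer(), q_end = integer(),
                   s_start = integer(), s_end = integer(),
                   s_strand = integer(), identity_pct = numeric(),
                   aln_length = integer(), mismatches = integer(),
                   gapopen = integer(), evalue = numeric(),
                   bitscore = numeric(), qcovhsp = numeric(),
                   q_len = integer(), s_len = integer(),
                   stringsAsFactors = FALSE)
  df
}

#' Per-HSP query coverage
#'
#' @param hit Either a numeric vector of alignment spans on the query
#'   (`q_end - q_start` in 0-based half-open coordinates) or a hit
#'   `data.frame` as returned by [search_sequences()].
#' @param query_length Query length(s) in nucleotides.
#' @return Coverage percentage(s), `100 * span / query_length`.
#' @export
qcovhsp <- function(hit, query_length) {
  span <- if (is.data.frame(hit)) hit$q_end - hit$q_start else hit
  stopifnot(all(query_length > 0))
  100 * span / query_length
}

blast_available <- function() {
  nzchar(Sys.which("blastn")) && nzchar(Sys.which("makeblastdb"))
}

engine_version <- function(cfg = dlis_config()) {
  if (cfg$backend == "external" && blast_available()) {
    v <- tryCatch(system2("blastn", "-version", stdout = TRUE)[1],
                  error = function(e) "blastn (version unknown)")
    v
  } else "dliscan builtin seed-and-extend"
}

#' Search query sequences against subject sequences
#'
#' Runs a local nucleotide homology search of every query against every
#' subject and returns all HSPs passing the E-value cutoff as one
#' `data.frame`.  Coordinates are 0-based half-open; minus-strand subject
#' intervals are normalised so `s_start < s_end` with `s_strand = -1`.
#' `qcovhsp` is recomputed from the interval span so that both backends
#' follow one definition.
#'
#' @param queries Named character vector of query sequences.
#' @param subjects Named character vector of subject sequences.
#' @param cfg A [dlis_config()]; `cfg$backend` selects the engine.
#' @param culling If not `NULL`, the per-query culling limit: among hits
#'   whose query intervals overlap by more than half of the shorter one,
#'   at most `culling` (best bitscore first) are retained.
#' @return A hit `data.frame` (possibly 0-row) with columns
#'   `query_id, subject_id, q_start, q_end, s_start, s_end, s_strand,
#'   identity_pct, aln_length, mismatches, gapopen, evalue, bitscore,
#'   qcovhsp, q_len, s_len`.
#' @export
search_sequences <- function(queries, subjects, cfg = dlis_config(),
                             culling = NULL) {
  stopifnot(length(queries) > 0, length(subjects) > 0,
            !is.null(names(queries)), !is.null(names(subjects)))
  queries <- toupper(queries); subjects <- toupper(subjects)
  hits <- if (cfg$backend == "external") {
    if (!blast_available())
      stop("NCBI BLAST+ (blastn/makeblastdb) not found on PATH; install ",
           "BLAST+ or use dlis_config(backend = \"builtin\")",
           call. = FALSE)
    blast_backend(queries, subjects, cfg)
  } else {
    builtin_backend(queries, subjects, cfg)
  }
  if (nrow(hits)) {
    hits$q_len <- nchar(queries)[hits$query_id]
    hits$s_len <- nchar(subjects)[hits$subject_id]
    hits$qcovhsp <- qcovhsp(hits$q_end - hits$q_start, hits$q_len)
    hits <- hits[hits$evalue <= cfg$evalue_cutoff, , drop = FALSE]
    hits <- hits[order(hits$query_id, -hits$bitscore, hits$q_start,
                       hits$subject_id, hits$s_start), , drop = FALSE]
    rownames(hits) <- NULL
  } else {
    hits <- empty_hits()
  }
  if (!is.null(culling)) hits <- apply_culling(hits, culling)
  hits
}

# --- external backend -------------------------------------------------------

blast_backend <- function(queries, subjects, cfg) {
  wd <- tempfile("dliscan_blast_")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE), add = TRUE)
  qf <- file.path(wd, "query.fa"); sf <- file.path(wd, "subject.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(queries), qf)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(subjects), sf)
  db <- file.path(wd, "db")
  out <- system2("makeblastdb",
                 c("-in", sf, "-dbtype", "nucl", "-out", db),
                 stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(out, "status")))
    stop("makeblastdb failed:\n", paste(out, collapse = "\n"),
         call. = FALSE)
  tab <- file.path(wd, "hits.tsv")
  args <- c("-query", qf, "-db", db, "-out", tab,
            "-outfmt", shQuote(paste("6 qseqid sseqid pident length",
                                     "mismatch gapopen qstart qend",
                                     "sstart send evalue bitscore")),
            "-evalue", format(cfg$evalue_cutoff, scientific = TRUE),
            "-num_threads", "1", "-max_target_seqs", "5000")
  if (!is.null(cfg$word_size)) args <- c(args, "-word_size", cfg$word_size)
  err <- system2("blastn", args, stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(err, "status")))
    stop("blastn failed:\n", paste(err, collapse = "\n"), call. = FALSE)
  if (!file.size(tab)) return(empty_hits())
  tb <- read.table(tab, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("query_id", "subject_id", "identity_pct",
                                 "aln_length", "mismatches", "gapopen",
                                 "qstart", "qend", "sstart", "send",
                                 "evalue", "bitscore"),
                   colClasses = c("character", "character", "numeric",
                                  "integer", "integer", "integer",
                                  "integer", "integer", "integer",
                                  "integer", "numeric", "numeric"))
  minus <- tb$sstart > tb$send
  data.frame(query_id = tb$query_id, subject_id = tb$subject_id,
             q_start = tb$qstart - 1L, q_end = tb$qend,
             s_start = ifelse(minus, tb$send, tb$sstart) - 1L,
             s_end = ifelse(minus, tb$sstart, tb$send),
             s_strand = ifelse(minus, -1L, 1L),
             identity_pct = tb$identity_pct, aln_length = tb$aln_length,
             mismatches = tb$mismatches, gapopen = tb$gapopen,
             evalue = tb$evalue, bitscore = tb$bitscore,
             qcovhsp = NA_real_, q_len = NA_integer_, s_len = NA_integer_,
             stringsAsFactors = FALSE)
}

# --- built-in backend -------------------------------------------------------

# Karlin-Altschul-like parameters for reward +1 / penalty -2 (megablast
# defaults); used only as a monotone score -> E-value mapping.
.ka_lambda <- 1.28
.ka_k <- 0.46

builtin_backend <- function(queries, subjects, cfg) {
  k <- if (is.null(cfg$word_size)) 16L else as.integer(cfg$word_size)
  n_total <- sum(nchar(subjects))
  res <- list()
  for (qi in names(queries)) {
    qseq <- queries[[qi]]
    if (nchar(qseq) < k) next
    for (si in names(subjects)) {
      sseq <- subjects[[si]]
      if (nchar(sseq) < k) next
      for (strand in c(1L, -1L)) {
        starget <- if (strand == 1L) sseq else revcomp(sseq)
        cands <- extend_on_diagonals(qseq, starget, k)
        if (is.null(cands) || !nrow(cands)) next
        if (strand == -1L) {
          slen <- nchar(sseq)
          s0 <- slen - cands$s_end
          cands$s_end <- slen - cands$s_start
          cands$s_start <- s0
        }
        cands$query_id <- qi; cands$subject_id <- si
        cands$s_strand <- strand
        res[[length(res) + 1L]] <- cands
      }
    }
  }
  if (!length(res)) return(empty_hits())
  hits <- do.call(rbind, res)
  score <- hits$aln_length - 3L * hits$mismatches  # +1 match, -2 mismatch
  hits$bitscore <- (.ka_lambda * score - log(.ka_k)) / log(2)
  m <- nchar(queries)[hits$query_id]
  hits$evalue <- m * n_total * 2^(-hits$bitscore)
  hits$gapopen <- 0L
  hits$qcovhsp <- NA_real_; hits$q_len <- NA_integer_
  hits$s_len <- NA_integer_
  hits[, hit_columns]
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Seed (stride-sampled query k-mers matched exactly in the subject), group
# seeds by alignment diagonal, chain nearby seeds and extend each chained
# segment in both directions with a vectorised ungapped X-drop extension.
extend_on_diagonals <- function(qseq, sseq, k, xdrop = 12L,
                                chain_gap = 200L) {
  qlen <- nchar(qseq); slen <- nchar(sseq)
  stride <- max(1L, k %/% 2L)
  qpos <- unique(c(seq(0L, qlen - k, by = stride), qlen - k))
  kmers <- substring(qseq, qpos + 1L, qpos + k)
  keep <- !grepl("[^ACGT]", kmers)
  qpos <- qpos[keep]; kmers <- kmers[keep]
  if (!length(qpos)) return(NULL)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(sseq))
  starts <- Biostrings::startIndex(mi)
  starts[vapply(starts, is.null, logical(1))] <- list(integer(0))
  nhit <- lengths(starts)
  if (!sum(nhit)) return(NULL)
  sq <- rep(qpos, nhit)
  sp <- unlist(starts, use.names = FALSE) - 1L
  dg <- sp - sq
  qraw <- charToRaw(qseq); sraw <- charToRaw(sseq)
  out <- list()
  for (d in unique(dg)) {
    qp <- sort(unique(sq[dg == d]))
    # split into chains where consecutive seeds are close
    brk <- c(0L, which(diff(qp) > chain_gap), length(qp))
    qlo <- max(0L, -d); qhi <- min(qlen, slen - d)
    m <- qraw[(qlo + 1L):qhi] == sraw[(qlo + d + 1L):(qhi + d)]
    v <- ifelse(m, 1L, -2L)
    for (ci in seq_len(length(brk) - 1L)) {
      cp <- qp[(brk[ci] + 1L):brk[ci + 1L]]
      a <- min(cp) - qlo + 1L          # local 1-based seed start
      b <- max(cp) + k - qlo           # local 1-based seed end
      extl <- xdrop_extend(v, a, -1L, xdrop)
      extr <- xdrop_extend(v, b, 1L, xdrop)
      lo <- a - extl; hi <- b + extr
      len <- hi - lo + 1L
      nmatch <- sum(m[lo:hi])
      out[[length(out) + 1L]] <- data.frame(
        q_start = qlo + lo - 1L, q_end = qlo + hi,
        s_start = qlo + lo - 1L + d, s_end = qlo + hi + d,
        identity_pct = 100 * nmatch / len, aln_length = len,
        mismatches = len - nmatch, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  # chains on the same diagonal can extend into each other; deduplicate
  res[!duplicated(res[, c("q_start", "q_end", "s_start", "s_end")]), ,
      drop = FALSE]
}

# Maximal-scoring ungapped extension from local position `from` in
# direction `dir` over score vector v, stopping when the running score
# falls more than `xdrop` below its running maximum.
xdrop_extend <- function(v, from, dir, xdrop) {
  if (from + dir < 1L || from + dir > length(v)) return(0L)
  idx <- if (dir > 0) seq.int(from + 1L, length(v)) else seq.int(from - 1L, 1L)
  cs <- cumsum(v[idx])
  stop_at <- which(cummax(cs) - cs > xdrop)[1]
  if (!is.na(stop_at)) cs <- cs[seq_len(stop_at - 1L)]
  if (!length(cs) || max(cs) <= 0) return(0L)
  which.max(cs)
}

#' Re-apply per-query hit culling
#'
#' Engine-agnostic culling: per query, hits are ranked by bitscore
#' (ties: smaller `q_start`), and a hit is dropped when `limit` or more
#' better hits overlap it on the query by more than half of the shorter
#' hit's span.  `limit = 1` keeps only the best hit per query region.
#'
#' @param hits A hit `data.frame` from [search_sequences()].
#' @param limit Culling limit (>= 1).
#' @return The culled hit `data.frame`.
#' @export
apply_culling <- function(hits, limit = 1L) {
  stopifnot(limit >= 1L)
  if (!nrow(hits)) return(hits)
  keep_all <- logical(nrow(hits))
  for (qi in unique(hits$query_id)) {
    idx <- which(hits$query_id == qi)
    ord <- idx[order(-hits$bitscore[idx], hits$q_start[idx])]
    kept <- integer(0)
    for (i in ord) {
      if (length(kept)) {
        ov <- pmin(hits$q_end[i], hits$q_end[kept]) -
          pmax(hits$q_start[i], hits$q_start[kept])
        shorter <- pmin(hits$q_end[i] - hits$q_start[i],
                        hits$q_end[kept] - hits$q_start[kept])
        n_over <- sum(ov > 0.5 * shorter)
      } else n_over <- 0L
      if (n_over < limit) kept <- c(kept, i)
    }
    keep_all[kept] <- TRUE
  }
  out <- hits[keep_all, , drop = FALSE]
  rownames(out) <- NULL
  out
}
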