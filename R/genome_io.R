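#' @importFrom methods is
#' @importFrom utils head tail read.table write.csv
#' @importFrom stats setNames runif
NULL

# ---------------------------------------------------------------------------
# Domain containers
#
# All coordinates inside the package are 0-based half-open [start, end);
# conversion to/from the 1-based closed GenBank convention happens only at
# the read/write boundary.

empty_features <- function() {
  df <- data.frame(kind = character(), start = integer(), end = integer(),
                   strand = integer(), stringsAsFactors = FALSE)
  df$qualifiers <- list()
  df
}

#' Create a genome record
#'
#' A genome record is one scaffold/replicon: an identifier, a DNA sequence
#' over `A,C,G,T,N` (upper-cased), an ordered feature table and a topology.
#'
#' @param record_id Unique scaffold/replicon identifier.
#' @param sequence DNA sequence as a single character string.
#' @param features Feature `data.frame` with columns `kind`, `start`, `end`
#'   (0-based half-open), `strand` (+1/-1) and a list column `qualifiers`
#'   of named character vectors.
#' @param description Free-text description.
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(record_id, sequence, features = empty_features(),
                          description = "", topology = "linear") {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence))
    stop("record '", record_id, "' has an empty sequence", call. = FALSE)
  if (grepl("[^ACGTNRYSWKMBDHV]", sequence))
    stop("record '", record_id, "' contains non-nucleotide characters",
         call. = FALSE)
  if (is.null(features$qualifiers))
    features$qualifiers <- rep(list(character()), nrow(features))
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$strand <- as.integer(features$strand)
  len <- nchar(sequence)
  if (nrow(features)) {
    bad <- features$start < 0L | features$end > len |
      features$start >= features$end
    if (any(bad))
      stop("record '", record_id, "': ", sum(bad),
           " feature(s) outside [0, ", len, ") or empty", call. = FALSE)
    if (!all(features$strand %in% c(1L, -1L)))
      stop("record '", record_id, "': feature strand must be +1 or -1",
           call. = FALSE)
  }
  structure(list(record_id = as.character(record_id),
                 description = as.character(description),
                 sequence = sequence,
                 features = features,
                 topology = match.arg(topology, c("linear", "circular")),
                 length = len),
            class = "genome_record")
}

#' Create an assembly
#'
#' @param records List of [genome_record()] objects.
#' @param label Optional `"query"` or `"reference"` label.
#' @return An object of class `assembly`. `is_draft` is `TRUE` when the
#'   assembly has more than one record or any record carries no annotation.
#' @export
assembly <- function(records, label = NULL) {
  if (inherits(records, "genome_record")) records <- list(records)
  if (!length(records)) stop("assembly must contain at least one record",
                             call. = FALSE)
  ids <- vapply(records, function(r) r$record_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate record_id in assembly: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(records) <- ids
  draft <- length(records) > 1L ||
    any(vapply(records, function(r) nrow(r$features) == 0L, logical(1)))
  structure(list(records = records, label = label, is_draft = draft),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat("<assembly>", if (!is.null(x$label)) paste0("[", x$label, "]"),
      length(x$records), "record(s),",
      if (x$is_draft) "draft" else "complete", "\n")
  for (r in x$records)
    cat("  ", r$record_id, ": ", r$length, " nt, ",
        nrow(r$features), " feature(s)\n", sep = "")
  invisible(x)
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record>", x$record_id, paste0("(", x$length, " nt, "),
      nrow(x$features), "features )\n")
  invisible(x)
}

assembly_seqs <- function(asm) {
  vapply(asm$records, function(r) r$sequence, character(1))
}

# ---------------------------------------------------------------------------
# GenBank flat file reader

# Parse one GenBank location string into (start, end, strand) 0-based
# half-open.  Handles 'a..b', 'complement(...)', 'join(...)' (overall span),
# partial-end markers '<' and '>', and single-base 'a' locations.
parse_gb_location <- function(loc) {
  strand <- 1L
  loc <- gsub("[<>]", "", loc)
  while (grepl("^(complement|join|order)\\(", loc)) {
    if (grepl("^complement\\(", loc)) strand <- -strand
    loc <- sub("^[a-z]+\\((.*)\\)$", "\\1", loc)
  }
  nums <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
  if (!length(nums)) return(NULL)
  list(start = as.integer(min(nums) - 1L), end = as.integer(max(nums)),
       strand = strand)
}

#' Read a GenBank flat file
#'
#' Reads one or several records from a GenBank flat file, converting feature
#' locations from the 1-based closed GenBank convention to the package's
#' internal 0-based half-open convention. Records without sequence
#' (feature-only files) are a fatal error.
#'
#' @param path Path to a GenBank flat file.
#' @param label Optional assembly label (`"query"`/`"reference"`).
#' @return An [assembly()].
#' @export
read_genbank <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(startsWith(lines, "LOCUS")))
    stop("not a GenBank flat file (no LOCUS line): ", path, call. = FALSE)
  rec_starts <- which(startsWith(lines, "LOCUS"))
  rec_ends <- c(rec_starts[-1] - 1L, length(lines))
  records <- vector("list", length(rec_starts))
  for (i in seq_along(rec_starts)) {
    records[[i]] <- parse_gb_record(lines[rec_starts[i]:rec_ends[i]])
  }
  assembly(records, label = label)
}

parse_gb_record <- function(lines) {
  locus <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  record_id <- if (length(locus) >= 2) locus[2] else "unknown"
  topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"
  def_i <- which(startsWith(lines, "DEFINITION"))
  description <- ""
  if (length(def_i)) {
    j <- def_i[1]
    def <- sub("^DEFINITION\\s*", "", lines[j])
    while (j < length(lines) && grepl("^\\s{5,}", lines[j + 1]) &&
           !startsWith(lines[j + 1], "FEATURES")) {
      j <- j + 1
      def <- paste(def, trimws(lines[j]))
    }
    description <- sub("\\.$", "", def)
  }
  # ACCESSION/VERSION preferred as record_id when present
  acc_i <- which(startsWith(lines, "VERSION"))
  if (length(acc_i)) {
    v <- strsplit(trimws(lines[acc_i[1]]), "[[:space:]]+")[[1]]
    if (length(v) >= 2) record_id <- v[2]
  }

  feat_i <- which(startsWith(lines, "FEATURES"))
  orig_i <- which(startsWith(lines, "ORIGIN"))
  if (!length(orig_i))
    stop("GenBank record '", record_id,
         "' has no ORIGIN sequence section", call. = FALSE)
  orig_i <- orig_i[1]

  features <- empty_features()
  if (length(feat_i)) {
    flines <- lines[(feat_i[1] + 1L):(orig_i - 1L)]
    features <- parse_gb_features(flines, record_id)
  }

  seq_lines <- lines[(orig_i + 1L):length(lines)]
  seq_lines <- seq_lines[!startsWith(seq_lines, "//")]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence))
    stop("GenBank record '", record_id, "' has an empty sequence",
         call. = FALSE)
  genome_record(record_id, sequence, features, description, topology)
}

parse_gb_features <- function(flines, record_id) {
  # A feature line has its key at column 6; continuation/qualifier lines are
  # indented to column 22.
  is_key <- grepl("^ {5}\\S", flines)
  keys_at <- which(is_key)
  kind <- character(0); start <- integer(0); end <- integer(0)
  strand <- integer(0); quals <- list()
  for (k in seq_along(keys_at)) {
    i0 <- keys_at[k]
    i1 <- if (k < length(keys_at)) keys_at[k + 1] - 1L else length(flines)
    header <- trimws(flines[i0])
    parts <- strsplit(header, "[[:space:]]+")[[1]]
    fkind <- parts[1]
    body <- flines[i0:i1]
    body[1] <- sub("^ {5}\\S+\\s*", "", flines[i0])
    body <- trimws(body)
    # location = leading lines up to the first qualifier
    qstart <- which(startsWith(body, "/"))[1]
    loc_lines <- if (is.na(qstart)) body else head(body, qstart - 1L)
    loc <- parse_gb_location(paste(loc_lines, collapse = ""))
    if (is.null(loc) || identical(fkind, "source")) next
    q <- character(0)
    if (!is.na(qstart)) {
      qlines <- body[qstart:length(body)]
      # re-join wrapped qualifier values
      joined <- character(0)
      for (ln in qlines) {
        if (startsWith(ln, "/")) joined <- c(joined, ln)
        else if (length(joined))
          joined[length(joined)] <- paste(joined[length(joined)], ln)
      }
      keysv <- sub("^/([^=]+)(=.*)?$", "\\1", joined)
      vals <- ifelse(grepl("=", joined),
                     gsub('^"|"$', "", sub("^/[^=]+=", "", joined)), "")
      q <- setNames(vals, keysv)
    }
    kind <- c(kind, fkind); start <- c(start, loc$start)
    end <- c(end, loc$end); strand <- c(strand, loc$strand)
    quals <- c(quals, list(q))
  }
  df <- data.frame(kind = kind, start = start, end = end, strand = strand,
                   stringsAsFactors = FALSE)
  df$qualifiers <- quals
  df
}

# ---------------------------------------------------------------------------
# FASTA

#' Read an assembly from FASTA
#'
#' Annotation-free fallback input: records carry empty feature tables and
#' downstream result tables then have empty CDS-context columns.
#'
#' @inheritParams read_genbank
#' @return An [assembly()].
#' @export
read_fasta_assembly <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  if (!length(ss)) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(ss), "[[:space:]]+"), `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate FASTA headers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  records <- lapply(seq_along(ss), function(i)
    genome_record(ids[i], as.character(ss[[i]]),
                  description = names(ss)[i]))
  assembly(records, label = label)
}

#' Read an IS library from a multi-FASTA file
#'
#' IS name, family and group are extracted from each FASTA header according
#' to `header_convention`. The default `"underscore"` convention splits the
#' first whitespace-delimited token on `"_"` into `name_family_group`
#' (ISFinder compilation layout); headers without separators keep the whole
#' token as the name with family and group `"unknown"` (with a warning).
#'
#' @param path Multi-FASTA file of IS nucleotide sequences.
#' @param header_convention `"underscore"`, or a function taking the header
#'   string and returning a list/character vector with elements `name`,
#'   `family`, `group`.
#' @param min_len Minimum IS length; shorter entries are dropped with a
#'   warning (default 100).
#' @return An object of class `is_library`: a `data.frame` with columns
#'   `name`, `family`, `group`, `sequence`.
#' @export
read_is_library <- function(path, header_convention = "underscore",
                            min_len = 100L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  if (!length(ss)) stop("empty IS library: ", path, call. = FALSE)
  headers <- names(ss)
  seqs <- toupper(as.character(ss))
  is_library(headers, seqs, header_convention, min_len)
}

parse_is_header <- function(header, header_convention) {
  if (is.function(header_convention)) {
    out <- header_convention(header)
    return(list(name = out[["name"]], family = out[["family"]],
                group = out[["group"]]))
  }
  token <- strsplit(header, "[[:space:]]+")[[1]][1]
  parts <- strsplit(token, "_", fixed = TRUE)[[1]]
  if (length(parts) >= 3)
    list(name = parts[1], family = parts[2], group = parts[3])
  else if (length(parts) == 2)
    list(name = parts[1], family = parts[2], group = "unknown")
  else
    list(name = token, family = "unknown", group = "unknown", warn = TRUE)
}

#' Build an IS library from sequences in memory
#'
#' @param headers Character vector of FASTA-style headers (or plain names).
#' @param sequences Character vector of IS DNA sequences.
#' @inheritParams read_is_library
#' @return An `is_library` data.frame.
#' @export
is_library <- function(headers, sequences, header_convention = "underscore",
                       min_len = 100L) {
  parsed <- lapply(headers, parse_is_header, header_convention)
  warn <- vapply(parsed, function(p) isTRUE(p$warn), logical(1))
  if (any(warn))
    warning(sum(warn), " IS header(s) without family/group metadata; ",
            "family and group set to 'unknown'", call. = FALSE)
  lib <- data.frame(name = vapply(parsed, `[[`, character(1), "name"),
                    family = vapply(parsed, `[[`, character(1), "family"),
                    group = vapply(parsed, `[[`, character(1), "group"),
                    sequence = toupper(sequences),
                    stringsAsFactors = FALSE)
  short <- nchar(lib$sequence) < min_len
  if (any(short)) {
    warning("dropping ", sum(short), " IS entr(y/ies) shorter than ",
            min_len, " nt", call. = FALSE)
    lib <- lib[!short, , drop = FALSE]
  }
  if (!nrow(lib)) stop("IS library is empty after filtering", call. = FALSE)
  if (anyDuplicated(lib$name))
    stop("duplicate IS names in library: ",
         paste(unique(lib$name[duplicated(lib$name)]), collapse = ", "),
         call. = FALSE)
  rownames(lib) <- lib$name
  class(lib) <- c("is_library", "data.frame")
  lib
}

#' @export
print.is_library <- function(x, ...) {
  cat("<is_library>", nrow(x), "entries,",
      length(unique(x$family)), "famil(y/ies)\n")
  print.data.frame(utils::head(data.frame(name = x$name, family = x$family,
                                          group = x$group,
                                          length = nchar(x$sequence))),
                   row.names = FALSE)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Writers

format_gb_location <- function(start, end, strand) {
  loc <- paste0(start + 1L, "..", end)  # to 1-based closed
  if (strand < 0) loc <- paste0("complement(", loc, ")")
  loc
}

wrap_qualifier <- function(key, value) {
  if (!nzchar(value)) return(paste0("                     /", key))
  text <- paste0("/", key, "=\"", value, "\"")
  strwrap(text, width = 58, exdent = 0) |>
    vapply(function(s) paste0(strrep(" ", 21), s), character(1))
}

write_gb_record <- function(rec, con) {
  writeLines(sprintf("LOCUS       %-16s %10d bp    DNA     %-8s BCT",
                     rec$record_id, rec$length,
                     ifelse(rec$topology == "circular", "circular",
                            "linear")), con)
  if (nzchar(rec$description))
    writeLines(paste0("DEFINITION  ", rec$description, "."), con)
  writeLines(paste0("VERSION     ", rec$record_id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     %-16s1..%d", "source", rec$length), con)
  fts <- rec$features
  if (nrow(fts)) {
    for (i in seq_len(nrow(fts))) {
      writeLines(sprintf("     %-16s%s", fts$kind[i],
                         format_gb_location(fts$start[i], fts$end[i],
                                            fts$strand[i])), con)
      q <- fts$qualifiers[[i]]
      for (k in names(q)) writeLines(wrap_qualifier(k, q[[k]]), con)
    }
  }
  writeLines("ORIGIN", con)
  s <- rec$sequence
  pos <- seq(1L, rec$length, by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, rec$length))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tolower(groups), collapse = " ")),
               con)
  }
  writeLines("//", con)
}

#' Write an assembly to GenBank or FASTA
#'
#' Round trip through [read_genbank()] preserves sequences and feature
#' intervals exactly.
#'
#' @param asm An [assembly()].
#' @param path Output file path.
#' @param format `"genbank"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(asm, path, format = c("genbank", "fasta")) {
  format <- match.arg(format)
  stopifnot(inherits(asm, "assembly"))
  for (rec in asm$records) {
    if (nrow(rec$features) && any(rec$features$end > rec$length))
      stop("record '", rec$record_id,
           "' has features beyond the sequence end; refusing to write",
           call. = FALSE)
  }
  if (format == "fasta") {
    ss <- Biostrings::DNAStringSet(assembly_seqs(asm))
    names(ss) <- names(asm$records)
    Biostrings::writeXStringSet(ss, path)
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (rec in asm$records) write_gb_record(rec, con)
  }
  invisible(path)
}

#' Write an IS library to multi-FASTA
#'
#' Headers follow the underscore convention `name_family_group`.
#'
#' @param lib An `is_library`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_is_library <- function(lib, path) {
  ss <- Biostrings::DNAStringSet(setNames(lib$sequence,
                                          paste(lib$name, lib$family,
                                                lib$group, sep = "_")))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
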