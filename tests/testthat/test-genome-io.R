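# GenBank/FASTA reading, coordinate conventions and round trips.

gb_fixture_text <- function() {
  c("LOCUS       testrec               120 bp    DNA     linear   BCT",
    "DEFINITION  test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             10..99",
    "                     /locus_tag=\"T_0001\"",
    "                     /product=\"made-up protein with a rather long",
    "                     wrapped description\"",
    "     gene            complement(100..110)",
    "ORIGIN",
    paste0("        1 ", paste(substring(strrep("acgtt", 12), seq(1, 51, 10),
                                         seq(10, 60, 10)), collapse = " ")),
    paste0("       61 ", paste(substring(strrep("ggcca", 12), seq(1, 51, 10),
                                         seq(10, 60, 10)), collapse = " ")),
    "//")
}

test_that("GenBank 1-based closed locations become 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gb_fixture_text(), f)
  asm <- read_genbank(f)
  expect_length(asm$records, 1)
  rec <- asm$records[[1]]
  expect_equal(rec$length, 120)
  cds <- rec$features[rec$features$kind == "CDS", ]
  expect_equal(cds$start, 9L)   # "CDS 10..99" -> [9, 99)
  expect_equal(cds$end, 99L)
  expect_equal(cds$strand, 1L)
  gene <- rec$features[rec$features$kind == "gene", ]
  expect_equal(gene$strand, -1L)
  expect_equal(gene$start, 99L)
  expect_equal(cds$qualifiers[[1]][["locus_tag"]], "T_0001")
  # wrapped qualifier value re-joined
  expect_match(cds$qualifiers[[1]][["product"]], "wrapped description")
})

test_that("multi-record files give draft assemblies; degenerate input errors", {
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c(gb_fixture_text(),
               sub("testrec", "testrec2", gb_fixture_text())), f)
  asm <- read_genbank(f)
  expect_length(asm$records, 2)
  expect_true(asm$is_draft)

  f2 <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       empt              0 bp DNA linear",
               "ORIGIN", "//"), f2)
  expect_error(read_genbank(f2), "empty sequence")
  f3 <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       feat_only         10 bp DNA linear",
               "FEATURES             Location/Qualifiers",
               "     CDS             1..9", "//"), f3)
  expect_error(read_genbank(f3), "feat_only")
  f4 <- withr::local_tempfile(fileext = ".gbk")
  writeLines("", f4)
  expect_error(read_genbank(f4), "LOCUS")
})

test_that("assembly/write/read round trip preserves sequences and features", {
  asm <- fx_bg3()
  f <- withr::local_tempfile(fileext = ".gbk")
  write_assembly(asm, f, "genbank")
  back <- read_genbank(f)
  r0 <- asm$records[[1]]; r1 <- back$records[[1]]
  expect_identical(r0$sequence, r1$sequence)
  expect_identical(r0$features$start, r1$features$start)
  expect_identical(r0$features$end, r1$features$end)
  expect_identical(r0$features$strand, r1$features$strand)
  expect_identical(r0$features$kind, r1$features$kind)
  # parsing is deterministic
  again <- read_genbank(f)
  expect_identical(back$records[[1]]$features, again$records[[1]]$features)

  ff <- withr::local_tempfile(fileext = ".fna")
  write_assembly(asm, ff, "fasta")
  fasta <- read_fasta_assembly(ff)
  expect_identical(names(fasta$records), names(asm$records))
  expect_identical(fasta$records[[1]]$sequence, r0$sequence)
  expect_equal(nrow(fasta$records[[1]]$features), 0)
})

test_that("feature crossing the record end is refused at write time", {
  rec <- genome_record("x", strrep("ACGT", 50))
  rec$features <- rbind(empty_features(),
                        data.frame(kind = "CDS", start = 10L, end = 500L,
                                   strand = 1L,
                                   qualifiers = I(list(character())),
                                   stringsAsFactors = FALSE))
  asm <- structure(list(records = list(x = rec), label = NULL,
                        is_draft = FALSE), class = "assembly")
  f <- withr::local_tempfile(fileext = ".gbk")
  expect_error(write_assembly(asm, f, "genbank"), "refusing to write")
})

test_that("FASTA assembly reading upper-cases and validates", {
  f <- withr::local_tempfile(fileext = ".fna")
  writeLines(c(">c1 first contig", "acgtacgtacgt", ">c2", "GGGTTTAAACCC",
               ">c3", "ACGT"), f)
  asm <- read_fasta_assembly(f)
  expect_length(asm$records, 3)
  expect_identical(asm$records[["c1"]]$sequence, "ACGTACGTACGT")
  expect_true(asm$is_draft)

  fdup <- withr::local_tempfile(fileext = ".fna")
  writeLines(c(">c1", "ACGT", ">c1", "ACGT"), fdup)
  expect_error(read_fasta_assembly(fdup), "duplicate")
  fe <- withr::local_tempfile(fileext = ".fna")
  writeLines(character(0), fe)
  expect_error(read_fasta_assembly(fe), "empty|read")
})

test_that("IS library header conventions parse name/family/group", {
  f <- withr::local_tempfile(fileext = ".fna")
  writeLines(c(">ISRm5_IS256_unknown", strrep("ACGT", 60),
               ">ISEx2_IS3_IS150", strrep("GTCA", 60)), f)
  lib <- read_is_library(f)
  expect_identical(lib["ISRm5", "family"], "IS256")
  expect_identical(lib["ISRm5", "group"], "unknown")
  expect_identical(lib["ISEx2", "group"], "IS150")

  f2 <- withr::local_tempfile(fileext = ".fna")
  writeLines(c(">IS30", strrep("ACGT", 60)), f2)
  expect_warning(lib2 <- read_is_library(f2), "unknown")
  expect_identical(lib2$name, "IS30")
  expect_identical(lib2$family, "unknown")

  f3 <- withr::local_tempfile(fileext = ".fna")
  writeLines(c(">IS30_IS30", strrep("ACGT", 60),
               ">IS30_IS30", strrep("TGCA", 60)), f3)
  expect_error(read_is_library(f3), "duplicate")
  f4 <- withr::local_tempfile(fileext = ".fna")
  writeLines(character(0), f4)
  expect_error(read_is_library(f4), "empty|read")
  # custom convention function
  lib4 <- is_library("X99|famZ", strrep("ACGT", 50),
                     header_convention = function(h) {
                       p <- strsplit(h, "|", fixed = TRUE)[[1]]
                       list(name = p[1], family = p[2], group = "unknown")
                     })
  expect_identical(lib4$family, "famZ")
})

test_that("short IS entries are dropped with a warning", {
  expect_warning(lib <- is_library(c("A_f_g", "B_f_g"),
                                   c(strrep("ACGT", 50), "ACGTACGT")),
                 "shorter")
  expect_identical(lib$name, "A")
  expect_error(suppressWarnings(is_library("B_f_g", "ACGTACGT")), "empty")
})
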