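# Whole-run behaviour: both directions, consolidation, annotation,
# output files.

test_that("simulated insertions are recovered as query-side DLIS", {
  res <- fx_res5()
  sim <- fx_sim5()
  rows <- res$dlis_records
  expect_equal(sum(rows$found_in == "query" &
                     rows$classification == "DLIS"), 5)
  expect_equal(sum(rows$found_in == "reference"), 0)
  sc <- score_against_truth(res, sim$truth)
  expect_equal(sc$scores$sensitivity, c(1, 1))
  expect_equal(sc$scores$precision, c(1, 1))
})

test_that("swapping the genomes mirrors the calls at the same loci", {
  res <- fx_res5()
  sim <- fx_sim5()
  swapped <- run_comparison(fx_genome60(), sim$assembly, fx_lib1())
  rows <- swapped$dlis_records
  expect_equal(sum(rows$found_in == "query"), 0)
  ref_rows <- rows[rows$found_in == "reference", ]
  expect_equal(nrow(ref_rows), 5)
  expect_true(all(ref_rows$classification == "DLIS"))
  fwd <- res$dlis_records[res$dlis_records$found_in == "query", ]
  expect_equal(sort(ref_rows$anchor_point), sort(fwd$anchor_point))
})

test_that("genome versus itself reports nothing", {
  g <- fx_bg3()
  res <- run_comparison(g, g, fx_lib3())
  expect_equal(nrow(res$dlis_records), 0)
  expect_equal(res$stats$removed_identical_query, 1L)
  expect_equal(sum(res$stats$categories), 0L)
})

test_that("CDS context annotation picks flanking genes", {
  res <- fx_res5()
  rows <- res$dlis_records[res$dlis_records$classification == "DLIS", ]
  # synthetic genomes carry a CDS every 3 kb, so within 5 kb of any site
  expect_true(all(nzchar(rows$query_left_cds) |
                    nzchar(rows$query_right_cds)))
  expect_true(all(grepl("hypothetical protein",
                        paste(rows$ref_left_cds, rows$ref_right_cds))))
  # FASTA-only (feature-free) assemblies yield empty context
  sim <- fx_sim5()
  bare_q <- assembly(genome_record("synchr1",
                                   sim$assembly$records[[1]]$sequence))
  bare_r <- assembly(genome_record("synchr1",
                                   fx_genome60()$records[[1]]$sequence))
  res2 <- run_comparison(bare_q, bare_r, fx_lib1())
  rows2 <- res2$dlis_records
  expect_equal(sum(rows2$classification == "DLIS"), 5)
  expect_true(all(rows2$query_left_cds == ""))
  expect_true(all(rows2$ref_right_cds == ""))
})

test_that("output tables carry the documented columns and are stable", {
  res <- fx_res5()
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  write_outputs(res, out1)
  write_outputs(res, out2)
  fr <- read.csv(file.path(out1, "FinalResults.csv"),
                 stringsAsFactors = FALSE)
  expect_identical(names(fr),
                   c("is_id", "is_start", "is_end", "query_id",
                     "query_flank_loc", "ref_id", "ref_flank_loc",
                     "found_in", "classification", "hit_quality",
                     "query_left_cds", "query_right_cds", "ref_left_cds",
                     "ref_right_cds"))
  expect_equal(nrow(fr), nrow(res$dlis_records))
  expect_true(all(fr$is_start >= 1))        # 1-based closed on output
  qis <- read.csv(file.path(out1, "QueryISs.csv"))
  expect_equal(nrow(qis), nrow(res$query_is))
  expect_true(file.exists(file.path(out1, "RefISs.csv")))
  expect_true(file.exists(file.path(out1, "ConsecutiveIS.csv")))
  # stats.txt category counts equal FinalResults rows per classification
  st <- read.table(file.path(out1, "stats.txt"), sep = "\t", fill = TRUE,
                   stringsAsFactors = FALSE)
  cat_rows <- st[st$V1 == "category", ]
  for (k in seq_len(nrow(cat_rows)))
    expect_equal(sum(fr$classification == cat_rows$V2[k]),
                 as.integer(cat_rows$V3[k]))
  js <- jsonlite::read_json(file.path(out1, "stats.json"))
  expect_equal(js$categories$DLIS, 5)
  # byte-identical rerun
  for (f in list.files(out1))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), info = f)
})

test_that("empty comparisons write headers-only tables with zero stats", {
  g <- fx_genome60()
  res <- run_comparison(g, g, fx_lib1())
  out <- withr::local_tempdir()
  write_outputs(res, out)
  fr <- read.csv(file.path(out, "FinalResults.csv"))
  expect_equal(nrow(fr), 0)
  js <- jsonlite::read_json(file.path(out, "stats.json"))
  expect_true(all(unlist(js$categories) == 0))
})

test_that("provenance records backend, engine and input digests", {
  res <- fx_res5()
  expect_true(res$provenance$backend %in% c("external", "builtin"))
  expect_match(res$provenance$engine, "blast|builtin", ignore.case = TRUE)
  expect_match(res$provenance$query_md5, "^[0-9a-f]{32}$")
  expect_false(identical(res$provenance$query_md5,
                         res$provenance$reference_md5))
})
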