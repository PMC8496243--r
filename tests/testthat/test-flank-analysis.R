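# QIF extraction geometry, related-IS flags, anchor mapping and
# classification.

test_that("QIF intervals follow the shift geometry and record bounds", {
  rec <- genome_record("r", random_dna(20000, seed = 61))
  asm <- assembly(rec)
  occ <- data.frame(occ_id = 1L, record_id = "r", start = 10000L,
                    end = 11000L, is_name = "X", family = "f", group = "g",
                    partial = FALSE, identity_pct = 100, evalue = 0,
                    aln_length = 1000L, consecutive = FALSE,
                    stringsAsFactors = FALSE)
  q0 <- extract_qifs(occ, asm, dlis_config())
  expect_equal(c(q0$left_start, q0$left_end), c(9500L, 10000L))
  expect_equal(c(q0$right_start, q0$right_end), c(11000L, 11500L))
  expect_true(q0$both_present)
  qS <- extract_qifs(occ, asm, dlis_config(shift = 3000))
  expect_equal(c(qS$left_start, qS$left_end), c(6500L, 7000L))
  expect_equal(c(qS$right_start, qS$right_end), c(14000L, 14500L))
  # IS ending at the record end: right flank absent
  occ2 <- occ; occ2$start <- 19000L; occ2$end <- 20000L
  q2 <- extract_qifs(occ2, asm, dlis_config())
  expect_true(is.na(q2$right_start))
  expect_false(q2$both_present)
  expect_false(nzchar(q2$right_seq))
  # flank shorter than minLength is dropped as absent
  occ3 <- occ; occ3$start <- 30L; occ3$end <- 1030L
  q3 <- extract_qifs(occ3, asm, dlis_config())
  expect_true(is.na(q3$left_start))
})

test_that("related-IS-in-flank is flagged at the most specific level", {
  lib <- synthetic_is_library(4, 1200, seed = 7,
                              family = c("famX", "famX", "famY", "famY"))
  # occurrence of entry 1; entry 2 shares its family, entry 3 does not
  mk <- function(flank_insert) {
    seqs <- paste0(random_dna(300, seed = 71), flank_insert,
                   random_dna(150, seed = 72), lib$sequence[1],
                   random_dna(600, seed = 73))
    asm <- assembly(genome_record("r", seqs))
    occ <- scan_is(asm, lib)
    occ <- occ[occ$is_name == "ISSyn1", , drop = FALSE]
    qifs <- extract_qifs(occ, asm, dlis_config())
    flag_related_is(qifs, occ, lib, dlis_config())
  }
  same_is <- mk(substr(lib$sequence[1], 1, 350))
  expect_equal(same_is$related, "same_is")
  same_fam <- mk(substr(lib$sequence[2], 1, 350))
  expect_equal(same_fam$related, "same_family")
  unrelated <- mk(substr(lib$sequence[3], 1, 350))
  expect_equal(unrelated$related, "none")
  clean <- mk(random_dna(350, seed = 74))
  expect_equal(clean$related, "none")
})

test_that("merged QIFs map contiguous reference loci as DLIS candidates", {
  sim <- fx_sim5()
  occ <- scan_is(sim$assembly, fx_lib1())
  qifs <- extract_qifs(occ, sim$assembly, dlis_config())
  merged <- map_merged(qifs, fx_genome60(), dlis_config())
  expect_length(merged, 5)   # 4 nt TSD does not defeat the >90 qcov test
  pts <- sort(vapply(merged, `[[`, integer(1), "point"))
  expect_true(all(abs(pts - sort(sim$truth$position)) <= 10))
})

test_that("classification partitions all occurrences exactly once", {
  res <- fx_res5()
  rows <- res$dlis_records
  expect_equal(nrow(rows) + res$stats$duplicates_merged,
               res$stats$occurrences_query +
                 res$stats$occurrences_reference)
  expect_true(all(rows$classification %in% CLASSIFICATIONS))
  expect_equal(sum(res$stats$categories), nrow(rows))
})

test_that("self-classification yields SLIS everywhere", {
  g <- fx_bg3()
  res <- run_comparison(g, g, fx_lib3(), filter_identical = FALSE)
  expect_gt(nrow(res$dlis_records), 0)
  expect_true(all(res$dlis_records$classification == "SLIS"))
  expect_equal(res$stats$categories[["DLIS"]], 0L)
})

test_that("flanks anchoring to different replicons are context mismatches", {
  lib <- fx_lib1()
  left_bg <- random_dna(3000, seed = 81)
  right_bg <- random_dna(3000, seed = 82)
  # reference keeps the two contexts on separate records
  ref <- assembly(list(genome_record("repA",
                                     paste0(random_dna(2000, seed = 83),
                                            left_bg)),
                       genome_record("repB",
                                     paste0(right_bg,
                                            random_dna(2000, seed = 84)))))
  qry <- assembly(genome_record("q", paste0(left_bg, lib$sequence[1],
                                            right_bg)))
  res <- run_comparison(qry, ref, lib)
  expect_equal(res$dlis_records$classification,
               "DISCARD_CONTEXT_MISMATCH")
})

test_that("flanks absent from the reference give no-anchor discards", {
  lib <- fx_lib1()
  qry <- assembly(genome_record("q", paste0(random_dna(2000, seed = 85),
                                            lib$sequence[1],
                                            random_dna(2000, seed = 86))))
  ref <- assembly(genome_record("r", random_dna(30000, seed = 87)))
  res <- run_comparison(qry, ref, lib)
  expect_equal(res$dlis_records$classification, "DISCARD_NO_ANCHOR")
})

test_that("a repeated single flank gives an unspecific multi-hit", {
  lib <- fx_lib1()
  unit <- random_dna(700, seed = 88)          # 3-copy repeat unit
  ref <- assembly(genome_record("r",
    paste0(random_dna(4000, seed = 89), unit,
           random_dna(4000, seed = 90), unit,
           random_dna(4000, seed = 91), unit,
           random_dna(4000, seed = 92))))
  # draft-like query contig: repeat unit then a partial IS at the contig
  # end; its only flank matches three reference loci
  qry <- assembly(genome_record("q",
    paste0(random_dna(100, seed = 93), unit,
           substr(lib$sequence[1], 1, 600))))
  res <- run_comparison(qry, ref, lib)
  expect_equal(res$dlis_records$classification,
               "VERIFY_UNSPECIFIC_MULTIHIT")
  expect_equal(res$stats$categories[["DLIS"]], 0L)
})

test_that("a single-flank contig-end IS resolves through one anchor", {
  lib <- fx_lib1()
  bg <- random_dna(8000, seed = 94)
  ref <- assembly(genome_record("r", bg))
  qry <- assembly(genome_record("q",
    paste0(substr(bg, 2001, 6000), substr(lib$sequence[1], 1, 650))))
  res <- run_comparison(qry, ref, lib)
  rows <- res$dlis_records
  expect_equal(rows$classification, "DLIS")
  expect_equal(rows$hit_quality, "partial")
  expect_equal(rows$anchor_point, 6000L)
})
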