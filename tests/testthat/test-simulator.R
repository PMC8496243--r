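# Insertion simulator invariants: length conservation, TSD structure,
# feature shifting, determinism, fragmentation.

test_that("inserted length is conserved exactly", {
  sim <- fx_sim5()
  expect_equal(sim$assembly$records[[1]]$length,
               fx_genome60()$records[[1]]$length + 5L * (1200L + 4L))
  expect_equal(nrow(sim$truth), 5)
  expect_equal(sim$truth$position + cumsum(c(0, rep(1204, 4))),
               sim$truth$position_modified)
})

test_that("the IS sequence and TSD are retrievable at every mapped site", {
  g <- fx_genome60()
  lib <- fx_lib1()
  sim <- simulate_insertions(g, lib[1, ],
                             simulation_spec(6, tsd_length = 6,
                                             min_spacing = 4000, seed = 5))
  mseq <- sim$assembly$records[[1]]$sequence
  oseq <- g$records[[1]]$sequence
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    got <- substr(mseq, tr$position_modified + 1,
                  tr$position_modified + tr$is_length)
    want <- if (tr$orientation == "+") lib$sequence[1]
            else dliscan:::revcomp(lib$sequence[1])
    expect_identical(got, want)
    # TSD: the 6 nt left of the insertion point appear again after the IS
    before <- substr(oseq, tr$position - 5, tr$position)
    after <- substr(mseq, tr$position_modified + tr$is_length + 1,
                    tr$position_modified + tr$is_length + 6)
    expect_identical(after, before)
  }
})

test_that("tsd 0 inserts the bare IS and feature sequences are unchanged", {
  g <- fx_genome60()
  lib <- fx_lib1()
  sim <- simulate_insertions(g, lib[1, ],
                             simulation_spec(4, tsd_length = 0,
                                             min_spacing = 6000, seed = 9))
  expect_equal(sim$assembly$records[[1]]$length,
               g$records[[1]]$length + 4L * 1200L)
  orig <- g$records[[1]]; mod <- sim$assembly$records[[1]]
  fo <- orig$features[orig$features$kind == "CDS", ]
  fm <- mod$features[mod$features$kind == "CDS", ]
  expect_equal(nrow(fo), nrow(fm))
  hit_inside <- vapply(seq_len(nrow(fo)), function(i)
    any(sim$truth$position > fo$start[i] & sim$truth$position < fo$end[i]),
    logical(1))
  for (i in which(!hit_inside)) {
    expect_identical(substr(orig$sequence, fo$start[i] + 1, fo$end[i]),
                     substr(mod$sequence, fm$start[i] + 1, fm$end[i]))
  }
})

test_that("simulation is deterministic per seed and checks feasibility", {
  g <- fx_genome60()
  lib <- fx_lib1()
  s1 <- simulate_insertions(g, lib[1, ], simulation_spec(5, seed = 77))
  s2 <- simulate_insertions(g, lib[1, ], simulation_spec(5, seed = 77))
  expect_identical(s1$assembly$records[[1]]$sequence,
                   s2$assembly$records[[1]]$sequence)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_insertions(g, lib[1, ], simulation_spec(5, seed = 78))
  expect_false(identical(s1$truth$position, s3$truth$position))
  expect_error(simulate_insertions(g, lib[1, ],
                                   simulation_spec(30, min_spacing = 5000,
                                                   seed = 1)),
               "infeasible")
})

test_that("synthetic genomes are seeded, GC-controlled and IS-seeded", {
  g1 <- make_synthetic_genome(50000, 0.5, seed = 13)
  g2 <- make_synthetic_genome(50000, 0.5, seed = 13)
  expect_identical(g1$records[[1]]$sequence, g2$records[[1]]$sequence)
  expect_equal(g1$records[[1]]$length, 50000L)
  hi_gc <- make_synthetic_genome(50000, 0.65, seed = 13)
  gc_frac <- function(s) {
    b <- table(strsplit(s, "")[[1]])
    (b[["G"]] + b[["C"]]) / nchar(s)
  }
  expect_gt(gc_frac(hi_gc$records[[1]]$sequence), 0.63)
  expect_lt(gc_frac(g1$records[[1]]$sequence), 0.52)
  withbg <- make_synthetic_genome(80000, 0.5, n_background_is = 4,
                                  library = fx_lib3(), seed = 14)
  expect_equal(withbg$records[[1]]$length, 80000L)
  occ <- scan_is(withbg, fx_lib3())
  expect_equal(nrow(occ), 4)
})

test_that("fragmentation splits at IS midpoints and maps back", {
  sim <- fx_sim5()
  draft <- fragment_assembly(sim$assembly, is_midpoint_breakpoints(sim$truth))
  expect_length(draft$records, 6)   # 5 cuts -> 6 contigs
  map <- attr(draft, "fragment_map")
  expect_equal(sum(map$length), sim$assembly$records[[1]]$length)
  # reassembling the contigs restores the full sequence
  glued <- paste(vapply(draft$records, function(r) r$sequence,
                        character(1)), collapse = "")
  expect_identical(glued, sim$assembly$records[[1]]$sequence)
  # no breakpoints: identity
  same <- fragment_assembly(sim$assembly, list())
  expect_identical(names(same$records), names(sim$assembly$records))
  expect_identical(same$records[[1]]$sequence,
                   sim$assembly$records[[1]]$sequence)
  # one explicit cut -> 2 contigs
  two <- fragment_assembly(sim$assembly, list(synchr1 = 30000L))
  expect_length(two$records, 2)
})
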