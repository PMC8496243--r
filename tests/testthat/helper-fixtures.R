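# Shared fixtures, built in code and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# one-entry synthetic IS library (1200 nt)
fx_lib1 <- function() fixture("lib1", function()
  synthetic_is_library(1, 1200, seed = 7))

# three-entry library across families/groups
fx_lib3 <- function() fixture("lib3", function()
  synthetic_is_library(3, c(1200, 1000, 1400), seed = 7))

# 60 kb clean background genome
fx_genome60 <- function() fixture("genome60", function()
  make_synthetic_genome(60000, 0.5, seed = 11))

# 60 kb genome + 5 simulated insertions (4 nt TSD, 5 kb spacing)
fx_sim5 <- function() fixture("sim5", function()
  simulate_insertions(fx_genome60(), fx_lib1()[1, ],
                      simulation_spec(5, tsd_length = 4,
                                      min_spacing = 5000, seed = 3)))

# full comparison of the simulated genome against its source
fx_res5 <- function() fixture("res5", function()
  run_comparison(fx_sim5()$assembly, fx_genome60(), fx_lib1()))

# small genome with 3 background IS copies (for self-comparison tests)
fx_bg3 <- function() fixture("bg3", function()
  make_synthetic_genome(40000, 0.5, n_background_is = 3,
                        library = fx_lib3(), seed = 21))

default_cfg <- function(...) dlis_config(...)

expect_same_hits <- function(a, b, tol_nt = 2) {
  key <- function(h) h[order(h$query_id, h$subject_id, h$s_strand,
                             h$s_start), ]
  a <- key(a); b <- key(b)
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$query_id, b$query_id)
  expect_equal(a$subject_id, b$subject_id)
  expect_equal(a$s_strand, b$s_strand)
  expect_true(all(abs(a$q_start - b$q_start) <= tol_nt))
  expect_true(all(abs(a$q_end - b$q_end) <= tol_nt))
  expect_true(all(abs(a$s_start - b$s_start) <= tol_nt))
  expect_true(all(abs(a$s_end - b$s_end) <= tol_nt))
}
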