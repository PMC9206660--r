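test_that("true effect parameters follow the stated mean/concentration", {
  lib <- make_test_library(3, seed = 31)
  eff <- draw_true_effects(lib, control_mean = 0.2, concentration = 50)
  expect_equal(eff$alpha, rep(10, 3))
  expect_equal(eff$beta, rep(40, 3))

  enh <- lib$peptide_id[2]
  eff2 <- draw_true_effects(lib, control_mean = 0.2, enhancer_ids = enh,
                            enhancer_fold = 1.7, concentration = 50)
  expect_equal(eff2$alpha[eff2$peptide_id == enh], 17)
  expect_equal(eff2$beta[eff2$peptide_id == enh], 33)

  # fold 1.0 leaves enhancers indistinguishable from the baseline law
  eff3 <- draw_true_effects(lib, enhancer_ids = enh, enhancer_fold = 1)
  expect_equal(unique(eff3$alpha), eff3$alpha[1])

  expect_error(draw_true_effects(lib, control_mean = 0.4, enhancer_ids = enh,
                                 enhancer_fold = 3), "must be < 1")
})

test_that("simulated screens conserve counts and record matching FASTQ", {
  lib <- make_test_library(4, seed = 33)
  eff <- draw_true_effects(lib)
  sim <- simulate_screen(lib, eff, depth = 120, replicates = 2, seed = 17,
                         out_dir = tempfile())
  tr <- sim$truth
  expect_true(all(tr$prime_edited + tr$unedited + tr$indel + tr$other == tr$n))
  expect_true(all(tr$n == 120L))
  for (s in seq_len(nrow(sim$sample_sheet))) {
    r1 <- Biostrings::readDNAStringSet(sim$sample_sheet$r1[s], format = "fastq")
    r2 <- Biostrings::readDNAStringSet(sim$sample_sheet$r2[s], format = "fastq")
    expect_equal(length(r1), 4L * 120L)
    expect_equal(length(r2), 4L * 120L)
    expect_identical(names(r1), names(r2))
  }
})

test_that("degenerate rates pin every read-2 allele", {
  lib <- make_test_library(2, seed = 35)
  spec <- example_edit_spec()
  never <- data.frame(peptide_id = lib$peptide_id, alpha = 1e-9, beta = 1)
  sim0 <- simulate_screen(lib, never, spec, depth = 80, replicates = 1,
                          indel_rate = 0, error_rate = 0, partial_frac = 0,
                          seed = 19, out_dir = tempfile())
  r2 <- as.character(Biostrings::readDNAStringSet(sim0$sample_sheet$r2[1],
                                                  format = "fastq"))
  expect_true(all(r2 == spec$ref_amplicon))

  always <- data.frame(peptide_id = lib$peptide_id, alpha = 1, beta = 1e-9)
  sim1 <- simulate_screen(lib, always, spec, depth = 80, replicates = 1,
                          indel_rate = 0, error_rate = 0, partial_frac = 0,
                          seed = 19, out_dir = tempfile())
  r2 <- as.character(Biostrings::readDNAStringSet(sim1$sample_sheet$r2[1],
                                                  format = "fastq"))
  edited <- paste0(substr(spec$ref_amplicon, 1, spec$edit_start), "GAATTC",
                   substr(spec$ref_amplicon, spec$edit_start + 7,
                          nchar(spec$ref_amplicon)))
  expect_true(all(r2 == edited))
})

test_that("identical inputs and seed give byte-identical FASTQ", {
  lib <- make_test_library(2, seed = 37)
  eff <- draw_true_effects(lib)
  s1 <- simulate_screen(lib, eff, depth = 60, replicates = 1, seed = 23,
                        out_dir = tempfile())
  s2 <- simulate_screen(lib, eff, depth = 60, replicates = 1, seed = 23,
                        out_dir = tempfile())
  expect_identical(readLines(s1$sample_sheet$r1[1]),
                   readLines(s2$sample_sheet$r1[1]))
  expect_identical(readLines(s1$sample_sheet$r2[1]),
                   readLines(s2$sample_sheet$r2[1]))
  expect_equal(unname(tools::md5sum(s1$sample_sheet$r2[1])),
               unname(tools::md5sum(s2$sample_sheet$r2[1])))
  s3 <- simulate_screen(lib, eff, depth = 60, replicates = 1, seed = 24,
                        out_dir = tempfile())
  expect_false(identical(readLines(s1$sample_sheet$r2[1]),
                         readLines(s3$sample_sheet$r2[1])))
})

test_that("replicate overdispersion tracks the concentration parameter", {
  lib <- make_test_library(1, seed = 39)
  depth <- 400L
  frac_var <- function(conc, seed) {
    eff <- draw_true_effects(lib, control_mean = 0.3, concentration = conc)
    sim <- simulate_screen(lib, eff, depth = depth, replicates = 40,
                           indel_rate = 0, error_rate = 0, partial_frac = 0,
                           seed = seed, out_dir = tempfile())
    stats::var(sim$truth$prime_edited / sim$truth$n)
  }
  binom_var <- 0.3 * 0.7 / depth
  v_small <- frac_var(5, 41)       # strong overdispersion
  v_large <- frac_var(1e6, 43)     # essentially binomial
  expect_gt(v_small, 4 * binom_var)
  expect_lt(v_large, 3 * binom_var)
})

test_that("dual-screen simulation is additive with Gaussian noise", {
  a <- c(CTRL = 0, N1 = 0.3, N2 = 0.6)
  b <- c(CTRL = 0, C1 = 0.2)
  flat <- simulate_dual_screen(c(CTRL = 0, N1 = 0), c(CTRL = 0, C1 = 0),
                               baseline = 1.5, noise_sd = 0, seed = 3)
  expect_true(all(flat$observations$normalized_edited_fraction == 1.5))

  sim <- simulate_dual_screen(a, b, baseline = 1, noise_sd = 0, seed = 3)
  expect_equal(nrow(sim$observations), 6L)
  got <- sim$observations
  expect_equal(got$normalized_edited_fraction,
               1 + unname(a[got$n_term_id]) + unname(b[got$c_term_id]))

  ten <- stats::setNames(seq(0, 0.9, by = 0.1), paste0("x", 1:10))
  grid <- simulate_dual_screen(ten, ten, noise_sd = 0.05, seed = 5)
  expect_equal(nrow(grid$observations), 100L)
  reps <- simulate_dual_screen(a, b, replicates = 3, seed = 7)
  expect_equal(nrow(reps$observations), 18L)
})
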