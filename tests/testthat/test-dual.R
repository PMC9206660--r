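# Additive decomposition of dual-peptide editing.

planted_effects <- function(k, seed = 1, prefix = "P") {
  set.seed(seed)
  stats::setNames(c(0, round(stats::runif(k - 1, -0.2, 0.8), 3)),
                  c("CTRL", paste0(prefix, seq_len(k - 1))))
}

test_that("noiseless additive grids are recovered exactly", {
  a <- planted_effects(4, seed = 81, prefix = "N")
  b <- planted_effects(4, seed = 82, prefix = "C")
  sim <- simulate_dual_screen(a, b, baseline = 1, noise_sd = 0, seed = 1)
  fit <- fit_additive(sim$observations, control_id = "CTRL")
  expect_equal(fit$pearson_r, 1)
  expect_equal(max(abs(fit$fitted$observed_median - fit$fitted$predicted)), 0,
               tolerance = 1e-12)
  expect_equal(fit$baseline, 1, tolerance = 1e-10)
  expect_equal(fit$n_effects[names(a)], a, tolerance = 1e-10)
  expect_equal(fit$c_effects[names(b)], b, tolerance = 1e-10)
})

test_that("least squares matches the normal-equations oracle under noise", {
  a <- planted_effects(3, seed = 83, prefix = "N")
  b <- planted_effects(3, seed = 84, prefix = "C")
  sim <- simulate_dual_screen(a, b, baseline = 1, noise_sd = 0.05,
                              replicates = 3, seed = 9)
  fit <- fit_additive(sim$observations, control_id = "CTRL")
  med <- stats::aggregate(normalized_edited_fraction ~ n_term_id + c_term_id,
                          data = sim$observations, FUN = stats::median)
  names(med)[3] <- "observed_median"
  oracle <- oracle_additive_fit(med, "CTRL")
  expect_equal(fit$baseline, unname(oracle["baseline"]), tolerance = 1e-8)
  for (id in setdiff(names(a), "CTRL")) {
    expect_equal(unname(fit$n_effects[id]), unname(oracle[paste0("N:", id)]),
                 tolerance = 1e-8)
  }
  for (id in setdiff(names(b), "CTRL")) {
    expect_equal(unname(fit$c_effects[id]), unname(oracle[paste0("C:", id)]),
                 tolerance = 1e-8)
  }
})

test_that("flat data yield zero effects and an undefined correlation", {
  obs <- expand.grid(n_term_id = c("CTRL", "x"), c_term_id = c("CTRL", "y"),
                     replicate = 1L, stringsAsFactors = FALSE)
  obs$normalized_edited_fraction <- 2.5
  fit <- fit_additive(obs, control_id = "CTRL")
  expect_equal(fit$baseline, 2.5)
  expect_true(all(abs(c(fit$n_effects, fit$c_effects)) < 1e-12))
  expect_true(is.na(fit$pearson_r))
  expect_warning(r <- additivity_r(fit), "undefined")
  expect_true(is.na(r))
})

test_that("pair predictions are the anchored sums of effects", {
  a <- planted_effects(4, seed = 85, prefix = "N")
  b <- planted_effects(4, seed = 86, prefix = "C")
  sim <- simulate_dual_screen(a, b, baseline = 1, noise_sd = 0, seed = 2)
  fit <- fit_additive(sim$observations, control_id = "CTRL")
  expect_equal(predict_pair(fit, "CTRL", "CTRL"), fit$baseline)
  best_n <- names(which.max(fit$n_effects))
  best_c <- names(which.max(fit$c_effects))
  preds <- outer(names(a), names(b),
                 Vectorize(function(x, y) predict_pair(fit, x, y)))
  expect_equal(max(preds), predict_pair(fit, best_n, best_c))
  expect_equal(predict_pair(fit, "N1", "C2"),
               fit$baseline + fit$n_effects[["N1"]] + fit$c_effects[["C2"]])
  expect_error(predict_pair(fit, "nope", "C1"), "unknown N-terminal")
})

test_that("predictions are invariant to the anchoring peptide", {
  ids <- c("CTRL", "A", "B")
  a <- stats::setNames(c(0, 0.4, 0.1), ids)
  b <- stats::setNames(c(0, 0.3, -0.1), ids)
  sim <- simulate_dual_screen(a, b, baseline = 1, noise_sd = 0.03, seed = 11)
  f1 <- fit_additive(sim$observations, control_id = "CTRL")
  f2 <- fit_additive(sim$observations, control_id = "A")
  for (x in ids) for (y in ids) {
    expect_equal(predict_pair(f1, x, y), predict_pair(f2, x, y),
                 tolerance = 1e-10)
  }
})

test_that("additivity r degrades with interaction and noise", {
  ten_n <- planted_effects(10, seed = 87, prefix = "N")
  ten_c <- planted_effects(10, seed = 88, prefix = "C")
  clean <- simulate_dual_screen(ten_n, ten_c, noise_sd = 0, seed = 13)
  r_clean <- additivity_r(fit_additive(clean$observations, "CTRL"))
  expect_equal(r_clean, 1, tolerance = 1e-12)

  noisy <- simulate_dual_screen(ten_n, ten_c, noise_sd = 0.05, seed = 13)
  r_noisy <- additivity_r(fit_additive(noisy$observations, "CTRL"))
  expect_gt(r_noisy, 0.9)
  expect_lt(r_noisy, r_clean)

  # planted multiplicative interaction lowers r below the additive case
  inter <- clean$observations
  mult <- (1 + ten_n[inter$n_term_id]) * (1 + ten_c[inter$c_term_id])
  inter$normalized_edited_fraction <- unname(mult)
  r_inter <- additivity_r(fit_additive(inter, "CTRL"))
  expect_lt(r_inter, 1)

  # anti-correlated observations give r = -1
  flip <- clean$observations
  fitc <- fit_additive(clean$observations, "CTRL")
  flip$normalized_edited_fraction <- 3 - flip$normalized_edited_fraction
  expect_equal(additivity_r(fitc, flip), -1, tolerance = 1e-10)
})

test_that("disconnected pair designs are rejected", {
  obs <- data.frame(
    n_term_id = c("CTRL", "A", "B", "B"),
    c_term_id = c("CTRL", "CTRL", "X", "Y"),
    replicate = 1L,
    normalized_edited_fraction = c(1, 1.2, 1.4, 1.1),
    stringsAsFactors = FALSE
  )
  expect_error(fit_additive(obs, control_id = "CTRL"), "disconnected")
})
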