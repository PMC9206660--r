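# Beta-binomial inference of per-peptide editing effects.
#
# Model: the editing rate of peptide i in replicate j is
# p_ij ~ Beta(alpha_i, beta_i) and the edited read count is
# y_ij ~ Bin(n_j, p_ij), so y_ij is beta-binomial. The MLE of
# (alpha_i, beta_i) over k replicates solves the digamma score equations
#   0 = sum_j [psi(y_j + a) - psi(n_j + a + b)] - k [psi(a) - psi(a + b)]
#   0 = sum_j [psi(n_j - y_j + b) - psi(n_j + a + b)] - k [psi(b) - psi(a + b)]
# (the stationarity conditions of the log-likelihood
#  sum_j ln B(y_j + a, n_j - y_j + b) - k ln B(a, b)).
# A moment-matching fall-back treats the beta-binomial as an overdispersed
# binomial: with m = mean_j(y_j/n_j),
#   obsvar = var_j(y_j/n_j)
#   expvar = m (1 - m) / mean_j(n_j)
#   a + b  = (mean_j(n_j) - 1) / (obsvar/expvar - 1) - 1,   a = m (a + b).

#' Beta-binomial probability mass
#'
#' @param y Edited counts.
#' @param n Depths.
#' @param alpha,beta Beta parameters (> 0).
#' @param log Return log probabilities?
#' @return Numeric vector of (log) probabilities.
#' @export
dbetabinom <- function(y, n, alpha, beta, log = FALSE) {
  stopifnot(all(alpha > 0), all(beta > 0))
  lp <- lchoose(n, y) + lbeta(y + alpha, n - y + beta) - lbeta(alpha, beta)
  lp[y < 0 | y > n] <- -Inf
  if (log) lp else exp(lp)
}

betabin_loglik <- function(alpha, beta, y, n) {
  sum(lbeta(y + alpha, n - y + beta)) - length(y) * lbeta(alpha, beta)
}

#' Mean and variance of a Beta distribution
#'
#' The fitted `(alpha, beta)` summarize a peptide's editing-rate law; its
#' mean is `alpha / (alpha + beta)` and its variance
#' `alpha * beta / ((alpha + beta)^2 (alpha + beta + 1))`.
#'
#' @param alpha,beta Positive Beta parameters.
#' @return List with `mean` and `variance`.
#' @examples
#' beta_moments(10, 40)
#' @export
beta_moments <- function(alpha, beta) {
  if (any(alpha <= 0) || any(beta <= 0)) {
    stop("alpha and beta must be positive")
  }
  s <- alpha + beta
  list(mean = alpha / s, variance = alpha * beta / (s^2 * (s + 1)))
}

#' Moment-matching estimate of beta-binomial parameters
#'
#' Matches the observed mean and variance of the per-replicate edited
#' fractions, viewing the beta-binomial as an overdispersed binomial (see
#' the formulas above). When the data are not overdispersed
#' (`obsvar <= expvar`, where the concentration formula is undefined) the
#' concentration is clamped to `cap_mult * mean(n)` while preserving the
#' mean; a mean of exactly 0 or 1 gets half a pseudocount so both
#' parameters stay finite.
#'
#' @param y Integer vector of edited counts, one per replicate.
#' @param n Integer vector of depths (same length).
#' @param cap_mult Concentration cap multiplier for the underdispersed /
#'   degenerate branch.
#' @return List with `alpha`, `beta`, and `clamped` (logical).
#' @examples
#' fit_moment_match(c(20, 40), c(100, 100))  # alpha+beta ~ 10.61
#' @export
fit_moment_match <- function(y, n, cap_mult = 10) {
  stopifnot(length(y) == length(n), length(y) >= 1L,
            all(y >= 0), all(y <= n), all(n >= 1))
  k <- length(y)
  m <- mean(y / n)
  if (m <= 0 || m >= 1) {
    m <- (sum(y) + 0.5) / (sum(n) + 1)
  }
  clamped <- TRUE
  conc <- cap_mult * mean(n)
  if (k >= 2L) {
    obsvar <- stats::var(y / n)           # k-1 denominator
    expvar <- m * (1 - m) / mean(n)
    if (obsvar > expvar) {
      cand <- (mean(n) - 1) / (obsvar / expvar - 1) - 1
      if (is.finite(cand) && cand > 0) {
        conc <- cand
        clamped <- FALSE
      }
    }
  }
  list(alpha = m * conc, beta = (1 - m) * conc, clamped = clamped)
}

#' Maximum-likelihood estimate of beta-binomial parameters
#'
#' Maximizes the beta-binomial log-likelihood over `(alpha, beta)` by
#' solving the digamma score equations (gradient-based optimization on the
#' log scale, started from the moment-matching estimate). When the solver
#' fails to converge to an interior stationary point -- including the
#' degenerate cases of a single replicate or all counts at a boundary --
#' the moment-matching estimate is returned instead, and the `method`
#' field says which route produced the answer.
#'
#' @inheritParams fit_moment_match
#' @param cap_mult Passed to the moment-matching fall-back.
#' @return List with `alpha`, `beta`, `method` (`"score_equations"` or
#'   `"moment_match"`).
#' @export
fit_betabin_mle <- function(y, n, cap_mult = 10) {
  stopifnot(length(y) == length(n), length(y) >= 1L,
            all(y >= 0), all(y <= n), all(n >= 1))
  k <- length(y)
  mm <- fit_moment_match(y, n, cap_mult)
  boundary <- all(y == 0) || all(y == n)
  if (k < 2L || boundary) {
    return(list(alpha = mm$alpha, beta = mm$beta, method = "moment_match"))
  }
  nll <- function(par) -betabin_loglik(exp(par[1]), exp(par[2]), y, n)
  grad <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    da <- sum(digamma(y + a) - digamma(n + a + b)) -
      k * (digamma(a) - digamma(a + b))
    db <- sum(digamma(n - y + b) - digamma(n + a + b)) -
      k * (digamma(b) - digamma(a + b))
    -c(da * a, db * b)                    # chain rule for the log scale
  }
  start <- log(pmax(c(mm$alpha, mm$beta), 1e-3))
  fit <- tryCatch(
    stats::optim(start, nll, grad, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(fit) && is.finite(fit$value)) {
    a <- exp(fit$par[1]); b <- exp(fit$par[2])
    g <- grad(fit$par)
    # accept an interior stationary point of the score equations
    if (a > 1e-8 && b > 1e-8 && a < 1e8 && b < 1e8 &&
        max(abs(g)) < 1e-3 * max(1, abs(fit$value))) {
      return(list(alpha = a, beta = b, method = "score_equations"))
    }
  }
  list(alpha = mm$alpha, beta = mm$beta, method = "moment_match")
}

#' Probability that a peptide out-edits the control law
#'
#' Computes `P(Y_pep > Y_ctrl) + 0.5 P(Y_pep = Y_ctrl)` where both counts
#' are beta-binomial with a common reference depth `n_ref`: the probability
#' of observing a higher edited read count under the peptide's inferred
#' effect parameters than under the control parameters. Identical
#' parameters give exactly 0.5. Exact enumeration sums the pmf product
#' (used automatically for `n_ref <= 5000`); Monte Carlo sampling is used
#' beyond that, deterministic given `seed`.
#'
#' @param pep,ctrl Lists (or vectors) with `alpha` and `beta`.
#' @param n_ref Reference read depth.
#' @param mode `"auto"`, `"exact_enumeration"` or `"monte_carlo"`.
#' @param draws Monte Carlo sample size.
#' @param seed Seed for Monte Carlo mode.
#' @return Probability in `[0, 1]`.
#' @export
prob_beat_control <- function(pep, ctrl, n_ref,
                              mode = c("auto", "exact_enumeration",
                                       "monte_carlo"),
                              draws = 1e5, seed = 1L) {
  mode <- match.arg(mode)
  pep <- as.list(pep); ctrl <- as.list(ctrl)
  stopifnot(n_ref >= 1L, pep$alpha > 0, pep$beta > 0,
            ctrl$alpha > 0, ctrl$beta > 0)
  if (mode == "auto") {
    mode <- if (n_ref <= 5000L) "exact_enumeration" else "monte_carlo"
  }
  if (mode == "exact_enumeration") {
    yy <- 0:n_ref
    fp <- dbetabinom(yy, n_ref, pep$alpha, pep$beta)
    fc <- dbetabinom(yy, n_ref, ctrl$alpha, ctrl$beta)
    Fc_below <- cumsum(fc) - fc           # P(Y_ctrl < y)
    sum(fp * Fc_below) + 0.5 * sum(fp * fc)
  } else {
    with_seed(seed, {
      yp <- stats::rbinom(draws, n_ref, stats::rbeta(draws, pep$alpha, pep$beta))
      yc <- stats::rbinom(draws, n_ref, stats::rbeta(draws, ctrl$alpha, ctrl$beta))
      mean(yp > yc) + 0.5 * mean(yp == yc)
    })
  }
}
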