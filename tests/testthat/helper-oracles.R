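# Independent oracles and fixture builders used across the suite. These
# deliberately avoid the package's own code paths: the alignment oracle
# enumerates every global alignment, the likelihood oracle maximizes on a
# grid, and the least-squares oracle solves the normal equations directly.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Random test proteins start with three high-codon-degeneracy residues
# (Leu/Ser/Arg) so that the 8-nt prefix space comfortably covers a tile
# plus all of its phosphomimetic variants; fully random starts can make
# prefix uniqueness unattainable (e.g. Met-Trp starts), which the encoder
# correctly reports as an error and which is tested separately.
random_protein <- function(len, start3 = TRUE) {
  body <- paste(sample(AA20, len, replace = TRUE), collapse = "")
  if (!start3 || len < 3) return(body)
  paste0(paste(sample(c("L", "S", "R"), 3, replace = TRUE), collapse = ""),
         substr(body, 4, len))
}

# n_screen + n_control random single-tile proteins -> encoded library
make_test_library <- function(n_screen, n_control = 0, seed = 1,
                              phosphomimetics = FALSE) {
  set.seed(seed)
  prots <- stats::setNames(
    vapply(seq_len(n_screen), function(i) random_protein(85), character(1)),
    sprintf("p%03d", seq_len(n_screen)))
  ctrls <- if (n_control > 0) {
    stats::setNames(
      vapply(seq_len(n_control), function(i) random_protein(85), character(1)),
      sprintf("hk%02d", seq_len(n_control)))
  } else character(0)
  design_library(prots, ctrls, phosphomimetics = phosphomimetics,
                 seed = seed + 1)
}

# Exhaustive enumeration of all global alignments under match +1 /
# mismatch -1 / gap open -5 / gap extend 0 (a gap run of any length costs
# 5, end gaps included). Recursion over the three moves with gap-run
# tracking; returns the optimal score.
oracle_align_score <- function(q, r) {
  qs <- strsplit(q, "")[[1]]
  rs <- strsplit(r, "")[[1]]
  m <- length(qs)
  n <- length(rs)
  best <- -Inf
  rec <- function(i, j, sc, last) {
    if (i > m && j > n) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= m && j <= n) {
      rec(i + 1L, j + 1L, sc + if (qs[i] == rs[j]) 1 else -1, "d")
    }
    if (i <= m) rec(i + 1L, j, sc - if (last == "i") 0 else 5, "i")
    if (j <= n) rec(i, j + 1L, sc - if (last == "j") 0 else 5, "j")
  }
  rec(1L, 1L, 0, "d")
  best
}

# Beta-binomial log-likelihood evaluated on vectors of (alpha, beta)
oracle_bb_loglik <- function(alpha, beta, y, n) {
  ll <- -length(y) * lbeta(alpha, beta)
  for (j in seq_along(y)) {
    ll <- ll + lbeta(y[j] + alpha, n[j] - y[j] + beta)
  }
  ll
}

# Grid maximization of the beta-binomial likelihood: a coarse sweep over
# logit(mean) x log(concentration) followed by iteratively shrinking local
# grids around the optimum. Returns the mean at the grid optimum.
oracle_grid_mle_mean <- function(y, n) {
  sweep_grid <- function(means, concs) {
    g <- expand.grid(m = means, s = concs)
    ll <- oracle_bb_loglik(g$m * g$s, (1 - g$m) * g$s, y, n)
    g[which.max(ll), ]
  }
  best <- sweep_grid(
    stats::plogis(seq(stats::qlogis(1e-4), stats::qlogis(1 - 1e-4),
                      length.out = 301)),
    exp(seq(log(0.05), log(1e6), length.out = 121)))
  w_m <- 0.1                            # logit-scale half-window
  w_s <- 0.2                            # log-scale half-window
  for (iter in 1:4) {
    best <- sweep_grid(
      stats::plogis(seq(stats::qlogis(best$m) - w_m,
                        stats::qlogis(best$m) + w_m, length.out = 41)),
      exp(seq(log(best$s) - w_s, log(best$s) + w_s, length.out = 41)))
    w_m <- w_m / 8
    w_s <- w_s / 8
  }
  best$m
}

# Closed-form least squares for the additive dual model: solve the normal
# equations of observed ~ intercept + N-effects + C-effects with the
# control level dropped from both factors.
oracle_additive_fit <- function(med, control_id) {
  nl <- setdiff(sort(unique(med$n_term_id)), control_id)
  cl <- setdiff(sort(unique(med$c_term_id)), control_id)
  X <- cbind(1, outer(med$n_term_id, nl, "==") * 1,
             outer(med$c_term_id, cl, "==") * 1)
  colnames(X) <- c("baseline", paste0("N:", nl), paste0("C:", cl))
  beta <- solve(t(X) %*% X, t(X) %*% med$observed_median)
  drop(beta)
}

# Rank-based AUROC of scores for binary labels (TRUE = positive)
auroc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

random_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
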