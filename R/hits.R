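# Screen-level inference: coverage filtering, per-peptide effect
# estimation against pooled controls, control normalization, paired
# t-tests and FDR-controlled hit calling.

#' Drop peptides with insufficient coverage
#'
#' Removes a peptide entirely if its total kept reads fall below
#' `min_reads` in any replicate (strictly less than: a peptide at exactly
#' the threshold everywhere is retained).
#'
#' @param counts Count table from [count_outcomes()] (long format:
#'   `peptide_id`, `replicate`, `n`, category columns).
#' @param min_reads Minimum reads per replicate (default 100).
#' @return The filtered count table.
#' @export
filter_low_coverage <- function(counts, min_reads = 100L) {
  stopifnot(all(c("peptide_id", "replicate", "n") %in% names(counts)))
  if (min_reads <= 0L) return(counts)
  low <- tapply(counts$n, counts$peptide_id, function(x) any(x < min_reads))
  keep_ids <- names(low)[!low]
  out <- counts[counts$peptide_id %in% keep_ids, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("no peptide has >= ", min_reads, " reads in every replicate; ",
         "nothing left to analyze")
  }
  rownames(out) <- NULL
  out
}

# long count table -> aligned y and n matrices (peptides x replicates)
count_matrices <- function(counts) {
  reps <- unique(counts$replicate)
  ids <- unique(counts$peptide_id)
  y <- matrix(0L, length(ids), length(reps), dimnames = list(ids, reps))
  n <- y
  i <- cbind(match(counts$peptide_id, ids), match(counts$replicate, reps))
  y[i] <- counts$prime_edited
  n[i] <- counts$n
  list(y = y, n = n)
}

#' Estimate per-peptide editing effects against pooled controls
#'
#' After coverage filtering, fits the beta-binomial law of every peptide
#' ([fit_betabin_mle()]), fits one pooled law to all control peptides'
#' counts (the comparison distribution), and computes for each peptide the
#' probability of out-editing the control law at a common reference depth
#' ([prob_beat_control()]).
#'
#' @param counts Count table from [count_outcomes()].
#' @param control_ids Peptide ids of the control (housekeeping-derived)
#'   peptides.
#' @param min_reads Coverage filter threshold (see
#'   [filter_low_coverage()]).
#' @param n_ref Reference depth for the exceedance probability; default is
#'   the median kept depth across the filtered screen.
#' @param cap_mult Concentration cap for the moment-matching branch.
#' @param seed Seed (used only if the exceedance computation falls back to
#'   Monte Carlo at very large `n_ref`).
#' @return `data.frame` with one row per retained peptide: `alpha`, `beta`,
#'   `method`, `mean`, `variance`, `p_beat_control`, `is_control`.
#'   Attributes `"control_fit"` and `"n_ref"` record the pooled control law
#'   and the reference depth.
#' @export
estimate_effects <- function(counts, control_ids, min_reads = 100L,
                             n_ref = NULL, cap_mult = 10, seed = 1L) {
  counts <- filter_low_coverage(counts, min_reads)
  mats <- count_matrices(counts)
  ids <- rownames(mats$y)
  ctrl_kept <- intersect(control_ids, ids)
  if (length(ctrl_kept) == 0L) {
    stop("no control peptide survives the coverage filter")
  }
  ctrl_y <- as.vector(mats$y[ctrl_kept, , drop = FALSE])
  ctrl_n <- as.vector(mats$n[ctrl_kept, , drop = FALSE])
  ctrl_fit <- fit_betabin_mle(ctrl_y, ctrl_n, cap_mult)
  n_ref <- as.integer(n_ref %||% stats::median(mats$n))

  fits <- lapply(ids, function(id) fit_betabin_mle(mats$y[id, ], mats$n[id, ],
                                                   cap_mult))
  alpha <- vapply(fits, `[[`, numeric(1), "alpha")
  beta <- vapply(fits, `[[`, numeric(1), "beta")
  mom <- beta_moments(alpha, beta)
  pbc <- vapply(seq_along(ids), function(i) {
    prob_beat_control(list(alpha = alpha[i], beta = beta[i]), ctrl_fit,
                      n_ref, seed = seed)
  }, numeric(1))
  out <- data.frame(
    peptide_id = ids,
    alpha = alpha,
    beta = beta,
    method = vapply(fits, `[[`, character(1), "method"),
    mean = mom$mean,
    variance = mom$variance,
    p_beat_control = pbc,
    is_control = ids %in% control_ids,
    stringsAsFactors = FALSE
  )
  attr(out, "control_fit") <- ctrl_fit
  attr(out, "n_ref") <- n_ref
  out
}

#' Control-normalize editing fractions and call hits
#'
#' Divides each peptide's per-replicate edited fraction by the mean edited
#' fraction of the control peptides in that replicate, tests each peptide's
#' fractions against the per-replicate control means with a two-sided
#' paired t-test, adjusts p values by Benjamini-Hochberg, and ranks
#' peptides by a composite priority: exceedance probability against the
#' control law first, then higher inferred mean, then lower inferred
#' variance. Replicates in which the controls show zero editing cannot be
#' normalized and are excluded with a warning.
#'
#' @param counts Count table (will be restricted to the peptides present
#'   in `estimates`).
#' @param estimates Output of [estimate_effects()].
#' @param control_ids Control peptide ids.
#' @param fdr False discovery rate for the significance call (default
#'   0.05).
#' @return `data.frame`, one row per peptide, sorted by `rank`: the
#'   estimate columns plus `fold_change` (mean control-normalized edited
#'   fraction), `p_value`, `q_value`, `significant`, `rank`.
#' @export
normalize_and_call <- function(counts, estimates, control_ids, fdr = 0.05) {
  stopifnot(fdr >= 0, fdr <= 1)
  counts <- counts[counts$peptide_id %in% estimates$peptide_id, , drop = FALSE]
  mats <- count_matrices(counts)
  frac <- mats$y / pmax(mats$n, 1L)
  ctrl_kept <- intersect(control_ids, rownames(frac))
  if (length(ctrl_kept) == 0L) stop("no control peptides in the estimates")
  ctrl_mean <- colMeans(frac[ctrl_kept, , drop = FALSE])
  usable <- ctrl_mean > 0
  if (!all(usable)) {
    warning("replicate(s) with zero control editing excluded from ",
            "normalization: ",
            paste(colnames(frac)[!usable], collapse = ", "))
  }
  if (!any(usable)) stop("no replicate has nonzero control editing")
  frac <- frac[, usable, drop = FALSE]
  ctrl_mean <- ctrl_mean[usable]
  norm <- sweep(frac, 2L, ctrl_mean, "/")

  fold <- rowMeans(norm)
  pvals <- apply(frac, 1L, function(f) {
    if (length(f) < 2L) return(NA_real_)
    d <- f - ctrl_mean
    if (stats::sd(d) == 0) return(if (all(d == 0)) 1 else NA_real_)
    stats::t.test(f, ctrl_mean, paired = TRUE)$p.value
  })
  qvals <- stats::p.adjust(pvals, method = "BH")

  out <- estimates[match(rownames(frac), estimates$peptide_id), , drop = FALSE]
  out$fold_change <- unname(fold)
  out$p_value <- unname(pvals)
  out$q_value <- unname(qvals)
  out$significant <- !is.na(qvals) & qvals <= fdr & fdr > 0
  ord <- order(-out$p_beat_control, -out$mean, out$variance)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "control_fit") <- attr(estimates, "control_fit")
  attr(out, "n_ref") <- attr(estimates, "n_ref")
  out
}
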