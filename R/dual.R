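# Additive decomposition of dual-peptide fusion effects.
#
# Model: the control-normalized edited fraction of the pair (i at the
# N-terminal position, j at the C-terminal position) is
#   observed(i, j) ~ baseline + a_i + b_j
# fitted by least squares on the per-pair median across replicates.
# Effects are identifiable only up to a constant shift; the control
# peptide's effect is anchored at 0 in each position, so the baseline is
# the predicted control-control level.

#' Normalize dual-screen counts to the control-control pair
#'
#' Converts raw dual-pair counts into normalized edited fractions by
#' dividing each pair's per-replicate edited fraction by the
#' control-control pair's fraction in the same replicate.
#'
#' @param counts `data.frame` with `n_term_id`, `c_term_id`, `replicate`,
#'   `edited`, `total`.
#' @param control_id Id of the control peptide (present at both
#'   positions).
#' @return `data.frame` of dual observations (`n_term_id`, `c_term_id`,
#'   `replicate`, `normalized_edited_fraction`).
#' @export
normalize_dual <- function(counts, control_id = "CTRL") {
  stopifnot(all(c("n_term_id", "c_term_id", "replicate", "edited", "total")
                %in% names(counts)))
  frac <- counts$edited / counts$total
  cc <- counts$n_term_id == control_id & counts$c_term_id == control_id
  if (!any(cc)) stop("control-control pair '", control_id, "' not found")
  base <- tapply(frac[cc], counts$replicate[cc], mean)
  if (any(base <= 0)) stop("control-control pair has zero editing in some replicate")
  data.frame(
    n_term_id = counts$n_term_id,
    c_term_id = counts$c_term_id,
    replicate = counts$replicate,
    normalized_edited_fraction = frac / unname(base[as.character(counts$replicate)]),
    stringsAsFactors = FALSE
  )
}

# median observation per pair
pair_medians <- function(obs) {
  stopifnot(all(c("n_term_id", "c_term_id", "normalized_edited_fraction")
                %in% names(obs)))
  agg <- stats::aggregate(normalized_edited_fraction ~ n_term_id + c_term_id,
                          data = obs, FUN = stats::median)
  names(agg)[3] <- "observed_median"
  agg
}

# verify that the pair design connects all peptides (bipartite BFS)
check_connected <- function(pairs) {
  nodes <- c(paste0("N:", unique(pairs$n_term_id)),
             paste0("C:", unique(pairs$c_term_id)))
  adj <- rbind(data.frame(from = paste0("N:", pairs$n_term_id),
                          to = paste0("C:", pairs$c_term_id)),
               data.frame(from = paste0("C:", pairs$c_term_id),
                          to = paste0("N:", pairs$n_term_id)))
  seen <- nodes[1]
  frontier <- nodes[1]
  while (length(frontier) > 0L) {
    nxt <- unique(adj$to[adj$from %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  if (length(setdiff(nodes, seen)) > 0L) {
    stop("pair design is disconnected; effects are not jointly ",
         "identifiable for: ",
         paste(setdiff(nodes, seen), collapse = ", "))
  }
  invisible(TRUE)
}

#' Fit the additive dual-peptide model
#'
#' Least-squares fit of `observed ~ baseline + a(n_term) + b(c_term)` to
#' the per-pair median normalized edited fraction, with the control
#' peptide's effect anchored at 0 in both positions.
#'
#' @param obs Dual observations (`n_term_id`, `c_term_id`, `replicate`,
#'   `normalized_edited_fraction`), e.g. from [normalize_dual()] or
#'   [simulate_dual_screen()].
#' @param control_id Peptide anchored at effect 0 (must appear at both
#'   positions).
#' @return An `additive_fit`: `baseline`, named `n_effects` and
#'   `c_effects` (control included at 0), per-pair `fitted`
#'   (`observed_median`, `predicted`), and `pearson_r` between the two.
#' @export
fit_additive <- function(obs, control_id = "CTRL") {
  med <- pair_medians(obs)
  if (nrow(med) < 3L) stop("need at least 3 pairs to fit the additive model")
  if (!(control_id %in% med$n_term_id) || !(control_id %in% med$c_term_id)) {
    stop("control peptide '", control_id, "' must appear at both positions")
  }
  check_connected(med)
  med$nf <- stats::relevel(factor(med$n_term_id), ref = control_id)
  med$cf <- stats::relevel(factor(med$c_term_id), ref = control_id)
  fit <- stats::lm(observed_median ~ nf + cf, data = med)
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("additive model is rank deficient for this design")
  get_eff <- function(prefix, levels) {
    eff <- stats::setNames(rep(0, length(levels)), levels)
    got <- grep(paste0("^", prefix), names(cf), value = TRUE)
    eff[sub(paste0("^", prefix), "", got)] <- cf[got]
    eff
  }
  med$predicted <- unname(stats::fitted(fit))
  structure(
    list(
      baseline = unname(cf["(Intercept)"]),
      n_effects = get_eff("nf", levels(med$nf)),
      c_effects = get_eff("cf", levels(med$cf)),
      control_id = control_id,
      fitted = med[, c("n_term_id", "c_term_id", "observed_median",
                       "predicted")],
      pearson_r = if (stats::sd(med$observed_median) == 0 ||
                      stats::sd(med$predicted) == 0) NA_real_
                  else stats::cor(med$observed_median, med$predicted)
    ),
    class = "additive_fit")
}

#' @export
print.additive_fit <- function(x, ...) {
  cat("additive_fit: baseline ", signif(x$baseline, 4), ", ",
      length(x$n_effects), " N-terminal x ", length(x$c_effects),
      " C-terminal effects, r = ", signif(x$pearson_r, 4), "\n", sep = "")
  invisible(x)
}

#' Predict the normalized editing of a peptide pair
#'
#' @param fit An [fit_additive()] result.
#' @param n_id,c_id Peptide ids at the N- and C-terminal positions.
#' @return Predicted normalized edited fraction
#'   `baseline + a(n_id) + b(c_id)`.
#' @export
predict_pair <- function(fit, n_id, c_id) {
  stopifnot(inherits(fit, "additive_fit"))
  if (!(n_id %in% names(fit$n_effects))) stop("unknown N-terminal id: ", n_id)
  if (!(c_id %in% names(fit$c_effects))) stop("unknown C-terminal id: ", c_id)
  unname(fit$baseline + fit$n_effects[n_id] + fit$c_effects[c_id])
}

#' Additivity of the dual screen (Pearson r)
#'
#' Pearson correlation between the additive model's predictions and the
#' observed per-pair medians (over pairs, not replicates). Returns `NA`
#' with a warning when either vector has zero variance, where the
#' correlation is undefined.
#'
#' @param fit An [fit_additive()] result.
#' @param obs Optional new observations; defaults to the pairs the model
#'   was fitted on.
#' @return Pearson correlation coefficient, or `NA` if undefined.
#' @export
additivity_r <- function(fit, obs = NULL) {
  stopifnot(inherits(fit, "additive_fit"))
  if (is.null(obs)) {
    med <- fit$fitted
  } else {
    med <- pair_medians(obs)
    med$predicted <- mapply(function(n, c) predict_pair(fit, n, c),
                            med$n_term_id, med$c_term_id)
  }
  if (nrow(med) < 3L) stop("need at least 3 pairs")
  if (stats::sd(med$observed_median) == 0 || stats::sd(med$predicted) == 0) {
    warning("zero variance in observed or predicted values; ",
            "correlation undefined")
    return(NA_real_)
  }
  stats::cor(med$observed_median, med$predicted)
}
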