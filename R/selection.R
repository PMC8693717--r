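#' Posterior inclusion probabilities
#'
#' For spike-and-slab fits, the inclusion probability of an effect is the
#' mean of its 0/1 indicator over the H stored sweeps (equivalently one minus
#' the fraction of sweeps in which the stored coefficient is exactly zero).
#'
#' @param fit a `gxe_fit` from a spike-and-slab method (`LADBLSS`, `BLSS`).
#' @return named numeric vector of length 1 + q: the main effect `G` then the
#'   interactions `GxE_k`.
#' @export
inclusion_probability <- function(fit) {
  if (!fit$method$sparse)
    stop("inclusion probabilities are only defined for spike-and-slab methods")
  ind <- cbind(fit$draws$ind_beta, fit$draws$ind_eta)
  p <- colMeans(ind)
  names(p) <- c("G", paste0("GxE_", seq_len(fit$q)))
  p
}

#' Credible-interval selection indicator
#'
#' Returns 1 when the equal-tailed credible interval of the draws at the
#' given level excludes zero. This is the per-level selection rule used to
#' evaluate methods without spike-and-slab priors.
#'
#' @param draws numeric vector of posterior draws for one effect.
#' @param level credible level in (0, 1), e.g. 0.95.
#' @return 0 or 1.
#' @export
ci_indicator <- function(draws, level) {
  if (level <= 0 || level >= 1) stop("level must lie strictly in (0, 1)")
  qs <- quantile(draws, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE)
  as.integer(qs[1] > 0 || qs[2] < 0)
}

#' Selection scores for every candidate effect of one fit
#'
#' Spike-and-slab methods score each effect by its posterior inclusion
#' probability. Non-sparse methods score it by the average of its
#' credible-interval selection indicator over a grid of credible levels
#' (default 0.01 to 0.99 in steps of 0.01), the "average identification
#' value" used for top-k ranking.
#'
#' @param fit a `gxe_fit`.
#' @param levels credible-level grid for non-sparse methods.
#' @return data.frame with `effect`, `score` in \[0, 1\] and the posterior
#'   median `estimate`.
#' @export
effect_scores <- function(fit, levels = seq(0.01, 0.99, by = 0.01)) {
  co <- cbind(fit$draws$beta, fit$draws$eta)
  est <- apply(co, 2, median)
  if (fit$method$sparse) {
    score <- unname(inclusion_probability(fit))
  } else {
    score <- apply(co, 2, function(d) mean(ci_level_indicators(d, levels)))
  }
  data.frame(effect = c("G", paste0("GxE_", seq_len(fit$q))),
             score = score, estimate = est, row.names = NULL)
}

# Vector of ci_indicator values over a whole level grid, from one quantile
# pass over the draws.
ci_level_indicators <- function(draws, levels) {
  lo <- quantile(draws, probs = (1 - levels) / 2, names = FALSE)
  hi <- quantile(draws, probs = 1 - (1 - levels) / 2, names = FALSE)
  as.integer(lo > 0 | hi < 0)
}

roc_points_from_selection <- function(sel, truth) {
  # sel: logical matrix, effects x cutoffs; truth: logical vector
  P <- sum(truth)
  N <- sum(!truth)
  tpr <- colSums(sel & truth) / P
  fpr <- colSums(sel & !truth) / N
  list(tpr = tpr, fpr = fpr)
}

auc_trapezoid <- function(fpr, tpr) {
  # anchor at (0,0) and (1,1), sort by (fpr, tpr), trapezoidal rule
  ord <- order(c(0, fpr, 1), c(0, tpr, 1))
  x <- c(0, fpr, 1)[ord]
  y <- c(0, tpr, 1)[ord]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' ROC curve and AUC from a cutoff sweep over selection scores
#'
#' Sweeps a grid of cutoffs (default 0, 0.01, ..., 1); at each cutoff an
#' effect is selected when its score is strictly greater than the cutoff, and
#' true/false positive rates are computed against the known truth. The AUC is
#' the trapezoidal area under the swept (FPR, TPR) points anchored at (0, 0)
#' and (1, 1).
#'
#' @param scores numeric score per candidate effect (e.g. inclusion
#'   probabilities).
#' @param truth logical (or 0/1) vector marking the truly nonzero effects;
#'   must contain both classes.
#' @param cutoffs increasing cutoff grid.
#' @return list of class `roc_result` with `cutoffs`, `tpr`, `fpr`, `auc`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc # 1
#' @export
roc_auc <- function(scores, truth, cutoffs = seq(0, 1, by = 0.01)) {
  truth <- as.logical(truth)
  if (all(truth) || !any(truth))
    stop("truth must contain both true and null effects")
  if (length(scores) != length(truth))
    stop("scores and truth must have equal length")
  sel <- outer(scores, cutoffs, ">")
  pts <- roc_points_from_selection(sel, truth)
  structure(list(cutoffs = cutoffs, tpr = pts$tpr, fpr = pts$fpr,
                 auc = auc_trapezoid(pts$fpr, pts$tpr)),
            class = "roc_result")
}

#' ROC curve and AUC from per-level credible-interval selections
#'
#' For methods without spike-and-slab priors the credible level plays the
#' role of the cutoff: at each level an effect is selected when its
#' equal-tailed interval excludes zero.
#'
#' @param sel logical/0-1 matrix, one row per candidate effect, one column
#'   per credible level.
#' @param truth logical vector marking truly nonzero effects.
#' @param levels the credible-level grid (column labels).
#' @return list of class `roc_result`.
#' @export
roc_auc_ci <- function(sel, truth, levels = seq(0.01, 0.99, by = 0.01)) {
  truth <- as.logical(truth)
  if (all(truth) || !any(truth))
    stop("truth must contain both true and null effects")
  pts <- roc_points_from_selection(sel == 1, truth)
  structure(list(cutoffs = levels, tpr = pts$tpr, fpr = pts$fpr,
                 auc = auc_trapezoid(pts$fpr, pts$tpr)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC over", length(x$cutoffs), "cutoffs: AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Count true signals among the top-k ranked effects
#'
#' Ranks effects by score (descending); ties are broken by larger absolute
#' posterior estimate, then by smaller index (stable and documented). Returns
#' how many of the top k are true signals.
#'
#' @param scores numeric score per effect.
#' @param truth logical vector of true signals.
#' @param k list length; must not exceed the candidate pool.
#' @param estimates optional posterior medians used for tie-breaking.
#' @return integer count.
#' @export
top_k <- function(scores, truth, k, estimates = NULL) {
  if (k > length(scores)) stop("k exceeds the candidate pool")
  if (is.null(estimates)) estimates <- numeric(length(scores))
  ord <- order(-scores, -abs(estimates), seq_along(scores))
  sum(as.logical(truth)[ord[seq_len(k)]])
}

#' Posterior medians of all sampled coefficients
#'
#' @param fit a `gxe_fit`.
#' @return list with `alpha`, `gamma`, `beta`, `eta` medians.
#' @export
posterior_estimates <- function(fit) {
  dr <- fit$draws
  if (dr$meta$H < 1) stop("no stored draws")
  list(alpha = apply(dr$alpha, 2, median),
       gamma = if (fit$m > 0) apply(dr$gamma, 2, median) else numeric(0),
       beta = median(dr$beta[, 1]),
       eta = apply(dr$eta, 2, median))
}
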