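#' Fit one method marginally across all genes
#'
#' Loops the marginal Gibbs sampler over the p genes of a study (optionally
#' in parallel). Per-gene RNG is keyed deterministically by `(seed, gene)`,
#' so serial and parallel runs agree and any subset of genes is reproducible
#' in isolation.
#'
#' @param y response vector (length n).
#' @param E n x q environmental matrix.
#' @param C n x m clinical matrix (or `NULL`).
#' @param X n x p genetic matrix.
#' @param method method name, see [method_spec()].
#' @param hyper a [gxe_hyper()] object.
#' @param iterations,burn_in MCMC length per gene.
#' @param seed base integer seed; per-gene seeds are derived from it.
#' @param levels credible-level grid used to score/select effects of
#'   non-sparse methods.
#' @param cores number of worker processes (`parallel::mclapply`).
#' @return An object of class `gxe_scan` with, per gene, the effect scores
#'   (`score_main` length p, `score_int` p x q), posterior medians
#'   (`est_main`, `est_int`) and, for non-sparse methods, the per-level
#'   credible-interval selection arrays used for ROC sweeps
#'   (`sel_main` p x L, `sel_int` p x q x L).
#' @export
fit_genome <- function(y, E, C, X, method = "LADBLSS", hyper = gxe_hyper(),
                       iterations = 10000, burn_in = 5000, seed = NULL,
                       levels = seq(0.01, 0.99, by = 0.01), cores = 1L) {
  spec <- if (is.character(method)) method_spec(method) else method
  X <- as.matrix(X)
  p <- ncol(X)
  q <- ncol(E)
  fit_one <- function(j) {
    if (!is.null(seed)) set.seed(gene_seed(seed, j))
    d <- marginal_design(y, E, C, X[, j])
    fit <- fit_marginal(d, method = spec, hyper = hyper,
                        iterations = iterations, burn_in = burn_in)
    co <- cbind(fit$draws$beta, fit$draws$eta)
    est <- apply(co, 2, median)
    if (spec$sparse) {
      score <- unname(inclusion_probability(fit))
      sel <- NULL
    } else {
      sel <- t(apply(co, 2, ci_level_indicators, levels = levels))
      score <- rowMeans(sel)
    }
    list(score = score, est = est, sel = sel)
  }
  res <- if (cores > 1L) {
    parallel::mclapply(seq_len(p), fit_one, mc.cores = cores)
  } else {
    lapply(seq_len(p), fit_one)
  }
  score <- do.call(rbind, lapply(res, `[[`, "score"))
  est <- do.call(rbind, lapply(res, `[[`, "est"))
  out <- list(method = spec, p = p, q = q, levels = levels,
              score_main = score[, 1], score_int = score[, -1, drop = FALSE],
              est_main = est[, 1], est_int = est[, -1, drop = FALSE],
              iterations = iterations, burn_in = burn_in, seed = seed)
  if (!spec$sparse) {
    sel <- lapply(res, `[[`, "sel")
    L <- length(levels)
    out$sel_main <- do.call(rbind, lapply(sel, function(s) s[1, ]))
    out$sel_int <- aperm(simplify2array(lapply(sel, function(s)
      s[-1, , drop = FALSE])), c(3, 1, 2)) # p x q x L
  }
  class(out) <- "gxe_scan"
  out
}

# deterministic per-gene substream key, kept inside 32-bit integer range
gene_seed <- function(seed, j) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(j)) %% 2147483647)
}

#' @export
print.gxe_scan <- function(x, ...) {
  cat(x$method$name, "genome scan over", x$p, "genes (",
    x$p * (1 + x$q), "candidate effects )\n")
  invisible(x)
}

#' Evaluate a genome scan against simulation truth
#'
#' Pools the p main effects and p*q interactions, computes the ROC/AUC from
#' the method's cutoff sweep (inclusion-probability cutoffs for
#' spike-and-slab methods, credible levels otherwise), and the top-k counts
#' of true signals among main effects, interactions, and their sum.
#' Interactions are indexed column-major: effect (j, k) sits at position
#' `p * (k - 1) + j` of the flattened vectors.
#'
#' @param scan a [fit_genome()] result.
#' @param truth_main logical vector (length p) of true main effects.
#' @param truth_int logical p x q matrix of true interactions.
#' @param k list length for the top-k counts (default 100).
#' @param cutoffs inclusion-probability cutoff grid for sparse methods.
#' @return list with `auc`, `roc`, `topk_main`, `topk_int`, `topk_total`,
#'   `k`.
#' @export
evaluate_scan <- function(scan, truth_main, truth_int, k = 100,
                          cutoffs = seq(0, 1, by = 0.01)) {
  truth_main <- as.logical(truth_main)
  truth_int <- matrix(as.logical(truth_int), nrow = scan$p)
  scores <- c(scan$score_main, as.vector(scan$score_int))
  truth <- c(truth_main, as.vector(truth_int))
  if (scan$method$sparse) {
    roc <- roc_auc(scores, truth, cutoffs = cutoffs)
  } else {
    sel <- rbind(scan$sel_main,
                 matrix(scan$sel_int, nrow = scan$p * scan$q,
                        ncol = length(scan$levels)))
    roc <- roc_auc_ci(sel, truth, levels = scan$levels)
  }
  topk_main <- top_k(scan$score_main, truth_main,
                     k = min(k, scan$p), estimates = scan$est_main)
  topk_int <- top_k(as.vector(scan$score_int), as.vector(truth_int),
                    k = min(k, scan$p * scan$q),
                    estimates = as.vector(scan$est_int))
  list(auc = roc$auc, roc = roc, topk_main = topk_main, topk_int = topk_int,
       topk_total = topk_main + topk_int, k = k)
}
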