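#' Method specifications for the four marginal samplers
#'
#' * `LADBLSS`: LAD (robust) likelihood + spike-and-slab priors; the flagship.
#' * `LADBL`: LAD likelihood, plain Laplace (scale-mixture) priors.
#' * `BLSS`: Gaussian likelihood + spike-and-slab priors.
#' * `BL`: Gaussian likelihood, plain Laplace priors (standard Bayesian
#'   LASSO hierarchy with Inverse-Gamma prior on the error variance).
#'
#' Non-sparse variants share the spike-and-slab code path with the spike
#' weights pinned at zero, so their coefficient conditionals are always the
#' slab normal and their slab variances always take the Bayesian-LASSO
#' (inverse-Gaussian) update.
#'
#' @param name one of `"LADBLSS"`, `"LADBL"`, `"BLSS"`, `"BL"`.
#' @return list with `name`, `robust` and `sparse` flags.
#' @export
method_spec <- function(name = c("LADBLSS", "LADBL", "BLSS", "BL")) {
  name <- match.arg(name)
  list(name = name,
       robust = name %in% c("LADBLSS", "LADBL"),
       sparse = name %in% c("LADBLSS", "BLSS"))
}

#' Fit one marginal G-by-E model
#'
#' Runs the Gibbs sampler of the requested method on one gene's marginal
#' design and returns the stored posterior draws together with selection
#' summaries.
#'
#' @param design a [marginal_design()].
#' @param method method name or a [method_spec()] list.
#' @param hyper a [gxe_hyper()] object.
#' @param iterations,burn_in MCMC length (defaults 10,000 / 5,000).
#' @param seed optional integer seed.
#' @param init optional initial chain state.
#' @param fix_pi optional length-2 vector pinning the spike weights (see
#'   [run_chain()]).
#' @return An object of class `gxe_fit`: the `posterior_draws` plus the
#'   method spec.
#' @export
fit_marginal <- function(design, method = "LADBLSS", hyper = gxe_hyper(),
                         iterations = 10000, burn_in = 5000, seed = NULL,
                         init = NULL, fix_pi = NULL) {
  if (is.character(method)) method <- method_spec(method)
  draws <- run_chain(design, hyper = hyper, iterations = iterations,
                     burn_in = burn_in, robust = method$robust,
                     sparse = method$sparse, seed = seed, init = init,
                     fix_pi = fix_pi)
  structure(list(draws = draws, method = method,
                 q = design$q, m = design$m, n = design$n),
            class = "gxe_fit")
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat(x$method$name, "marginal fit:", x$draws$meta$H, "stored sweeps\n")
  print(summary(x))
  invisible(x)
}

#' Per-effect summary table for one marginal fit
#'
#' One row per effect (main genetic effect `G` and each interaction
#' `GxE_k`): posterior median, equal-tailed 95% credible bounds and, for
#' spike-and-slab methods, the posterior inclusion probability.
#'
#' @param object a `gxe_fit`.
#' @param ... unused.
#' @return data.frame with columns `effect`, `median`, `q2.5`, `q97.5` and
#'   (spike methods) `pip`.
#' @export
summary.gxe_fit <- function(object, ...) {
  dr <- object$draws
  co <- cbind(dr$beta, dr$eta)
  labs <- c("G", paste0("GxE_", seq_len(object$q)))
  out <- data.frame(
    effect = labs,
    median = apply(co, 2, median),
    q2.5 = apply(co, 2, quantile, probs = 0.025),
    q97.5 = apply(co, 2, quantile, probs = 0.975),
    row.names = NULL)
  if (object$method$sparse) out$pip <- inclusion_probability(object)
  out
}
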