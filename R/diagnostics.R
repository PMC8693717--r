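#' Potential scale reduction factor (Gelman-Rubin, Brooks-Gelman corrected)
#'
#' For m parallel chains of length n the between-chain variance B and the
#' mean within-chain variance W give the pooled posterior-variance estimate
#' `Vhat = (n-1)/n W + (1 + 1/m) B/n`. The corrected statistic is
#' `sqrt((d+3)/(d+1) * Vhat / W)` with `d = 2 Vhat^2 / var(Vhat)` estimated
#' by the method of moments; an upper 97.5% limit replaces the random
#' between/within ratio by its F-quantile. Chains with zero variance
#' everywhere (e.g. exact copies of a constant) return the defined limit 1.
#'
#' @param chains numeric matrix, one column per chain (>= 2 columns, >= 2
#'   rows): draws of a single scalar parameter.
#' @return list with `psrf` and `upper` (97.5% limit).
#' @examples
#' x <- matrix(rnorm(2000), ncol = 2)
#' psrf(x)$psrf # close to 1
#' @export
psrf <- function(chains) {
  chains <- as.matrix(chains)
  m <- ncol(chains)
  n <- nrow(chains)
  if (m < 2) stop("at least two chains are required")
  if (n < 2) stop("chains must contain at least two draws")
  s2 <- apply(chains, 2, var)       # within-chain variances
  xbar <- colMeans(chains)
  W <- mean(s2)
  B <- n * var(xbar)                # between-chain variance (times n)
  if (W == 0) {
    if (B == 0) return(list(psrf = 1, upper = 1))
    return(list(psrf = Inf, upper = Inf))
  }
  Vhat <- (n - 1) / n * W + (1 + 1 / m) * B / n
  # moment-matched df of Vhat (Brooks & Gelman)
  var.w <- var(s2) / m
  var.b <- 2 * B^2 / (m - 1)
  cov.wb <- (n / m) * (cov_vec(s2, xbar^2) - 2 * mean(xbar) * cov_vec(s2, xbar))
  var.V <- ((n - 1)^2 * var.w + (1 + 1 / m)^2 * var.b +
              2 * (n - 1) * (1 + 1 / m) * cov.wb) / n^2
  d <- if (var.V > 0) 2 * Vhat^2 / var.V else Inf
  corr <- if (is.finite(d)) (d + 3) / (d + 1) else 1
  R2 <- Vhat / W
  # fixed + random split for the upper limit
  R2.fixed <- (n - 1) / n
  R2.random <- (1 + 1 / m) * B / (n * W)
  df.W <- if (var.w > 0) 2 * W^2 / var.w else Inf
  R2.upper <- R2.fixed + qf(0.975, m - 1, df.W) * R2.random
  list(psrf = sqrt(corr * R2), upper = sqrt(corr * R2.upper))
}

cov_vec <- function(x, y) {
  if (length(x) < 2) return(0)
  sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1)
}

#' PSRF report for a set of parallel marginal chains
#'
#' Runs `n_chains` chains of the requested method from overdispersed initial
#' coefficient values (default 1, 0, -1) and reports the PSRF of every
#' regression coefficient (alpha, gamma, beta, eta) and of the scale
#' parameter (tau or sigma2), with the convergence flag PSRF <= 1.1.
#'
#' @param design a [marginal_design()].
#' @param method method name, see [method_spec()].
#' @param n_chains number of parallel chains.
#' @param inits initial coefficient values, one per chain.
#' @param threshold convergence cutoff (default 1.1).
#' @param ... passed to [fit_marginal()] (iterations, burn_in, hyper, ...).
#' @return data.frame of class `psrf_report` with `parameter`, `psrf`,
#'   `upper`, `converged`.
#' @export
psrf_report <- function(design, method = "LADBLSS", n_chains = 3,
                        inits = c(1, 0, -1), threshold = 1.1, ...) {
  if (length(inits) < n_chains)
    inits <- rep_len(inits, n_chains)
  spec <- if (is.character(method)) method_spec(method) else method
  fits <- lapply(seq_len(n_chains), function(ch) {
    fit_marginal(design, method = spec,
                 init = init_chain_state(design, coef_init = inits[ch]), ...)
  })
  mats <- chain_parameter_matrix(fits)
  res <- lapply(mats, psrf)
  out <- data.frame(parameter = names(mats),
                    psrf = vapply(res, `[[`, 0, "psrf"),
                    upper = vapply(res, `[[`, 0, "upper"),
                    row.names = NULL)
  out$converged <- out$psrf <= threshold
  class(out) <- c("psrf_report", "data.frame")
  out
}

# named list of (draws x chains) matrices for the inference targets
chain_parameter_matrix <- function(fits) {
  q <- fits[[1]]$q; m <- fits[[1]]$m
  robust <- fits[[1]]$method$robust
  grab <- function(f) {
    dr <- f$draws
    cbind(dr$alpha,
          if (m > 0) dr$gamma,
          dr$beta, dr$eta,
          if (robust) dr$tau else dr$sigma2)
  }
  labs <- c(paste0("alpha", seq_len(q)),
            if (m > 0) paste0("gamma", seq_len(m)),
            "beta", paste0("eta", seq_len(q)),
            if (robust) "tau" else "sigma2")
  cols <- lapply(fits, grab)
  stats::setNames(lapply(seq_along(labs), function(j) {
    sapply(cols, function(mm) mm[, j])
  }), labs)
}

#' PSRF trajectory over increasing iteration windows
#'
#' Recomputes the PSRF of each parameter on the first `t` stored draws for a
#' grid of `t` values, yielding the data for convergence-trajectory plots
#' (PSRF against iterations).
#'
#' @param fits list of `gxe_fit` objects run from overdispersed initials (or
#'   the output chains of [psrf_report()] recomputed manually).
#' @param at iteration checkpoints (defaults to 20 points up to the stored
#'   length).
#' @return data.frame with `iteration`, `parameter`, `psrf`, `upper`.
#' @export
psrf_trajectory <- function(fits, at = NULL) {
  mats <- chain_parameter_matrix(fits)
  H <- nrow(mats[[1]])
  if (is.null(at)) at <- unique(round(seq(10, H, length.out = 20)))
  out <- do.call(rbind, lapply(at, function(t) {
    res <- lapply(mats, function(mm) psrf(mm[seq_len(t), , drop = FALSE]))
    data.frame(iteration = t, parameter = names(mats),
               psrf = vapply(res, `[[`, 0, "psrf"),
               upper = vapply(res, `[[`, 0, "upper"), row.names = NULL)
  }))
  out
}
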