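#' Prior constants for the marginal G-by-E samplers
#'
#' Collects every fixed prior constant used by the Gibbs samplers. Defaults
#' are all 1: Gamma(1, 1) on the Laplace inverse-scale `tau` and on the two
#' squared penalty parameters `phi1sq` (main effect) and `phi2sq`
#' (interactions), Beta(1, 1) on the spike weights `pi1`/`pi2`, unit prior
#' variances `alpha0`/`gamma0` on the environmental and clinical coefficients,
#' and Inverse-Gamma(1, 1) on the error variance of the non-robust
#' (least-squares) variants.
#'
#' The quantile level is fixed at `theta = 0.5` (LAD regression, i.e. the
#' median), for which the asymmetric-Laplace mixture constants reduce to
#' `xi1 = (1 - 2 theta) / (theta (1 - theta)) = 0` and
#' `xi2^2 = 2 / (theta (1 - theta)) = 8`.
#'
#' @param a,b Gamma(shape `a`, rate `b`) prior on `tau`.
#' @param c1,d1 Gamma prior on `phi1sq`, the squared main-effect penalty.
#' @param c2,d2 Gamma prior on `phi2sq`, the squared interaction penalty.
#' @param r1,u1 Beta prior on `pi1`, the prior spike probability of the main
#'   genetic effect.
#' @param r2,u2 Beta prior on `pi2`, the prior spike probability of each
#'   interaction effect.
#' @param alpha0,gamma0 prior variances of the environmental and clinical
#'   coefficients.
#' @param sigma_a,sigma_b Inverse-Gamma prior on the error variance `sigma^2`
#'   used by the BL/BLSS (Gaussian-likelihood) variants.
#' @return An object of class `gxe_hyper`.
#' @examples
#' h <- gxe_hyper()
#' h$xi2sq # 8
#' @export
gxe_hyper <- function(a = 1, b = 1, c1 = 1, d1 = 1, c2 = 1, d2 = 1,
                      r1 = 1, u1 = 1, r2 = 1, u2 = 1,
                      alpha0 = 1, gamma0 = 1, sigma_a = 1, sigma_b = 1) {
  vals <- c(a = a, b = b, c1 = c1, d1 = d1, c2 = c2, d2 = d2,
            r1 = r1, u1 = u1, r2 = r2, u2 = u2,
            alpha0 = alpha0, gamma0 = gamma0,
            sigma_a = sigma_a, sigma_b = sigma_b)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all hyperparameters must be finite and strictly positive")
  theta <- 0.5
  out <- c(as.list(vals),
           list(theta = theta,
                xi1 = (1 - 2 * theta) / (theta * (1 - theta)),
                xi2sq = 2 / (theta * (1 - theta))))
  class(out) <- "gxe_hyper"
  out
}

#' @export
print.gxe_hyper <- function(x, ...) {
  cat("G-by-E prior constants (theta = ", x$theta, ", xi2^2 = ", x$xi2sq,
      ")\n", sep = "")
  flat <- unlist(x[c("a", "b", "c1", "d1", "c2", "d2", "r1", "u1", "r2", "u2",
                     "alpha0", "gamma0", "sigma_a", "sigma_b")])
  print(flat)
  invisible(x)
}
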