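#' Assemble one gene's marginal regression design
#'
#' The marginal model for gene j is
#' `y = E alpha + C gamma + x beta_j + W eta_j + e`, where `W` holds the q
#' gene-environment interaction columns `W[, k] = x * E[, k]`. Shared
#' covariates `E` (environmental) and `C` (clinical) are re-used across genes;
#' only `x` and `W` change from gene to gene.
#'
#' @param y numeric response vector, length n (continuous phenotype).
#' @param E n x q matrix of environmental exposures (q >= 1).
#' @param C optional n x m matrix of clinical covariates (may be `NULL`).
#' @param x numeric genetic measurement for one gene, length n; continuous
#'   expression or 0/1/2 SNP dosage.
#' @return An object of class `marginal_design`: list with elements `y`, `E`,
#'   `C`, `x`, `W` and dimensions `n`, `q`, `m`.
#' @examples
#' n <- 20
#' d <- marginal_design(rnorm(n), matrix(rnorm(n * 2), n), NULL, rnorm(n))
#' all(d$W == d$x * d$E)
#' @export
marginal_design <- function(y, E, C = NULL, x) {
  y <- as.numeric(y)
  E <- as.matrix(E)
  x <- as.numeric(x)
  n <- length(y)
  if (n < 1L) stop("empty response")
  if (nrow(E) != n || length(x) != n)
    stop("y, E and x must share the same number of samples")
  if (ncol(E) < 1L) stop("at least one environmental factor is required")
  if (is.null(C)) {
    C <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    C <- as.matrix(C)
    if (nrow(C) != n) stop("C must have one row per sample")
  }
  if (!all(is.finite(y)) || !all(is.finite(E)) || !all(is.finite(C)) ||
      !all(is.finite(x)))
    stop("all design entries must be finite")
  W <- x * E # recycles x down each column: W[i, k] = x[i] * E[i, k]
  structure(list(y = y, E = E, C = C, x = x, W = W,
                 n = n, q = ncol(E), m = ncol(C)),
            class = "marginal_design")
}

#' @export
print.marginal_design <- function(x, ...) {
  cat("marginal G-by-E design: n =", x$n, ", q =", x$q, "environmental,",
      "m =", x$m, "clinical, 1 gene +", x$q, "interactions\n")
  invisible(x)
}
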