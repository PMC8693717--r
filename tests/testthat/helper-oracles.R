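# Independent numeric oracles used across the suite. These deliberately use
# brute-force quadrature / closed-form textbook formulas, never the package's
# own sampling code paths.

# Posterior mean/variance of a single coefficient b with prior N(0, prior_var)
# and likelihood prod_i N(pr_i | b z_i, 1/w_i), by grid integration.
grid_normal_posterior <- function(pr, z, w, prior_var, width = 12, K = 20001) {
  loglik <- function(b) -0.5 * sum(w * (pr - b * z)^2)
  # center the grid on the closed-form-free mode found numerically
  opt <- optimize(function(b) -(loglik(b) - b^2 / (2 * prior_var)),
                  interval = c(-100, 100))
  ctr <- opt$minimum
  sdapprox <- 1 / sqrt(sum(w * z^2) + 1 / prior_var)
  grid <- seq(ctr - width * sdapprox, ctr + width * sdapprox, length.out = K)
  lp <- vapply(grid, loglik, 0) - grid^2 / (2 * prior_var)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  m <- sum(grid * p)
  v <- sum((grid - m)^2 * p)
  list(mean = m, variance = v)
}

# Posterior spike probability of the two-component mixture
#   b = 0 with prior prob pi, else b ~ N(0, slab_var),
# with the same likelihood as above; slab marginal likelihood by quadrature.
spike_prob_oracle <- function(pr, z, w, slab_var, pi_spike, width = 14,
                              K = 40001) {
  loglik <- function(b) -0.5 * sum(w * (pr - b * z)^2)
  sdapprox <- 1 / sqrt(sum(w * z^2) + 1 / slab_var)
  ctr <- sum(w * pr * z) / (sum(w * z^2) + 1 / slab_var)
  grid <- seq(ctr - width * sdapprox, ctr + width * sdapprox, length.out = K)
  h <- grid[2] - grid[1]
  lp <- vapply(grid, loglik, 0) + dnorm(grid, 0, sqrt(slab_var), log = TRUE)
  mx <- max(lp)
  log_slab_marg <- mx + log(sum(exp(lp - mx)) * h)
  log_spike <- log(pi_spike) + loglik(0)
  log_slab <- log1p(-pi_spike) + log_slab_marg
  1 / (1 + exp(log_slab - log_spike))
}

# Closed-form Inverse-Gaussian(mean mu, shape lambda) cdf (textbook formula).
ig_cdf <- function(x, mu, lambda) {
  ifelse(x <= 0, 0,
         pnorm(sqrt(lambda / x) * (x / mu - 1)) +
           exp(2 * lambda / mu) * pnorm(-sqrt(lambda / x) * (x / mu + 1)))
}

# Numeric cdf of GIG(p = 1/2, a, b): density ~ x^(-1/2) exp(-(a x + b / x)/2).
gig_half_cdf_fun <- function(a, b, K = 200001) {
  med <- sqrt(b / a) # rough scale
  hi <- med
  while (exp(-0.5 * (a * hi + b / hi)) * hi^(-0.5) >
         1e-18 * exp(-sqrt(a * b))) hi <- hi * 2
  grid <- exp(seq(log(med * 1e-8), log(hi), length.out = K))
  dens <- grid^(-0.5) * exp(-0.5 * (a * grid + b / grid) + sqrt(a * b))
  mids <- (dens[-1] + dens[-K]) / 2 * diff(grid)
  cdf <- c(0, cumsum(mids))
  cdf <- cdf / cdf[K]
  approxfun(grid, cdf, yleft = 0, yright = 1)
}

# Brute-force Mann-Whitney concordance: P(score_true > score_null) + .5 ties.
mw_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  st <- scores[truth]
  sn <- scores[!truth]
  tot <- 0
  for (a in st) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(st) * length(sn))
}

# Textbook Gelman-Rubin with Brooks-Gelman (d+3)/(d+1) correction,
# independently coded (plain formulas, no shared helpers).
psrf_oracle <- function(chains) {
  m <- ncol(chains); n <- nrow(chains)
  s2 <- apply(chains, 2, var)
  mu <- colMeans(chains)
  W <- mean(s2)
  B <- n * var(mu)
  Vhat <- (n - 1) / n * W + (1 + 1 / m) * B / n
  var.w <- var(s2) / m
  var.b <- 2 * B^2 / (m - 1)
  cov.wb <- (n / m) * (cov(s2, mu^2) - 2 * mean(mu) * cov(s2, mu))
  var.V <- ((n - 1)^2 * var.w + (1 + 1 / m)^2 * var.b +
              2 * (n - 1) * (1 + 1 / m) * cov.wb) / n^2
  d <- 2 * Vhat^2 / var.V
  sqrt((d + 3) / (d + 1) * Vhat / W)
}

# Small simulated dataset shared by smoke tests.
tiny_sim <- function(p = 12, n = 80, error_model = "normal", seed = 42) {
  sim_gxe(sim_config(n = n, p = p, n_true_main = 3, n_true_int = 4,
                     error_model = error_model, seed = seed))
}
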