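test_that("precision weights follow tau / (xi2^2 v) with monotone behavior", {
  h <- gxe_hyper()
  expect_equal(lad_weights(v = 1 / 8, tau = 1, h), 1)
  expect_equal(lad_weights(v = c(1, 2), tau = 2, h), c(0.25, 0.125))
  set.seed(1)
  v <- sort(runif(10, 0.1, 5))
  w <- lad_weights(v, tau = 1.3, h)
  expect_true(all(diff(w) < 0))           # decreasing in v
  expect_true(all(lad_weights(v, 2.6, h) > w)) # increasing in tau
  expect_error(lad_weights(c(1, -1), 1, h), "positive")
  expect_error(lad_weights(1, 0, h), "positive")
})

test_that("normal coefficient conditional matches closed form and quadrature", {
  # all-zero predictor returns the prior
  set.seed(2)
  up <- normal_coef_update(rnorm(6), rep(0, 6), runif(6, 0.5, 2), prior_var = 3)
  expect_equal(up$mean, 0)
  expect_equal(up$variance, 3)
  # 1-point plug-in: variance (1 + 1)^-1, mean = var * 2
  up <- normal_coef_update(2, 1, 1, prior_var = 1)
  expect_equal(up$variance, 0.5)
  expect_equal(up$mean, 1.0)
  # 5-point toys against grid integration of prior x likelihood
  for (s in 1:3) {
    set.seed(s)
    pr <- rnorm(5, 1); z <- rnorm(5); w <- runif(5, 0.2, 3)
    pv <- runif(1, 0.3, 4)
    up <- normal_coef_update(pr, z, w, pv)
    or <- grid_normal_posterior(pr, z, w, pv)
    expect_equal(up$mean, or$mean, tolerance = 1e-6)
    expect_equal(up$variance, or$variance, tolerance = 1e-6)
  }
  expect_error(normal_coef_update(1, 1, 1, prior_var = 0), "positive")
})

test_that("spike-and-slab conditional: degenerate cases and mixture oracle", {
  set.seed(3)
  pr <- rnorm(5, 0.5); z <- rnorm(5); w <- runif(5, 0.5, 2)
  up1 <- spike_slab_update(pr, z, w, slab_var = 1, pi_spike = 1)
  expect_equal(up1$spike_prob, 1)
  expect_equal(up1$value, 0)
  up0 <- spike_slab_update(pr, z, w, slab_var = 1, pi_spike = 0)
  expect_equal(up0$spike_prob, 0)
  expect_true(up0$value != 0)
  # computed spike probability against the two-component quadrature oracle
  for (s in 1:4) {
    set.seed(s + 10)
    pr <- rnorm(5, ifelse(s %% 2, 0, 2)); z <- rnorm(5); w <- runif(5, 0.2, 2)
    sv <- runif(1, 0.5, 3); pi <- runif(1, 0.1, 0.9)
    up <- spike_slab_update(pr, z, w, sv, pi)
    expect_equal(up$spike_prob, spike_prob_oracle(pr, z, w, sv, pi),
                 tolerance = 1e-5)
  }
  # no overflow for very strong signal (log-space computation)
  up <- spike_slab_update(rep(50, 20), rep(1, 20), rep(10, 20), 1, 0.5)
  expect_equal(up$spike_prob, 0)
  expect_true(is.finite(up$value))
  # empirical zero frequency over many draws matches the oracle probability
  set.seed(4)
  pr <- rnorm(5, 0.4); z <- rnorm(5); w <- runif(5, 0.5, 2)
  l <- spike_prob_oracle(pr, z, w, 1, 0.5)
  nrep <- 1e5
  zf <- mean(vapply(seq_len(nrep), function(i)
    spike_slab_update(pr, z, w, 1, 0.5)$value == 0, TRUE))
  expect_lt(abs(zf - l), 3 * sqrt(l * (1 - l) / nrep))
})

test_that("slab variance update: exponential spike branch, IG slab branch", {
  set.seed(5)
  # coef == 0: s ~ Exponential(rate phi^2 / 2), mean 2 / phi^2
  for (phisq in c(2, 0.7)) {
    s <- vapply(1:1e5, function(i) update_slab_variance(0, phisq), 0)
    expect_lt(abs(mean(s) - 2 / phisq), 3 * (2 / phisq) / sqrt(1e5))
  }
  # coef != 0: 1/s ~ IG(sqrt(phi^2/coef^2), phi^2); KS against closed-form cdf
  coef <- 0.8; phisq <- 1.7
  inv_s <- vapply(1:2e4, function(i) 1 / update_slab_variance(coef, phisq), 0)
  ks <- suppressWarnings(
    ks.test(inv_s, function(q) ig_cdf(q, sqrt(phisq) / abs(coef), phisq)))
  expect_gt(ks$p.value, 0.01)
})

test_that("penalty and mixing-weight conditionals match their stated laws", {
  h <- gxe_hyper()
  set.seed(6)
  # phi1^2 ~ Gamma(c1+1, s1/2 + d1): mean check
  d <- vapply(1:1e5, function(i) update_phi1sq(2, h), 0)
  expect_lt(abs(mean(d) - 1), 3 * sd(d) / sqrt(1e5))
  # phi2^2 ~ Gamma(c2+q, sum s2/2 + d2), q = 4, s2 = 1,1,1,1 -> Gamma(5, 3)
  d <- vapply(1:1e5, function(i) update_phi2sq(rep(1, 4), h), 0)
  expect_lt(abs(mean(d) - 5 / 3), 3 * sd(d) / sqrt(1e5))
  # q = 1 reduces to the phi1 form
  set.seed(7); a <- vapply(1:2e4, function(i) update_phi2sq(2, h), 0)
  set.seed(7); b <- vapply(1:2e4, function(i) update_phi1sq(2, h), 0)
  expect_equal(mean(a), mean(b), tolerance = 0.02)
  # pi1 | ind: Beta(r1+1-I, u1+I)
  set.seed(8)
  d0 <- vapply(1:1e5, function(i) update_pi1(0, h), 0)
  d1 <- vapply(1:1e5, function(i) update_pi1(1, h), 0)
  expect_lt(abs(mean(d0) - 2 / 3), 3 * sd(d0) / sqrt(1e5))
  expect_lt(abs(mean(d1) - 1 / 3), 3 * sd(d1) / sqrt(1e5))
  # pi2 | ind: Beta(r2+q-k, u2+k); q=4, k=2 -> Beta(3,3) mean .5
  d <- vapply(1:1e5, function(i) update_pi2(c(1, 0, 1, 0), h), 0)
  expect_lt(abs(mean(d) - 0.5), 3 * sd(d) / sqrt(1e5))
  # posterior-mean ordering between all-spike and all-slab states
  m0 <- mean(vapply(1:2e4, function(i) update_pi2(rep(0, 4), h), 0))
  mq <- mean(vapply(1:2e4, function(i) update_pi2(rep(1, 4), h), 0))
  expect_gt(m0, mq)
})

test_that("tau conditional: plug-in shape/rate, empty-sum edge, quadrature", {
  h <- gxe_hyper()
  set.seed(9)
  # n=2 plug-in: shape 4, rate 5
  d <- vapply(1:1e5, function(i) update_tau(c(4, 4), c(1, 1), h), 0)
  expect_lt(abs(mean(d) - 4 / 5), 3 * sd(d) / sqrt(1e5))
  expect_lt(abs(var(d) - 4 / 25), 10 * 4 / 25 / sqrt(1e5))
  # n=0 edge: prior Gamma(a, b)
  d <- vapply(1:1e5, function(i) update_tau(numeric(0), numeric(0), h), 0)
  expect_lt(abs(mean(d) - 1), 3 * sd(d) / sqrt(1e5))
  # 5-point toy: empirical mean against 1-D quadrature of prior x likelihood,
  # where the likelihood is the full scale-mixture kernel in tau
  set.seed(10)
  resid <- rnorm(5); v <- runif(5, 0.3, 2)
  logkern <- function(tau)
    (h$a + 1.5 * 5 - 1) * log(tau) -
      tau * (h$b + sum(resid^2 / (2 * h$xi2sq * v) + v))
  grid <- seq(1e-6, 10, length.out = 2e5)
  lk <- logkern(grid); pk <- exp(lk - max(lk)); pk <- pk / sum(pk)
  oracle_mean <- sum(grid * pk)
  set.seed(99)
  d <- vapply(1:1e5, function(i) update_tau(resid, v, h), 0)
  expect_lt(abs(mean(d) - oracle_mean), 3 * sd(d) / sqrt(1e5))
})

test_that("latent scale conditional is GIG(1/2, 2 tau, tau r^2/xi2^2)", {
  h <- gxe_hyper()
  set.seed(11)
  # mean parameter of 1/v equals 1 when resid^2 = 16, xi2^2 = 8, any tau:
  # E[1/v] = mu = sqrt(2*8/16) = 1
  iv <- 1 / vapply(1:1e5, function(i) update_latent_v(4, tau = 1.7, h), 0)
  expect_lt(abs(mean(iv) - 1), 3 * sd(iv) / sqrt(1e5))
  # draws strictly positive
  v <- update_latent_v(c(-3, 0, 0.001, 5), tau = 2, h)
  expect_true(all(v > 0))
  # KS of v against numerically normalized GIG density
  tau <- 1.3; resid <- 2.2
  v <- vapply(1:2e4, function(i) update_latent_v(resid, tau, h), 0)
  cdf <- gig_half_cdf_fun(a = 2 * tau, b = tau * resid^2 / h$xi2sq)
  ks <- suppressWarnings(ks.test(v, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("inverse-Gaussian sampler matches the closed-form cdf", {
  set.seed(12)
  for (par in list(c(1, 1), c(0.3, 2.5), c(4, 0.8))) {
    x <- rinvgauss(2e4, par[1], par[2])
    ks <- suppressWarnings(
      ks.test(x, function(q) ig_cdf(q, par[1], par[2])))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("a sweep is deterministic under a fixed seed and keeps invariants", {
  sim <- tiny_sim()
  d <- marginal_design(sim$y, sim$E, sim$C, sim$X[, 1])
  st <- init_chain_state(d)
  set.seed(13); s1 <- gibbs_sweep(st, d)
  set.seed(13); s2 <- gibbs_sweep(st, d)
  expect_identical(s1, s2)
  expect_true(all(s1$v > 0))
  expect_true(s1$tau > 0 && s1$s1 > 0 && all(s1$s2 > 0))
  expect_equal(s1$ind_beta, as.integer(s1$beta != 0))
  expect_equal(as.vector(s1$ind_eta), as.integer(s1$eta != 0))
})

test_that("run_chain honors the iteration contract and reproducibility", {
  sim <- tiny_sim()
  d <- marginal_design(sim$y, sim$E, sim$C, sim$X[, 2])
  expect_error(run_chain(d, iterations = 100, burn_in = 100), "exceed")
  dr <- run_chain(d, iterations = 400, burn_in = 150, seed = 14)
  expect_equal(nrow(dr$beta), 250)
  expect_equal(dr$meta$H, 250)
  dr2 <- run_chain(d, iterations = 400, burn_in = 150, seed = 14)
  expect_identical(dr$beta, dr2$beta)
  expect_identical(dr$eta, dr2$eta)
  expect_identical(dr$tau, dr2$tau)
  # indicator / exact-zero consistency across every stored sweep
  expect_identical(dr$ind_beta[, 1], as.integer(dr$beta[, 1] != 0))
  expect_identical(as.vector(dr$ind_eta), as.integer(as.vector(dr$eta) != 0))
  # default call stores H = 5000 sweeps
  dr <- run_chain(d, seed = 15)
  expect_equal(nrow(dr$beta), 5000)
})

test_that("posterior recovers a strong environmental coefficient", {
  # conjugate-style toy: q=1, m=0, strong alpha, weak everything else
  set.seed(16)
  n <- 200
  E <- matrix(rnorm(n), n, 1)
  x <- rnorm(n)
  y <- as.vector(2 * E[, 1]) + rnorm(n, sd = 0.5)
  d <- marginal_design(y, E, NULL, x)
  dr <- run_chain(d, iterations = 3000, burn_in = 1000, seed = 17)
  a <- dr$alpha[, 1]
  expect_lt(abs(mean(a) - 2), 3 * sd(a))
})

test_that("LAD posterior locations scale with the response (no-spike config)", {
  set.seed(18)
  n <- 150
  E <- matrix(rnorm(n * 2), n, 2)
  x <- rnorm(n)
  y <- E %*% c(1, -0.5) + 0.8 * x + rnorm(n, sd = 0.4)
  d1 <- marginal_design(as.vector(y), E, NULL, x)
  d5 <- marginal_design(as.vector(5 * y), E, NULL, x)
  dr1 <- run_chain(d1, iterations = 4000, burn_in = 1000, seed = 19,
                   sparse = FALSE)
  dr5 <- run_chain(d5, iterations = 4000, burn_in = 1000, seed = 20,
                   sparse = FALSE)
  m1 <- c(colMeans(dr1$alpha), mean(dr1$beta))
  m5 <- c(colMeans(dr5$alpha), mean(dr5$beta))
  expect_equal(m5 / m1, rep(5, 3), tolerance = 0.15)
})
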