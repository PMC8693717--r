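test_that("environmental/clinical generator has AR1 structure and unit scale", {
  set.seed(61)
  ec <- gen_env_clinical(1e5, q = 4, m = 3, rho = 0.5)
  expect_equal(dim(ec$E), c(1e5, 4))
  expect_equal(dim(ec$C), c(1e5, 3))
  expect_lt(abs(cor(ec$E[, 1], ec$E[, 2]) - 0.5), 0.01)
  expect_lt(abs(cor(ec$E[, 1], ec$E[, 3]) - 0.25), 0.01)
  expect_lt(abs(var(ec$E[, 4]) - 1), 0.02)
  expect_lt(abs(mean(ec$C[, 2])), 0.02)
  # q = 1: independent standard normal column
  e1 <- gen_env_clinical(1e5, q = 1, m = 0, rho = 0.5)$E
  expect_lt(abs(var(e1[, 1]) - 1), 0.02)
})

test_that("continuous gene generator matches the AR1 moments", {
  set.seed(62)
  X <- gen_gene_continuous(1e5, p = 5, rho = 0.5)
  expect_lt(abs(cor(X[, 1], X[, 3]) - 0.25), 0.01)
  expect_lt(abs(cor(X[, 2], X[, 3]) - 0.5), 0.01)
  expect_lt(abs(mean(X[, 5])), 0.02)
  expect_lt(abs(var(X[, 5]) - 1), 0.02)
})

test_that("quartile dichotomization yields 0/1/2 with 1/4-1/2-1/4 mass", {
  set.seed(63)
  X <- gen_gene_continuous(2e4, p = 3, rho = 0.5)
  S <- dichotomize_to_snp(X)
  expect_true(all(S %in% 0:2))
  fr <- table(S[, 1]) / nrow(S)
  expect_lt(abs(fr[["0"]] - 0.25), 0.02)
  expect_lt(abs(fr[["1"]] - 0.50), 0.02)
  expect_lt(abs(fr[["2"]] - 0.25), 0.02)
  expect_error(dichotomize_to_snp(matrix(1, 10, 1)), "degenerate")
})

test_that("LD SNP generator reproduces HWE margins and pairwise correlation", {
  set.seed(64)
  S <- gen_snp_ld(1e5, p = 4, maf = 0.3, ld_r = 0.6)
  expect_true(all(S %in% 0:2))
  # HWE genotype frequencies at each locus: (0.49, 0.42, 0.09) for maf 0.3
  fr <- table(S[, 1]) / nrow(S)
  expect_lt(abs(fr[["0"]] - 0.49), 0.01)
  expect_lt(abs(fr[["1"]] - 0.42), 0.01)
  expect_lt(abs(fr[["2"]] - 0.09), 0.01)
  expect_lt(abs(mean(S[, 3]) - 0.6), 0.01) # mean minor-allele count = 2*maf
  # adjacent-locus genotype correlation equals the haplotype correlation r
  expect_lt(abs(cor(S[, 1], S[, 2]) - 0.6), 0.01)
  expect_lt(abs(cor(S[, 2], S[, 3]) - 0.6), 0.01)
  # invalid haplotype frequencies rejected
  expect_error(gen_snp_ld(10, 2, maf = 0.3, ld_r = 1.5), "haplotype")
})

test_that("effect assignment respects counts, support and the seed contract", {
  cf <- sim_config(p = 100)
  set.seed(65); e1 <- assign_effects(cf)
  set.seed(65); e2 <- assign_effects(cf)
  expect_identical(e1, e2)
  expect_equal(sum(e1$beta_mask), 8)
  expect_equal(sum(e1$eta_mask), 12)
  expect_true(all(e1$alpha >= 0.1 & e1$alpha <= 0.5))
  expect_true(all(e1$gamma >= 0.1 & e1$gamma <= 0.5))
  expect_true(all(e1$beta[e1$beta_mask] >= cf$gcoef_low &
                    e1$beta[e1$beta_mask] <= cf$gcoef_high))
  expect_true(all(e1$eta[e1$eta_mask] >= cf$gcoef_low &
                    e1$eta[e1$eta_mask] <= cf$gcoef_high))
  # weak-hierarchy-friendly placement: interactions sit on main-effect genes
  expect_true(all(which(rowSums(e1$eta_mask) > 0) %in% which(e1$beta_mask)))
})

test_that("error models have their stated supports and tails", {
  set.seed(66)
  e <- gen_errors(1e5, "normal")
  expect_lt(abs(var(e) - 1), 0.02)
  expect_lt(abs(mean(e)), 0.02)
  expect_true(all(is.finite(gen_errors(1e4, "t2"))))
  ln <- gen_errors(1e4, "lognormal")
  expect_true(all(ln > 0))
  # median of LogNormal(0, 2) is 1 (sdlog = 2, rlnorm convention)
  expect_lt(abs(median(ln) - 1), 0.08)
  # Cauchy mixtures: P(|x| > 10) is essentially the contamination tail
  p10 <- 1 - 2 / pi * atan(10) # per-Cauchy-draw tail mass
  mix <- c(cauchy10 = 0.1, cauchy20 = 0.2)
  for (nm in names(mix)) {
    x <- gen_errors(1e5, nm)
    frac <- mean(abs(x) > 10)
    expect_lt(abs(frac - mix[[nm]] * p10),
              3 * sqrt(mix[[nm]] * p10 / 1e5) + 2e-4)
  }
  expect_error(gen_errors(10, "gumbel"))
})

test_that("assembled datasets are self-consistent and reproducible", {
  cf <- sim_config(n = 100, p = 20, seed = 67)
  sim <- sim_gxe(cf)
  sim2 <- sim_gxe(cf)
  expect_identical(sim$y, sim2$y)
  expect_identical(sim$X, sim2$X)
  # stored components re-sum to y exactly
  yhat <- as.vector(sim$E %*% sim$alpha) + as.vector(sim$C %*% sim$gamma) +
    as.vector(sim$X %*% sim$beta) + sim$errors
  for (k in 1:cf$q)
    yhat <- yhat + (sim$X * sim$E[, k]) %*% sim$eta[, k]
  expect_equal(as.vector(yhat), sim$y, tolerance = 1e-12)
  # settings 2 and 3 emit only 0/1/2
  s2 <- sim_gxe(sim_config(n = 60, p = 10, setting = 2, seed = 68))
  s3 <- sim_gxe(sim_config(n = 60, p = 10, setting = 3, seed = 69))
  expect_true(all(s2$X %in% 0:2))
  expect_true(all(s3$X %in% 0:2))
})

test_that("OLS on the true support recovers the generating coefficients", {
  sim <- sim_gxe(sim_config(n = 1e4, p = 12, n_true_main = 3, n_true_int = 4,
                            seed = 70))
  tm <- which(sim$beta_mask)
  ti <- which(sim$eta_mask, arr.ind = TRUE)
  D <- cbind(sim$E, sim$C, sim$X[, tm],
             sapply(seq_len(nrow(ti)), function(i)
               sim$X[, ti[i, 1]] * sim$E[, ti[i, 2]]))
  fit <- lm(sim$y ~ D - 1)
  truth <- c(sim$alpha, sim$gamma, sim$beta[tm], sim$eta[ti])
  se <- summary(fit)$coefficients[, 2]
  expect_true(all(abs(coef(fit) - truth) < 3.5 * se))
})

test_that("dataset bundles round-trip through CSV", {
  sim <- sim_gxe(sim_config(n = 30, p = 5, n_true_main = 2,
                            n_true_int = 2, seed = 71))
  dir <- tempfile()
  write_sim_bundle(sim, dir)
  expect_true(all(file.exists(file.path(
    dir, c("y.csv", "E.csv", "C.csv", "X.csv", "truth.json")))))
  y <- read.csv(file.path(dir, "y.csv"))$y
  expect_equal(y, sim$y, tolerance = 1e-12)
  X <- as.matrix(read.csv(file.path(dir, "X.csv")))
  expect_equal(unname(X), unname(sim$X), tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
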