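#' Simulation configuration for the marginal G-by-E benchmark
#'
#' Defaults reproduce the benchmark design: n = 200 subjects, p = 500 genes,
#' q = 4 environmental and m = 3 clinical covariates drawn from multivariate
#' normals with unit marginal variance and AR1 correlation rho = 0.5; 8 true
#' main genetic effects and 12 true interactions; five error models.
#' Environmental/clinical coefficients are drawn from Unif\[0.1, 0.5\]; the
#' genetic main and interaction magnitudes from Unif\[0.2, 0.8\] (the
#' benchmark leaves these unstated, and signals below ~0.2 are marginally
#' undetectable at n = 200 -- see the methods vignette). Settings: 1 = continuous AR1 expression,
#' 2 = expression dichotomized at the quartiles into 0/1/2 genotypes,
#' 3 = 0/1/2 SNPs under pairwise linkage disequilibrium (MAF 0.3, pairwise
#' correlation 0.6, Hardy-Weinberg equilibrium).
#'
#' @param n,p,q,m sample size, number of genes, environmental and clinical
#'   covariates.
#' @param rho AR1 correlation for E, C and Setting-1 genes.
#' @param n_true_main,n_true_int number of truly nonzero main and interaction
#'   effects.
#' @param coef_low,coef_high support of the uniform environmental/clinical
#'   coefficient draws.
#' @param gcoef_low,gcoef_high support of the uniform draws for the true
#'   genetic main and interaction magnitudes.
#' @param error_model one of `"normal"`, `"t2"`, `"lognormal"`, `"cauchy10"`,
#'   `"cauchy20"` (the last two are 90/10 and 80/20 normal-Cauchy mixtures).
#' @param setting genetic-matrix generator: 1, 2 or 3.
#' @param maf minor allele frequency for Setting 3.
#' @param ld_r target pairwise LD correlation for Setting 3.
#' @param center_errors if `TRUE`, subtract the error distribution's
#'   theoretical median (1 for the lognormal, 0 otherwise) so the model
#'   without intercept sees location-free noise; the benchmark does not say
#'   whether its errors were centered, so the default is `FALSE`.
#' @param seed optional integer seed consumed by [sim_gxe()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n = 200, p = 500, q = 4, m = 3, rho = 0.5,
                       n_true_main = 8, n_true_int = 12,
                       coef_low = 0.1, coef_high = 0.5,
                       gcoef_low = 0.2, gcoef_high = 0.8,
                       error_model = c("normal", "t2", "lognormal",
                                       "cauchy10", "cauchy20"),
                       setting = 1, maf = 0.3, ld_r = 0.6,
                       center_errors = FALSE, seed = NULL) {
  error_model <- match.arg(error_model)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (maf <= 0 || maf >= 0.5) stop("maf must lie in (0, 0.5)")
  if (!setting %in% 1:3) stop("setting must be 1, 2 or 3")
  if (n_true_main > p) stop("more true main effects than genes")
  if (n_true_int > p * q) stop("more true interactions than (gene, env) slots")
  structure(list(n = n, p = p, q = q, m = m, rho = rho,
                 n_true_main = n_true_main, n_true_int = n_true_int,
                 coef_low = coef_low, coef_high = coef_high,
                 gcoef_low = gcoef_low, gcoef_high = gcoef_high,
                 error_model = error_model, setting = setting,
                 maf = maf, ld_r = ld_r, center_errors = center_errors,
                 seed = seed),
            class = "sim_config")
}

# n x k matrix with N(0,1) margins and AR1 correlation rho^|j-k|, by the
# sequential construction x_j = rho x_{j-1} + sqrt(1-rho^2) z_j.
ar1_normal <- function(n, k, rho) {
  if (k == 0) return(matrix(numeric(0), n, 0))
  X <- matrix(0, n, k)
  X[, 1] <- rnorm(n)
  if (k > 1)
    for (j in 2:k) X[, j] <- rho * X[, j - 1] + sqrt(1 - rho^2) * rnorm(n)
  X
}

#' Generate environmental and clinical covariate matrices
#'
#' Both matrices have independent rows with standard normal margins and AR1
#' column correlation `rho^|j-k|`.
#'
#' @param n,q,m dimensions.
#' @param rho AR1 parameter.
#' @return list with `E` (n x q) and `C` (n x m).
#' @export
gen_env_clinical <- function(n, q, m, rho = 0.5) {
  list(E = ar1_normal(n, q, rho), C = ar1_normal(n, m, rho))
}

#' Generate continuous gene-expression matrix (Setting 1)
#'
#' n x p matrix with standard normal margins and AR1 correlation `rho^|j-k|`
#' between genes j and k.
#'
#' @param n,p dimensions.
#' @param rho AR1 parameter.
#' @return n x p numeric matrix.
#' @export
gen_gene_continuous <- function(n, p, rho = 0.5) {
  ar1_normal(n, p, rho)
}

#' Dichotomize expression values into 0/1/2 genotypes (Setting 2)
#'
#' Per column, values below the first quartile code 0 (aa), values between
#' the first and third quartiles code 1 (Aa), and values at or above the
#' third quartile code 2 (AA). Low expression mapping to genotype 0 is an
#' arbitrary but fixed direction.
#'
#' @param X numeric matrix of continuous expression values.
#' @return integer matrix with entries in \{0, 1, 2\}.
#' @export
dichotomize_to_snp <- function(X) {
  X <- as.matrix(X)
  apply(X, 2, function(col) {
    qs <- quantile(col, probs = c(0.25, 0.75), names = FALSE)
    if (qs[1] == qs[2]) stop("degenerate quartiles: constant column")
    as.integer((col >= qs[1]) + (col >= qs[2]))
  })
}

#' Generate 0/1/2 SNP genotypes under pairwise LD (Setting 3)
#'
#' Adjacent loci share minor allele frequency `maf` and target pairwise
#' correlation `ld_r`, giving LD coefficient
#' `delta = ld_r * sqrt(q1 (1-q1) q2 (1-q2))` and haplotype frequencies
#' `pAB = q1 q2 + delta`, `pab = (1-q1)(1-q2) + delta`,
#' `pAb = q1 (1-q2) - delta`, `paB = (1-q1) q2 - delta`. Under random mating
#' each subject carries two independent haplotypes, each a Markov chain over
#' loci with transition P(B | A) = pAB / q1 and P(B | a) = paB / (1 - q1);
#' the first locus is drawn under Hardy-Weinberg equilibrium. The genotype is
#' the minor-allele count, so the implied conditional genotype probability
#' matrix between adjacent loci is reproduced exactly.
#'
#' @param n,p dimensions.
#' @param maf minor allele frequency at every locus.
#' @param ld_r target pairwise correlation between adjacent loci.
#' @return n x p integer matrix with entries in \{0, 1, 2\}.
#' @export
gen_snp_ld <- function(n, p, maf = 0.3, ld_r = 0.6) {
  q1 <- maf; q2 <- maf
  delta <- ld_r * sqrt(q1 * (1 - q1) * q2 * (1 - q2))
  hap <- c(AB = q1 * q2 + delta, ab = (1 - q1) * (1 - q2) + delta,
           Ab = q1 * (1 - q2) - delta, aB = (1 - q1) * q2 - delta)
  if (any(hap < 0) || any(hap > 1))
    stop("LD coefficient delta yields invalid haplotype frequencies")
  p_b_given_a <- hap["AB"] / q1        # P(next allele B | current A)
  p_b_given_not <- hap["aB"] / (1 - q1) # P(next allele B | current a)
  # two haplotypes per subject, each a Markov chain along the loci
  h1 <- matrix(0L, n, p)
  h2 <- matrix(0L, n, p)
  h1[, 1] <- rbinom(n, 1, q1)
  h2[, 1] <- rbinom(n, 1, q1)
  if (p > 1) {
    for (j in 2:p) {
      h1[, j] <- rbinom(n, 1, ifelse(h1[, j - 1] == 1, p_b_given_a,
                                     p_b_given_not))
      h2[, j] <- rbinom(n, 1, ifelse(h2[, j - 1] == 1, p_b_given_a,
                                     p_b_given_not))
    }
  }
  h1 + h2
}

#' Draw the true effect pattern
#'
#' All environmental and clinical coefficients are nonzero, drawn from
#' Unif\[coef_low, coef_high\]. `n_true_main` genes receive a nonzero main
#' effect; `n_true_int` (gene, env) interaction slots are placed on the
#' main-effect genes first (weak-hierarchy-friendly), spilling onto
#' additional random genes only if more than `n_true_main * q` are requested.
#' Main and interaction magnitudes are drawn from
#' Unif\[gcoef_low, gcoef_high\].
#'
#' @param config a [sim_config()].
#' @return list with `alpha`, `gamma`, `beta` (length p, zeros off-support),
#'   `eta` (p x q), and logical masks `beta_mask`, `eta_mask`.
#' @export
assign_effects <- function(config) {
  cf <- config
  runif_ec <- function(k) runif(k, cf$coef_low, cf$coef_high)
  runif_g <- function(k) runif(k, cf$gcoef_low, cf$gcoef_high)
  alpha <- runif_ec(cf$q)
  gamma <- runif_ec(cf$m)
  main_genes <- sort(sample.int(cf$p, cf$n_true_main))
  beta <- numeric(cf$p)
  beta[main_genes] <- runif_g(cf$n_true_main)
  eta <- matrix(0, cf$p, cf$q)
  slots_main <- as.matrix(expand.grid(gene = main_genes, env = seq_len(cf$q)))
  if (cf$n_true_int <= nrow(slots_main)) {
    pick <- slots_main[sample.int(nrow(slots_main), cf$n_true_int), ,
                       drop = FALSE]
  } else {
    extra_pool <- as.matrix(expand.grid(
      gene = setdiff(seq_len(cf$p), main_genes), env = seq_len(cf$q)))
    extra <- extra_pool[sample.int(nrow(extra_pool),
                                   cf$n_true_int - nrow(slots_main)), ,
                        drop = FALSE]
    pick <- rbind(slots_main, extra)
  }
  eta[pick] <- runif_g(nrow(pick))
  list(alpha = alpha, gamma = gamma, beta = beta, eta = eta,
       beta_mask = beta != 0, eta_mask = eta != 0)
}

#' Draw random errors from one of the five benchmark error models
#'
#' `"normal"` = N(0,1); `"t2"` = Student t with 2 df; `"lognormal"` =
#' LogNormal(0, 2) in the `rlnorm` convention -- log-scale mean 0, log-scale
#' standard deviation 2, not centered (median 1, extremely heavy right
#' tail);
#' `"cauchy10"` / `"cauchy20"` = 90%/80% N(0,1) contaminated with 10%/20%
#' Cauchy(0,1), component membership drawn per observation.
#'
#' @param n number of draws.
#' @param error_model model label.
#' @return numeric vector of length n.
#' @export
gen_errors <- function(n, error_model = c("normal", "t2", "lognormal",
                                          "cauchy10", "cauchy20")) {
  error_model <- match.arg(error_model)
  switch(error_model,
    normal = rnorm(n),
    t2 = rt(n, df = 2),
    lognormal = rlnorm(n, meanlog = 0, sdlog = 2),
    cauchy10 = ifelse(runif(n) < 0.1, rcauchy(n), rnorm(n)),
    cauchy20 = ifelse(runif(n) < 0.2, rcauchy(n), rnorm(n)))
}

#' Assemble a complete simulated G-by-E dataset
#'
#' Generates E, C, the genetic matrix for the configured setting, the true
#' effect pattern and the errors, and assembles
#' `y = E alpha + C gamma + X beta + sum_k (X_j E_k) eta_jk + e`.
#' Everything needed to reconstruct y (components, masks, errors) is stored.
#'
#' @param config a [sim_config()].
#' @return object of class `gxe_sim`: the data (`y`, `E`, `C`, `X`), the
#'   truth (`alpha`, `gamma`, `beta`, `eta`, `beta_mask`, `eta_mask`), the
#'   stored `errors` and the `config`.
#' @examples
#' sim <- sim_gxe(sim_config(n = 50, p = 10, seed = 1))
#' sum(sim$beta_mask) # 8
#' @export
sim_gxe <- function(config = sim_config()) {
  cf <- config
  if (!is.null(cf$seed)) set.seed(cf$seed)
  ec <- gen_env_clinical(cf$n, cf$q, cf$m, cf$rho)
  X <- switch(cf$setting,
              gen_gene_continuous(cf$n, cf$p, cf$rho),
              dichotomize_to_snp(gen_gene_continuous(cf$n, cf$p, cf$rho)),
              gen_snp_ld(cf$n, cf$p, cf$maf, cf$ld_r))
  storage.mode(X) <- "double"
  eff <- assign_effects(cf)
  errors <- gen_errors(cf$n, cf$error_model)
  if (isTRUE(cf$center_errors) && cf$error_model == "lognormal")
    errors <- errors - 1 # median of LogNormal(0, 2)
  y <- as.vector(ec$E %*% eff$alpha) + X %*% eff$beta + errors
  if (cf$m > 0) y <- y + as.vector(ec$C %*% eff$gamma)
  for (k in seq_len(cf$q)) {
    active <- which(eff$eta_mask[, k])
    for (j in active) y <- y + X[, j] * ec$E[, k] * eff$eta[j, k]
  }
  structure(c(list(y = as.vector(y), E = ec$E, C = ec$C, X = X,
                   errors = errors, config = cf), eff),
            class = "gxe_sim")
}

#' @export
print.gxe_sim <- function(x, ...) {
  cf <- x$config
  cat("simulated G-by-E dataset: n =", cf$n, ", p =", cf$p,
      ", setting", cf$setting, ", error", cf$error_model, "\n",
      sum(x$beta_mask), "true main effects,", sum(x$eta_mask),
      "true interactions\n")
  invisible(x)
}

#' Write a simulated dataset as a CSV bundle
#'
#' Writes `y.csv`, `E.csv`, `C.csv`, `X.csv` and `truth.json` (a plain-text
#' JSON-like file with the true coefficients and masks) into `dir`.
#'
#' @param sim a `gxe_sim`.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_sim_bundle <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(data.frame(y = sim$y), file.path(dir, "y.csv"), row.names = FALSE)
  write.csv(as.data.frame(sim$E), file.path(dir, "E.csv"), row.names = FALSE)
  write.csv(as.data.frame(sim$C), file.path(dir, "C.csv"), row.names = FALSE)
  write.csv(as.data.frame(sim$X), file.path(dir, "X.csv"), row.names = FALSE)
  truth <- list(alpha = sim$alpha, gamma = sim$gamma,
                beta = sim$beta, eta = as.vector(sim$eta),
                beta_mask = as.integer(sim$beta_mask),
                eta_mask = as.integer(sim$eta_mask))
  json <- paste0("{", paste(sprintf(
    '"%s": [%s]', names(truth),
    vapply(truth, function(v) paste(format(v, digits = 15), collapse = ", "),
           "")), collapse = ", "), "}")
  writeLines(json, file.path(dir, "truth.json"))
  invisible(dir)
}
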