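#' Marginal OLS prescreen
#'
#' For each gene, fits the marginal linear model (response on E, C, the gene
#' and its q interactions) by ordinary least squares and counts the main and
#' interaction coefficients with two-sided p-value below `p_threshold`.
#' Genes with at least `min_hits` such effects are kept. This is the filter
#' used to reduce a genome-wide SNP panel before the Bayesian analysis.
#'
#' @param y response vector.
#' @param E n x q environmental matrix.
#' @param C n x m clinical matrix (or `NULL`).
#' @param X n x p genetic matrix.
#' @param p_threshold two-sided p-value cutoff (default 0.05).
#' @param min_hits minimum number of sub-threshold main/interaction effects
#'   (default 2; 0 keeps every gene).
#' @return integer vector of retained gene indices.
#' @export
marginal_prescreen <- function(y, E, C, X, p_threshold = 0.05, min_hits = 2) {
  X <- as.matrix(X)
  E <- as.matrix(E)
  if (is.null(C)) C <- matrix(numeric(0), nrow = length(y), ncol = 0)
  q <- ncol(E)
  base <- cbind(E, C)
  keep <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    W <- X[, j] * E
    dmat <- cbind(base, x = X[, j], W)
    fit <- tryCatch(lm(y ~ dmat - 1), error = function(e) NULL)
    if (is.null(fit)) {
      warning("gene ", j, " skipped: model could not be fitted")
      next
    }
    ct <- summary(fit)$coefficients
    # rows for the gene's own main effect and interactions
    rows <- (ncol(base) + 1):(ncol(base) + 1 + q)
    if (any(is.na(coef(fit)[rows]))) {
      warning("gene ", j, " skipped: rank-deficient marginal design")
      next
    }
    pv <- ct[rows, 4]
    keep[j] <- sum(pv < p_threshold) >= min_hits
  }
  which(keep)
}

#' Study configuration for the simulation benchmark
#'
#' @param sim a [sim_config()] describing one dataset (its `error_model` is
#'   overridden by `errors`).
#' @param methods method names to run.
#' @param errors error models to cross with the methods.
#' @param replicates replicate datasets per error model (the benchmark
#'   convention is 30; reduced counts are fine for smoke runs).
#' @param iterations,burn_in MCMC length per gene.
#' @param k top-k list length (default 100).
#' @param base_seed integer; replicate seeds are derived deterministically.
#' @param cores workers for the per-gene loop.
#' @return list of class `study_config`.
#' @export
study_config <- function(sim = sim_config(), methods = c("LADBLSS", "LADBL",
                                                         "BLSS", "BL"),
                         errors = "normal", replicates = 30,
                         iterations = 10000, burn_in = 5000, k = 100,
                         base_seed = 1, cores = 1L) {
  structure(list(sim = sim, methods = methods, errors = errors,
                 replicates = replicates, iterations = iterations,
                 burn_in = burn_in, k = k, base_seed = base_seed,
                 cores = cores),
            class = "study_config")
}

#' Run the full simulation study grid
#'
#' For every error model and replicate, generates a dataset, fits each
#' method marginally over all genes, and scores AUC and top-k counts against
#' the simulated truth. Replicate seeds are derived deterministically from
#' `base_seed` so the whole study is reproducible.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; per-replicate and summary CSVs are
#'   written there when given.
#' @return list with `per_replicate` (one row per method x error x
#'   replicate) and `summary` (mean and sd per method x error cell of AUC
#'   and top-k counts).
#' @export
run_study <- function(config, out_dir = NULL) {
  cf <- config
  rows <- list()
  for (err in cf$errors) {
    for (rep in seq_len(cf$replicates)) {
      data_seed <- gene_seed(cf$base_seed, 100000 * match(err, cf$errors) + rep)
      sim_cf <- cf$sim
      sim_cf$error_model <- err
      sim_cf$seed <- data_seed
      sim <- sim_gxe(sim_cf)
      for (met in cf$methods) {
        scan <- tryCatch(
          fit_genome(sim$y, sim$E, sim$C, sim$X, method = met,
                     iterations = cf$iterations, burn_in = cf$burn_in,
                     seed = data_seed + match(met, cf$methods),
                     cores = cf$cores),
          error = function(e) {
            warning("scan failed (", met, ", ", err, ", rep ", rep, "): ",
                    conditionMessage(e))
            NULL
          })
        if (is.null(scan)) next
        ev <- evaluate_scan(scan, sim$beta_mask, sim$eta_mask, k = cf$k)
        rows[[length(rows) + 1]] <- data.frame(
          method = met, error = err, replicate = rep, auc = ev$auc,
          topk_main = ev$topk_main, topk_int = ev$topk_int,
          topk_total = ev$topk_total, seed = data_seed)
      }
    }
  }
  per_rep <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(v), sd = if (length(v) > 1) sd(v) else NA)
  cells <- unique(per_rep[, c("method", "error")])
  summ <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- per_rep[per_rep$method == cells$method[i] &
                     per_rep$error == cells$error[i], ]
    data.frame(method = cells$method[i], error = cells$error[i],
               n_rep = nrow(sub),
               auc_mean = mean(sub$auc), auc_sd = sd(sub$auc),
               topk_main_mean = mean(sub$topk_main),
               topk_main_sd = sd(sub$topk_main),
               topk_int_mean = mean(sub$topk_int),
               topk_int_sd = sd(sub$topk_int),
               topk_total_mean = mean(sub$topk_total),
               topk_total_sd = sd(sub$topk_total))
  }))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(per_rep, file.path(out_dir, "per_replicate.csv"),
              row.names = FALSE)
    write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
  }
  list(per_replicate = per_rep, summary = summ)
}
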