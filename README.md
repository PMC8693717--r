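# rmbvs — robust marginal Bayesian variable selection for G×E interactions

`rmbvs` identifies gene–environment (G×E) interactions associated with a
continuous phenotype by fitting one small Bayesian regression per genetic
variant ("marginal" analysis), the strategy used in genome-scale association
studies where a joint model over all variants is impractical. For variant
*j*,

    Y_i = E_i α + C_i γ + X_ij β_j + W̃_i η_j + ε_i,

where `E` (n×q) holds environmental exposures, `C` (n×m) clinical
covariates, `X_j` the variant (expression value or 0/1/2 SNP dosage) and
`W̃` its q interaction columns `X_j·E_k`.

The flagship sampler, **LADBLSS**, combines

* a **least-absolute-deviation (LAD) likelihood** — Laplace errors written
  as a normal scale mixture with exponential latents (Kozumi–Kobayashi,
  θ = 1/2, ξ₂² = 8) — for robustness to heavy-tailed or contaminated
  phenotypes, and
* **spike-and-slab priors** on β_j and each η_jk — a point mass at zero
  mixed with a Bayesian-LASSO (Laplace scale-mixture) slab — so every
  effect carries a posterior inclusion probability (PIP)
  `p_j = (1/H) Σ_h φ_j^(h)`.

All full conditionals are conjugate and the Gibbs sampler is written in
C++ (RcppArmadillo). Three comparators share the machinery: `LADBL`
(robust, no spike), `BLSS` (least-squares, spike-and-slab) and `BL`
(plain Bayesian LASSO). Selection is evaluated by sweeping
inclusion-probability cutoffs (or credible levels for the non-spike
methods) into TPR/FPR curves, trapezoidal AUC, and Top-k true-signal
counts; convergence by Gelman–Rubin/Brooks–Gelman PSRF with the
PSRF ≤ 1.1 rule. A synthetic-data module generates the benchmark designs
(AR1 expression, quartile-dichotomized SNPs, SNPs under pairwise LD) with
known truth.

## Worked example

```r
library(rmbvs)

# a Setting-1 dataset: n = 200, 100 genes, 20% Cauchy-contaminated errors
sim <- sim_gxe(sim_config(n = 200, p = 100, error_model = "cauchy20",
                          seed = 7))

# gene 6 truly carries a main effect (0.49) and interactions with E2 (0.69)
# and E4 (0.61)
d <- marginal_design(sim$y, sim$E, sim$C, sim$X[, 6])
fit <- fit_marginal(d, "LADBLSS", seed = 3)   # 10,000 iterations, 5,000 burn-in
summary(fit)
#>   effect    median       q2.5     q97.5    pip
#> 1      G 0.6101108  0.0000000 1.0771458 0.9420
#> 2  GxE_1 0.0000000 -0.4303449 0.2106378 0.3012
#> 3  GxE_2 0.8801210  0.4622335 1.3102762 0.9978
#> 4  GxE_3 0.0000000 -0.4509808 0.3435366 0.3158
#> 5  GxE_4 0.0000000 -0.0394122 0.7145200 0.4770
```

Despite the contamination, the true main effect and the stronger interaction
are recovered with inclusion probabilities 0.94 and 0.998 and posterior
medians near their generating values; the two null interactions sit at the
noise floor with medians exactly zero (the spike produces exact zeros,
unlike a plain Bayesian LASSO), and the weaker true interaction with E4 is
only partially detected (PIP 0.48) — marginal power at n = 200 is finite.

Scanning all genes and scoring against the simulated truth:

```r
scan <- fit_genome(sim$y, sim$E, sim$C, sim$X, method = "LADBLSS", seed = 42)
ev <- evaluate_scan(scan, sim$beta_mask, sim$eta_mask, k = 100)
ev$auc         # 0.9181 — ranking quality over all 500 candidate effects
ev$topk_main   # 8  — all 8 true main effects inside the top 100
ev$topk_int    # 11 — 11 of the 12 true interactions inside the top 100
```

The robustness payoff shows under heavy-tailed noise: on a LogNormal(0, 2)
dataset (`error_model = "lognormal"`, seed 11) the same scan gives LADBLSS
AUC ≈ 0.85 while the least-squares `BLSS` drops to ≈ 0.66 — the motivation
for the LAD likelihood. `psrf_report(d)` runs three overdispersed chains and
confirms PSRF ≤ 1.1 for every coefficient; `marginal_prescreen()` provides
the OLS p-value filter used before genome-scale runs, and `run_study()`
drives the full methods × error-models × replicates benchmark grid.

## Acceptance script

`scripts/acceptance.R` regenerates the benchmark quantities from scratch:
it simulates Setting-1 datasets (n = 200, reduced scale p = 300, 2
replicates per error model), fits the relevant methods marginally over all
genes with the default 10,000-iteration protocol, and recomputes mean AUC
(normal, lognormal and 80/20 Cauchy-mixture errors; LADBLSS/LADBL/BLSS as
applicable) and mean Top-100 true-signal counts (90/10 and 80/20 mixtures),
writing one JSON object to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Runtime is roughly 12–15 minutes on one CPU.
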