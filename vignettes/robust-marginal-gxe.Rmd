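---
title: "Robust marginal Bayesian variable selection for G×E interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust marginal Bayesian variable selection for G×E interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In gene–environment (G×E) interaction studies, a continuous phenotype $Y$ is
modeled against $p$ genetic variants (gene expressions or 0/1/2 SNP dosages),
$q$ environmental exposures $E$, $m$ clinical covariates $C$, and the $p
\times q$ candidate interactions. Marginal analysis fits one small model per
variant $j$:

$$Y_i = E_i\alpha + C_i\gamma + X_{ij}\beta_j + \tilde W_i \eta_j +
\epsilon_i, \qquad \tilde W_i = (X_{ij}E_{i1}, \dots, X_{ij}E_{iq}),$$

so the per-gene unknowns are the shared covariate coefficients, one main
genetic effect $\beta_j$, and $q$ interaction coefficients $\eta_{jk}$.
Phenotypes in such studies are frequently heavy-tailed or contaminated, which
is why the flagship sampler here replaces the Gaussian likelihood with a
least-absolute-deviation (LAD, i.e. median-regression) likelihood.

## The model behind `LADBLSS`

**Robust likelihood.** The errors are Laplace with inverse scale $\tau$.
Using the Kozumi–Kobayashi scale-mixture representation at quantile level
$\theta = 1/2$,

$$Y_i = \mu_i + \tau^{-1/2}\,\xi_2 \sqrt{v_i}\, z_i, \qquad
v_i \mid \tau \sim \mathrm{Exp}(\text{rate } \tau), \quad z_i \sim N(0,1),$$

with $\xi_1 = 0$ and $\xi_2^2 = 2/(\theta(1-\theta)) = 8$. Conditional on the
latent $v_i$, every observation is Gaussian with precision weight $w_i =
\tau/(\xi_2^2 v_i)$, so all coefficient updates are conjugate. (The package
fixes $\theta = 1/2$; other quantile levels are out of scope.)

**Sparsity.** The Bayesian LASSO writes the Laplace prior on $\beta_j$ as a
normal with an exponential-mixed variance, $\beta_j \mid s_1 \sim N(0, s_1)$,
$s_1 \sim \mathrm{Exp}(\phi_1^2/2)$, but never produces exact zeros. The
spike-and-slab mixture restores them:

$$\beta_j \mid s_1, \pi_1 \sim (1-\pi_1)\,N(0, s_1) + \pi_1\,\delta_0, \qquad
\eta_{jk} \mid s_{2k}, \pi_2 \sim (1-\pi_2)\,N(0, s_{2k}) + \pi_2\,\delta_0,$$

with conjugate $\mathrm{Beta}(1,1)$ priors on $\pi_1, \pi_2$ and
$\mathrm{Gamma}(1,1)$ priors on $\tau$, $\phi_1^2$, $\phi_2^2$. The
environmental/clinical coefficients carry plain normal priors (their
selection is not of interest). Every full conditional is available in closed
form; a sweep updates, in order, each $\alpha_k$, each $\gamma_t$, $\beta_j$,
each $\eta_{jk}$, the slab variances, $\phi_1^2$, $\phi_2^2$, $\pi_1$,
$\pi_2$, $\tau$, and the latents $v_i$. The spike probability of each
coefficient draw is evaluated in log space, so strong signals cannot overflow
the $\exp(\mu^2/2\sigma^2)$ Bayes-factor term.

The four method variants share this machinery:

| method | likelihood | coefficient prior |
|---|---|---|
| `LADBLSS` | LAD (Laplace) | spike-and-slab × Laplace slab |
| `LADBL` | LAD (Laplace) | plain Laplace (scale mixture) |
| `BLSS` | Gaussian, $\sigma^2 \sim$ Inv-Gamma(1,1) | spike-and-slab |
| `BL` | Gaussian | plain Laplace |

The non-sparse variants are implemented as the sparse code path with the
spike weights pinned at zero, which makes `LADBL` literally `LADBLSS` with
$\pi_1 = \pi_2 = 0$ (a property the tests verify draw for draw). The plain
Bayesian LASSO hierarchy for `BL`/`BLSS` is the canonical Park–Casella
construction; its hyperpriors (`sigma_a = sigma_b = 1`) are this package's
documented defaults, not a claim about any external implementation.

## Selection and evaluation

For spike-and-slab fits, each effect's **posterior inclusion probability**
(PIP) is the mean of its 0/1 indicator over the $H$ stored sweeps. Sweeping a
cutoff grid (0, 0.01, …, 1; selection requires score strictly above the
cutoff, so nothing is selected at 1) against known simulation truth yields
TPR/FPR per cutoff and a trapezoidal AUC anchored at (0,0) and (1,1) — with a
grid that resolves the score values, this equals the Mann–Whitney
concordance with ties counted 1/2, which the tests assert exactly. For
methods without spike-and-slab priors, the credible level plays the role of
the cutoff: an effect is selected at level $c$ when its equal-tailed $c$
credible interval excludes zero. The level grid is 0.01–0.99 in steps of
0.01; the per-effect average of these indicators ("average identification
value") is the ranking score for Top-$k$ counts. Ties in Top-$k$ rank are
broken by larger absolute posterior median, then by index — stable and
documented.

## MCMC protocol and diagnostics

Defaults follow the benchmark protocol: 10,000 iterations, the first 5,000
discarded, no thinning, all hyperparameters 1, all regression coefficients
initialized at 1. Unstated latents start at neutral values ($v_i = s = \tau
= \phi^2 = 1$, $\pi = 0.5$). Convergence is assessed with the Gelman–Rubin
potential scale reduction factor with the Brooks–Gelman $(d+3)/(d+1)$
correction, computed from 3 chains started at overdispersed coefficient
values (1, 0, −1), with the rule PSRF ≤ 1.1. PSRF is reported for the
regression coefficients and the scale parameter; the $n$ latent $v_i$ are
not inference targets and are excluded. Identical chains return the defined
limit 1.

## The synthetic world

`sim_config()` encodes the benchmark design: $n = 200$, $p = 500$, $q = 4$
environmental and $m = 3$ clinical covariates from multivariate normals with
unit variance and AR1($\rho = 0.5$) correlation; 8 true main effects and 12
true interactions; five error models — $N(0,1)$, $t_2$, LogNormal(0, 2),
and 90/10 and 80/20 normal–Cauchy mixtures. Genetic matrices come in three
flavors: continuous AR1 expression (Setting 1), expression dichotomized at
the quartiles into 0/1/2 genotypes (Setting 2), and SNPs under pairwise LD
(Setting 3; MAF 0.3, pairwise correlation 0.6, haplotype frequencies
$p_{AB} = q_1 q_2 + \delta$ etc. with $\delta = r\sqrt{q_1(1-q_1)q_2(1-q_2)}$,
simulated as two independent haplotype Markov chains per subject under
Hardy–Weinberg equilibrium and random mating).

Choices the benchmark leaves open, fixed here once and exposed in the config:

* **G/G×E effect sizes.** Only the environmental/clinical range
  (Unif[0.1, 0.5]) is stated. A power calculation shows signals near 0.1 are
  marginally undetectable at $n = 200$ (the marginal standard error is
  $\approx 1/\sqrt{n} = 0.07$), and an ordinary-least-squares ranking oracle
  caps the achievable AUC far below the published cells if the genetic
  magnitudes are drawn that small. The default is therefore Unif[0.2, 0.8]
  for the true $\beta$ and $\eta$ magnitudes — the conventional choice in
  this literature's simulation designs (`gcoef_low`/`gcoef_high`).
* **Interaction placement.** The 12 true interactions are placed on the 8
  main-effect genes first (weak-hierarchy-friendly), spilling over only when
  more than $8q$ are requested.
* **LogNormal(0, 2)** is read in the `rlnorm` convention — log-scale mean 0,
  log-scale *standard deviation* 2 — and not centered. Its median is 1, so
  with no intercept in the model the robust methods absorb the location
  shift through the scale parameter, while its enormous right tail
  (sd ≈ 54) is what collapses the least-squares variants to near-chance
  ranking. Read as log-variance 2 instead, the tail is far lighter and the
  least-squares methods visibly retain ranking power — inconsistent with
  this error model's published role as the robust methods' showcase.
  `center_errors` optionally subtracts the median.
* **Genotype direction.** Low expression maps to genotype 0; SNP codes enter
  the regression as numeric 0/1/2 dosages.

What a green simulation test does *not* establish: the generator draws
independent subjects with exactly the stated correlation structure; real
cohort data (population structure, missingness, genotyping error,
non-normal exposures) are outside what these tests certify.

## Numerical choices

* Inverse-Gaussian draws use the Michael–Schucany–Haas transform;
  parametrization is (mean $\mu$, shape $\lambda$) with density
  $\propto x^{-3/2}\exp\{-\lambda(x-\mu)^2/(2\mu^2 x)\}$.
* The conditional of $v_i$ is improper at a zero residual; residual squares
  are floored at $10^{-12}$, and $|{\rm coef}|$ at $10^{-10}$ in the slab
  variance update. Both events have probability zero in exact arithmetic.
* The running residual is maintained incrementally across sweeps and fully
  recomputed every 1,000 iterations to cap floating-point drift.
* The update order within a sweep is fixed (any systematic scan is valid;
  fixing one gives bit-for-bit reproducibility under a seed). Per-gene RNG
  streams are keyed by (base seed, gene index), so genome scans are
  reproducible gene by gene and independent of execution order or
  parallelism.

## Correctness strategy

Three independent layers back the sampler: (i) every full conditional is
checked against a brute-force quadrature or closed-form density oracle on
tiny inputs; (ii) a "getting it right" (successive-conditional) simulation
on a tiny model verifies that one full Gibbs sweep leaves the joint prior
invariant — a test that fails for essentially any conditional-distribution
bug; (iii) reduced-scale simulation gates check the scientific claims
(robust ≫ non-robust under heavy tails, spike-and-slab ≫ plain shrinkage,
published AUC/Top-100 cells at reduced scale).

## Known limitations

* Reduced-scale gates ($p = 150$–300, 2–3 replicates) trade Monte-Carlo
  precision for runtime; published cells used $p = 500$ and more replicates.
* Because the true G/G×E effect-size distribution is unstated in the
  benchmark, AUC levels are reproduced to within a few points rather than to
  printed precision; orderings between methods are stable.
* Only $\theta = 0.5$ (LAD), continuous univariate phenotypes, and linear
  interactions are supported; strong-hierarchy refitting is left to the
  user.
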