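---
title: "Lambda-scaled Bayesian PGLS over tree samples: models, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lambda-scaled Bayesian PGLS over tree samples: models, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`bayespgls` fits phylogenetic generalized least squares (PGLS) regressions by
MCMC, repeats each fit over a sample of dated trees, and tests individual taxa
against the fitted model by phylogenetic imputation. This vignette is the
package's own account of the statistics: the model and its assumptions, the
decision rules, the synthetic-data generator, and the design choices made where
several reasonable options existed.

## The model

For a response vector $y$ (a log-scale trait over $n$ taxa), a design matrix
$X$ (intercept, predictors, optional product interactions), and a phylogeny
with covariance matrix $V$ ($V_{ij}$ = branch length shared from the root by
taxa $i$ and $j$),

$$y \sim \mathcal{N}\!\big(X\beta,\; \sigma^2\, V(\lambda)\big),
\qquad V(\lambda) = \lambda V + (1-\lambda)\,\mathrm{diag}(V),$$

where Pagel's $\lambda \in [0,1]$ scales the off-diagonal (shared-history)
entries: $\lambda = 1$ is pure Brownian covariance, $\lambda = 0$ statistical
independence. The assumptions are the usual ones: traits on a scale where
evolution is additive (log scale for lengths, masses, volumes), residual
covariance proportional to shared time, a single rate over the tree, and no
measurement-error term beyond $\sigma^2$.

Non-ultrametric trees (fossil tips at internal dates) need no special
handling: their shorter root-to-tip paths simply shrink the corresponding
diagonal entries of $V$. Polytomies are likewise harmless because the
shared-path definition of $V$ never requires bifurcation.

Priors follow the study design: independent $\mathcal{N}(0, 5^2)$ on every
regression coefficient (wide on the log scale, where slopes of interest are
order 0.1-1), uniform on $[0,1]$ for $\lambda$, and — where the source design
is silent — a half-Cauchy with scale 5 on $\sigma$, a standard weakly
informative choice whose influence at $n \approx 95$ is negligible.

### Log base

Continuous traits are $\log_{10}$-transformed throughout. Log-log regression
slopes are base-invariant, so the headline coefficients do not depend on this
choice; intercepts do, and are reported on the $\log_{10}$ scale. Brain-region
and endocranial volumes are converted to masses at 1 g : 1 cm³ before logging
(an identity on the numbers), for consistency with the bulk of comparative
brain-mass compilations.

## The sampler

`sample_posterior()` runs a compiled (RcppArmadillo) chain with three updates
per iteration:

* **$\beta$** — an exact Gibbs draw from its conditional normal
  $\mathcal{N}\big(A^{-1}b,\ A^{-1}\big)$ with
  $A = X^\top V(\lambda)^{-1} X/\sigma^2 + I/25$ and
  $b = X^\top V(\lambda)^{-1} y/\sigma^2$;
* **$\sigma^2$** — random-walk Metropolis on $\log\sigma^2$ (the half-Cauchy
  prior and Jacobian enter the acceptance ratio);
* **$\lambda$** — random-walk Metropolis reflected at the bounds of $[0,1]$,
  which keeps the kernel symmetric without rejection at the boundary.

All solves go through Cholesky factorizations of $V(\lambda)$; no explicit
inverse is ever formed, and the factorization is cached across updates that do
not change $\lambda$. Proposal scales adapt toward a ~30% acceptance rate
during burn-in only, so the post-burn-in kernel is a fixed, valid MCMC kernel.
All randomness comes from R's RNG: a seed fixes the entire draw sequence
bit-for-bit.

Defaults mirror the study schedule — 1,000,000 post-burn-in iterations thinned
every 10,000 (100 retained draws), 100,000 burn-in, and at least 3 replicate
chains compared by split-chain potential scale reduction ($\hat R$; values
above 1.05 raise a warning). "After convergence" is thus made operational:
burn-in plus a replicated-chain diagnostic gate. Simulation studies in the
tests use shorter schedules (typically 1,000-4,000 iterations, 100-400 retained
draws, one chain) after verifying against the closed-form conjugate posterior
that the sampler targets the right distribution; chain length changes Monte
Carlo error, not the target.

Degenerate options `lambda_fixed` and `sigma2_fixed` freeze those parameters,
which is how the sampler is validated: with both fixed, the posterior for
$\beta$ is Gaussian in closed form, and the sampled mean and covariance must
match it to Monte Carlo error.

## Significance across a tree sample

Each model is fitted once per tree of the sample (the package was built around
samples of 100 dated trees), with per-tree chain seeds derived
deterministically from the master seed so that parallel or sequential execution
gives identical results. Two rules summarise a coefficient:

1. **Per tree:** $p_x$, the proportion of the posterior crossing zero, taken
   as the *smaller* tail mass $\min\{\Pr(\beta \le 0), \Pr(\beta \ge 0)\}$ so
   that the statistic is sign-agnostic ($0 \le p_x \le 0.5$). A tree counts as
   significant when $p_x \le 0.05$.
2. **Across trees:** the coefficient is significant overall only when rule 1
   holds in at least 95% of the trees.

Point estimates are summarised as the posterior median per tree and reported
as the *range of per-tree medians* across the sample. No additional
multiple-testing correction is applied beyond this two-part rule.

An important caveat, quantified during development: the cross-tree median
range measures sensitivity to the tree sample, *not* estimation uncertainty.
Its width (about 0.01-0.04 for slopes at realistic dating jitter) is of the
same order as — often smaller than — the posterior standard deviation on any
one dataset, so the range should never be read as a confidence interval, and
the true value of a parameter will frequently sit outside it even when the
model is exactly right. The per-tree posterior intervals, not the cross-tree
range, carry the uncertainty.

## Phylogenetic imputation and the outlier rule

`predictive_draws()` predicts a held-out taxon from both the regression and
its position on the tree. For each retained draw $(\beta, \sigma^2, \lambda)$,
with the joint $V(\lambda)$ over observed taxa and target partitioned into
$(V_{oo}, v_{ot}, v_{tt})$:

$$\hat y_t \sim \mathcal{N}\!\Big(x_t^\top\beta +
   v_{ot}^\top V_{oo}^{-1}(y_o - X_o\beta),\;
   \sigma^2\big[v_{tt} - v_{ot}^\top V_{oo}^{-1} v_{ot}\big]\Big).$$

The $\lambda$ transform is applied to the whole joint matrix before
conditioning, so at $\lambda = 0$ there is no borrowing (the prediction is the
regression line with variance $\sigma^2 v_{tt}$) and at $\lambda = 1$, with
$\sigma^2$ known, the predictive mean is the classical phylogenetic BLUP.
The model must have been fitted *excluding* the target (and any co-excluded
set, e.g. all hominins); the function raises an error otherwise. Negative
conditional variances (numerically possible at machine precision) are clamped
at zero with a warning.

`tail_mass()` locates the observed value in its own predictive distribution:
by default the smaller of the two tail masses (two-sided protection in one
number), estimated from the $N$ draws with the add-one correction
$(r+1)/(N+1)$ so a finite draw set never reports an exact zero. The sidedness
is configurable (`side = "upper"` or `"lower"`) because the "overlaps the true
value by less than 5%" phrasing admits a one-sided reading; the two-sided
minimum is the package default.

`outlier_test()` then applies the cross-tree consensus: a taxon is a
phylogenetic outlier when its tail mass falls below 0.05 in *strictly more
than* 95% of the trees — 96 of 100 trees flag, 95 do not.

Calibration, measured on data simulated from the fitted model itself: a
two-sided min-tail is uniform on $[0, 0.5]$ under perfect calibration, so the
*per-tree* event `tail < 0.05` fires for about 10% of null taxon-tree pairs by
construction (measured 9.7% at $n=95$). It is the *consensus* flag that is
conservative on null taxa (well under 7% in the test suite), and the consensus
rule is the decision the analysis reports. Tree-sample heterogeneity
(topology error relative to the generating tree) inflates the per-tree rate
slightly; the consensus rule absorbs this as well.

## The synthetic-data generator

`simulate_tree()` draws a pure-birth (Yule) tree rescaled to unit root-to-tip
depth, so all rates are per-total-depth. `jitter_tree_sample()` emulates a
sample of dated phylogenies by multiplying each branch by independent
lognormal noise (default sd 0.15) and applying random NNI moves (default 8) —
deliberately substantial, since independently inferred and dated topologies
differ far more than by a few percent in branch lengths. Tree 1 of the sample
is always the unmodified generating tree.

`simulate_traits()` implements exactly the generative model the PGLS assumes:

* predictors evolve as Brownian motion on the tree — finger length
  ($\log_{10}$ mm, mean 1.2, rate 0.09), brain mass ($\log_{10}$ g, mean 1.5,
  rate 0.10), brain-region volumes (rates 0.20); extra digit columns are the
  finger trait plus small independent BM perturbations, giving the strongly
  correlated alternative measurements real hands show;
* tool use is a liability threshold: an independent unit-rate BM liability
  dichotomised at the $(1 - 28/95)$ quantile of its marginal distribution, so
  the expected frequency matches the study's 28/95 while retaining
  phylogenetic clustering; stricter definitions (true tool use, manufacture)
  are nested higher thresholds;
* the response is $X\beta_{\mathrm{true}} + \varepsilon$,
  $\varepsilon \sim \mathcal{N}(0, \sigma^2_{\mathrm{true}} V(\lambda_{\mathrm{true}}))$,
  with defaults $\beta = (0, 0.9, 0.12)$, $\sigma^2 = 0.0015$,
  $\lambda = 0.85$ — the magnitudes of the real system.

Outlier taxa can be shifted two ways. A *direct* shift adds $\Delta$ to the
response after the regression: detectable under every model, removable by
none. A *driver-mediated* shift (used by the packaged fixture) elevates a
named predictor by $\Delta/\beta_{\mathrm{driver}}$ before the response is
computed: the response still rises by $\Delta$ relative to any model that
omits the driver, but the taxa conform again once the driver is included.
The packaged fixture (`make_study_fixture()`) uses `driver = "brain"` with
$\Delta = 0.15$ $\log_{10}$ units — a brain elevation of $0.15/0.12 = 1.25$
$\log_{10}$ units for the six-taxon "hominin-analogue" clade, which is the
magnitude of real hominin brain residuals — so the finger-only model flags the
clade and the whole-brain model explains it, reproducing the structure the
outlier analyses are designed to probe. The scales were chosen once so that
$\Delta = 0.15$ equals about four predictive standard deviations under the
finger-only model, the regime in which the consensus rule should detect
essentially every shifted taxon.

What the generator does *not* emulate: measurement error and specimen-level
sampling, fossil sampling processes, rate variation across clades or time
(single-rate BM only), correlated evolution between the tool liability and the
response, and model misspecification beyond tree error. Tests passing on this
generator therefore certify the inference machinery, not the biology of any
real dataset.

## Numerical and degenerate-input choices

* All covariance factorizations are Cholesky-based; a singular $V(\lambda)$
  (duplicated tips, zero-length cherries at $\lambda = 1$) raises an error
  suggesting jitter rather than silently regularising.
* `prune_to_taxa()` keeps the dropped stem as a root edge, and `phylo_vcv()`
  counts a root edge as history shared by all taxa, so pruning commutes
  exactly with taking a submatrix of the full-tree covariance.
* Design matrices are checked for rank deficiency (constant or collinear
  predictors raise an under-determined error rather than letting the ridge
  prior mask the problem) and for a minimum of $p + 2$ complete taxa.
* $p_x$ counts ties at zero in both tails and is capped at 0.5.
* Taxon labels are whitespace-trimmed and internal spaces replaced by
  underscores on every read path; mismatches between table and tree are
  reported, never silently dropped.
* Specimen aggregation averages on the raw scale (weighted by specimen counts,
  unit weight when missing; most recent source wins for duplicated specimens)
  and logs afterwards — the order matters because the log of a mean is not the
  mean of logs.

## Problem sizes in the test suite

The validation suite exercises: the likelihood against a dense multivariate
normal oracle on 500 random instances of up to 6 taxa; the conjugate
closed-form posterior at $n = 60$; predictive conditioning against brute-force
joint-normal moments at $10^5$ draws; parameter recovery and interval coverage
over 200 simulated datasets of 95 taxa; outlier calibration on 14 fixtures
(112 null taxa over 12-tree samples) and power on 20 replicate fixtures with
4-SD shifts; and the full pipeline on the packaged 95-taxon, 100-tree fixture.
These sizes were chosen to keep the whole suite in the tens of minutes on one
CPU while leaving Monte Carlo error well below each assertion's margin.

## Known limitations

* Single-rate Brownian errors with $\lambda$ only: no OU, rate shifts, or
  multivariate (joint multi-trait) imputation. Ancestral states are not
  reconstructed.
* No model comparison (no marginal likelihoods or Bayes factors); the
  two-part significance rule is the only inferential output.
* The cross-tree median range understates uncertainty by design (see above).
* The per-tree outlier event at the 5% threshold has a ~10% null rate under
  the two-sided min-tail definition; only the cross-tree consensus flag is
  calibrated conservatively. Users wanting a ~5% per-tree null rate should use
  the one-sided `side = "upper"` tail.
* With ~100 retained draws per tree (the study schedule), tail masses are
  coarse; the add-one correction stabilises the 5% rule but resolution below
  1/101 is unattainable. More draws sharpen the per-tree tails at linear cost.
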