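---
title: "Joint random-effects transition models by pairwise composite likelihood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint random-effects transition models by pairwise composite likelihood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jmtrans)
```

## The model

Chronic-disease cohorts often track several related measurements of one
underlying condition — in the motivating dementia setting, a five-level
global Clinical Dementia Rating (codes 0, 0.5, 1, 2, 3), a five-level
functional-disability grade, a dichotomized 0–30 cognitive screen, and a
binary clinician rating of whether cognition is normal for age — at a
handful of annual visits. The scientific questions are about *transitions*:
given today's state, where will the patient be next year, and how do age,
education and APOE-ε4 copy number shift those probabilities?

jmtrans models each process $g = 1, \dots, G$ with its own first-order (or
$q$th-order) Markov regression. Conditional on the history and on a
subject-level random-effect vector $b_{gi}$, the current state follows an
exponential-family distribution whose linear predictor is

$$\eta_{gij} = x_{gij}'\beta_g + f_g(H_{gij}; \gamma_g) + z_{gij}' b_{gi},$$

where $H_{gij}$ collects the previous $q$ states. The built-in lag feature
is linear in the numeric level codes ($f = \gamma_g\, y_{g,i,j-1}$ for
$q = 1$); for counts a Zeger–Qaqish floored-log feature
$\gamma[\log \max(y_{prev}, c) - x'\beta]$ is available, where the floor
$c \in (0,1)$ (default 0.5) keeps a zero count from becoming absorbing.
Ordinal processes use a cumulative-logit (proportional-odds) transition
model with increasing cutpoints,

$$\operatorname{logit} P(Y_{gij} \le k \mid H, b) = \alpha_{gk} + \eta_{gij},
\qquad \alpha_{g1} < \dots < \alpha_{g,K-1},$$

oriented so that *higher levels are worse states*: negative age, APOE or
lag coefficients push probability mass toward worse outcomes. A binary
process is exactly the two-level special case (the package's test suite
asserts the identity to machine precision). This orientation is what makes
the published coefficient tables reproduce the published transition
matrices, which is verified cell-by-cell in the acceptance suite.

The processes are coupled only through the random effects: the stacked
vector $b_i = (b_{1i}', \dots, b_{Gi}')'$ is multivariate normal with
unrestricted covariance $\Sigma$. Its correlations are the quantities of
clinical interest — how strongly heterogeneity in one measurement's
transition propensity tracks another's. A shared-parameter variant
($b_{gi} \equiv b_i$, all loadings fixed at 1) is available as a covariance
constraint; free per-process loadings would require an explicit scaling
rule and are deliberately out of scope.

## Estimation: pairwise composite conditional likelihood

The full conditional likelihood integrates the product of all $G$
processes' transition densities over the $d$-dimensional random-effect
distribution, conditioning on each process's first $q$ states (whose
marginal distribution the transition model never specifies). Beyond
$G = 2$ that integral becomes expensive, so estimation maximizes the
pairwise composite conditional likelihood

$$c\ell(\theta) = \sum_{i=1}^n \sum_{g < h} \log \int\!\!\int
\prod_{j > q} f_g(y_{gij} \mid H, b_g)\, f_h(y_{hij} \mid H, b_h)\,
\phi(b_g, b_h; \Sigma_{gh})\, db_g\, db_h,$$

with equal pair weights. Every parameter of every submodel and every block
of $\Sigma$ appears in at least one pair, so the composite estimator is
consistent under the usual composite-likelihood regularity conditions,
and for $G = 2$ the composite and full conditional likelihoods are the
same integral (asserted to 1e-10 in the tests). No initial-state model
exists anywhere in the package: the first $q$ visits are conditioned on in
estimation, prediction and simulation alike.

Inference uses the Godambe sandwich. With per-subject composite scores
$s_i$, the sensitivity matrix $H = -(1/n) \sum_i \nabla^2 c\ell_i$, the
variability matrix $J = (1/n) \sum_i s_i s_i'$ (centered), and
$\widehat{\operatorname{cov}}(\hat\theta) = H^{-1} J H^{-1}/n$. Per-parameter
Wald tests use the sandwich SEs; variances and correlations of $\Sigma$
are reported with delta-method SEs. For nested models the composite LRT
$2(c\ell_1 - c\ell_0)$ is referred to a Satterthwaite-matched scaled
chi-square whose weights are the eigenvalues of
$[(H^{-1})_{\eta\eta}]^{-1}(H^{-1} J H^{-1})_{\eta\eta}$ on the tested
block $\eta$; when $H = J$ this reduces to the ordinary LRT, which the
tests assert. A two-stage comparison estimator (univariate ML fits, then
Pearson correlations of paired empirical-Bayes intercepts with Fisher-z
intervals) is provided for benchmarking only and carries no sandwich
inference.

## Numerical choices

**Quadrature.** All integrals are Gauss–Hermite. The default rule
(`quad_rule(15, adaptive = TRUE)`) recenters the node grid at each
subject's posterior mode of the random effects and rescales by the
posterior curvature; for random-intercept logistic and ordinal integrands
this makes even small node counts accurate, and the test suite checks both
a dense-trapezoid oracle (1e-6 on an 800×800 grid) and stability of the
composite log-likelihood under node refinement 9 → 15 → 21 (< 1e-6).
Posterior modes are found by damped Newton iteration; every built-in
family has a log-concave conditional density in the linear predictor, so
the per-subject problems are strictly concave and the iteration is safe.
The two-dimensional pair integrals run through a fused compiled kernel;
higher-dimensional blocks (the full-likelihood oracle up to $d \le 4$) use
an R implementation of the same algorithm, and agreement between the two
routes is part of the test suite.

**Parameterization.** The optimizer works on an unconstrained packing:
ordinal cutpoints as first cutpoint plus softplus-positive increments,
Gaussian SDs as logs, and $\Sigma$ as log-SDs plus a row-normalized
Cholesky factor of the correlation matrix. Every packing maps to a
symmetric positive-definite $\Sigma$ and the map is a bijection (round-trip
asserted to 1e-12). Reported increments mirror the sequential-difference
convention of the published coefficient tables.

**Optimization.** `fit_jmtrans()` maximizes $c\ell$ with bounded
quasi-Newton (PORT) iterations on the packed vector, using
finite-difference gradients that only re-evaluate the pairs a parameter
touches (central differences by default; an optional forward-difference
mode halves the cost in long simulation loops). Warm starts come from
univariate ML fits of each process with cross-correlations at zero.
Convergence requires a relative log-likelihood change below 1e-8 (on the
per-subject scale) *and* a per-subject score max-norm below
1e-5 · (1 + |cℓ|/n); if the function tolerance triggers first, the fit is
polished with a tighter tolerance before the flag is set. Generous box
bounds (|log-SD| ≤ 8, correlation-factor entries ≤ 30 in absolute value)
never bind at an identified optimum but prevent excursions along the flat
ridges that a weakly identified correlation produces. Zero-variance truths
drive the log-SD toward its boundary; fits with any log-SD below −6 are
flagged and sandwich inference is withheld rather than computed on a
boundary.

**Finite differences throughout.** Scores, Hessians and delta-method
Jacobians are finite differences with per-parameter relative steps (1e-5
for first derivatives, 1e-3 for second differences). The families are few
but the lag forms are pluggable, and numerical derivatives keep the
estimator correct for any differentiable extension; the score is checked
against Richardson extrapolation in the tests.

## The synthetic-data generator

`simulate_panel()` draws $b_i \sim N(0, \Sigma)$, per-subject covariates,
initial states from a fixed categorical distribution per process
(consistent with the conditional likelihood, which never models them), and
then iterates the conditional transition distributions forward. The
packaged scenario `ad_fixture()` emulates the structure of the motivating
cohort: 746 subjects (`"full"`) or 200 (`"ci"`, the scale used in the
repeated-fit studies so they complete in minutes on one CPU) with five
annual visits; two 5-level ordinal processes, two binary ones, first-order
lags, random intercepts. True coefficients sit at the magnitudes estimated
in that cohort (ordinal lag coefficients −3.7 to −8.9, age slopes −0.035
to −0.075, cutpoint chains up to ≈ 22.8), variances (2.26, 0.96, 8.95,
1.02), and correlations 0.51/0.58/0.75 among the first three processes and
0 with the fourth. Covariates: age uniform on 55–85 years, education
integer-uniform 8–20 years, APOE-ε4 copies categorical (0.6, 0.3, 0.1)
coded as two dummies. Initial-state probabilities (0.30, 0.25, 0.20, 0.15,
0.10) for the ordinal processes and (0.5, 0.5) for the binary ones were
chosen once so that every region of the state space contributes
transitions; real dementia cohorts are more concentrated in mild states,
so absolute information per subject here is, if anything, optimistic.

What the generator does *not* emulate: dropout and intermittent missing
visits (the model class assumes none; the panel reader truncates
non-consecutive visit runs rather than imputing), covariate measurement
error, time-varying covariates, non-normal random effects, and any
dependence of a process's transition on *other* processes' histories
(allowed by the general model, exposed through ordinary covariates, but
not a built-in lag form). Passing the recovery and coverage studies
therefore says the estimator is calibrated *under the model*; it says
nothing about robustness to those violations.

## Calibration studies shipped in the test suite

* **Parameter recovery** — 50 replicates of the cohort-like scenario at
  n = 200: every regression parameter's median estimate within 3
  Monte-Carlo SEs of truth and median absolute bias below 20% of |truth|;
  the random-intercept correlation pattern (high/high/near-zero) recovered
  in sign and ordering. These fits use 3-node adaptive quadrature, truth
  initialization and capped iterations — the standard Monte-Carlo
  trade-off (a Laplace-grade rule is accurate for random-intercept models,
  and initialization does not move a unimodal optimum, which the
  multi-start agreement test verifies separately).
* **Sandwich calibration** — 200 replicates of a two-process n = 150
  scenario (3-node adaptive rule): 95% Wald intervals cover each
  regression truth at a rate inside [0.90, 0.99].
* **Bartlett identity** — one correctly specified single-process fit at
  n = 1000: $H$ and $J$ agree elementwise within 15%.
* **Determinism** — identical seeds and configs produce byte-identical
  panels, fit reports and transition tables end-to-end.

## Known limitations

Pairs are equally weighted; optimal pair weighting is not implemented.
Composite-likelihood model-selection criteria, score tests, and
boundary-corrected tests for zero variances are out of scope, as is
inference robust to a misspecified random-effects distribution. The
forecast operation treats the fitted first-order model as a homogeneous
chain with frozen covariates — self-consistent here because age enters as
age at initial visit, but not a model of covariate aging. Transition-table
uncertainty (delta-method bands on matrix entries) is not propagated. The
COGSTAT-like weakly informative binary process shows, at n = 200, how flat
the composite likelihood can be in cross-correlation directions: estimates
of those correlations are diffuse even when the point pattern is
recovered, and their score norm may not reach the convergence tolerance —
such fits are reported with `converged = FALSE` and should be read as
ridge-limited rather than wrong. Relatedly, the recovery study shows that
effects of rare covariates (the ~10% two-allele APOE group) on that weakly
informative process are attenuated toward zero at n = 200 — a
finite-sample limitation of the composite fit on short binary panels, not
of the ordinal submodels, whose coefficients recover within a few percent.
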