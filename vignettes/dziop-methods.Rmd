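---
title: "Modelling misreported zeros in ordered survey outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling misreported zeros in ordered survey outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dziop)
```

## The problem

Self-reported consumption of stigmatised or illegal goods ("social bads":
illicit drugs, heavy drinking, risky sexual behaviour) typically shows a
large spike of zeros. A zero can mean three different things:

1. the respondent genuinely does not participate in the activity;
2. the respondent participates but **misreports**, stating zero out of fear
   of legal or social repercussions;
3. the respondent participates and reports truthfully, but happens to have
   consumed nothing in the survey window (an infrequent, "corner-solution"
   consumer).

Standard ordered probit (OP) models conflate the three; zero-inflated
ordered probits (ZIOP) separate the first from the rest. This package
implements the *double*-inflated model (DZIOP) that separates all three,
plus its correlated-error extension (DZIOPC) and the nested comparators OP,
GOP, ZIOP and ZIOPC.

## The model

Three latent equations with standard-normal errors drive the observed
ordinal outcome $y \in \{0, \dots, J\}$:

$$r^* = x_r'\beta_r + \varepsilon_r, \qquad
  m^* = x_m'\beta_m + \varepsilon_m, \qquad
  \tilde y^* = x_y'\beta_y + \varepsilon_y .$$

Participation is $r = 1\{r^* > 0\}$; *truthful reporting* is
$m = 1\{m^* > 0\}$ (so $m = 0$ marks a misreporter); consumption
$\tilde y$ follows the usual threshold mapping with strictly increasing
cut points $\mu_1 < \dots < \mu_{J-1}$, the lowest boundary normalised to
$0$ and the extremes to $\pm\infty$. Only the product is observed:

$$y = r \cdot m \cdot \tilde y .$$

With independent errors the zero probability is the sum of the three
sources,

$$\Pr(y=0\mid x) = \underbrace{1-\Phi(x_r'\beta_r)}_{\text{nonparticipation}}
 + \underbrace{\Phi(x_r'\beta_r)\,[1-\Phi(x_m'\beta_m)]}_{\text{misreporting}}
 + \underbrace{\Phi(x_r'\beta_r)\,\Phi(x_m'\beta_m)\,\Phi(-x_y'\beta_y)}_{\text{true zero}},$$

and positive categories multiply the two hurdle probabilities into ordered
probit band probabilities. The correlated extension lets
$(\varepsilon_r, \varepsilon_m, \varepsilon_y) \sim N(0, \Omega_3)$ with
unit variances and free correlations $(\rho_{rm}, \rho_{ry}, \rho_{my})$,
turning the products into bivariate and trivariate normal rectangle
probabilities.

### One signed-region primitive

Every joint probability in the correlated model is a rectangle probability
of the transformed vector $(-\varepsilon_r, -\varepsilon_m, \varepsilon_y)$
or a sub-vector of it: negating a component negates exactly that
component's correlations ($\rho'_{k\ell} = s_k s_\ell\, \rho_{k\ell}$). The
package derives *all* category probabilities from this single primitive, so
there is one audited code path and no per-formula sign bookkeeping. Where
the printed forms of such models are ambiguous about the sign carried by a
correlation inside a $\Phi_2$ or $\Phi_3$ argument, the primitive resolves
it mechanically, and the resulting probabilities are validated in the test
suite against brute-force Monte-Carlo counts of the latent regions.

### Identification

The two hurdle equations are never observed directly, so identification
leans on exclusion restrictions: covariates that shift participation but
not misreporting (peer use, early drinking) and covariates that shift
misreporting only (survey administration conditions). `build_design()`
warns — deliberately does not fail — when the double-inflated variants lack
such instruments. The correlations $\rho_{ry}$ and $\rho_{my}$ are weakly
identified because $m$ and $\tilde y$ are only observed jointly through
$y$; the optimiser bounds all correlations inside $[-0.99, 0.99]$ through
its transform, and the misreporting block approaches its asymptotics slowly
(poorly identified samples can push its intercept into a flat region — the
fit then reports a near-singular Hessian rather than failing).

## Probability engine

* **Bivariate CDF** (`pnorm2`): Gauss–Legendre quadrature on the angular
  (Drezner–Wesolowsky) representation, which is smooth in $\theta$ for all
  $|\rho| < 1$; composite panels are doubled for $|\rho| > 0.925$. Absolute
  accuracy is ~1e-14, tested against an independent
  `integrate()`-based oracle.
* **Trivariate CDF** (`pnorm3`): either deterministic adaptive quadrature
  (the conditional bivariate CDF integrated over the first component) or
  the GHK simulator.
* **GHK** (`ghk_rect_prob`): recursive conditioning with antithetic,
  randomly shifted Halton draws (bases 2 and 3). The shift is a
  deterministic function of the seed, each observation owns a contiguous
  segment of the sequence, and the draws are fixed across likelihood
  evaluations (common random numbers), which keeps the simulated likelihood
  smooth. The default is 500 draws per observation (antithetic pairs count
  as two). Two properties are worth noting:
  * at $\rho = 0$ the GHK factors are exact, so the correlated likelihood
    reproduces the independent one to machine precision — the nesting tests
    exploit this;
  * all terms of a row's probability vector are assembled from one
    recursive pass, so each row's categories sum to one *exactly*, not just
    within simulation error, and the three zero components sum exactly to
    the zero probability.

## Estimation

`dziop()` / `dziop_fit()` maximise the mean log-likelihood by quasi-Newton
search in an unconstrained parameterisation:

* thresholds through cumulative exponentials
  ($\mu_1 = e^{c_1}$, $\mu_j = \mu_{j-1} + e^{c_j}$), so ordering holds at
  every iterate;
* correlations through $0.99\tanh$ of free parameters, the third being the
  *partial* correlation of $(m, y)$ given $r$ — positive definiteness of
  $\Omega_3$ is guaranteed by construction;
* GOP thresholds through cumulative exponentials of
  $c_j + z'\gamma_j$, so covariate-dependent thresholds stay ordered for
  every row and any coefficients.

Gradients are central finite differences with step
$10^{-5}(1 + |\theta_k|)$; for the simulated (DZIOPC) likelihood all $2p+1$
perturbed configurations run through one compiled pass that reuses the
early GHK stages whenever a perturbation leaves them unchanged.
Probabilities are floored at $10^{-300}$ before logging.

Two optimisers are available: plain BFGS (`optimizer = "BFGS"`, the
default, matching the standard practice for these models) and a scaled
`nlminb` (`optimizer = "nlminb"`) that preconditions the search with
diagonal curvature computed at the start. The likelihood surface has long
flat valleys in the misreporting and correlation directions, and the scaled
variant typically needs 3–5 times fewer iterations there; the two agree on
the optimum. Convergence is declared when the optimiser's relative
log-likelihood improvement falls below `tol_loglik` (1e-9) *and* the
infinity norm of the mean-log-likelihood gradient is below `tol_grad`
(1e-4); `converged = FALSE` with diagnostics, never an exception, reports
failure.

Starting values are staged: a probit of $1\{y>0\}$ on $x_r$, a plain OP fit
on all rows mapped to the $\mu_0 = 0$ normalisation (an OP on the positive
rows alone would leave the intercept and first threshold undetermined,
which is why the warm start uses every row), a neutral misreporting start
(intercept 1: high truthful-reporting probability), and zero correlations.

For simulated likelihoods a *staged-draws* fit is standard practice and
used in the package's own experiments: converge first with few draws, then
polish with the full draw count from the warm point.

### Covariances

`se = "sandwich"` (default) computes $H^{-1}(\sum_i g_i g_i')H^{-1}$ with a
finite-difference Hessian and per-row scores in the unconstrained space,
mapped to the reported parameterisation by the numerical Jacobian of the
transform; `"hessian"` stops at $(-H)^{-1}$; `"opg"` uses the outer product
of scores only — the cheap, information-equality-based choice for large
simulated-likelihood fits where a full finite-difference Hessian is
disproportionate. Sandwich and inverse-Hessian errors agree within ~15% on
well-specified simulated data (tested), which is the practical check of the
information equality.

## Post-estimation

**Partial effects** (`partial_effects`) perturb *data columns* and rebuild
the design, so a covariate appearing in several equations automatically
accumulates its effect through all channels, and the three zero-source
effects sum to the overall zero effect by construction (asserted to 1e-8 in
the tests). Continuous covariates get central derivatives (step 1e-6);
binary covariates a discrete 0→1 change by default (`dummies =
"derivative"` switches to derivatives — both satisfy additivity).
Evaluation is at arithmetic column means (`at_means`) or averaged row-wise
(`average`). A quadratic term stored as its own column is treated as a
distinct regressor: it is held at *its own* mean and is not moved when its
parent is perturbed, mirroring how such tables are conventionally reported.
Standard errors are delta-method with a numerical Jacobian over the
reported parameters.

**Zero attribution.** `prior_zero_summary()` averages the three zero
components over all rows (their sum is the average zero probability);
`posterior_zero_shares()` conditions on an observed zero, normalising the
components row by row (only $y=0$ rows enter the average). Because rows are
*selected* by $y=0$, the averaged posterior shares estimate the realised
composition of the observed zeros — the property the recovery tests check
against stored latent states. The posterior computation uses the
uncorrelated components for a DZIOP fit and the rectangle-probability
components for a DZIOPC fit. Reported standard errors combine three
pieces: the delta-method parameter term, the sampling variability of the
average, and — when the average runs over the estimation sample itself —
the cross-covariance between the two, built from per-row scores and the
Hessian. The combination reproduces a 200-replicate nonparametric
bootstrap within a few percent at $n = 8000$ (tested at 20% tolerance).
At very small samples (around $n = 2000$) the share functionals are
visibly curved over the parameter spread and any first-order method
understates the dispersion by tens of percent; prefer a bootstrap there.

**Independence test.** `lr_independence_test()` compares the correlated
fit with its uncorrelated counterpart: $LR = 2(\ell_C - \ell)$, clipped at
zero because a simulated likelihood can fall microscopically below the
analytic one, against $\chi^2_3$ (or $\chi^2_1$ for ZIOPC/ZIOP). Standard
chi-square critical values are used; no boundary correction is applied
because the correlations are interior parameters. When the correlated fit
uses few draws, re-evaluating its likelihood once at the estimates with
many draws before forming the statistic strips most of the simulation noise
out of the test; the type-I-error experiment uses this two-stage
evaluation.

## The synthetic-data generator

`cannabis_preset()` encodes the study conditions the package is exercised
under: an outcome with four ordered categories massed at ~89% zeros, binary
demographics at realistic prevalences (e.g. male 0.466, married 0.625), a
standardised age score with a separate centred quadratic column, a
log-price-style continuous covariate, and instrument-style columns
exclusive to participation (peer use 0.042, early drinking 0.597) and to
misreporting (survey conditions 0.298/0.179). Coefficients carry the signs
and magnitudes a large household drug survey produces; thresholds are
$(0.819, 1.568)$ and the correlated preset uses
$(\rho_{rm}, \rho_{ry}, \rho_{my}) = (-0.591, 0.038, 0.280)$. Intercepts
were tuned once, by simulation, so the three zero sources average
approximately $0.815 / 0.044 / 0.029$ of the sample (overall zero share
0.888, with ~24% of participants misreporting). Three designs are
provided: `full` (~10 covariates), `condensed` (a 12-parameter design for
recovery experiments) and `minimal` (one standard-normal covariate per
equation, for cheap replication studies).

Draw order is documented and single-streamed: covariates first (in the
order listed), then the $n \times 3$ matrix of latent shocks through the
lower Cholesky factor of $\Omega_3$, so every experiment is reproducible
from one integer seed.

What the generator does **not** emulate: the sampling design and weights of
a real household survey, dependence between covariates (they are drawn
independently; a real survey's demographics are correlated), state-by-year
price panels, and item nonresponse. Passing tests therefore demonstrate
correctness of the estimator under the model's own assumptions — not
robustness to survey artefacts the model does not describe.

```{r quick-example}
cfg <- cannabis_preset("minimal", n = 2000, seed = 1)
sim <- simulate_dziop(cfg)
mean(sim$data$y == 0)            # ~0.89 observed zeros
truth_shares(sim$latent)         # realised origin of those zeros
```

## Problem sizes used by the automated experiments

The package's experiments are sized to run comfortably on a single CPU:
parameter recovery uses a single replicate at $n = 20{,}000$ — the
condensed design for the independent model, and the minimal design for the
correlated one (64-draw warm-up, 500-draw polish, sandwich covariance with
64-draw scores and Hessian — standard errors need far less draw precision
than point estimates). The correlated model needs the minimal design's
continuous instruments: with a weak binary survey instrument its
misreporting block is close to unidentified, and a single replicate's
simulated MLE can drift far along a near-flat manifold while staying
inside the likelihood's confidence region — an instructive identification
property in its own right; the misspecification comparison (OP and ZIOP
understating participation prevalence on double-inflated data) runs at
$n = 20{,}000$, where the asymptotic ZIOP bias under the preset clears
three binomial standard errors; the type-I-error study of the independence
test uses 100 replicates of the minimal design at $n = 2{,}000$ with
48-draw fits and 512-draw statistic evaluation; the probability-engine
cross-validation compares 25 random rectangles against $10^7$-draw Monte
Carlo counts. Recovery is judged against the fit's own robust standard
errors — at these sizes they are the practical equivalent of
replication-based errors, whose computation would require hundreds of
refits.

## Known limitations

* The misreporting block is intrinsically weakly identified; at small $n$
  (or with weak instruments) its parameters can drift into flat regions.
  The fit reports this through large standard errors or a flagged
  near-singular Hessian; it is a property of the model, not the optimiser.
* $\rho_{ry}$ and $\rho_{my}$ are close to unidentified in most designs —
  estimates near the $\pm 0.99$ bound should be read as boundary symptoms.
* GHK bias decays as draws grow; with the 500-draw default it is well below
  statistical noise at the tested sizes, but very small simulated
  probabilities (deep tails) are estimated with relative error.
* Partial effects for formula terms other than plain columns are out of
  scope: transforms (squares, logs) should be precomputed as columns, which
  is also what makes the quadratic-term convention explicit.
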