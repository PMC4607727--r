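---
title: "Hierarchical Bayesian trajectory models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian trajectory models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The generative model

`bayestraj` models a longitudinal measurement — a local tissue volume or
density at one voxel/region, or any per-subject biomarker — as a
subject-specific polynomial trajectory of age observed with noise.
Vectorizing all scans in person-scan order (all scans of subject 1, then
subject 2, ...), the two levels are

$$y = X^{(1)}\theta^{(1)} + \epsilon^{(1)}, \qquad
  \theta^{(1)} = X^{(2)}\theta^{(2)} + \epsilon^{(2)},$$

where $X^{(1)}$ is block diagonal with one block per subject holding raw
powers $(t_{ij}-t_r)^d$, $d = 0,\dots,D$, of centred age, and $X^{(2)}$ maps
group-level parameters (per-group mean coefficients and covariate effects)
to the expected subject coefficients; for one group without covariates it is
$1_N \otimes I_{D+1}$. The model assumes Gaussian errors at both levels,
i.i.d. isotropic measurement noise, and independent identically distributed
coefficient residuals across subjects (the same residual covariance $R$ for
every subject of a group) — the identifiability-driven simplification that
sparse longitudinal designs require.

Key modelling conventions:

* **Reference age** $t_r$ defaults to the mean age over all scans and is
  user-overridable (`traj_data(ref_age = )`). Centring makes the intercept
  the expected value at $t_r$ and keeps the polynomial well scaled.
* **Raw powers** of centred age are used, not orthogonal polynomials, so
  coefficients keep their direct interpretation (value, rate of change per
  year, acceleration). For wide age ranges and high degrees this conditions
  worse than an orthogonal basis; rescaling time (e.g. decades) is a pure
  units choice left to the user.
* **Fixed effects** of degrees $D{+}1,\dots,D_f$ are higher-order terms
  shared across subjects. They are carried hierarchically: their
  second-level error variance is clamped to $\sigma_f^2 = e^{-32}$, which
  forces the first- and second-level fixed-effect parameters to coincide
  while keeping a single inference machinery for all parameters. With
  several groups the fixed-effect columns are per group.
* **Covariates** are subject-level, constant within subject, and centred
  globally across the sample (not per group). Global centring keeps a single
  interpretation of the group mean parameters; per-group centring would
  silently change what "group mean" means in unbalanced covariate
  distributions. With several groups, covariate effects are estimated per
  group by default — the block second-level design gives each group its own
  ones column and covariate columns — with `shared_covariates = TRUE`
  constraining them equal across groups. Covariate effects apply to all
  trajectory coefficients; per-coefficient covariate selection is out of
  scope.
* Subjects with fewer scans than $D{+}1$ are accepted with a warning: the
  hierarchy shrinks their coefficients toward the group expectation, which
  is exactly the point of the empirical prior.

## Covariance components and the augmented system

All error covariances are linear combinations of known diagonal basis
matrices with positive coefficients $e^{\lambda_k}$: one isotropic
first-level basis ($I_M$, measurement noise) and, at the second level, one
diagonal indicator per trajectory coefficient per group, so a $G$-group
degree-$D$ model has $1 + G(D{+}1)$ free hyperparameters. Optimizing
log-variances both enforces positivity and stabilizes the Fisher scoring.

Treating the second-level errors as parameters, the model is rearranged into
one non-hierarchical system and augmented with pseudo-observation rows for
the prior expectations $E[\epsilon^{(2)}] = 0$ and
$E[\theta^{(2)}] = \eta_\theta^{(2)}$:

$$\bar y = \begin{bmatrix} y \\ 0 \\ \eta_\theta^{(2)} \end{bmatrix},\qquad
  \bar X = \begin{bmatrix} X^{(1)} & X^{(1)}X^{(2)} \\ I & 0 \\ 0 & I
  \end{bmatrix},$$

with block-diagonal error covariance carrying, in order, the noise
variance, the second-level covariance (with the fixed-effect clamp), and the
top-level prior covariance. The default top-level prior is flat:
$\eta_\theta^{(2)} = 0$ and $C_\theta^{(2)} = e^{32} I$. `traj_prior()`
accepts an informative mean/variance instead (the interface hook for fully
Bayesian or empirical-Bayes priors); nothing else changes.

## EM inversion

**E-step.** At fixed hyperparameters the posterior is Gaussian:
$C_{\theta|y} = (\bar X' C_\epsilon^{-1} \bar X)^{-1}$,
$\eta_{\theta|y} = C_{\theta|y}\bar X' C_\epsilon^{-1}\bar y$. Because every
covariance here is diagonal, $C_\epsilon^{-1}$ is a weight vector and the
posterior precision is formed by one sparse weighted cross-product.

**Free energy.** The bound $F$ is reported with *all* constants — Gaussian
normalizers and the posterior entropy — so that after an exact E-step $F$
equals the log marginal likelihood $\ln p(y|\lambda)$ of the collapsed
two-level model exactly (the test suite checks this against a closed-form
Gaussian marginal to 1e-8). Differences of $F$ between models with
different parameter counts are therefore meaningful log Bayes factors; the
flat-prior magnitude enters them as the natural Occam penalty per
additional group-level parameter.

**M-step.** One Fisher-scoring update
$\lambda \leftarrow \lambda + H^{-1} g$ per M-step, with the analytic
gradient and Fisher information evaluated through
$P = C_\epsilon^{-1} - C_\epsilon^{-1}\bar X C_{\theta|y}\bar X' C_\epsilon^{-1}$,
then immediately re-entering the E-step. Because all bases are diagonal
indicators with disjoint support, every trace reduces to sums over index
sets and small Gram matrices; no $n \times n$ matrix is ever formed. The
per-unit fit at $N = 200$ subjects, $M = 1000$ scans, $D = 1$ runs in well
under a second on one CPU (asserted in the test suite at a 2 s bound).

**Safeguards and stopping (the optimizer's own conventions):**

* raw Fisher steps are capped at $|\Delta\lambda_k| \le 8$ and halved (at
  most 6 times) while $F$ decreases — $e^\lambda$ overflows and the bound is
  not globally quadratic, so accepted iterations never reduce $F$;
* log-variances are kept in $[-32, 32]$, consistent with the flat-prior and
  clamp magnitudes; degenerate (zero-variance) components converge to the
  floor rather than overflowing the weights;
* initialization: $\log\sigma^2$ from the pooled within-subject residual
  variance of per-subject least squares; each $\lambda_d$ from the log
  between-subject variance of the per-subject coefficients in that group,
  floored at $e^{-8}$; fallback $-4$ when too few subjects support it;
* convergence when $\Delta F < 10^{-6}\max(1, |F|)$ **and**
  $\max|\Delta\lambda| < 10^{-3}$, or after 64 iterations; non-convergence
  is flagged, never silently dropped;
* all hyperparameters are updated jointly in one Fisher step (serial
  updates would also be admissible; the joint update is what the Fisher
  information is for);
* a singular Fisher information (typical when a variance sits on the floor)
  falls back to a ridge-regularized solve, with one warning per fit.

**Numerical linear algebra.** The flat prior ($e^{32}$) and the
fixed-effect clamp ($e^{-32}$) put a spread of $e^{64}$ into the assembled
precision. All solves go through Cholesky after symmetric Jacobi scaling,
and the E-step mean gets two steps of iterative refinement: the normal
equations square the conditioning, and the near-interpolation limit (noise
variance $\to e^{-30}$) needs the extra forward accuracy — with refinement
the fitted line passes through the data to machine-level error, as the test
suite asserts.

## Inference and model comparison

A contrast $c$ over group-level (or, via the joint posterior, subject-level)
parameters yields the exceedance probability
$p(c'\theta > \gamma \mid y) = 1 - \Phi\left((\gamma - c'\eta)/\sqrt{c'Cc}\right)$
with suprathreshold flag at $p_t$ (default 0.95). Two-sided questions are
expressed as two one-sided probabilities (the mirror identity
$p_{-c,-\gamma} = 1 - p_{c,\gamma}$ holds exactly). No multiplicity
correction is applied to PPMs; calibration is assessed empirically (below).
For compound hypotheses the package returns the joint posterior of the
stacked contrasts and, as a scalar summary, the squared standardized
distance of the null point with its $\chi^2$ posterior mass — an extension
beyond the one-sided construct, and labelled as such: there is no single
canonical decision rule for compound trajectory hypotheses, so the package
reports the joint posterior and leaves thresholding to the analyst.

Model comparison fits each candidate specification by an independent EM
optimization and differences the free energies (log Bayes factors).
Non-converged candidates are excluded from winner selection and reported.

## The synthetic-data suite

`sim_config()` / `simulate_ensemble()` generate ground-truth ensembles in
the generative direction of the model itself. The defaults are the
validation conditions used throughout the package's tests: 64 subjects,
5 annual scans, linear trajectories with group means $(1.2, -5\cdot10^{-3})$
in arbitrary tissue-density units, "large individual differences"
(intercept variance $10^{-2}$, slope variance $10^{-4}$; the "small"
condition $10^{-4}, 10^{-6}$ is one argument away), Gaussian noise sd 0.01,
study interval 20–80 years. Balanced designs give every subject the same
annual grid centred on the interval midpoint; unbalanced designs draw each
subject's mean age uniformly over the interval while keeping the
within-subject spacing (keeping the balanced within-subject spacing under "unbalanced" designs is
a deliberate simplification; only the mean-age margin is randomized). Sparsity is the
number of scans per subject, down to a cross-sectional single scan. Truth
trajectories are parameterized at the interval midpoint and the simulated
dataset carries that reference age, so recovered intercepts are directly
comparable to the generating ones.

Non-Gaussian errors come in two moment-matched generalized-normal families,
whose exact densities are the package's own parameterization choice: **type I** is the symmetric exponential-power
family, shape solved by one-dimensional root finding so the population
excess kurtosis hits its target; **type II** is a shifted log-normal
transform of a Gaussian, shape solved so the population skewness hits its
target. Both are standardized to exact zero mean and target variance. The
noise schedule of the accuracy experiments is
$\sigma^2 = 0.01/(1 + 25(p-1)^2)$, $p = 1,\dots,10$.

The suite also provides the classical two-stage comparator
(`summary_statistic_test()`: per-subject OLS, one-sided one-sample t test of
slopes), an RMSE experiment over the noise schedule
(`rmse_experiment()`), and false-positive calibration
(`empirical_fpr()`): fit many null units, compute the slope-decline PPM,
report the suprathreshold fraction per threshold. The default null is
direct simulation under zero slope; a permutation mode permutes
whole-subject response blocks against the design (within strata of equal
scan counts, since subjects may differ in their number of scans).

What the generator does **not** emulate: spatial correlation between units,
registration or segmentation artifacts, scanner and site effects, and any
real anatomy. Passing tests therefore establish the statistical behaviour
of the estimator under its own model class (and moderate violations of
normality), not performance on real images.

## Problem sizes used by the tests

The validation experiments are run at desk scale, chosen once as the
package's own test conditions: 50 replicate ensembles of $N = 200$ subjects
for parameter and hyperparameter recovery, 200 replicates for
posterior-interval coverage (accepted band 90–99% at nominal 95%), 1000
null units of $N = 60$ for PPM calibration at $p_t = 0.95$, 30 replicates
of $N = 100$ for the model-comparison winner rates, and $\le 16^3$ voxel
grids for the imaging runner. Replicate counts in the simulation functions
are arguments, so larger runs are one call away.

## Known limitations

* Gaussian likelihood only; heavy-tailed or bounded measurements are only
  covered through the robustness of the mean parameters (hyperparameters
  are biased under strong kurtosis, as the non-Gaussian simulations show).
* Second-level residuals are independent across coefficients (diagonal
  $R$); correlated random effects are not modelled.
* No first-level (time-varying) covariates.
* Hyperparameter point estimates are plugged into the posterior (empirical
  Bayes): posterior uncertainty ignores hyperparameter uncertainty, which
  makes thresholded PPMs behave like z- rather than t-tests. At the sample
  sizes validated here the empirical false-positive rate stays at or below
  the nominal level, but very small samples would inherit the usual
  plug-in optimism.
* Units are fitted independently; no spatial regularization or smoothing of
  maps.
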