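---
title: "Scalar-on-image quantile regression for brain age: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scalar-on-image quantile regression for brain age: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainquantile)
```

## The problem

Brain-age models predict chronological age from a structural brain image; the
difference between predicted and observed age (brainPAD) is used as a
biomarker of atypical ageing. Most published models output a single number.
`brainquantile` instead treats the registered 3D image as a functional
covariate and fits *quantile* regressions of age on the image, so that every
subject receives a point prediction (the conditional median) **and** a
prediction interval with a chosen nominal coverage. The interval width is
subject-specific: the same brainPAD can be alarming for a subject with a
narrow interval and unremarkable for one with a wide interval.

The model is trained on control subjects only (a *normative* model). Applied
to patient groups, the prediction reads as "the age of a healthy brain that
looks like this one", and subjects whose chronological age falls below the
interval's lower limit (star-positive) have brains that look older than they
should.

## The model, stage by stage

### Masking

The raw binary brain mask is smoothed with an isotropic Gaussian kernel
(default SD 2 voxels) and thresholded at 0.5, regularising the boundary.
Smoothing uses reflective boundary handling so edge voxels are not
artificially eroded — the choice matters only within a kernel radius of the
grid edge, and for brain masks the tissue sits well inside the grid.

### Basis expansion

Each image \(X_i\) on the \(P_1 \times P_2 \times P_3\) grid is projected by
ordinary least squares onto a tensor product of univariate quadratic B-spline
bases with equidistant distinct knots (default spacing 12 mm; the synthetic
desk-scale default is 4 mm on a 24³ grid),

\[
\hat x_i(t) = \sum_{k=1}^{K} \tilde c_{ik} \varphi_k(t),
\qquad \varphi = S^{(3)} \otimes S^{(2)} \otimes S^{(1)},
\]

restricted to masked voxels (rows) and to basis functions with support inside
the mask (columns, `active_columns`). With \(l_j\) distinct knots and degree
\(r\), each axis carries \(Q_j = l_j + r - 1\) functions; boundary knots are
repeated to full multiplicity (clamped basis), the only convention under
which that count, unit sum, and exact representation of constants all hold.
Coefficients solve one shared Cholesky factorisation of the masked
normal-equations matrix, so per-image projections are independent and cheap.
The per-image \(R^2\) (about the image's masked mean; constant images report
1 by convention) diagnoses whether the knot spacing is fine enough — around
0.95 or better is a good working target.

Raster order is fixed: first axis fastest, matching the Kronecker order
above, so design rows align with vectorised voxels. Image intensities are
taken as-is; any intensity rescaling of the input maps (e.g. TBM units) must
be done upstream.

### Functional PCA in coefficient space

With centered coefficients \(C\) and the basis Gram matrix
\(W_{kl} = \langle \varphi_k, \varphi_l \rangle\) (computed as the unit-weight
cross product over masked voxels — cheaper than quadrature, and any positive
rescaling of \(W\) provably cancels in the predictions, which the test suite
checks end to end), the covariance-operator eigenproblem reduces to the SVD
of \(A = (N-1)^{-1/2} C L\) where \(W = L L^\top\): eigenvalues are squared
singular values, eigenfunction coefficients are \(\xi = (L^\top)^{-1} u\),
and \(\xi^\top W \xi = I\). Scores for any image centered with the
*training* mean are \(\nu = C W \xi\); only training scores have mean zero
and variance \(\lambda_m\).

Numerical choices:

* singular values below \(10^{-10}\) of the largest are discarded (numerical
  rank);
* eigenfunction signs are fixed deterministically by making the largest
  absolute coefficient positive (any sign convention is statistically
  arbitrary; a deterministic one makes runs reproducible);
* if the plain Cholesky factorisation of \(W\) fails (close knot spacings
  make neighbouring basis functions nearly collinear), a pivoted Cholesky
  factorisation is used, the triangular solve is permutation-corrected, and
  the system is truncated to the pivoted rank. The fallback is logged; with a
  rank-deficient \(W\) the recovered eigenfunctions are one representative of
  an equivalence class, which is the natural resolution given that the basis
  itself is degenerate there.

The truncation \(M\) is the smallest number of components reaching a
proportion of variance explained (PVE) threshold, default 0.8. A sensitivity
grid over PVE, knot spacing and nominal coverage is built in
(`sensitivity_grid()`).

### Penalised quantile regression

For each quantile level \(\tau\) the model
\(Q_\tau(Y \mid X) = \alpha_\tau + \sum_m \nu_{im} b_{m,\tau}\) is fitted by
minimising the check-loss objective with a LASSO penalty,

\[
\sum_i \rho_\tau\!\left(y_i - \alpha - \textstyle\sum_m \nu_{im} b_m\right)
  + h \sum_m |b_m|,
\qquad \rho_\tau(u) = [\tau - 1\{u \le 0\}]\, u .
\]

Design decisions:

* **Standardisation.** Score columns are scaled to unit variance before
  penalisation and coefficients are back-transformed; without this the first
  component (largest \(\lambda\)) dominates the penalty. The intercept is
  unpenalised.
* **Solver.** The objective is an exact linear program. The solver is a
  primal-dual interior-point method on the quantile-regression LP dual with
  Mehrotra predictor-corrector steps, followed by an exact vertex polish
  (interpolating the \(p\) observations nearest the fit and keeping the
  result when it does not worsen the objective). The \(\ell_1\) penalty is
  folded in exactly via paired pseudo-observations, using
  \(\rho_\tau(v) + \rho_\tau(-v) = |v|\): two rows with response 0 and design
  \(\pm h\, e_m\) contribute exactly \(h |b_m|\). One exact solver therefore
  covers the whole path, and the test suite checks it against exhaustive
  LP-vertex enumeration to \(10^{-8}\) on small instances.
* **Tuning.** \(h\) is chosen by 5-fold cross-validated check loss on a
  geometric grid of 25 values from \(h_{\max}\) (the smallest penalty that
  nulls the model, computed from one-sided directional derivatives of the
  check loss at the empirical \(\tau\)-quantile) down to
  \(10^{-3} h_{\max}\). Folds are shuffled once per tuning call from a
  recorded seed and reused across the grid; ties go to the largest \(h\).
  Tuning is seeded independently per quantile level, and the seeds are
  recorded in the fitted objects.
* **Post-\(\ell_1\).** Optionally, the LASSO is used only for selection and
  an unpenalised refit on the support debiases the coefficients. Off by
  default: point and interval prediction metrics do not improve after
  debiasing, which is why the default reports the penalised fit.
* Empirical quantiles use the type-1 (left-continuous inverse CDF)
  definition, which is always an exact minimiser of the summed check loss.

### Intervals, metrics, crossings

A nominal \(1-\delta\) interval pairs fits at \(\tau = \delta/2\) and
\(1 - \delta/2\) with the median fit for the point prediction. Reported
metrics: MAE and RMSE of the median prediction, Pearson correlation between
predicted and chronological age with a Fisher-z 95% CI
(\(\tanh(\operatorname{atanh} r \pm z_{0.975}/\sqrt{n-3})\)), empirical
coverage, and star-positive/negative rates. Because each \(\tau\) is fitted
separately, fitted quantiles can *cross* (upper below lower);
`detect_crossings()` reports them and nothing corrects them — crossed
intervals still score coverage as the ordered pair (min, max), treating
crossing as a sanity flag rather than an exclusion rule. Monotonisation
(rearrangement, isotonic regression) is deliberately out of scope.

### Normative cross-validation

Control-group predictions come from 10-fold cross-validation: within each
fold, the mean, eigenfunctions, truncation and all three quantile fits are
estimated on the other folds only, and held-out subjects are centered,
scored and predicted with those training quantities — every control
prediction is strictly out-of-sample, and the fold bookkeeping (who trained
whom) is stored on the result and asserted in the tests. Fold assignment is
a seeded uniform shuffle without stratification. Case groups are predicted
from a single refit on *all* controls (the two-regime protocol); coefficient
maps are likewise reconstructed from the full-control fit. All control
metrics, including the correlation CI, are computed from the CV predictions.

### Coefficient maps

The functional coefficient
\(\hat\beta_\tau(t) = \sum_m \hat b_{m,\tau}\, \psi_m(t)\) is rendered on the
grid through the basis and masked. Since \(W\) uses unit-weight voxel sums,
the plug-in prediction \(\hat\alpha_\tau + \sum_{\text{voxels}} (x - \hat\mu)
\hat\beta_\tau\) uses the same unit-weight sum — the test suite verifies the
score-space and voxel-space routes agree to \(10^{-6}\), the central identity
tying all stages together. Interpreting \(\hat\beta_\tau\) magnitudes
requires knowing that convention: values are "years per unit intensity per
voxel", not per mm³.

## The synthetic generator

Real cohorts of registered clinical images are access-restricted, so the
package ships a generator whose outputs exercise every pipeline stage
against known truth:

* volumes are \(\mu + \sum_m \nu_m \psi^*_m\) with \(\psi^*_m\) random smooth
  fields W-orthonormalised in a generating B-spline basis (QR under the W
  inner product), so FPCA can in principle recover them; the generating and
  analysis bases may differ to probe misspecification;
* scores are centered with variances \(\lambda^* = (25, 16, 9, 4, 2, 1)\)
  (well-separated, so eigenfunction matching is unambiguous), normal by
  default with a shifted-exponential option to exercise distribution-free
  coverage;
* ages follow \(\mathrm{age} = \alpha + \nu \cdot b + \sigma(\nu)\,
  \varepsilon\) with \(\alpha = 75\) years and
  \(b = (0.8, -0.6, 0.5, 0, 0, 0)\), giving roughly a 60–90 year range, and
  homoskedastic \(\sigma_0 = 3\) years by default — the residual scale
  typical of structural brain-age models; the location-scale option
  \(\sigma(\nu) = \sigma_0 + \sigma_1 |\nu_1|\) makes interval widths
  genuinely subject-specific, the case that motivates quantile over
  least-squares intervals;
* the default grid is 24³ voxels at 1 mm with 4 mm generating knots: large
  enough for a nontrivial tensor basis (512 functions), small enough that
  the full pipeline runs in seconds;
* `true_quantile()` returns exact conditional quantiles
  \(\alpha + \nu \cdot b + \sigma(\nu) F_\varepsilon^{-1}(\tau)\) for any
  level, monotone in \(\tau\) by construction.

What the generator does **not** emulate: anatomical structure, realistic TBM
intensity distributions, registration error, scanner effects, or voxel-level
measurement noise (volumes lie exactly in the generating span). Passing
tests therefore establish the correctness of the statistical machinery under
the stated model, not robustness to the artefacts of real imaging pipelines.

## Problem sizes used in the tests

Unit tests run on 6³–16³ grids with cohorts of 10–80. The deeper checks use:
a 24³ cohort of 200 with 10-fold CV and three quantile levels for the
end-to-end run; 20 replicates of \(n_{\text{train}} = 1000\),
\(n_{\text{test}} = 5000\) scalar-covariate simulations for nominal coverage
at 90% and 80%; and 20 replicates of \(N = 500\) cohorts for slope recovery,
where the replicate-averaged post-\(\ell_1\) median coefficients are required
to sit within 10% of the generating slopes (an unbiasedness check;
single-replicate slopes carry sampling noise of order 10–15% at that
\(N\)). These sizes were chosen so the whole suite completes in a few
minutes on one core while leaving each assertion statistically meaningful.

## Known limitations

* No quantile-crossing correction (detection only).
* No smoothing penalty inside FPCA; regularisation happens through basis
  coarseness, PVE truncation, and the LASSO.
* Coverage is nominal under a correctly specified linear-in-scores quantile
  model; under misspecification (true coverage drifting with covariates) the
  empirical coverage can fall below nominal, which is exactly what the
  sensitivity grid is there to reveal.
* The interior-point solver targets dense, desk-to-moderate problem sizes
  (thousands of observations, tens of scores); it is not a sparse
  large-scale LP code.
* Identity-basis variants (one coefficient per voxel, i.e. no smoothing) are
  possible in principle but need large-memory tooling out of scope here.

## A worked example

```{r example, eval = FALSE}
library(brainquantile)

cohort <- generate_cohort(synthetic_config(120, seed = 1))
basis <- build_basis_system(c(24, 24, 24), 1, knot_spacing_mm = 4,
                            degree_r = 2, mask = cohort$mask)
proj <- project_cohort(cohort$volumes, basis, cohort$mask)

cv <- run_normative_cv(proj, basis, cohort$table,
                       spec = interval_spec(0.1), folds = 10, seed = 1)
compute_metrics(cv)

fit <- fit_brainage(proj, basis, cohort$table, seed = 1)
beta_map <- reconstruct_beta(fit$models$median, fit$eigen, basis, cohort$mask)
plot_slices(beta_map)
```
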