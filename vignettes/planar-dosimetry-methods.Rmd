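---
title: "Methods: conjugate-view planar dosimetry, kernel convolution, and dose regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conjugate-view planar dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planardose)
```

## The quantification model

Planar scintigraphy records two opposed projections of the patient. For
an organ at anterior depth $d$ inside a body of thickness $T$ with
effective linear attenuation coefficient $\mu_e$, the anterior and
posterior ROI count rates are attenuated by $e^{-\mu_e d}$ and
$e^{-\mu_e (T-d)}$ respectively. Their geometric mean cancels the
unknown depth, leaving only the total thickness:

$$A \;=\; \sqrt{\frac{I_A\,I_B}{e^{-\mu_e T}}}\times\frac{1}{C},$$

where $C$ (counts MBq$^{-1}$ s$^{-1}$) is measured from a planar scan of
a known activity. The assumptions this rests on, and the places they
bend in practice, are:

* a *single* $\mu_e$ summarizes all tissues between organ and detector.
  We take the arithmetic mean of the per-tissue coefficients, and keep
  the three lung thirds separate because the surrounding rib/soft-tissue
  mix changes markedly from apex to base;
* $T$ is measurable. The package takes it from two cursor points on the
  45° oblique view ($T = \|p_2-p_1\| \cdot s / 10$ cm for pixel size $s$
  mm), with a configurable obliquity factor defaulting to 1 because the
  apparent oblique chord is used as-is;
* counts are background-contaminated. We subtract the mean background
  pixel value from the mean ROI pixel value (floored at zero) and scale
  back by the ROI pixel count, which removes any spatially uniform
  background exactly;
* small objects lose apparent activity to the partial volume effect.
  An optional recovery-coefficient divisor is interpolated piecewise-
  linearly from a sphere-phantom curve; outside the calibrated diameter
  range we clamp to the nearest end value and warn, because
  extrapolating an RC curve can produce nonphysical values.

Units are fixed throughout: rates in counts/s, $\mu_e$ in cm$^{-1}$,
$T$ in cm, activities in MBq (1 mCi = 37 MBq exactly). Decay correction
of counts to a common reference time is off by default; a helper applies
$\lambda_{phys} = \ln 2 / 192.5\ \mathrm{h}^{-1}$ (¹³¹I) when wanted.

## Time-integrated activity

Organ activity sampled at 24/72/168 h is fitted by least squares with
$A(t) = A_1 e^{-\lambda_1 t} (+\,A_2 e^{-\lambda_2 t})$ and integrated in
closed form, $\tilde A = \sum_i A_i/\lambda_i$ (MBq·h, reported ×3600 as
MBq·s). A free biexponential has four parameters; three scans cannot
determine it. Rather than silently regularizing, `fit_tac()` refuses the
underdetermined fit and offers three well-posed options: monoexponential
(default for 2–3 points), biexponential with one rate pinned (e.g. to
$\lambda_{phys}$, 3+ points), or the free biexponential for 4+ points.
Initialization is deterministic — slow rate from a log-linear regression
on the last two points, amplitude from the first point, rates bounded
below at $10^{-6}$ h$^{-1}$ — so fits are reproducible. A trapezoid rule
with an optional analytic physical-decay tail ($A_{last}/\lambda_{phys}$)
is the model-free fallback.

Because uncorrected counts are fitted, the fitted rates are *effective*
(biological + physical) clearances, and integrating to $t=\infty$ is the
default.

## Kernel-convolution dosimetry

The dose map is the discrete 2D convolution $D = \tilde A \otimes K$
of the per-pixel cumulated activity with an organ-specific dose point
kernel: an odd $K\times K$ grid of Gy per MBq·s in the central source
pixel, exported from Monte-Carlo simulation and ingested here (kernel
generation is out of scope). Choices that were genuinely open:

* **edge handling** — zero padding, because activity outside the field
  deposits no dose in it, and because it makes interior conservation
  provable: when the activity support stays half a kernel away from the
  borders, $\sum D = \sum \tilde A \cdot \sum K$ exactly;
* **convolution vs correlation** — true convolution (index-reversed
  kernel) for fidelity to the defining equation; validated kernels are
  rotation- and mirror-symmetric, so the distinction is immaterial in
  practice;
* **validation** — `validate_kernel()` enforces odd size, non-negative
  entries, central maximum, and symmetry within a tolerance, and
  computes a coverage profile (fraction of the kernel sum inside each
  central $n\times n$ block). The default 9×9 at 2.3976 mm is warned
  about when coverage falls below 0.95, and `kernel_size_study()`
  quantifies the truncation deficit of 3×3 … 13×13 crops on a uniform
  disc phantom;
* **S-values** — two are exposed, because either could feed a feature
  table: the kernel center value (`s_value_center`) and the organ
  self-dose per unit cumulated activity spread uniformly over the mask
  (`organ_s_value()`). The self-absorption assumption (cross-organ dose
  only via the kernel support) is inherited from the method, not
  corrected for.

## Dose regression

One pooled model is fitted with the organ as a one-hot feature (the
feature list is organ-agnostic; per-organ error breakdowns are part of
the report instead). Preprocessing: drop rows with a missing target;
impute missing features (mean by default — linear interpolation along
patient/organ order is available but the ordering is arbitrary for
cross-sectional data); remove rows with any $|z|>3$ (conventional
default for an unspecified z-filter); min–max scale the imaging-derived
count features, z-score everything else. All constants are fitted on
the training split only, saved, and re-applied verbatim to the test
split; re-applying them to an already-normalized table is a no-op,
which is what the leakage test checks.

Model families and their fixed configurations:

* **MLP** — dense 3×6 hidden layers, leaky-ReLU ($\alpha=0.01$), linear
  output, Adam (lr 0.001, batch 50), L2 weight penalty, early stopping
  on a held-out quarter of the training split. The penalty is an
  approximation: the historical "Bayesian regularization" scheme is
  Levenberg–Marquardt-specific and contradicts the simultaneously
  stated Adam/batch details, so we keep the optimizer and express the
  regularization as weight decay. The network is implemented in base R
  (no multi-hidden-layer perceptron exists in the dependency set) and
  is seed-deterministic.
* **SVR** — radial kernel, $C=100$, $\gamma=10$ (e1071).
* **Decision tree** — minimum leaf 5; grown with cp = 0 and pruned back
  to at most 20 splits via the complexity table (rpart has no direct
  split cap). Ties resolve to the first-encountered best split.
* **Linear regression** — closed-form least squares; an optional
  quasi-Newton path (L-BFGS-B, ≤1000 iterations) is provided for parity
  with gradient-based tooling.

Evaluation reports MAE, MSE and RMSE (so RMSE² = MSE and MAE ≤ RMSE by
construction) overall and per organ; the "MSE %" notation sometimes
attached to squared errors is treated as plain MSE in squared dose
units. External validation uses a Shapiro–Wilk gate on the paired
differences at $\alpha$: normal → paired t-test, otherwise Wilcoxon
signed-rank; identical vectors short-circuit to a flagged degenerate
result with $p=1$.

## What the synthetic phantom does and does not emulate

The forward projector is a 2D slab model: each organ is an ellipse with
one activity, one depth and one thickness, projected with the exact
exponential attenuation the quantifier inverts, plus optional uniform
background and per-pixel Poisson noise. This is deliberate: it tests
the quantification chain, not a reconstruction engine. It does *not*
emulate scatter, collimator-detector response, septal penetration,
organ overlap along the projection axis (overlap in-plane is permitted
and flagged), motion, or body-contour variation — so a passing phantom
recovery says the algebra and bookkeeping are right, not that clinical
accuracy is this good. The oblique view is rendered as the anterior
geometry with a ground-truth body chord, giving the thickness
measurement a defined truth; the kernel generator uses an exponential
radial falloff, which is a stand-in shape (kernels are interchangeable
inputs, and physical ¹³¹I realism is a non-goal).

Cohort generation draws age 20–80 y, BMI 17–40, thickness 15–35 cm,
$\mu_e$ 0.09–0.13 cm$^{-1}$, lognormal count rates and S-values — the
clinical ranges — and produces the target either as a linear form of
the features (for exact coefficient-recovery tests) or as a smooth
nonlinear function shaped like the dosimetry chain itself
(geometric-mean counts × attenuation recovery × S-value, plus a
saturating age term) for the MLP benchmark.

## Numerical choices and problem sizes

Default test problem sizes are small by design: 64×64 phantoms, three
organs, kernels up to 13×13, maps up to 32×32 for oracle comparisons,
cohorts of 100–500 rows, 100–200 replicates for the stochastic
properties. At these sizes the full suite runs in seconds while still
exercising every code path; the forward/inverse identity is exact to
machine precision, so tolerances (1% noiseless recovery, 5% under
Poisson noise at ≥10⁵ organ counts, 0.1% closed-form vs quadrature,
$10^{-10}$ for convolution against brute force) are dominated by the
stated statistical conditions rather than the grid.

Known limitations, beyond the phantom simplifications above: no
organ-overlap or scatter correction; $\mu_e$ values are config inputs
(no CT pipeline); the calibration point-source method is implemented as
the single-scan ratio only; and the stochastic acceptance band for the
paired-comparison type-I error (±2 points around 5% over 200
replicates) is a ±1.3σ binomial interval, so it is expected to fail
occasionally under reseeding even when the procedure is exact.
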