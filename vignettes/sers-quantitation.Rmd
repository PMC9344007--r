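---
title: "Quantifying pesticide residues from SERS spectra: models and methods"
author: "SERSQuant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pesticide residues from SERS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SERSQuant)
```

# Scope

SERSQuant implements a complete chemometric pipeline for quantifying an
analyte (the reference case is the fungicide thiram on fruit epidermis)
from surface-enhanced Raman spectra: spectral simulation, preprocessing,
calibration/prediction splitting, RBF-kernel principal component analysis,
and regression-based quantitation with RMSECV, calibration-curve, LOD and
RSD statistics. This vignette documents the models, the tunable parameters
and their defaults, the numerical choices, and what the synthetic data can
and cannot tell you about real instrument data.

# The spectral model

## Line shapes

A vibrational band is modelled as a pseudo-Voigt profile — the standard
approximation to the Gaussian/Lorentzian convolution as a weighted sum of
the two shapes with shared center $\omega$ and width parameter $\gamma$:

$$V(\nu)=\theta\,\alpha\,\exp\!\left[-\frac{4\ln 2\,(\nu-\omega)^2}{\gamma^2}\right]
 +(1-\theta)\,\frac{\alpha\,\gamma^2}{(\nu-\omega)^2+\gamma^2}$$

with mixing coefficient $\theta\in[0,1]$ and height $\alpha$ (at
$\nu=\omega$ both terms peak, so $V(\omega)=\alpha$ for every $\theta$).
Note a deliberate quirk: the Gaussian term uses $\gamma$ as a full width at
half maximum (the $4\ln 2$ factor) while the Lorentzian term uses it as a
half width. This mixed convention is how the form circulates in the
vibrational-spectroscopy literature; we implement it verbatim and document
it rather than silently "fixing" it, because the calibration behaviour of
the pipeline only depends on the peak height, which is convention-free.
The same applies to the stand-alone Lorentzian `lorentzProfile()`, whose
$\gamma_L^2$ numerator makes its peak value $1/\pi$ independent of width —
it is not unit-area normalized, and we keep it that way.

## Composition, baseline, noise

A synthetic spectrum on the default 550–1550 cm⁻¹ axis (1 cm⁻¹ step, the
detection window of a typical dispersive instrument) is

$$I(\nu)=\sum_p V_p(\nu) + A\,e^{-(\nu-\nu_0)/\tau} + c,$$

followed by multiplicative Gaussian noise with relative SD `noiseRsd` and
optional additive dark noise. Concentration enters through the
*quantitation band*: all concentration-sensitive peaks are rescaled
jointly so that the quantitation band's clean height above baseline equals
$slope\cdot N + intercept$ exactly (defaults 11644 and 4536.5 a.u., the
linear regime of thiram's 1379 cm⁻¹ band over 0.1–5.0 µg/mL). Choices and
rationale:

- **Thiram library**: bands at 562, 929, 1146, 1379, 1514 cm⁻¹ with
  relative heights (0.45, 0.55, 0.50, 1.00, 0.65), $\theta=0.7$,
  $\gamma=10$ cm⁻¹. Only the band positions and the dominance of
  1379 cm⁻¹ are physically constrained; the relative heights and widths
  are free parameters fixed once at values typical of published thiram
  SERS traces.
- **Baseline**: one decaying exponential plus offset
  ($A=2000$, $\tau=500$ cm⁻¹, $c=200$ a.u.). Fluorescence backgrounds are
  smooth and broad; any such function serves, and this one is easy to
  state and to recover in tests. Its magnitude is set so the background is
  comparable to the calibration intercept — large enough that skipping
  baseline correction visibly biases the calibration.
- **Noise**: multiplicative at `noiseRsd = 0.015`, because SERS substrate
  variability is conventionally quoted as an RSD of replicate peak
  intensities, and well-prepared Au-NP substrates show ~1.4–1.6%.
  Dark (additive) noise defaults to 0.
- **Seeds** are explicit in the config; generation under a seed never
  touches the global RNG state.

With `noiseRsd = 0` the generator is a deterministic function of its
configuration, and the fitted peak-height calibration recovers the
configured slope and intercept to machine precision — the generator's core
correctness invariant.

# Preprocessing

The default chain follows the usual narration for SERS quantitation:
replicate averaging (optional), smoothing, baseline subtraction, optional
derivatives, then feature-range extraction.

- **Savitzky–Golay smoothing**, window 9 points, polynomial order 3. SG is
  standard for Raman because it preserves peak heights far better than a
  moving average; with $\gamma=10$ cm⁻¹ bands on a 1 cm⁻¹ grid the
  height attenuation is well under 1%. Exactness on polynomials up to the
  fitting order holds at interior points; boundary points use the filter's
  polynomial extrapolation rows and carry no guarantee.
- **Baseline correction**: iterative polynomial fitting ("modpoly",
  degree 5, up to 50 iterations, relative tolerance $10^{-4}$) as default;
  asymmetric least squares (Whittaker smoother, $\lambda=3\times 10^4$,
  $p=0.005$) as the alternative. The ALS parameters are the region where
  the estimator simultaneously tracks the pure default background to
  within 1% of its amplitude and preserves an isolated 16000 a.u. band's
  height to within 5%; stiffer settings fail the former, softer ones eat
  the peak.
- **Derivatives** are computed with the same SG machinery (differentiation
  amplifies noise, so smoothing and differentiation happen in one
  least-squares step), scaled to the wavenumber axis: a constant maps to 0
  under order 1, a linear ramp to 0 under order 2. Derivatives default to
  *off* in the quantitation chain: peak-height calibration needs the
  un-differentiated signal, and the derivative stage exists for
  exploratory drift removal.
- **Feature ranges** are closed intervals; boundary grid points are
  included. The defaults (653–683, 705–728, 847–872 cm⁻¹) mirror the
  reference workflow's choice. They do not cover the thiram marker bands —
  an oddity of that workflow we deliberately did not "correct"; the ranges
  are fully configurable and the examples use a range around the
  quantitation band where that is the scientifically sensible choice.

# Max–min sample splitting

Calibration/prediction splitting uses the deterministic max–min strategy:
seed the calibration set with the samples nearest to and farthest from the
mean spectrum, then repeatedly add, from each iteration's table of
minimum-Euclidean-distances to the current calibration set, the most
distant and the least distant remaining samples (one only if a single
slot remains). Both the max and the min of an iteration are taken from the
*same* distance table; recomputing between the two picks would contradict
the procedure's own worked example. All ties break to the lowest input
index, making the split reproducible; each pick's distance is logged in
the returned object. Distance is Euclidean on whatever representation you
pass (raw or preprocessed intensities, or a feature matrix). The default
calibration fraction is 3:1.

# Kernel principal component analysis

For training features $x_1,\dots,x_M$ the RBF Gram matrix
$K_{\mu\nu}=\exp(-\lVert x_\mu-x_\nu\rVert^2/2\sigma^2)$ is centered
(equivalently $HKH$, $H=I-\tfrac1M\mathbf{1}\mathbf{1}^\top$) so the
implicit feature map is zero-mean, and eigendecomposed. Numerical and
scaling choices:

- **Eigenvector normalization**: coefficients are scaled so
  $\lambda_k(\alpha_k\cdot\alpha_k)=1$ (unit-norm feature-space
  eigenvectors, the Schölkopf convention). Without it the projection sums
  are ill-scaled across components.
- **Out-of-sample projection** centers the test kernel rows against the
  *training* kernel statistics before applying
  $[v^k\cdot\Phi(x)]=\sum_i\alpha_i^k k(x_i,x)$; this is what makes
  transforming the training matrix reproduce the training scores, and is a
  documented extension of the training-only centering.
- **Sign convention**: each coefficient vector is flipped so its
  largest-magnitude entry is positive — scores are deterministic across
  platforms and repeated fits.
- **Degenerate components** with $\lambda\le 10^{-12}\lambda_{max}$ are
  dropped with a warning; centering always removes one dimension, so at
  most $M-1$ components exist.
- **Explained variance** is $\lambda_k/\sum_j\lambda_j$ over the
  non-negative eigenvalues (the denominator is not restricted to retained
  components, so reported ratios do not artificially sum to 1).
- **Solver**: full symmetric `eigen()`; $M$ is tens of samples, an
  iterative solver would be noise.
- A **linear-kernel** variant ($k(x,y)=x^\top y$) exists to support the
  classical-PCA comparison; its scores equal covariance-PCA scores up to
  sign, which doubles as the module's independent test oracle.

σ has the units of the feature-space Euclidean distance. On raw intensity
features those distances are in the tens of thousands, which is why the
conventional sweep grid {1000, 5000, 8000, 10000} is sensible there; on
normalized features you must rescale σ accordingly. `sigmaSweep()`
cross-validates the whole KPCA + regression chain (KPCA refitted inside
every fold — anything less leaks the held-out samples into the kernel) and
exhibits the characteristic U-shape: $\sigma$ far below the typical
inter-sample distance makes the Gram matrix effectively diagonal, so
held-out samples project to ~0 and RMSECV approaches the response SD;
$\sigma$ far above it collapses the kernel towards the linear regime,
losing the non-linear features; intermediate widths (a few times the
median pairwise distance) perform best on non-linear
concentration–intensity maps.

# Quantitation

- **PLS**: NIPALS PLS1 (single response — one analyte concentration),
  deterministic, with coefficients assembled as $W(P^\top W)^{-1}q$. With
  all latent variables on full-rank data it reproduces OLS, the test
  oracle. A constant response yields zero coefficients and mean
  predictions rather than an error.
- **MLR**: QR least squares with intercept; rank-deficient or wide designs
  are rejected with a pointer towards PLS/KPCA compression.
- **RMSECV**: $\sqrt{\frac1n\sum_i(\hat y_{(-i)}-y_i)^2}$ with
  deterministic fold assignment — samples sorted by response and cut into
  contiguous blocks, so every fold spans the concentration range.
  Default leave-one-out, matching sample counts in the tens.
- **Calibration curve**: OLS of intensity on concentration; $r^2$ is the
  squared Pearson correlation of fitted vs observed. Two distinct points
  are accepted (exact line, $r^2=1$), though three or more are needed for
  a meaningful fit.
- **LOD**: blank mean plus three blank sample-SDs, through the calibration
  line, floored at 0. The alternative rule `3s_only` (three times the
  blank signal) is available; both conventions circulate in the
  trace-analysis literature. The blank signal is the preprocessed
  intensity at the quantitation wavenumber, not total spectral energy.
- **Peak detection**: interior local maxima filtered by height relative to
  the spectrum's intensity range (hence offset-invariant), greedy
  minimum-separation enforcement from the tallest candidate down, and
  three-point parabolic refinement of each center (sub-grid accuracy on
  symmetric bands).

# What the synthetic data does and does not show

The generator emulates the *statistical structure* the analysis assumes:
pseudo-Voigt bands at known positions, a smooth fluorescence background,
multiplicative intensity noise at the few-percent level, and a designed
concentration–height law. Passing tests therefore demonstrate that the
pipeline recovers what it is mathematically supposed to recover under
those assumptions — e.g. the calibration slope within ~1–2% at 1.5% noise,
the band positions within the grid resolution, the RMSECV U-shape over σ.

They do not demonstrate robustness to what real SERS data adds: matrix
bands overlapping the analyte's, hot-spot intensity fluctuations that are
neither Gaussian nor independent across the axis, wavenumber calibration
drift, cosmic-ray spikes, detector saturation, and baseline shapes less
benign than a single exponential. Published absolute RMSECV values from
instrument data are likewise not reproducible from simulation; only
qualitative patterns (model rankings, the σ response) transfer.

# Problem sizes and runtime

The shipped tests and the acceptance script run study sizes matching the
reference designs — 20-sample concentration series (5 levels × 4
replicates or 20 log-spaced levels), 30-sample non-linear sweeps,
1001-point spectra — and complete in seconds on one core; KPCA at these
sizes is dominated by the 81-point feature extraction, not the
eigendecomposition.

# Known limitations

- Single-analyte (PLS1) calibration only; no PLS2 / multi-response.
- No support-vector regression; the regression interface is deliberately
  small (PLS/MLR) and a kernel regressor can be added without touching the
  KPCA module.
- MSC, SNV, wavelet, DOSC and EMD preprocessing are out of scope.
- LOD is a point estimate; no uncertainty interval is attached.
- JCAMP-DX / vendor binary formats are not parsed; spectra exchange as
  plain CSV.

# Session info

```{r}
sessionInfo()
```
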