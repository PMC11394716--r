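---
title: "Online NIR calibration: models, parameters and design choices"
author: "nircal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online NIR calibration: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nircal)
```

## The problem

A quantitative NIR calibration maps an absorbance spectrum
$x \in \mathbb{R}^p$ (here $p = 512$ channels over 900–1700 nm) to a
constituent value $y$ (fat content, % by mass). Models are calibrated
once, on one measurement campaign, and then meet sample batches whose
storage history, origin and acquisition conditions differ. Those
differences enter the spectra both as per-sample multiplicative/additive
scatter and as systematic between-batch shape changes; a frozen model's
predictions degrade accordingly. `nircal` implements an
*online-updatable* calibration: scatter correction whose reference
tracks the incoming stream, band selection with an expanded feature set,
and a recursive PLS model updated one sample at a time.

## Preprocessing

**MSC.** With reference spectrum $\bar{x}$ (the calibration-set channel
mean), each sample is fit by least squares as
$x_i = a_i \bar{x} + b_i$ and corrected to
$x_{i,\mathrm{MSC}} = (x_i - b_i)/a_i$. The reference must not be
constant (the slope is undefined); fitted slopes below a configurable
floor (default $10^{-6}$) flag the sample and leave it uncorrected
rather than dividing by a vanishing number.

**OMSC.** Online, the reference is the running mean
$\bar{x}_{n+1} = (n\,\bar{x}_n + x_{n+1})/(n+1)$; the new sample is
regressed on the *updated* reference and corrected as above. Only the
$(\text{mean}, n)$ pair is retained — correction never needs the raw
calibration spectra, which is the premise that makes the method
deployable. A design note: one published pseudocode line regresses the
updated reference on the old one, which would not yield a correction of
the new spectrum; we follow the equation form (new spectrum on updated
reference), the only orientation under which the correction step is
well-defined. The per-update reference movement is bounded:
$\|\bar{x}_{n+1}-\bar{x}_n\|_\infty < E/(n+1)$ with $E$ the maximum
pairwise absorbance deviation at any wavelength — the package records
the realized shift at every update and the test suite checks the bound
against a brute-force $E$. Because the deviation of the running mean
from a plain batch mean carries a $1/(n+1)$ factor, OMSC-corrected
spectra converge to their batch-MSC counterparts at rate $O(1/n)$; this
envelope is asserted over $n \in \{10, 100, 1000\}$.

**Savitzky–Golay smoothing** (default window 11 channels, order 2)
removes high-frequency noise, which the simulated instrument
concentrates at the long-wavelength end (≥1500 nm). Each sample is
smoothed independently; smoothing is applied after scatter correction in
both the offline and online paths. The implementation delegates to
`signal::sgolayfilt`; interior points equal a textbook sliding-window
least-squares polynomial fit (tested against one at $10^{-10}$), and
edge points evaluate the full-window fit off-center, the standard
filter-matrix treatment. The interior is the contract-bearing region.

## Band selection

**UVE.** A uniform-random noise block with the same column count as the
spectra, scaled to $10^{-10}\times$ the mean absolute absorbance, is
appended; a PLS model of $y$ on the combined matrix is cross-validated
(leave-one-out by default, fold count configurable), and every column is
scored by $C_i = \mathrm{mean}(b_i)/\mathrm{sd}(b_i)$ over the per-fold
coefficients $b_i$. The PLS inside UVE runs on *centered, unscaled*
data: autoscaling would blow the noise block up to unit variance and
defeat its purpose as a do-no-harm yardstick. Selection keeps the top-k
of $|C|$ among real variables (ties to the lower index); the classic
cutoff — retain variables beating $\max|C_\text{noise}|$ — is kept as a
diagnostic (`uveClassicCutoff`). Defaults are $k=70$ for the offline
model and $k=100$ for the online model: the expansion hedges against
drift re-weighting bands just outside the original selection. Where the
online re-selection should run is genuinely open; we re-run UVE on the
offline calibration set at $k=100$ and rebuild the online state there,
keeping the procedure independent of the (unlabeled-at-that-point)
stream.

**Eigen monitoring.** To watch which bands carry the model as updates
accumulate, the symmetric eigendecomposition of the current standardized
cross-product matrix is taken and every feature is scored by
$\sum_{j \le m} \lambda_j \Gamma_{ij}^2$ over the leading $m = 30$
eigenvalues. The attribution rule from eigenvalues to wavelengths is not
canonical; eigenvalue-weighted squared loadings are this package's
documented choice. Tiny negative eigenvalues of a numerically PSD matrix
are clamped to zero.

## Regression

**Offline PLS** is NIPALS with autoscaling of both $X$ and $y$
(convergence tolerance $10^{-12}$, at most 500 inner iterations per
component — immediate for a single response). The latent-variable count
is chosen by 10-fold RMSECV, ties to the smaller count, and then frozen
into the online state. **Kernel PLS** extracts the same components from
$(X'X, X'y)$ alone (verified equal to NIPALS at $10^{-8}$, and to the
normal-equation solve in the full-component limit); its coefficients are
invariant to a common rescaling of both cross-products, so the
$(N-1)$-denominator convention is immaterial.

**RPLS.** The state holds $X'X(t)$, $X'y(t)$, running moments
$\bar{x}(t), \bar{y}(t), \delta_x(t), \delta_y(t)$, the count $N$, the
forgetting factor $\lambda$ and the selected bands. Per sample:
$N \leftarrow N+1$; means by the exact recursion
$\bar{x}(t) = \frac{N-1}{N}\bar{x}(t-1) + \frac{1}{N}x(t)$; variances by
the recursive form
$\delta_x^2(t) = \frac{N-2}{N-1}\delta_x^2(t-1) +
\frac{1}{N-1}(x(t)-\bar{x}(t-1))^2$; the sample is standardized with the
*updated* moments and accumulated as
$X'X(t) = \lambda X'X(t-1) + \hat{x}(t)'\hat{x}(t)$ (likewise $X'y$).
Two fidelity notes. First, the variance recursion as printed uses a
$1/(N-1)$ innovation weight where the exact running (Welford) form uses
$1/N$; the printed form — which slightly overstates the spread — is the
default, and an exact mode sits behind the `exact_variance` flag (the
tests assert both the exactness of that mode and the documented
direction of the discrepancy). Second, the recursion accumulates samples
standardized with time-varying moments onto old cross-products without
re-standardizing history; that is the algorithm, and a frozen-moments
mode exists purely so oracle tests can compare against exact batch
cross-products. $\lambda$ defaults to 1 (no forgetting) and is
configurable; $\lambda = 0$ is outside the admissible $(0, 1]$, so the
full-forgetting limit is exercised in tests through an unrolled
weighted-sum oracle at $\lambda = 0.5$ and a tiny-$\lambda$
approximation.

**Metrics.** RMSECV/RMSEP are root mean squared errors on
cross-validation folds and held-out predictions. The default $R^2$ is
the standard $1 - \mathrm{SS}_\text{res}/\mathrm{SS}_\text{tot}$; the
as-printed variant $\sum(\hat{y}_i-y_i)^2 / \sum(\hat{y}_i-\bar{y})^2$
is preserved under `variant = "paper"` because some reports print it,
with the caveat — asserted in the tests — that it returns 0, not 1, for
perfect predictions. Reported $R^2$ values in this package are the
standard variant unless labeled otherwise. Dataset splitting is random
at 2:1 with the samples attaining $\min y$ and $\max y$ pinned to the
calibration set, which guarantees the calibration range covers the
prediction range; the pinning mechanism is this package's choice of how
to enforce that rule.

## The synthetic study generator

No real pine nut spectra are distributed, so the generator supplies
studies with known truth. Ideal spectra follow a Beer–Lambert-style
mixture: Gaussian-peak component spectra weighted by concentrations,
on a smooth background. Choices that matter, and why:

- **Grid and sizes.** 512 channels over 900–1700 nm; 120 offline
  samples, 75 online samples streamed in batches of 5 — the study
  design the package is meant to serve. The analyte range defaults to
  55–75 % fat, a plausible pine nut kernel interval; it is configurable
  and carries no claimed provenance.
- **Components.** The analyte ("fat") absorbs at 1210 and 1360 nm
  (σ = 20 nm); its concentration is $y/100$. The channels within one σ
  of those centers are the study's *true informative bands* (50 of 512).
  Three nuisance constituents with deliberately small amplitudes and
  $y$-independent concentrations occupy 970/1460, 1020/1540 and
  1100/1620 nm.
- **A dominant static matrix background.** The baseline is a low-order
  polynomial plus broad fixed absorption bands (bumps near 950, 1150
  and 1650 nm) that dominate the mean spectrum, as the bulk sample
  matrix does in real diffuse-reflectance NIR. This is load-bearing:
  the MSC slope is estimated against the reference's channel-to-channel
  structure, and if analyte-driven deviations were a large share of that
  structure, the estimated slope itself would become an analyte proxy
  and every structured channel would inherit a spurious, noiseless $y$
  correlation. With a dominant static matrix the ghost is negligible and
  band selection recovers the true fat bands (top-70 coverage ≥ 80% at
  the default noise, checked across seeds).
- **Scatter and noise.** Per-sample slope $a_i \sim 1 + N(0, 0.08)$ and
  offset $b_i \sim N(0, 0.03)$; observed $= a_i \cdot \text{ideal} +
  b_i + \varepsilon$ with $\varepsilon$ of sd 0.004 below 1500 nm and
  0.01 at and above it. At zero noise the per-sample least-squares fit
  of observed on ideal recovers $(a_i, b_i)$ exactly — the generator's
  own oracle.
- **Drift.** The online stream's drift is *heterogeneous and
  progressive*: each sample carries a stage $g$ that ramps 0 → 2 along
  the stream (jitter ± 0.2), scaling a spectral drift shape (flat shift
  0.2, tilt 0.7, and a broad curved band of amplitude 2.2 centered at
  1300 nm, deliberately non-collinear with the mean spectrum), shifts of
  the scatter-parameter means, and a −2 %-per-unit-stage analyte shift.
  Each element is there for a reason established during design: a
  perfectly homogeneous shape shift is absorbed exactly by any affine
  scatter correction (making a static reference look artificially
  perfect), and a drift collinear with the mean spectrum is removed by
  the MSC slope itself; only a large, sample-varying, non-collinear
  component reproduces the phenomenon the method exists for — statically
  corrected new-batch features that a linear model cannot use, against
  dynamically corrected ones that it can. The held-out prediction batch
  for streaming sessions is drawn at the newest stage
  ($g \in [1.6, 2]$), the deployment-relevant target
  (`generateNewBatch`).
- **What passing tests do not show.** The generator emulates smooth
  mixture spectra, affine scatter, heteroscedastic noise and trending
  batch drift. It does not model instrument line shapes, wavelength
  miscalibration, nonlinear detector response, or chemistry-driven
  nonlinearity between absorbance and composition. Results on it
  demonstrate the algorithms' mechanics and their relative ordering
  under drift — not absolute performance on any real instrument.

## Numerical choices and degenerate inputs

MSC slope floor $10^{-6}$ (flag, don't divide); constant reference is an
error; zero coefficient spread in UVE maps $C$ to signed infinity with a
warning (zero mean maps to 0); selection ties break to the lower index;
eigen monitoring symmetrizes its input within a $10^{-8}$ relative
tolerance and errors beyond it; `rplsUpdate` rejects non-finite inputs
and errors if a running variance hits zero; spectra files are written at
17 significant digits so write→read round-trips are bit-lossless and
repeated runs are byte-identical.

## Problem sizes in the test suite

Unit tests run on reduced grids (64 channels, 40 + 20 samples) chosen so
each property is exercised in seconds; the acceptance checks run the
full default study (512 channels, 120 + 75 samples, batches of 5, ten
seeds for the directional comparisons), the scale the package's claims
are stated at.

## Known limitations

The dynamic reference is a running mean over *all* samples seen, so
after $t$ stream samples it has moved only $t/(n_0+t)$ of the way toward
a new regime ($n_0$ = calibration count); under strong drift the online
model's error floor reflects that bounded tracking, and the final
$R^2$ on a severely drifted batch can remain modest even while RMSEP
improves by orders of magnitude over the frozen model. The forgetting
factor discounts the model's history but — by construction of the
recursions — not the reference's or the moments'. Single-response PLS
only; no SNV/derivative preprocessing; no automatic preprocessing
selection.
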