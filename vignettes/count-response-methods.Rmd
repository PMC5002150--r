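---
title: "Modeling PET image quality as a function of detected counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling PET image quality as a function of detected counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petiq)
```

## The problem

The noise in a PET image is governed by the number of detected coincidence
events, which scales with injected dose and scan time. If screening-type
protocols are to lower the injected activity, one needs to know how far the
counts can be reduced before lesion conspicuity (CNR), organ signal-to-noise
(SNR) and SUV quantification (bias, ensemble noise, reproducibility) degrade
past an acceptable level. `petiq` implements the count-response methodology
end to end: reduced doses are *simulated* from a single high-statistics
acquisition by randomly discarding list-mode events, so every count level is
measured on the same anatomy and the count axis is the only variable.

The package is organized around one pipeline:

1. **phantom** — synthesize digital thorax subjects (liver, lung background,
   spherical lung lesions, in SUV units) and full-statistics event streams;
2. **listmode** — thin (or bootstrap-resample) the stream to a schedule of
   count fractions, with R independent realizations per fraction;
3. **recon** — turn every realization into an SUV image (linear binning
   backend, or a 2D OSEM surrogate);
4. **voi** — delineate lesions by percent-of-SUVmax thresholding on the
   full-statistics image, build background shells by morphological
   dilation, place spherical organ VOIs;
5. **metrics** — SNR, CNR, bias, COV and STE per region, fraction and
   realization ensemble;
6. **models** — the sensitivity-corrected SNR²–counts line and the
   normalized CNR saturation curve;
7. **mincounts** — minimum counts needed to keep each error metric below a
   target percent level, per region, statistic and lesion-size subgroup.

## Statistical model of dose reduction

A full-statistics scan is represented as an ordered stream of events; true
events are drawn **multinomially over voxels with probability proportional
to the activity (SUV) map, with a fixed total** equal to the subject's net
true count. The fixed-total convention makes "counts in the scan" — the
x-axis of every analysis — exact rather than Poisson-fluctuating, while
per-voxel counts remain asymptotically Poisson for the statistical
properties that matter downstream. Random coincidences, when requested, are
appended at a configurable randoms fraction, distributed uniformly over the
occupied field (they carry no spatial structure; hardware delayed-window
estimation is out of scope).

A reduced dose at fraction $f$ is simulated by retaining every event
independently with probability $f$ (binomial thinning); trues and randoms
are thinned by the same procedure. The retained count is
$\mathrm{Bin}(N, f)$, so realized counts fluctuate around $fN$ — this is
deliberate, and matches how counts behave when the dose itself is reduced.
A bootstrap resampler (draw $\lfloor fN \rceil$ events with replacement) is
provided as an alternative; the fitted count-response coefficients are very
close under either resampler. Sub-seeds for the realization ensembles are
derived deterministically from (master seed, fraction index, realization
index), so any single realization is reproducible in isolation.

### Realizations from one parent are not independent

All realizations at one fraction are thinned from the *same* parent stream.
For a voxel with parent count $\lambda$, the across-realization covariance
of retained counts is $f^2\lambda$, so the voxelwise variance of the mean
image over $R$ realizations is

$$\mathrm{Var} = \lambda\left(\frac{f(1-f)}{R} + f^2\right),$$

not $\lambda f(1-f)/R$: the parent's own noise is "frozen" into every
realization and does not average out. Consequently liver
$\mathrm{SNR}^2$ on the mean image is proportional to counts **only where
$Rf \ll 1$**; at larger fractions it bends below the line. This is exactly
why the per-subject sensitivity factor is estimated on a restricted count
range (`estimate_ki(count_range = ...)`), mirroring the observation that
the proportionality regime must be selected before fitting. The default
desk-scale fraction schedule (`run_config()`) therefore uses the five
smallest fractions of the standard ten
($1.67\times10^{-2}$ down to $5\times10^{-4}$), for which the correction
term biases the pooled slope by under 3%.

## Reconstruction backends

**Binning backend.** Each voxel value is (event count) × calibration. It is
linear in the stream, so its statistical behavior is exactly predictable —
it is the oracle backend for the count-response analyses. Calibration is
anchored so that the full-statistics liver mean equals the phantom's liver
SUV; a reduced-fraction image uses the reference calibration divided by the
nominal fraction (dose and counts scale together, and SUV normalizes by
dose), which makes SUVmean bias at fraction 1 exactly zero by construction.

**OSEM surrogate.** A 2D parallel-beam geometry with an explicit sparse
system matrix (pixel-driven, linear interpolation between radial bins; the
back projector is the exact adjoint). OSEM uses multiplicative updates over
interleaved angular subsets in fixed order (3 iterations × 21 subsets by
default), a uniform positive initialization, optional Gaussian PSF blurring
in the projector, and a 5 mm Gaussian post-filter applied after the last
iteration (FWHM/σ conversion $2\sqrt{2\ln 2}$, kernel truncated at
$3\sigma$, renormalized at edges). The surrogate reproduces the *regime*
properties of clinical OP-OSEM — positivity, positive bias in cold regions
at low counts, super-linear SNR² loss — without attempting vendor-matched
quantification; attenuation, scatter and randoms corrections are outside
its scope, and the grid is configurable isotropic rather than a particular
scanner's.

## VOIs and metrics

Lesions are delineated **once on the full-statistics image** and the masks
are copied to all reduced-count images. The mask is the 26-connected
component, containing the local maximum reached from a user seed, of voxels
at or above `pct`% of that maximum (default 40%); the mask is provably
monotone in `pct`. Because the linear binning backend produces unsmoothed
images, delineation operates on a 5 mm Gaussian-smoothed view of the
reference (matching the clinical post-filter); without it, threshold
segmentation percolates through voxel noise. Lesions whose contrast is too
low to segment (threshold below the lung background floods the field) are
dropped, as they would be in practice, and would not survive the CNR ≥ 2
inclusion filter anyway.

The background shell is dilation(lesion, 2 voxels) minus the lesion, with a
Euclidean ball as the structuring element (a Chebyshev cube — two iterated
unit dilations — is available by flag; a bare "2-voxel dilation" does not
by itself determine the element). In the threshold-sensitivity protocol
(20/40/60/80%), the shell from the 20% mask is reused for all four
thresholds.

Metric conventions, chosen deliberately:

* Spatial SD within a VOI uses the **population divisor** $N_{VOI}$;
  SNR = mean/SD on the ensemble mean image.
* Across-realization SD (SD image, STE) uses the **sample divisor** $R-1$,
  because $R = 10$ is small; this is a documented deviation from the
  population convention used for the spatial SD.
* COV is SD/mean × 100, the universal coefficient-of-variation definition,
  matching its role as ensemble noise; some formulations of this metric
  write the ratio the other way up, so the inverted orientation is
  available with `inverse_ratio = TRUE`.
* Bias metrics enter the minimum-counts analysis by magnitude.
* SUVmax ties are resolved by value only; locations are never compared.

The default liver region for cohort fits is the phantom's anatomical liver
mask rather than a 3 cm sphere: ground truth is available in simulation and
the larger homogeneous VOI stabilizes the spatial-SD estimate behind the
SNR² fits at desk-scale counts. The conventional 3 cm sphere is kept
alongside (`liver_sphere`), and the clear-lung region is a 3 cm sphere.

## Count-response models

Per subject, the composite sensitivity factor $K_i$ (lumping the
proportionality constant, reconstruction noise-reduction factor, scanner
sensitivity and attenuation, which grows monotonically with weight —
modeled as $e^{0.012\,m}$, though only monotonicity matters since $K_i$ is
estimated empirically) is the **through-origin slope** of liver SNR² on
counts in units of $10^6$, over the proportional count range. Dividing a
subject's SNR² by $K_i$ pools all subjects onto a common line of slope ~1;
the pooled line is refitted with a free intercept, so any residual offset
is visible rather than absorbed.

Normalized lesion CNR (CNR at a count level divided by CNR at full
statistics, lesions filtered to volume ≤ 20 ml and CNR ≥ 2) is fitted with
the heuristic saturation curve

$$y = \frac{1}{1 + a\,x^{-b}}, \qquad x = \text{counts}/10^6,$$

by Levenberg–Marquardt least squares started from the best point of a small
$(a,b)$ grid (multi-start guards against the shallow valley in $b$). No
interpretative model is claimed for this curve; it is a prediction device.
With the cohort-fitted pair $(a,b) = (2.41, 0.8)$ it evaluates to 0.60 at
$x = 5$: five million counts retain 60% of full-statistics CNR. The
closed-form inverse $x = (a/(1/y-1))^{1/b}$ answers "how many counts for a
target CNR fraction"; $y \ge 1$ is rejected (the curve saturates at 1).
$R^2$ is computed identically for linear and nonlinear fits
($1 - SS_{res}/SS_{tot}$, $SS_{tot}$ about the mean).

## Minimum-counts analysis

For one case (a subject–region–statistic series across count levels) and an
allowed error level $p$, the required counts $N^*$ is the smallest level at
which the metric is ≤ $p$ **and stays ≤ $p$ at every higher available
level** — a guard against non-monotone noise in the series. Cases that
never meet the level are censored and reported separately ("above max
level"); the analysis of the per-case distribution reports its mean, median
("half of the cases") and maximum, computed over the set of cases that meet
*every* requested level, so all three summary curves are non-increasing in
$p$ by construction. The exceedance histogram bins $N^*$ at $10^6$-count
width for display; its mean/max summaries are computed on the $N^*$ values
themselves (bin-center weighting would shift the mean by half a bin).
Lesion cases carry their volume, and `subgroup_curves()` splits them at
5 ml — a lesion exactly at 5 ml goes to the large group, consistent with a
small-lesion group that tops out below 5 ml.

## What the synthetic cohort does and does not emulate

`sample_cohort()` draws weight uniform on 45–79 kg, liver SUVmean
N(1.57, 0.40) truncated positive, lesion SUVmean N(1.92, 0.95) truncated at
0.5, lesion volumes uniform on 1.2–17.58 ml, injected dose N(168.6, 50)
truncated to 118–260.5 MBq, and full-statistics net trues
N(1.32 × 10⁸, 3.91 × 10⁷) truncated positive — the cohort summary
statistics the generator is parameterized by, with uniform distributions
where only a range is available and truncation bounds as stated here. The
lung background SUV is a package choice (0.5, configurable).
Phantoms are geometric (cylindrical body, spherical liver and lesions):
no respiratory motion, no scatter, no anatomical texture. Passing tests on
this cohort therefore demonstrate the *statistical machinery* — count
scaling, ensemble metrics, fitting, minimum-counts logic — not clinical
values; patient-derived thresholds (which depend on a particular cohort)
are intentionally not targeted.

## Problem sizes and numerical choices

Desk-scale defaults: a 64³ grid at 4 mm isotropic voxels, cohort count
scale 0.02 (≈2.6 × 10⁶ events per subject at full statistics), the five
smallest fractions of the standard schedule, 10 realizations per fraction.
A 16-subject cohort study at these sizes runs in about two minutes on one
CPU; the full 10-fraction schedule at scale 1 is supported but is a
cluster-sized job. Degenerate inputs are handled explicitly: zero-SD VOIs
flag SNR/CNR as infinite sentinels rather than erroring; a zero-count
sinogram reconstructs to a zero image with a warning flag; empty fraction
schedules, out-of-grid events, clipped spheres and boundary-clipped shells
are rejected with messages.

## Known limitations

* The 2D OSEM surrogate is a regime model, not a scanner model; absolute
  SUV bias magnitudes at low counts are not transferable.
* Ensemble realizations share a parent stream; fits must respect the
  proportional regime (above).
* The rasterized sphere volume on coarse voxels systematically exceeds
  $(\pi/6)d^3$ (lattice overcount: a 30 mm sphere on 4 mm voxels holds 251
  voxels = 16.1 ml against 14.1 ml analytic); volumes converge as voxels
  shrink and all volume filters operate on rasterized volumes consistently.
* Manual reader adjustment of lesion VOIs is replaced by the
  seed-component restriction.
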