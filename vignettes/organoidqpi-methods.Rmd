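---
title: "Methods: label-free organoid characterization with organoidqpi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free organoid characterization with organoidqpi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoidqpi)
```

## What the package models

`organoidqpi` implements an analysis pipeline for label-free imaging of
neural organoids by quantitative oblique back-illumination microscopy
(qOBM).  In qOBM, four LEDs (720 nm) arranged 90 degrees apart around the
objective illuminate the sample in epi-mode; multiply-scattered photons
form a virtual oblique source below the focal plane, so refractive-index
(RI) gradients modulate the collected intensity.  Subtracting frames from
opposing sources gives two orthogonal differential phase contrast (DPC)
images, and deconvolution with the system's phase transfer function
recovers quantitative phase.  Phase converts to RI contrast through

$$\Delta n = \frac{\lambda\,\Delta\phi}{2\pi\,\Delta z},$$

where $\Delta z$ is the effective optical section thickness and the
surrounding medium has $n_m = 1.3440$.  Material with $n \ge 1.46$ —
lipid droplets, membranes, dense nucleic material — is segmented by
thresholding.  Downstream, the pipeline quantifies whole-organoid
morphology, neural-rosette geometry, tile-wise image features, and
control-vs-experimental group contrasts over a multi-week culture with a
mid-study switch to neuronal differentiation medium.

Because no public image data accompany this kind of study, the package is
organized around a synthetic phantom generator whose ground truth is
recorded exactly: every quantitative claim a test makes is checked
against construction.

## The phantom generator and the study conditions it emulates

`phantom_spec()` describes one 2-D organoid section: an elliptical body
(cytoplasm, RI 1.370) containing

* **rosettes** — disks of nucleus-dense tissue (RI 1.390) with an
  interior lumen at medium RI, optionally offset from the rosette center;
* **fissures** — quadratic-Bezier clefts at medium RI, flanked within a
  12 um band by **directional cells**: aligned ellipses (default 8 um
  long, aspect 2.5) at a configurable surface density;
* **droplets** — high-RI (1.500) disks of 4–8 um diameter placed until a
  target area fraction is met (the last droplets are sized to the
  remaining area, so realized fractions track the target to ~1–2%).

Phantoms are single focal planes: reconstruction and all metrics operate
per-plane, so a z-stack is represented as independent sections.

`cohort_spec()` emulates the two-group longitudinal design: control and
experimental organoids imaged weekly (default 6 + 6 organoids, weeks 1–4,
switch after week 2).  Trends are multiplicative weekly rates applied to
the generator's ground truth after the switch: control directional-cell
retention 0.5/week versus experimental 1.0 (directional phenotypes vanish
in controls but persist in the disease model); droplet-fraction growth
1.2/week (control) versus 1.5/week (experimental); rosette retention 0.6
versus 1.0.  Before the switch both groups share one trajectory
(droplet growth 1.1/week), which makes pre-switch contrasts null by
construction — the calibration the false-positive checks rely on.  These
rates are the package's fixed emulation conditions, chosen to reproduce
the qualitative patterns of the study design (rapid post-switch decline
of directional phenotypes in controls; faster lipid accumulation in the
experimental group) at effect sizes a 6-vs-6 weekly comparison can
resolve.

Cohort phantoms default to 192 px at 2 um/px (384 um field) rather than
the full 720 um field of a 20X acquisition; the structures scale with
physical units, so this only reduces the tile count per organoid (49
tiles of 50 um).  The standalone phantom default is 512 px at 1 um/px.

What the phantoms deliberately do **not** model: 3-D light transport and
multiple scattering (the forward model is the same linear transfer
function the reconstructor inverts, plus a 10%-cutoff-mismatch variant to
avoid testing only the inverse crime), optical aberrations, stage drift,
and histology sectioning artifacts.  Passing tests therefore demonstrate
correctness of the analysis chain under its stated forward model, not
instrument-level validity of absolute phase.

## Image formation and reconstruction

The per-axis transfer function is $H_j(k) = i\,g\,(\hat s_j \cdot \hat
k)\,A(|k|)$ with a raised-cosine envelope $A$ cutting off at the
partially coherent limit $2\,\mathrm{NA}/\lambda$ and $A(0)=1$; $H$ is
purely imaginary and odd, and the Nyquist bins are zeroed so the impulse
response is exactly real.  The DPC gain default $g = 0.25$ rad$^{-1}$
keeps simulated frame intensities positive for the phantom's phase range
(droplets reach $\approx 3.4$ rad at $\Delta z = 2.5$ um).  Frames are
$I_\pm = I_0(1 \pm \mathrm{DPC})$ plus Gaussian noise at a configured
SNR (default experiments use 20 dB); Poisson noise is available.

Reconstruction is Tikhonov-regularized least squares over both DPC
channels; because the two obliquity axes are orthogonal,
$\sum_j |H_j|^2 = g^2 A^2$ with no angular nulls, and only the DC
component is unobservable.  The additive phase constant is fixed by
zeroing the median of an 8-px border band (the medium), which is what
makes $\Delta\phi$ absolute with respect to $n_m$, as the RI conversion
requires.  The default $\beta = 7\times10^{-3}$ sits near the Wiener
level for 20 dB acquisitions (DPC noise power over typical in-band
signal power): small enough that high-RI droplet edges blur by well
under one droplet radius, large enough to keep deconvolution noise from
dominating the phase error budget.  Round-trip error grows monotonically
with $\beta$, and the noiseless round trip at $\beta = 10^{-6}$
reconstructs to well under 1% RMSE of the phase range.

The RI threshold is applied to absolute $n \ge 1.46$ by default (the
equivalent $\Delta n \ge 0.116$ form is available via `on = "delta"`),
since a RI *difference* of 1.46 is not physically meaningful for
cellular material in a 1.344 medium.  $\Delta z$ is not a measured
quantity here; it is exposed in `optical_config()` (default 2.5 um) and
used self-consistently by the simulator and the analysis, so segmentation
results do not depend on its exact value.

## Tile features

Images are subdivided into 50 um tiles (full tiles only).  Four families
are computed per tile:

* **Texture** — gray-level co-occurrence features (contrast, energy,
  homogeneity, correlation, entropy) on a symmetric matrix averaged over
  the four 1-px offsets, after quantization to 32 levels across the
  robust 1–99% intensity range.
* **Fractal / morphological** — box-counting dimension over a size
  ladder that prefers exact divisors of the (foreground-cropped) extent,
  avoiding partial-box bias; band-limited dimensions restricted to box
  sizes of 5–9 um and 17–23 um (the scales of the oblong directional
  cells); a curvilinear pattern score for 4–8 um structures (area kept by
  a 6 um line opening in its best of four orientations but removed by the
  6 um disk opening); and a circular pattern score (area fraction
  surviving a disk opening of 36 um^2, matching droplet cross-sections of
  34–38 um^2).
* **Fourier** — Hann-windowed band powers partitioning the spectrum at
  periods 23, 17, 9 and 5 um (they sum to the windowed variance by
  Parseval), spectral orientation anisotropy (angle-doubled resultant
  length), and the dominant frequency/orientation.
* **Autocorrelation** — normalized via the Fourier method; correlation
  length as the 1/e radius of the azimuthal mean; anisotropy as
  $1 - \text{minor}/\text{major}$ of the moment ellipse of the supra-1/e
  region (the moment form is used because direct directional radii are
  upward-biased when the correlation is near a delta, as in white noise).

Binarization for the fractal family uses a robust local rule, foreground
$>$ median $+\,2\,$MAD.  A per-tile Otsu split (available as
`binarize = "otsu"`) misbehaves on the many tiles that contain only
cytoplasm: forced to split unimodal noise, it produces dense speckle that
dominates the morphological scores.  The MAD rule leaves such tiles
nearly empty while cells and droplets sit several MADs above background.
Otsu remains the right choice for genuinely bimodal inputs (the fixture
calibrations use it), and for degenerate flat tiles the features are
zero with an `empty` flag.

A known limitation: on 50 um tiles the 17–23 um box sizes admit only
2–3 boxes per side, so the coarse band dimension is heavily quantized;
the curve/circle pattern scores, not the coarse band dimension, carry the
discriminative weight in the trend analyses.

## Feature selection and statistics

Rankings: greedy mRMR (MID difference scheme; MIQ optional) on
equal-frequency 8-bin discretizations; neighborhood component analysis
(gradient ascent on expected leave-one-out accuracy with per-feature
weights, weighted L1 metric, L2 penalty defaulting to $1/n$, step-halving
line search, standardized inputs so raw scaling cannot change the
ranking); and chi-square on bin-by-class contingency tables.  All
tie-breaks are lexicographic on feature name, so rankings are
deterministic.  The consensus is the union of each method's top-$k$
(default 150) with per-method ranks retained.

Group comparisons are the two-tailed unpaired Welch t-test and the
variance F-test with two-tailed convention
$p = 2\min(\mathrm{CDF}, 1-\mathrm{CDF})$; the convention is fixed and
documented here because mixed conventions are common in published
per-figure statistics.  Tiles are averaged within organoid before
testing, so the organoid is the experimental unit.  No multiple-testing
correction is applied by default (per-week raw p-values are the
reported quantity); Benjamini–Hochberg is available via `adjust_bh()`.
The test suite checks both tests against an independent
incomplete-beta/binomial-sum oracle to 1e-8.

## Histology quantification

Oil-Red-O images convert to optical density ($-\log_{10} I/I_0$, zero
intensities clipped to one count with a flag), are unmixed with the
standard FastRed/FastBlue color-deconvolution vectors (third vector:
normalized cross product, kept as a residual QC channel), thresholded
(Otsu within tissue by default — the original protocol does not publish
its threshold), and counted as 8-connected components of at least 4 px,
with an optional closing.  Both the component count and the
tissue-normalized positive-pixel fraction are reported, since "particle
count" is ambiguous between the two.

## Numerical and design notes

* Seeds: every generator routes randomness through a private RNG stream;
  identical spec + seed is bit-identical.  The pipeline derives stage
  seeds as `seed + stage index` so stages are individually reproducible.
* The 20X field is taken as 720 um square at analysis defaults (the
  alternative "850 um^2" figure quoted in some protocol text is
  inconsistent with a 720 um x 720 um image and is not used).
* Perimeters use the coarea formula on a Gaussian-mollified mask
  (sigma = 1 px): rasterized disks score circularity $\ge 0.99$ while a
  100x50 rectangle stays near its analytic 0.698, which pixel-edge
  counting cannot do.  Circularity and solidity are clamped at 1.
* Aspect ratio comes from second central moments (+1/12 per-pixel
  variance), giving exactly 2.0 for a 100x50 rectangle.
* Lumen centeredness is reported in um and normalized by the rosette
  equivalent radius; group comparisons should prefer the normalized form
  to remove the rosette-size confound.
* Problem sizes used by the automated checks: 512 px reconstruction
  phantoms; 256 px droplet-recovery phantoms (fractions 0.01/0.05/0.10,
  10 seeds each); 10 emulation cohorts and 20 null cohorts of 48 phantoms
  at 192 px; selection benchmarks with n = 200, 50 features, 20 seeds.

## A worked example

```{r example, eval = FALSE}
ph <- generate_organoid_phantom(phantom_spec(seed = 1))
raw <- simulate_qobm_acquisition(ph, acquisition_spec(snr_db = 20), seed = 1)
rec <- reconstruct_phase(compute_dpc(raw), phase_transfer_model(), recon_config())
seg <- segment_high_ri(phase_to_ri(rec), organoid_mask(ph))
seg$area_fraction          # compare against ph$droplet_fraction

res <- run_pipeline(run_config(seed = 1), output_dir = tempfile())
subset(res$analyze$per_week, feature == "curve_pattern_4_8um")
```
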