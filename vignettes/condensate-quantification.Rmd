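---
title: "Quantifying biomolecular condensates: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biomolecular condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensr)
```

## The measurement problem

Biomolecular condensates are micrometre-scale, membraneless assemblies
formed by liquid–liquid phase separation. A typical characterization
campaign combines five kinds of quantitative readout, and `condensr`
implements each as a separate module behind a common set of containers
(`image_frame`, `cell_mask`, `condensate_set`, `frap_trace`,
`titration_series`, `spectrum1d`):

1. morphometry of bright near-circular objects in cell images and in
   in vitro droplet fields;
2. enrichment and pixel-wise co-localization of proteins in the
   detected objects;
3. exchange kinetics by fluorescence recovery after photobleaching
   (FRAP);
4. dependence of condensate formation on a regulator concentration
   (here Ca²⁺), summarized by a Hill-model affinity, plus conventional
   one-site binding isotherms;
5. two-state conformational populations from slow-exchange NMR
   doublets.

Because raw microscopy data are bulky and often unavailable, every
module is paired with a synthetic generator that produces its input
with exact ground truth. The generators are first-class, tested code:
all validation in this package is parameter *recovery* — generate at
known truth, analyze, compare.

## Detection

**Cell segmentation.** Otsu's threshold on the intensity histogram,
hole filling, and removal of components below `min_cell_area_um2`
(default 20 μm²). A constant image has no histogram structure and is
rejected explicitly. Whether thresholding for condensate detection is
then applied per cell or per image is a genuine design fork; we
threshold **per cell**, since expression levels (and hence background
and noise) vary strongly between cells. This is exposed by the fact
that detection parameters act within each cell label.

**Condensate detection.** Within each cell the local background is the
grayscale morphological opening with a disc of radius
`local_bg_radius_um` (default 1 μm, comfortably larger than the
objects). Two numerical details matter:

* Out-of-cell pixels are raised to the in-cell median before the
  opening. Otherwise the structuring element cannot fit into
  high-curvature cell tips, and the clipped background there
  masquerades as bright objects.
* The opening residual (a top-hat) is non-negative and carries a
  pedestal wherever the background texture varies on scales comparable
  to the structuring element, so candidate pixels are those more than
  `k_sigma` robust standard deviations (MAD) **above the residual's
  median**, not above zero. With exactly zero noise the MAD collapses;
  a floor of 2% of the image-wide residual maximum then keeps object
  supports from bleeding along their faint smooth skirts.

Connected components are filtered on area (0.05–20 μm²) and on
circularity 4πA/P² ≥ 0.4, defaults chosen to admit sub-micrometre foci
while rejecting elongated tubule fragments; all are configurable
(`condensate_params()`). The perimeter uses the 4-direction Crofton
(discretized Cauchy–Crofton) estimate, because raw pixel-boundary
perimeters overestimate P for small objects and would bias circularity
low; measured circularity is clipped at 1. On rendered discs the
estimate gives circularity ≥ 0.9.

**Droplet detection.** A gradient-vote circular Hough transform: Sobel
edge pixels vote at distance r along their gradient (which points
toward the centre of a bright droplet) for every candidate radius on an
integer grid; per-radius accumulators are pooled over 3×3
neighbourhoods; peaks are thresholded **in absolute votes** (default:
the circumference of the smallest searched radius) so that runs are
reproducible across image sizes, then reduced by non-maximum
suppression on the centre distance. The radius is refined as the
vote-weighted mean over radius bins scoring at least half the best bin.
On noiseless fields detection is exact (count, centres within 1 px,
radii within 1 px); at a peak signal-to-noise ratio of 10, recall and
precision stay above 0.95 on the test fields.

## Enrichment, co-localization, profiles, statistics

The condensed fraction of a cell is the integrated intensity over
detected condensate pixels divided by the integrated intensity over all
cell pixels; condensed and dispersed fractions sum to one by
construction and are invariant to global intensity rescaling. When
absolute enrichment matters, the image should be background-subtracted
first (the detection module's background estimate can be reused);
otherwise the dispersed pool is inflated by camera offset.

PCC is computed within the cell mask, per cell and pooled. We use plain
Pearson correlation with no automatic thresholding: auto-threshold
variants (e.g. Costes) change the estimand, and per-cell PCC values are
the common reporting unit. Computing PCC on whole images instead would
mix inter-cell expression differences into the correlation; this is the
main divergence risk when comparing against numbers produced by other
tools.

Line profiles sample channels by bilinear interpolation along a
segment, averaged over parallel lines, with distances in μm.

The Mann–Whitney U test enumerates all group assignments exactly for
combined n ≤ 12 and otherwise uses the normal approximation with tie
correction and a 0.5 continuity correction. The crossover is cheap to
enumerate below 12 and the approximation is within 0.02 of the exact
p-value by n₁ = n₂ = 10, the regime of typical per-cell comparisons.
The t-test is the pooled-variance Student form by default (Welch
optional), with explicit handling of zero-variance degeneracies.

## FRAP

The trace model has a prebleach plateau, an instantaneous bleach at a
frame boundary, and exchange-limited recovery

I(t) = I_post + m·(I_pre − I_post)·(1 − 2^(−t/t½)),

with the recovery clock zero at the first postbleach frame (that frame
reads exactly the bleach depth). Normalization modes: background
subtraction followed by division by the mean prebleach intensity
(plateau ≡ 1); mapping the first postbleach point to 0% and the
prebleach mean to 100%; or double normalization against a reference
region to correct acquisition bleaching. Fits use
I(t) = I₀ + A·(1 − e^(−kt)) (single phase, default) or a two-term sum
for two-phase recoveries (fast diffusion phase plus slow exchange
phase); t½ = ln 2/k is taken on the dominant-amplitude term. The rate
is initialized from a log-linear regression of (plateau − I) with the
plateau guessed as the mean of the last 10% of frames; this makes
noiseless fits recover generating parameters to ~10⁻⁶ and avoids
manual starting values. Traces whose initial recovery amplitude is
below 2% of the bleach depth are reported as immobile (t½ undefined)
rather than fitted.

The conversion to an apparent diffusion coefficient uses the
uniform-disk spot-photobleaching approximation D = γ·w²/t½ with
γ = 0.224. The bleach-spot radius w is user-supplied and is the single
largest source of systematic uncertainty in D: reported D values should
be read as conditional on the assumed geometry (for w ≈ 1.18 μm a 78 s
half-time maps to 4 × 10⁻³ μm²/s).

## Binding

**Hill model.** nc(c) = nc_min + (nc_max − nc_min)/(1 + (K_D/c)ⁿ),
defined at c = 0 by continuity as nc_min. Fits run on the individual
per-field counts, not per-concentration means, weighting fields equally
(a Poisson weighting option exists); this keeps the information content
of unequal field numbers per concentration. The Hill coefficient is
constrained to (0.3, 12] and a fit pinned at the boundary warns.
`nc_min` is bounded below by 0 — a count baseline cannot be negative —
and left free by default, with `fix_nc_min = 0` available since
droplet-count titrations often show no droplets below the transition.
When the free fit lands on the nc_min = 0 boundary, the remaining
parameters are re-optimized with nc_min fixed there, because bounded
Levenberg–Marquardt steps can stall on an active constraint.
Initialization follows the data: extreme per-concentration means for
nc_min/nc_max, the concentration nearest the midpoint count for K_D,
n = 2.

**One-site isotherms.** The response interpolates free → bound by the
exact bound fraction from the quadratic in total concentrations,
f_b = (L + T + K_D − sqrt((L + T + K_D)² − 4LT))/(2L). This is exact at
any labeled concentration L; note that because binding depletes free
titrant, f_b lies *below* the hyperbola T/(T + K_D) in total titrant
and reaches it only as L → 0. Fits flag two failure modes instead of
reporting a bare number: `extrapolated` (fitted K_D outside the tested
titrant range — the transition was not spanned) and `stoichiometric`
(labeled concentration above the fitted K_D — a titration regime where
K_D is poorly determined). The kd start value is laddered over several
scales because the response surface flattens in K_D in the
stoichiometric regime.

**Bootstrap.** Uncertainties come from case-resampling percentile
bootstrap (fields within concentration for titrations, points for
isotherms), seeded and deterministic, erroring out if more than 20% of
resample fits fail.

## NMR populations

In slow exchange each conformation contributes a separate resonance
whose area is proportional to its population, so per-residue
populations are area ratios p_P = A_P/(A_P + A_O), averaged over
residues with their s.d. Areas come from direct trapezoidal
integration, not lineshape fitting — linewidths may differ between
exchange-broadened states, and fitting would import lineshape
assumptions. A peak-height estimator is provided for comparison; on
clean resolvable doublets the two agree to within ~2 population points.

Numerical choices: the integration window is symmetric about the peak
with a constant baseline taken as the median of the two flanking
regions of equal width; for doublet analysis the default half-window is
half a linewidth. The narrow window plus flank-median baseline keeps
the partner peak's Lorentzian tail from leaking across: at the default
doublet design (separation four linewidths) the estimator's bias is
below one population point even at a 93:7 equilibrium, whereas wide
windows without baseline correction bias a 93:7 doublet toward 88:12.
Lorentzian tails die slowly — a ±20-FWHM window still misses 1.6% of
the analytic area (πhΓ/2) — but truncation cancels exactly in the
ratio, which is what the population estimate uses. Overlapping doublets
(separation under two linewidths) are rejected rather than deconvolved,
mirroring the restriction of such analyses to non-overlapping residues.
Populations are invariant to intensity scaling and to the axis unit
(Hz vs ppm).

## The synthetic generators: what they emulate, and what not

* `sim_cell_field()` renders elliptical cells with a smooth
  multiplicative "ER-like" texture (Gaussian random field, correlation
  length ~0.8 μm at the default pixel size), condensates as
  radially-symmetric Gaussian-smoothed discs (integral
  I·π(R² + σ²), recorded per object), additive Gaussian camera noise.
  Per-cell counts are negative binomial (Poisson-like with overdispersion
  across cells), or exact on request. Condensate intensity above
  background is a free parameter: published cell images rarely report
  it, so the default (peak 400 over background 100, noise σ 10) was
  chosen once as a realistic mid-SNR regime.
* `sim_droplet_field()` renders non-overlapping smooth-edged circles by
  rejection sampling (erroring with the retry cap when packing is
  infeasible).
* `sim_titration()` draws Poisson counts around the Hill mean — counts
  are the observable, so Poisson is the natural noise model.
* `sim_frap_trace()` uses single-exponential exchange-limited recovery
  (optionally two-phase), instantaneous bleach at a frame boundary, and
  additive Gaussian noise.
* `sim_nmr_doublets()` sums two equal-width Lorentzians with area ratio
  p_P : 1 − p_P plus white noise at a stated SNR.
* `sim_isotherm()` evaluates the exact one-site response over a
  geometric serial dilution with Gaussian response noise.

Not emulated: realistic ER tubule geometry, optical point-spread
functions, fission/fusion dynamics, detector offset/gain structure,
spectral baseline roll. Passing recovery tests on these synthetics
therefore demonstrates correctness of the estimators under their
stated models — not robustness to every artifact of real microscopes
and spectrometers.

## Problem sizes and determinism

All generators are bit-reproducible under a fixed seed, and the
pipeline driver (`run_pipeline()`) records the seed, parameters and
output checksums in a manifest. The standard validation runs use
512² or smaller images, 100-seed Monte-Carlo ensembles for FRAP, Hill
and isotherm recovery, and 50-seed ensembles for NMR populations —
sizes chosen so the entire suite re-runs in about a minute on a laptop
while holding Monte-Carlo error well below the tolerances being
checked.

## Known limitations

* Detection is 2D; stacks are treated frame-by-frame and objects are
  not tracked through time.
* The Hough accumulator searches an integer radius grid; radii are
  refined by vote weighting but very broad radius ranges dilute votes.
* The diffusion conversion assumes a uniform circular bleach spot.
* Enrichment depends on the detection mask; systematically missed dim
  condensates bias the condensed fraction low.
* The exact Mann–Whitney enumeration is combinatorial; the default
  crossover (combined n = 12) should be raised only deliberately.
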