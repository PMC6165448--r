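---
title: "Non-destructive quality assessment of ham cold cuts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-destructive quality assessment of ham cold cuts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hamqa` implements a three-channel, non-destructive quality assessment of
ham cold cuts — digital image texture, CIELAB colorimetry, and mid-infrared
(FT-IR) band intensities — together with the statistical machinery used to
turn those measurements into class discriminations (meat type and
processing) and shelf-life statements (refrigerated storage over three
weeks, sampled every three days). Because no instrument data ship with the
package, a synthetic-data module generates images, colour readings and
spectra whose statistics match the documented class parameters; every stage
of the pipeline is exercised and tested against that generator.

This vignette is the package's account of its models, parameter choices and
known limitations.

## The feature model

Each ham slice is represented by a fixed, ordered 28-slot feature vector
(`ham_feature_names()`):

* **4 first-order statistics** of the grey-level histogram — mean, standard
  deviation, skewness, kurtosis. These are population moments; kurtosis is
  *raw* (a normal histogram scores 3, not 0). On a constant image the sd is
  zero, skewness and kurtosis are undefined and propagate as `NA`; such
  patterns are rejected from classification with a warning rather than
  silently zero-filled.
* **13 co-occurrence (Haralick) features** — angular second moment,
  contrast, correlation, sum of squares, inverse difference moment, entropy,
  sum entropy, sum average, sum variance, difference variance, difference
  entropy, and the two information measures of correlation. Entropies use
  log base 2 (a scale choice only; discrimination is unaffected). Sum
  variance is taken about the sum average, and grey levels enter the
  moment-type features at their 0-based values.
* **5 run-length features** — short- and long-run emphasis, grey-level
  nonuniformity, run-length nonuniformity, run percentage.
* **6 colour parameters** — L\*, a\*, b\* from a colorimeter plus derived
  chroma $C^* = \sqrt{a^{*2} + b^{*2}}$, hue angle
  $h = \operatorname{atan2}(b^*, a^*)$ in degrees wrapped to $[0, 360)$, and
  the CIE76 colour difference
  $\Delta E^* = \lVert (L^*,a^*,b^*) - \mathrm{ref} \rVert_2$ against a
  white calibration plate (97.83, −0.45, +1.88) by default.

### Texture conventions the source material leaves open

The quantization depth, co-occurrence offset, direction handling and region
of interest are not dictated by the measurements themselves, so the package
fixes conventions and documents them:

* **Quantization**: co-occurrence and run-length matrices are computed at
  `G = 32` levels (uniform binning from 256). 32 levels keep a 32×32
  matrix statistically filled for the ~10^4–10^5-pixel regions the package
  processes; first-order statistics always use the full 256 levels.
* **Offset and directions**: distance `d = 1`, the four standard directions
  {0°, 45°, 90°, 135°} accumulated into one symmetrized, normalized matrix
  (the classic convention). Run-length features are computed per direction
  and averaged. With all four directions the 22-feature vector is invariant
  under 90° image rotation — a tested property.
* **ROI**: callers may crop to a central rectangle (`crop_center()`,
  default fraction 0.6 in `texture_config(roi_frac = )`) to exclude
  background around a photographed slice. Synthetic images have no
  background, so the generator pipeline computes on the full frame.

A consequence worth stating plainly: since these are conventions, *absolute*
texture-feature values are not comparable with any instrument-specific
report; only orderings and trends are, and the tests assert exactly those.

## Colour: what is reproducible and what is not

Chroma and hue recomputed from the documented class mean a\*, b\* agree with
the documented class means within 1.5 % relative error for four of the five
classes; the boiled-pork row is internally inconsistent with its own a\*,
b\* means (13.02 / 36.66 printed vs 14.35 / 32.65 recomputed) and is
excluded from that check. The documented ΔE\* column is *not* reproducible
from the printed L\*, a\*, b\* under CIE76 against the stated white plate
(boiled turkey: 45.59 reported vs 33.12 recomputed); the reference or
formula actually used by the instrument is unstated. The package therefore
computes ΔE\* under the documented default (CIE76, white plate), makes the
reference configurable, and records the mismatch instead of guessing a
hidden convention.

## Spectra: band extraction

A spectrum is a strictly monotone wavenumber series (nominally 4000→500
cm⁻¹ at 4 cm⁻¹ resolution) with absorbances. The band registry
(`ftir_bands()`, a plain CSV under `inst/extdata/`) lists the fifteen
diagnostic regions plus two auxiliaries (717 cm⁻¹ unsaturation marker,
1083 cm⁻¹ symmetric P=O). Choices:

* **Intensity = window maximum**, not integral: the documented intensities
  are on peak-absorbance scale (0.01–0.15 AU). Single-wavenumber regions
  expand to ±8 cm⁻¹ (twice the nominal resolution).
* **Baseline**: optional linear subtraction anchored at 3800 and 520 cm⁻¹
  (both outside every band). Default off — synthetic spectra are generated
  baseline-free — and recommended on for instrument spectra. Adding a
  constant offset shifts uncorrected intensities by exactly that constant
  and corrected ones not at all (tested).
* **Band presence** (the 717 cm⁻¹ turkey marker): a local maximum within
  ±8 cm⁻¹ whose prominence exceeds `k = 5` times the spectrum's noise scale
  (median absolute successive difference). On featureless noise this fires
  in well under 5 % of cases (tested over 100 replicates).
* **Carbonyl/phosphate attribution**: the ratio I(1744)/I(1240) attributes
  the P=O band to phospholipids when it lies in [1.9, 2.3] and to nucleic
  acids otherwise. Recomputed from the documented class means the ratio is
  ~1.31–1.37 for smoked turkey and roasted pork (consistent with the
  reported 1.3–1.4), but 1.46 (boiled turkey) and 1.58 (boiled pork) —
  outside the range claimed for "all samples". The ratio basis behind those
  two rows is unknowable from the printed means, so only the consistent
  classes are used in acceptance checks.

## Classification

Features are z-normalized — $(f - \mu)/\sigma$ with $\mu, \sigma$ pooled
over all patterns of the classes being discriminated. The *population*
standard deviation is used, which pins the two-pattern closed form
$\{x, -x\} \mapsto \{+1, -1\}$; the choice is immaterial to classification
because leave-one-out results are invariant under per-feature affine maps
(tested, including sign flips).

The classifier is a Gaussian-kernel probabilistic neural network: class
score $s_c(q) = \frac{1}{n_c} \sum_i \exp(-\lVert q - x_{ci}
\rVert^2 / 2\sigma_k^2)$ with equal priors, argmax assignment, ties to the
lowest class index in registration order. `pnn_classify()` works in the log
domain (row-shifted log-sum-exp), so as $\sigma_k \to 0$ the decision
degrades gracefully to exact 1-nearest-neighbour assignment instead of
underflowing — a tested limit.

**Leave-one-out** is exact: for each pattern the model is rebuilt from the
other $n-1$. Two normalization modes exist because the textbook procedure
normalizes once over all patterns (mode `"pooled"`), which leaks the
held-out pattern's value into the scaling. The default mode `"fold"`
recomputes $\mu, \sigma$ from the $n-1$ retained patterns. The
implementation exploits the fact that means cancel in pattern differences,
so fold-wise distances need only per-fold variances (closed form), making
the exhaustive scan tractable; a literal per-fold rebuild is kept as a test
oracle and agrees exactly.

**Kernel width**: no width is prescribed by the source material. Policy
`"auto"` evaluates the grid $\{0.05, 0.1, 0.2, 0.5, 1, 2\} \times \sqrt{p}$
($p$ = subset size) by LOO accuracy and takes the best (smallest width on
ties). This is a single-level selection on the same folds — a deliberate
simplification: per-fold nested selection multiplies the exhaustive subset
scan by another factor of $n$ for no change in which subsets win on
well-separated data. Two consequences are documented and tested: the
selected accuracy is an optimistic estimate for the selected width, and on
*chance-level* data the maximization lifts accuracy above the binomial
band, so calibration checks (the "two identical distributions ≈ 50 %"
property) must use a fixed width. A fixed-σ override exists throughout.

**Subset search** enumerates every feature combination of size ≤
`max_size` (default 3 — the documented discriminants all use three
features), preferring on ties fewer features and then the lexicographically
earliest subset, deterministically. Sizes above 6 (≥ 10^5 subsets from 28
features) require `force = TRUE`; the notion of scanning all $2^{28}$
combinations is treated as rhetorical.

One degenerate case deserves a note: for *literally duplicated* patterns
under two labels, LOO-PNN assigns every held-out pattern to the *other*
class (its zero-distance twin sits there), giving 0 % — not 50 % — accuracy.
Label symmetry in the statistical sense (two classes drawn iid from one
distribution) is what yields chance accuracy, and that is what the tests
assert.

## Trends and group comparisons

Storage trends are least-squares quadratics $v = c_0 + c_1 d + c_2 d^2$;
goodness of fit is Spearman's rank correlation between observed and fitted
values, with a trend *accepted* when $|r| > 0.2$. Two open points were
settled as follows: the correlation pairs observed-vs-fitted (value-vs-day
is available behind `rank_against = "day"`), and the threshold applies to
$|r|$ since monitored features both rise and fall. Constant series have
undefined rank correlation and are never accepted.

Group comparisons are one-way ANOVA followed by Tukey's HSD at α = 0.05,
with a compact letter display assembled by a deterministic insert-and-absorb
sweep over groups sorted by decreasing mean. With equal group sizes Tukey
significance is monotone in the mean difference, so sharing a letter is
exactly the complement of pairwise significance — asserted on fixtures. The
day-effect scan applies the same ANOVA across sampling days per variable
and reports the direction between first and last day; its type-I error under
day-shuffled nulls is calibrated at α (tested against binomial 99 % bounds).

One documented deviation: at the printed colour moments (n = 30, independent
normals), Tukey separates boiled from roasted pork on L\* (difference 3.79
vs HSD ≈ 2.3), so the documented "all three pork classes share a letter"
pattern is not reproducible under this generator; the tests assert the
robust parts of the pattern (turkey pair separated; turkey vs pork
separated). Real replicate structure is presumably correlated in ways the
independence assumption does not capture.

## The synthetic generator: what it emulates, and what it does not

The generator's defaults are the study conditions: five classes
(boiled/smoked turkey; boiled/smoked/roasted pork), 30 replicates per class,
sampling days 0–21 at 3-day intervals.

* **Colour**: L\*, a\*, b\* drawn independently from normals at the
  documented class means/sds. No covariance is modelled (none is
  documented); a hook exists in principle but the default is independence.
  Derived C\*, h, ΔE\* are always computed, never sampled.
* **Spectra**: sums of Gaussian bands (FWHM 15 cm⁻¹, a typical condensed-
  phase mid-IR width) at the registry band centers snapped to the 4 cm⁻¹
  grid, amplitude = class mean × (1 + drift(day)) + amplitude noise at the
  class sd, plus white noise (sd 0.001 AU). Drift is zero through day 10
  and linear to a signed ±10 % at day 20 — direction per the documented
  storage findings (1744, 1170–1154, 1627, 1541, 3100–3020 down; 2950–2920,
  2852, 1117, 966 up), magnitude a package choice since only direction and
  significance are documented. Turkey spectra carry the 717 cm⁻¹ marker
  (amplitude 0.010 ± 0.001 AU, a weak band); pork spectra do not.
* **Images**: luminance = class base level (mean Lab colour → sRGB, D65) +
  smoothed Gaussian blob field + horizontal streak plateaus + i.i.d. pixel
  noise, tinted with the class colour. The texture parameters were
  calibrated once so the documented orderings hold with wide margins: boiled
  pork is smooth with a narrow grey range (highest ASM among pork), smoked
  pork has low pixel noise with long smooth structures and streaks (highest
  LRE), roasted pork is fine-grained and noisy (lowest ASM and LRE), boiled
  turkey has a large intensity spread (higher SD), smoked turkey a narrow
  one concentrated in few grey levels (higher GLNU).

What passing tests therefore *do* show: the full pipeline — image synthesis,
feature extraction, normalization, exhaustive LOO search, band extraction,
trend and group statistics — recovers planted class structure, planted
drifts, and planted correlations at realistic noise levels, determinis-
tically under a root seed. What they do *not* show: performance on real ham
images (no photorealism, no illumination artefacts, no slice segmentation),
real spectra (no ATR/scatter artefacts, no correlated baselines), or real
replicate correlation structure. Absolute texture values and the documented
headline accuracies (95.5 %, 98 %, 100 %) are not reproducible without the
original raw images, which were never deposited; the synthetic analogue
asserts ≥ 90 % LOO accuracy with ≤ 3 features instead.

## Numerical choices and degenerate inputs

* Entropy terms use the 0·log 0 = 0 convention; IMC2's radicand is clamped
  at 0.
* Zero-variance features are dropped from normalization with a warning;
  per-fold variances are floored at machine epsilon.
* Constant images: sd = 0 → skewness/kurtosis `NA`; single-cell GLCM →
  correlation and both IMCs `NA`; affected patterns are rejected from
  classification, with a count in the warning.
* Quantization is floor binning, `floor(pixel × levels / G)`, order-
  preserving for any target depth.
* PNG is the supported raster format (8-bit RGB or grey; alpha dropped).
* All stochastic generators take an explicit seed, restore the caller's RNG
  state, and are bit-reproducible; study-level generators derive per-
  artefact seeds from the root seed.

## Problem sizes used by the shipped analyses

The workflow under `analysis/` and the test suite run at the default study
scale: 150 images of 128×128 pixels for the discrimination table, 1 200
spectra (876 points each) for the storage series, 100-replicate simulations
for drift-direction and calibration checks, and the full ≤ 3-feature scan
(3 682 subsets) per comparison. These sizes were chosen so the whole
workflow reruns from scratch in a few minutes on a single core while keeping
every statistical check well-powered.
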