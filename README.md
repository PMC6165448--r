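# hamqa — quality assessment of ham cold cuts from image texture, colorimetry and FT-IR

Non-destructive quality control of cold cuts asks three questions of a ham
slice: what meat is it (pork or turkey), how was it processed (boiled,
smoked, roasted), and how far along is its refrigerated shelf life. `hamqa`
implements a complete analysis pipeline that answers all three from cheap
measurements — a photograph of the slice surface, a tristimulus colorimeter
reading, and a mid-infrared absorbance spectrum — for food scientists and
quality-control analysts working on meat products.

## What it computes

**Features (28 per slice).** From the grayscale image: 4 first-order
histogram statistics (mean, SD, skewness, raw kurtosis), the 13 classic
grey-level co-occurrence (Haralick) features at d = 1 over four directions
(ASM, contrast, correlation, sum of squares, IDM, entropy, sum entropy, sum
average, sum variance, difference variance, difference entropy, IMC1, IMC2),
and 5 run-length features (SRE, LRE, GLNU, RLNU, RP). From the colorimeter:
L\*, a\*, b\* plus derived chroma *C\** = √(a\*² + b\*²), hue angle
*h* = atan2(b\*, a\*) in degrees, and the CIE76 colour difference ΔE\*
against a white calibration plate.

**Classification.** Features are z-normalized pooled over the classes being
compared, then a Gaussian-kernel probabilistic neural network (PNN) —
score_c(q) = (1/n_c) Σᵢ exp(−‖q − x_ci‖²/2σ²), argmax with deterministic
tie-breaks — is evaluated by exact leave-one-out (LOO) over **every**
feature subset up to a size cap (default 3), returning the truth table of
the best design with the fewest features.

**Spectra.** Band intensities (window peak absorbance, optional linear
baseline correction) at 15 diagnostic mid-IR regions from 3500–3200 down to
870 cm⁻¹, the carbonyl/phosphate ratio I(1744)/I(1240) with its
phospholipid (1.9–2.3) vs nucleic-acid attribution, presence calls for the
717 cm⁻¹ unsaturation marker, and Pearson colour–band correlations.

**Shelf life.** Quadratic storage-time trends value = c₀ + c₁·day + c₂·day²
accepted when Spearman |r| > 0.2 between observed and fitted values, and
per-day ANOVA/Tukey comparisons with compact letter displays.

**Synthetic data.** Class-conditioned generators for images, colour
readings and spectra at the documented class statistics (five ham classes,
30 replicates, 3-day sampling over three weeks, band drifts after day 10),
so the whole pipeline runs and is tested without instrument data.

## Worked example

```r
library(hamqa)

# colour features of a roasted-pork reading (class mean values)
color_features(L = 58.20, a = 14.11, b = 10.19)
#>      L     a     b    C     h    dE
#> 1 58.2 14.11 10.19 17.4 35.84 43.03

# carbonyl/phosphate ratio from the roasted-pork band means
co_po_ratio(0.125, 0.091)
#>      ratio  attribution
#> 1 1.373626 nucleic_acid

# discriminate boiled vs smoked turkey on a small synthetic study
ft <- gen_feature_table(classes = c("turkey_boiled", "turkey_smoked"),
                        n = 12, seed = 7, image_size = 96)
discriminate(ft, c("turkey_boiled", "turkey_smoked"), max_size = 2)
#> turkey_boiled vs turkey_smoked: best subset {sd}, LOO accuracy 100.0% (sigma 0.05, 406 subsets)
#>                assigned
#> true            turkey_boiled turkey_smoked
#>   turkey_boiled            12             0
#>   turkey_smoked             0            12
```

The chroma 17.40 and hue 35.84° recompute the documented roasted-pork
colour coordinates; the ratio 1.37 falls outside the 1.9–2.3 phospholipid
window, attributing the P=O band to nucleic acids; and the subset search
finds that a single texture feature (image-intensity SD) already separates
the two synthetic turkey classes perfectly under leave-one-out.

## The analysis workflow

Numbered drivers under `analysis/` rerun the full study on synthetic data
and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R              # features.csv, bands.csv
Rscript analysis/02_discriminate.R          # per-comparison JSON + summary
Rscript analysis/03_spectra_interpretation.R# letters, ratios, marker, correlations
Rscript analysis/04_shelflife.R             # trends.csv, day_scan.csv
```

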