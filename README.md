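# patquant

Quantitative comparison of photoacoustic tomography (PAT) contrast with
3D light-sheet virtual histology in breast biopsies.

## The problem

Breast-conserving surgery fails in a large share of cases because tumor
margins are assessed destructively and slowly. Dual-wavelength PAT with
co-registered ultrasound can read out tissue *composition* — 1210 nm
light excites lipid-specific contrast, 1100 nm hemoglobin-specific
contrast — at clinically useful depth, and low lipid content is a strong
marker of malignant breast tissue. Validating that contrast against
histology, however, requires a quantitative bridge between volumetric
PAT/ultrasound data and histology-grade imagery. Inverted selective plane
illumination microscopy (iSPIM) of cleared tissue, with an eosin channel
(stroma) and a DRAQ5 channel (nuclei), provides that bridge as 3D
"virtual histology".

`patquant` implements the analysis side of that workflow as a tested,
reusable R package:

* **Binarization** — Otsu's method for PAT channels (threshold maximizing
  the between-class variance sigma_b^2(t) = w0*w1*(mu0-mu1)^2), and
  smoothed-histogram valley thresholds computed per analysis region and
  averaged, for the light-sheet channels.
* **Composition-positive maps** — each analysis region is 3 contiguous
  scan slices (0.386 mm of biopsy at the 0.193 mm scan step); per pixel,
  the number of binarized slices positive for a channel (count 0..3).
  Percent composition is the share of valid tissue pixels positive.
* **ROI scoring** — square 0.66 x 0.66 mm ROIs (one third of the 2 mm
  imaging depth) scored 1-3. Vascular/lipid rubric: 1 = no contrast,
  2 = composition-positive pixels present, 3 = pixels with count >= 2
  covering at least 50% of the ROI. Nuclei rubric: 1 = no cellular
  content, 2 = count-1 pixels, 3 = any count >= 2 pixel.
* **Classifier readout** — rank-based (Mann-Whitney) ROC AUC of the
  ordinal scores for cancerous vs non-cancerous ROIs, with low-lipid
  polarity for the lipid channels.
* **Statistics** — OLS regression of cross-modality composition,
  Shapiro-Wilk-gated log/reciprocal transforms, one-way ANOVA + Tukey
  HSD, Kruskal-Wallis + Dunn post-hoc z tests (tie-corrected).
* **Synthetic phantom** — a seeded generator for co-registered multimodal
  biopsy volumes (~5 x 5 x 2 mm block: adipose lobules, fibrous stroma,
  ducts with nuclei-dense walls, lipid-poor carcinoma foci,
  hemoglobin-rich vessels; exponential fluence decay, anisotropic PAT
  blur, channel noise, stitching stripes) with full ground truth, so
  every stage is testable without instrument data.

## Worked example

```r
library(patquant)

ph <- generatePhantom(phantomParams(extentMM = c(4.2, 1.98, 3.6), seed = 7),
                      sides = "anterior", channels = "pat_lipid")
ph$truth
#> PhantomTruth: 210 x 99 x 180 voxels at 0.020 mm
#>   tissue voxels: 3009600 (80.4%); nuclei: 15678
#>   adipose      24.80% of tissue
#>   stroma       61.67% of tissue
#>   duct_lumen    2.00% of tissue
#>   duct_wall     1.95% of tissue
#>   carcinoma     7.76% of tissue
#>   vessel        1.83% of tissue
ph$anterior$pat_lipid
#> ChannelVolume [pat_lipid, anterior]
#>   22 slices x 66 depth x 72 lateral voxels
#>   spacing (mm): scan 0.193, depth 0.030, lateral 0.050
#>   extent (mm): 4.25 x 1.98 x 3.60
#>   wavelength: 1210 nm
#>   intensity range: [0, 1.005]
```

Full pipeline on a phantom, five 3-slice regions, 5 cancerous + 10
non-cancerous ROIs:

```r
cfg <- list(seed = 7, sides = "anterior",
            phantom = list(extentMM = c(4.2, 1.98, 3.6),
                           ispimSpacingMM = rep(0.02, 3)),
            roi = list(n_cancerous = 5, n_noncancerous = 10))
m <- runFull(cfg, outDir = "run1")

aggregate(percent ~ channel, m$tables$composition, function(x) round(mean(x), 1))
#>          channel percent
#> 1    ispim_lipid    26.1
#> 2   ispim_nuclei     2.9
#> 3 pat_hemoglobin    15.0
#> 4      pat_lipid    23.0
unlist(m$auc)
#>    pat_lipid  ispim_lipid ispim_nuclei
#>         0.67         0.72         0.45
round(m$stats$lipid_regression$r2, 2)
#> [1] 0.96
```

Reading the numbers: PAT-derived lipid composition (23.0%) tracks the
light-sheet-derived lipid composition (26.1%) region by region
(regression R^2 = 0.96 across the five regions of this phantom), and
carcinoma-centred ROIs score *lower* on both lipid channels than
non-cancerous ROIs, so with low-lipid polarity the AUCs exceed 0.5 —
lipid contrast separates cancerous from non-cancerous tissue, the
nuclei channel does not. `run1/` holds the tidy CSV/JSON artifacts and a
manifest; re-running with the same config and seed reproduces every
number.

A command-line wrapper with `generate`, `run` and `validate` subcommands
is installed at `inst/scripts/patquant.R`:

```sh
Rscript inst/scripts/patquant.R run --config experiment.yaml --out run1
```

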