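# lucency

Imaging biomarkers of tumor radiolucency, and their prognostic value.

Lung tumors often contain internal regions of decreased CT density —
cavitation, cysts, reticulation, air-bronchogram signs. `lucency` measures
this internal architecture from multi-slice **binary tumor segmentations**
and relates it to post-surgical survival. It is aimed at imaging
researchers who have segmentation masks plus a clinical table and want a
reproducible pipeline from pixels to survival statistics.

## What it computes

Each slice is a pair of binary images: the solid image *A* and the mask
*B* = *A* with enclosed holes filled. With `P_A`, `P_B` the active-pixel
counts and `n` the tumor-bearing slice count, the nine biomarkers are

| biomarker | definition |
|---|---|
| RDC | mean over slices of `P_A / P_B` (radio-dense composition) |
| RLC | mean of `(P_B − P_A) / P_B`; satisfies RDC + RLC = 1 |
| DoC | `√((RDC − RLC)²)` |
| AT_R | mean of `(P_B − P_A) / P_{B∩A}` (air-to-tissue ratio) |
| LoSA | thickest wall: max over slices of the directed max–min distance from the largest lucent region's boundary to the mask boundary |
| LoSA_R | LoSA / Span (Span = max Feret diameter of the mask boundary) |
| LoCA | mean area-equivalent hole diameter `2√(area/π)` over lucency-bearing slices |
| LoCA_R | LoCA / Span |
| Solidity | solid pixels over the mask's bounding-box area (a.k.a. extent) |

Around the biomarkers the package provides: clinical covariate encoding
(0/1 nominals, cohort-proportion staging), solid-dominant vs
non-solid-dominant (SD/NSD) dichotomization at a 0.6 threshold,
stratified 10-fold cross-validated five-year survival classification
(logistic / random forest / SVM / neural network) with pooled ROC/AUC and
integrated discrimination improvement (IDI), Kaplan–Meier / log-rank /
Cox survival association, and a synthetic cohort generator with
controlled lucent fractions and known hazard ratios. See the methods
vignette (`vignettes/lucency-methods.Rmd`) for definitions, assumptions
and design choices.

## Worked example

```r
library(lucency)

# a synthetic 4-slice tumor, 35% lucent, single central cavity
vol <- simulateTumorVolume(0.35, nSlices = 4, radius = 14,
                           morphology = "cavity", seed = 42)
round(computeIBM(vol), 4)
#>    rdc    rlc    doc   at_r   losa losa_r   loca loca_r solidity ...
#> 0.6504 0.3496 0.3007 0.5376 6.0000 0.2137 14.1728 0.5049  0.5099
```

The measured radio-lucent composition (0.3496) recovers the generator's
35% target; the thickest wall is 6 px and the mean cavity caliber 14.2 px
on a tumor of Span ≈ 28 px.

```r
# a 120-subject cohort whose hazard is driven by lucency, with
# clinical covariates independent of outcome
co   <- simulateCohort(n = 120, outcomeModel = "rdc", seed = 42)
clin <- co[, c("subject_id", "gender", "age", "weight", "smoking_years",
               "histology", "t_stage", "n_stage", "m_stage", "tumor_size",
               "survival_time", "event", "five_year_label")]
res <- runPipeline(co[, c("subject_id", ibmNames())], clin,
                   families = "lr", folds = 10, seed = 42)
res$comparison
#> ModelComparison: 1 families x 3 feature sets, 108 subjects
#>  family set   auc
#>      lr CBM 0.549
#>      lr IBM 0.869
#>      lr HBM 0.862
#> IDI vs CBM
#>  family set   idi    z        p
#>      lr IBM 0.463 7.41 1.26e-13
#>      lr HBM 0.467 8.30 1.05e-16
```

The clinical pool classifies the five-year endpoint at chance (AUC 0.55,
as designed — its covariates are independent of outcome), the imaging
pool reaches AUC 0.87, and the IDI of ≈0.46 is strongly significant. The
survival stage of the same run gives, for the RDC grouping, an NSD-vs-SD
hazard ratio of 8.6 (95% CI 5.0–14.6) with log-rank p ≈ 3e-19 — the
wired-in lucency effect recovered end to end.

A thin command-line wrapper over the same functions is available at
`inst/scripts/lucency-cli.R` (subcommands `simulate`, `extract`,
`run-all`).

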