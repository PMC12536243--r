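# intestseg

Hierarchical machine-learning segmentation of the piglet small-intestinal
wall in H&E histology, built for the data regime veterinary pathology
actually works in: a handful of training slides, sparse brush annotations,
and laptop-class compute.

Quantitative assessment of post-weaning diarrhea and other enteropathies
needs per-layer areas (tissue, mucosa, epithelium, lamina propria) measured
reproducibly across hundreds of sections. `intestseg` implements a
three-step separation model for calibrated RGB sections:

1. **Tissue detection** — the mean RGB image at a 7.03 µm/px working
   resolution is Gaussian-smoothed (σ = 2.0) and thresholded at 205
   (strictly below = tissue); the classification becomes measurable objects
   with a minimum object size of 10,000 µm² and a minimum hole size of
   100,000 µm² (holes smaller than this are absorbed, so unstained vessels
   and edematous spaces above it survive as holes).
2. **Mucosal segmentation** — a random-forest pixel classifier (100 trees,
   √p features per split) over a multiscale feature bank — Gaussian,
   Laplacian of Gaussian, weighted deviation (Gaussian-weighted local SD),
   and Hessian determinant at σ ∈ {1.0, 2.0} — computed on the R, G, B and
   hematoxylin channels, applied **inside the step-1 tissue objects**, with
   the same object rules.
3. **Epithelial segmentation** — a second forest at the native 3.51 µm/px
   resolution adds gradient magnitude and structure-tensor coherence (all at
   σ = 1.0) and separates epithelium from lamina propria **inside the step-2
   mucosa objects**; objects use minimum object and hole sizes of 1,000 µm².

The hematoxylin channel comes from per-image H&E stain-vector estimation
(Macenko-style: SVD of the tissue-pixel optical densities, robust 1st/99th
percentile angular extremes) followed by least-squares deconvolution of
OD = −log₁₀(I/I₀).

Performance is evaluated the way the companion evaluation suite defines it:
signed relative deviation RD = (A_model − A_manual)/A_manual × 100 %,
agreement categories on |RD| (<5 % very good, 5–10 % good, 10–20 % fair,
>20 % poor), intersection over union (IoU, with >0.50 acceptable, >0.75
good, >0.90 near-perfect), Pearson correlation between model and manual
areas, per-age-group summary tables and modified Bland–Altman exports.

Because no real slides ship with the package, a first-class **synthetic
generator** produces calibrated H&E-like full-wall sections with exact
ground truth: a white lumen, capsule-shaped villi with an epithelial rim and
lamina-propria core over crypt, submucosal and muscular bands; age-dependent
morphology (4–67 days: younger animals get tighter villus packing and more
pale fetal-type vacuolated enterocytes); and injectable artifact classes —
stained luminal debris, dilated unstained submucosal vessels, goblet cells,
and crypt abscesses — that reproduce the pipeline's characteristic error
modes with known sign.

## Worked example

Simulate a ten-sample cohort, train both classifiers on five samples with a
small brush budget, and evaluate the held-out five:

```r
library(intestseg)

cohort    <- generate_cohort(2, seed = 42)            # 2 per age group
train_ids <- cohort$sample_id[c(1, 3, 5, 7, 9)]
m2 <- train_step2_classifier(cohort, train_ids, total_annotations = 80, seed = 1)
m3 <- train_step3_classifier(cohort, train_ids, total_annotations = 80, seed = 2)

val <- setdiff(cohort$sample_id, train_ids)
seg <- segment_cohort(cohort, m2, m3, sample_ids = val)
seg$records[, c("sample_id", "age_group", "step", "target", "rd", "category", "iou")]
#> 1 S002_age04         4     1 tissue      -4.45  very_good 0.923
#> 2 S002_age04         4     2 mucosa      -9.25  good      0.864
#> 3 S002_age04         4     3 epithelium -24.6   poor      0.644
#> 4 S004_age14        14     1 tissue       0.198 very_good 0.946
#> ...
#> 13 S010_age67        67     1 tissue      3.34  very_good 0.968
#> 14 S010_age67        67     2 mucosa      7.09  good      0.926
#> 15 S010_age67        67     3 epithelium 15.8   fair      0.863
```

Each row compares one step's model area against the exact ground truth:
tissue detection is near-perfect everywhere (IoU 0.92–0.97), and the
hardest case is — as on real neonatal tissue — the epithelium of the
youngest sample, where vacuolated fetal-type enterocytes drag the IoU down
to 0.64 and the area deviation to −25 % ("poor"). Pooled summaries follow
the same table layout as the evaluation suite:

```r
summarize_performance(seg$records) |> dplyr::filter(age_group == "All")
#>   step target         n rd_mean rd_sd   pcc pcc_interpretation iou_mean iou_sd
#> 1    1 tissue         5   0.905  3.25 0.938 very_strong           0.953 0.0190
#> 2    2 mucosa         5   0.158  6.11 0.940 very_strong           0.907 0.0265
#> 3    3 epithelium     5   1.59  16.5  0.397 weak                  0.799 0.0943
```

`autoplot(seg$records)` draws the modified Bland–Altman plot (RD against
age group); `plot_area_correlation()` the model-vs-manual scatter. The
paired ad-hoc vs age-balanced training-design comparison is
`run_design_experiment()`, and `simulate_cohort()`/`read_cohort()` move
cohorts through TIFF + YAML sidecars with a CSV manifest.

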