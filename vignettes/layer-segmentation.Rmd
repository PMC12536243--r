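---
title: "Hierarchical layer segmentation of the piglet intestinal wall: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical layer segmentation of the piglet intestinal wall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`intestseg` reimplements, as an offline and fully scripted pipeline, an
interactive trainable-segmentation workflow for piglet small-intestine
histology: threshold-based tissue detection followed by two random-forest
pixel classifiers applied hierarchically, with area extraction and an
agreement-focused evaluation suite. This vignette records the model, its
tunable parameters, the synthetic benchmark that stands in for real slides,
and the design decisions taken where the underlying workflow leaves choices
open.

## The three-step model

Sections are calibrated RGB rasters (µm/px is carried everywhere; areas and
size rules are physical, never pixel counts at an unstated scale).

**Step 1 — tissue detection.** The per-pixel mean of R, G and B is smoothed
with a Gaussian prefilter (σ = 2.0 working pixels) at a working resolution
of 7.03 µm/px and thresholded at 205: strictly below is tissue. The binary
classification is converted to measurable objects: 8-connected components
smaller than 10,000 µm² are discarded and interior holes (4-connected,
not touching the image border) smaller than 100,000 µm² are filled.
Remaining components are traced to polygons (marching squares at the 0.5
level on pixel-boundary coordinates; areas by the shoelace formula, holes
subtracted).

**Step 2 — mucosal segmentation.** A random forest (100 trees, √p features
per split, unlimited depth, no class weighting, fixed seed) classifies
mucosa vs submucosa/muscularis from a multiscale feature bank — Gaussian,
Laplacian of Gaussian, weighted deviation and Hessian determinant at
σ ∈ {1.0, 2.0} — over the R, G, B and hematoxylin channels at 7.03 µm/px.
Classification is restricted to the step-1 tissue objects; the mucosa class
becomes objects with the step-1 rules.

**Step 3 — epithelial segmentation.** A second forest separates epithelium
from lamina propria at the native 3.51 µm/px inside the step-2 mucosa
objects, with the six-filter bank (adding gradient magnitude and
structure-tensor coherence) at σ = 1.0, and object rules of 1,000 µm² for
both minimum object and minimum hole.

Restriction masks are hard contracts: pixels outside them are "unclassified"
and can never carry a class, which makes the containment chain
(step-3 labels ⊆ mucosa objects ⊆ tissue objects) exact by construction.
Hole filling cannot break it: any hole filled at step k is enclosed by that
step's class and would have been filled by the enclosing step's (equal or
larger) hole rule as well.

## Stain handling

Each image is handled in its own stain basis (the per-image colour
normalisation step of the original workflow). Optical density is
OD = −log₁₀(max(I, 1)/I₀) per channel, with intensities clamped at 1 so
black pixels stay finite — the clamp is part of the contract, not an error.
Stain vectors are estimated Macenko-style: tissue pixels (mean RGB ≤ 205,
reusing the step-1 threshold), OD magnitudes below 0.10 dropped, top-2
right-singular plane of the uncentred OD cloud, and the 1st/99th percentile
angular extremes of the projected cloud as the two stain directions.
Hematoxylin is the direction with the larger red-channel density (hematoxylin
absorbs red/green and transmits blue). Images with fewer than 200 usable
tissue pixels fall back to the published default H&E basis and are flagged.
Deconvolution is the least-squares projection onto the two vectors with
negative concentrations clipped; bases within 1° of collinearity are
refused. Only the hematoxylin channel feeds the classifiers — the eosin
channel is computed for diagnostics. We interpret "per-image colour
normalisation" as refitting the deconvolution basis per image (the
alternative reading — rewriting the RGB pixels themselves — would change
the classifiers' input distribution; the ambiguity is acknowledged here).

## Feature bank: definitions and numerics

All filters are built from sampled Gaussian-derivative kernels truncated at
4σ, applied by FFT on reflect-padded copies (no edge-darkening bias), with
derivative kernels mean-corrected to sum exactly to zero — a constant image
therefore yields identically zero derivative responses. Per scale σ (a
*sigma in working-resolution pixels*; the workflow's "scaling factors" are
taken to be the sigmas themselves, which is how the source tool
parameterises its features — the alternative reading, factors multiplying a
base sigma, is noted as a risk):

* `gaussian`: G_σ ∗ I
* `laplacian_of_gaussian`: (G_xx + G_yy) ∗ I
* `weighted_deviation`: √max(0, G_σ∗I² − (G_σ∗I)²). The source workflow
  never defines "weighted deviation"; we implement the name's plain reading,
  a Gaussian-weighted local standard deviation.
* `gradient_magnitude`: ‖(G_x ∗ I, G_y ∗ I)‖₂
* `hessian_determinant`: (G_xx∗I)(G_yy∗I) − (G_xy∗I)²
* `structure_tensor_coherence`: (λ₁−λ₂)/(λ₁+λ₂+ε) of the σ-smoothed outer
  product of the σ-scale gradient, ε = 1e−12, defined as 0 where the tensor
  trace is ≤ 1e−8 (constant regions).

Every filter is verified in the test suite against dense brute-force
convolution with explicitly constructed kernels on 32×32 images (interior
pixels, 1e−6), plus rotation-consistency and non-negativity properties.

## Resolutions

The two printed working resolutions, 3.51 and 7.03 µm/px, are not an exact
2× pair (7.03/3.51 = 2.0028). Generation is native at 3.51 µm/px and the
coarse steps downsample by exact 2× block averaging: `resample()` snaps to
an integer ratio when the request is within 0.5 %, so a 7.03 µm/px request
on a 3.51 µm/px image yields a 7.02 µm/px raster, and all calibration
comparisons use that 0.5 % tolerance. Areas always use the realised
calibration. Non-integer ratios fall back to area-weighted averaging;
upsampling of images is refused (masks may be upsampled nearest-neighbour to
carry a coarse restriction onto the fine grid exactly).

## Thresholding and object rules: boundary conventions

* A smoothed mean RGB of exactly 205 is background — the verbal rule
  ("below … tissue, above … background") leaves the boundary unassigned, and
  we fix it with a strict less-than for tissue.
* Smoothing is applied to the mean-RGB image, not per channel before
  averaging (for a linear filter the two orders are identical anyway).
* "Minimum hole size" means holes *smaller* than the stated value are
  filled, matching the source tool's semantics: only large unstained spaces
  (dilated vessels, edema) survive as holes. The original rationale sentence
  reads inverted against this; we follow tool semantics.
* Objects are 8-connected and holes 4-connected — the standard
  complementary pairing that avoids topological paradoxes.

## The synthetic benchmark

The study's 145 whole-slide images are not deposited, so the package ships
a generator whose defaults *are* the emulated study conditions. It draws
layer topology, not anatomy: a white lumen; capsule-shaped villi
(disc-swept segments) rising from a crypt band; submucosal and muscular
bands with undulating parallel boundaries; an epithelial rim defined as the
mucosal pixels within 35 µm of the luminal surface. Colours are fixed
class palettes (near-white background ≥ 235; dark purple epithelium; mid
pink lamina propria with nuclear speckle; pale pink submucosa; saturated
pink muscularis with oriented banding), perturbed by per-image illumination
jitter (σ = 4) and per-pixel Gaussian noise (σ = 8, 8-bit units), rounded
to integers so TIFF round-trips are exact. Background pixels are clamped to
≥ 235, so the raw-pixel brightness contract P(mean RGB > 205 | background)
= 1 holds by construction and the step-1 threshold is meaningful.

Age groups (4, 14, 25, 49, 67 days) map monotonically to morphology:
younger animals get tighter villus packing (centre spacing 170→230 µm),
longer villi (520→400 µm) and a higher vacuolation fraction
(0.60→0). Vacuolation recolours whole villi to a pale phenotype until the
configured fraction of epithelial pixels is covered (stochastic rounding on
the marginal villus keeps the expectation equal to the configured
fraction); the pale palette sits deliberately close to the submucosa so
classifiers never shown vacuolation misread it — the synthetic analogue of
the real age effect. Goblet cells (default 4 per mm of epithelial surface,
10 µm radius) stay ground-truth epithelium.

Artifact classes reproduce known error modes with known sign:

* **Luminal debris** — stained irregular blobs carved from the lumen,
  labelled lumen content (not tissue): step-1 area deviation becomes
  positive.
* **Edema vessels** — one near-white ellipse (half-axes 460 × 80 µm,
  ≈ 1.16 × 10⁵ µm² > the 10⁵ µm² hole rule) inside the submucosal band,
  still labelled submucosa/muscularis: the hole survives filling and the
  step-1 deviation becomes negative.
* **Crypt abscesses** — debris-filled circular lumina carved from the
  crypt band, ringed by epithelium. Their ground truth is lumen content —
  part of neither epithelium nor lamina propria — matching the manual
  convention under which calling them lamina propria is an error.

Brush annotations are disc-swept random walks (default radius 15 µm at the
coarse resolution, 8 µm at the fine one; path length 160 µm) constrained so
the disc fits entirely inside one ground-truth class region — every
annotated pixel is correctly labelled by construction, mirroring careful
interactive brushing. Requests that cannot fit (a brush wider than the
target stratum) fail loudly.

What the generator does **not** emulate: real stain chemistry and scanner
optics, nuclear morphology, villus branching and fusion, tissue folds, pen
marks, Peyer's patches, or whole-slide pyramids. Passing tests on synthetic
cohorts therefore demonstrate that the pipeline's machinery — thresholds,
feature bank, hierarchical masking, object rules, metrics — behaves
correctly and reproduces the documented directional error modes; they do
not certify accuracy on real slides.

## Training-set designs

Two presets mirror the published budgets. The ad-hoc design: mucosal step
15 samples (2, 2, 2, 8, 1 across the five age groups) with 236 annotations;
epithelial step 8 samples (0, 1, 2, 3, 2) with 172. The age-balanced
design: mucosal step as printed (identical to ad hoc), epithelial step 10
samples with 285 annotations taken as 2 per age group — the stated per-age
counts in the source add to one more than its stated sample total, and we
resolve the conflict in favour of the stated total and literal age balance.
Stroke budgets are distributed over samples and the two classes as evenly
as possible (the 236-stroke budget works out to ~8 strokes per class per
image). `run_design_experiment()` trains both designs on one cohort with
identical validation samples, so only the training-sample selection
differs.

## Evaluation conventions

* RD is signed; agreement categories fold the sign (|RD|) with half-open
  intervals [0,5), [5,10), [10,20), [20,∞) — boundaries go upward. The
  folding matches how near-zero negative deviations are described as very
  good agreement in practice.
* IoU is computed on rasters at each step's working resolution, not on
  traced polygons, avoiding floating-point geometry caveats; model and
  manual areas feeding RD are measured by the same traced-object estimator
  on both rasters.
* IoU interpretation uses strict thresholds (0.50/0.75/0.90); Pearson
  labels use |r| ≥ 0.90 very strong, 0.70–0.90 strong, 0.50–0.70 moderate,
  0.30–0.50 weak (these bands reproduce every printed label/value pairing
  in the source tables), below 0.30 negligible.
* Summary tables pool the "All" rows over records (not group averages);
  groups with n < 3 or zero variance report the correlation as not
  computable while all other statistics are still emitted.
* Real-slide validation restricted measurements to a manually chosen 5 mm
  segment along the lamina muscularis; that selection has no algorithmic
  definition, so synthetic sections are evaluated whole-frame.

## Determinism and problem sizes

One master seed drives everything; per-element seeds derive by a stated
counter scheme (master + 7919·i, mod a prime below 2³¹), so cohorts are
reproducible element-wise and forests are fitted single-threaded with fixed
seeds. The default test suite and the acceptance script use scaled-down
problem sizes chosen as the package's own benchmark conditions: 304×320 px
sections with proportionally shortened villi for unit tests; a 30-sample
default-size cohort (384×448 px, ≈1.35×1.57 mm) with 10 training and 20
validation samples for the end-to-end checks; 10 seeds per condition for
the directional artifact experiments; and a 20-sample cohort (10 train, 10
held out) in `scripts/acceptance.R`.

## Known limitations

* The synthetic palette is far cleaner than real H&E; absolute IoU/RD
  values on synthetic cohorts are optimistic and only the directional and
  structural claims transfer.
* Step-2/step-3 working resolutions inherit a 0.1 % calibration shift from
  the 2× snap (7.02 vs the printed 7.03 µm/px); areas are consistent
  internally but differ in the fourth digit from a hypothetical exact-7.03
  raster.
* The random-forest hyperparameters ("default random trees") are not
  printed in the source; 100 trees with √p splits is a common default and
  is recorded in every model manifest, but it is a choice, not a fact.
* Single-process, tile-free execution: sections at laptop scale, no
  whole-slide pyramids.
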