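---
title: "Field-of-view aware augmentation for lung ultrasound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-of-view aware augmentation for lung ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lusaug)
```

## The problem

Joint-embedding self-supervised learning (SSL) trains an image encoder by
pulling together the representations of two randomly augmented views of the
same image (a *positive pair*). The quality of the learned representation
therefore depends directly on the augmentation pipeline: transformations
should produce genuinely different views while preserving the semantics a
downstream task cares about. B-mode ultrasound breaks several assumptions
behind the photographic augmentation recipes commonly used for this purpose.
Its field of view (FOV) is a rectangle for linear probes but a circular
sector for curvilinear and phased arrays; content exists only inside the FOV;
and its characteristic artifacts (speckle, A-line reverberations, B-line
rays, anechoic fluid) carry the diagnostic signal in lung ultrasound.

`lusaug` implements, in R, the three ingredients needed to study this at the
level of the augmentation pipeline itself:

1. **Semantics-preserving preprocessing** — multiply the frame by a binary
   FOV mask (so burnt-in annotations vanish) and crop to the tight bounding
   box of the mask.
2. **Three augmentation pipelines** — the photographic baseline
   (`standard_aug`, transforms A00–A05), a twelve-transform
   ultrasound-specific pipeline (`aug_us_o`, B00–B11) built on scan-conversion
   geometry, and a distilled four-transform pipeline (`aug_us_d`,
   `[B03, A02, B11, A00]`).
3. **A leave-one-out ablation harness** — patient-grouped cross-validation,
   AUROC scoring of a linear probe, and a Friedman → Wilcoxon signed-rank →
   Holm–Bonferroni cascade that decides which transforms are *contributory*
   (their omission significantly lowers performance on at least one task).

Everything is testable offline: a schematic phantom generator renders lung
ultrasound images with known geometry and findings.

## Geometry model

An FOV is parameterised by `fov_geometry(kind, apex, theta0, r_min, r_max,
width)`. Coordinates are 0-based `(row, col)` with the origin at the top-left
pixel centre; depth increases with row; angles are measured from the vertical
centreline, positive rightward. A fan is the set of points with radius in
`[r_min, r_max]` and angle in `[-theta0, theta0]` about the apex (which may
lie above the frame). `phased` is the sub-case `r_min <= 0.05 * r_max`.
The fan's bottom corners — where the outer arc meets the lateral edges —
are separated laterally by `2 * r_max * sin(theta0)`, strictly increasing in
`theta0`, which is exactly the quantity the convexity-change transform (B01)
manipulates.

Scan conversion (`scan_convert` / `inverse_scan_convert`) maps between beam
space (rows = depth, columns = beam angle) and Cartesian display space by
bilinear interpolation with constant-0 fill; bilinear is the conventional
choice for display-side scan conversion and keeps round trips cheap and
smooth. Beam-space lattices use the same depth resolution as the radial
range (`round(r_max - r_min)` rows), so round trips are near-isometric:
on band-limited images the mean absolute round-trip error is below 0.02.

`fit_fov_geometry` recovers a geometry from a binary mask. Row-width
constancy separates linear from fan masks. For fans, total-least-squares
fits to the two lateral flank edges give an initial apex and half-width;
because extrapolating two nearly parallel lines to their intersection
amplifies pixel quantisation noise, all five parameters are then refined by
least squares on subpixel boundary samples (each edge pushed half a pixel
outward, frame-border samples excluded as clipping artifacts). On rendered
masks this recovers `theta0` within 0.02 rad and `r_max` within 2 px. An
RMS flank residual above 1.5 px raises a fit error — the mask matches
neither model. The package's mask *estimator* (threshold at 2/255, 5×5
closing, largest connected component, hole filling) is a stand-in for
clean or synthetic inputs; frames from real scanners with vendor overlays
should supply externally produced masks.

## The transforms

Each transform separates its random **draw** from a deterministic **apply**,
so a logged draw replays bit-exactly. All transforms operate on `[0, 1]`
doubles (8-bit quantisation happens only on save, with round-half-up, to
avoid accumulating quantisation across a pipeline), and every transform
re-zeroes content outside its (possibly transformed) mask.

Key parameter choices, each a config key on its pipeline spec:

| id | transform | stochastic parameters (defaults) |
|----|-----------|-----------------------------------|
| A00 | crop and resize | area fraction U[0.08, 1], aspect log-U[3/4, 4/3] |
| A02 | colour jitter | brightness/contrast factors U[1±0.8]; saturation/hue are exact no-ops after grayscale collapse |
| A04 | Gaussian blur | σ ~ U[0.1, 2] px, radius ⌈3σ⌉, reflective boundary |
| A05 | solarization | fixed threshold 0.5 |
| B00 | probe type change | fan half-width θ0 ~ U[0.3, 0.7] rad |
| B01 | convexity change | θ0 multiplier U[0.7, 1.3], clamped to [0.1, 1.2] rad |
| B02 | wavelet denoising | depth 3, Birgé–Massart exponent α = 3 |
| B03 | CLAHE | clip limit U[1, 4], 8×8 tiles |
| B04 | gamma | log-U[0.7, 1.5] |
| B05 | brightness/contrast | a ~ U[0.8, 1.2], b ~ U[−0.12, 0.12] |
| B06 | depth change | zoom U[0.85, 1.25] |
| B07 | speckle | field σ 0.25, smoothing σ 1 px |
| B08 | Gaussian noise | multiplicative σ 0.1 |
| B09 | salt & pepper | rate 0.01 |
| B11 | rotate/shift | angle U[±15°], shift U[±10%] per axis |

The jitter/blur/solarize strengths follow the published settings of the
SimCLR/BYOL augmentation family; the ultrasound-side ranges are the
package's own defaults chosen to span the plausible clinical variation of
each control, and every one is overridable per pipeline spec.

Details worth knowing:

* **A00 crop windows** use `ceiling` when converting the sampled area
  fraction to integer window sides, so the realised area never falls below
  the sampled fraction — the `[8%, 100%]` area contract holds exactly. After
  10 rejected samples (window larger than the frame) a centred window at
  `sqrt(c_min)` linear scale guarantees termination.
* **B00** converts a linear FOV to a fan by treating the in-FOV rectangle as
  beam space, placing the fan apex so the new sector fills the frame with an
  inner radius at 15% of the outer; fans convert to linear by inverse scan
  conversion resized to the frame. Applying B00 twice returns the original
  FOV kind.
* **B02** uses an orthonormal Daubechies 4-tap DWT with periodic boundary
  (implemented in the package, with perfect-reconstruction and
  energy-conservation tests) and the Birgé–Massart retention rule: at detail
  level *j* (1 = coarsest) only the `m/(j+1)^α` largest-magnitude detail
  coefficients survive, with `m` the size of the coarsest approximation
  band. Frames are edge-padded to a multiple of `2^levels` and cropped back.
* **B03** delegates the equalization to `EBImage::clahe()`. Tile histograms
  would be dominated by out-of-FOV zeros, so the background is filled with
  the in-FOV mean before equalization and re-masked after; this also makes a
  constant in-FOV image map to a constant, as adaptive equalization should.
* **B06** rescales content radially about the apex (fans) or vertically
  about the FOV top edge (linear) while keeping mask and geometry untouched
  — the paper's reading of a depth-control change: the FOV shape is a
  property of the probe, not the anatomy. A zoom of exactly 1 short-circuits
  to the identity.
* **B07 speckle** is a smoothed multiplicative Gaussian field — zero-mean
  noise, scaled by the local intensity, spatially correlated by a σ = 1 px
  Gaussian kernel. This realises synthetic speckle with the granularity of
  B-mode texture without simulating RF physics (Rayleigh/K-distribution
  modelling is out of scope). The smoothing attenuates the per-pixel standard
  deviation by `sqrt(sum(k^2))` of the 2-D kernel, which the tests verify by
  Monte-Carlo.
* **B11** re-binarises the warped mask at 0.5 and re-masks the content (fill
  regions stay black). After B11 or A00 the parametric geometry descriptor
  is dropped: a rotated or cropped FOV no longer matches the linear/fan
  model; the mask itself remains the ground truth.

## Pipelines, probabilities, and the RNG contract

A pipeline is an ordered list of `(id, probability, params)` specs plus a
final resize (default 128×128, applied after the transforms; bilinear, mask
re-binarised). `apply_pipeline` walks the specs in order, drawing an
independent Bernoulli gate per spec and fresh parameters on success, and
logs the applied ids with their draws; `replay_pipeline` reproduces a view
bit-exactly from that log. The application probabilities of the builtins
are fixed constants of the method (`builtin_pipeline`): A00 1.0, A01 0.5,
A02 0.8, A03 0.2, A04 0.5, A05 0.1; B00 0.3, B01 0.75, B02 0.5, B03 0.2,
B04–B06 0.5, B07/B08 0.333, B09 0.1, B10/B11 0.5; `aug_us_d` keeps each
transform's probability from its source table.

Randomness is organised as substreams: every (image index, view, transform,
purpose) tuple hashes, together with the master seed, to its own 31-bit
seed (`substream_seed`). The gate is drawn before the parameters, and a
skipped transform consumes no randomness. Two consequences matter for the
ablation study: removing one transform never shifts the draws of the
others (lower-variance leave-one-out comparisons), and positive pairs are
reproducible from a single master seed.

## The phantom generator

Phantoms are schematic, not physically simulated: their purpose is to put
the canonical findings at known locations inside a known FOV. Rendering
happens in beam space — a gently attenuating base intensity multiplied by a
smoothed exponential speckle texture, log-compressed (`log(1+20x)`
normalised) to mimic B-mode dynamic range — followed by scan conversion.
The pleural line is a bright depth band; A-lines are dimming replicas at
integer multiples of the probe–pleura distance (amplitude halving per
order); B-lines are bright constant-angle rays from the pleural line to the
outer arc; pleural effusion is a near-anechoic wedge below the pleural
line. `generate_dataset` mirrors the patient/video/frame hierarchy of
clinical collections: one geometry per patient, one label per video
(applying to all its frames), speckle re-drawn per frame.

What the phantoms do *not* emulate: real speckle statistics, attenuation
and time-gain compensation, rib shadows, probe pressure, motion, or vendor
post-processing. Tests passing on phantoms therefore certify the geometric
and statistical machinery — mask bookkeeping, scan-conversion correctness,
pipeline probabilities, the decision cascade — not clinical performance of
any encoder.

## The ablation harness

`run_leave_one_out` scores the baseline pipeline and every single-omission
variant. The packaged stand-in for "an encoder pretrained under pipeline P"
is deliberately cheap: an embedding function receives the image and the
condition's pipeline and returns a feature vector
(`default_embedder()` augments once and extracts radial-profile, histogram
and ray statistics). A ridge-regularised linear probe (closed-form
least squares on standardised features, λ = 1) is trained per fold of a
patient-grouped k-fold split — every patient's images land in exactly one
fold, fold patient-counts differing by at most one — and validation AUROC
(rank statistic, ties counted half) is recorded per fold.

Per task, a Friedman test (within-fold average ranks, standard tie
correction, χ² reference with k−1 df) gates post-hoc two-sided Wilcoxon
signed-rank comparisons of each ablation against the baseline. The Wilcoxon
implementation drops zero differences, average-ranks ties, enumerates all
`2^m` sign assignments exactly for m ≤ 12 and falls back to the
tie-corrected normal approximation above. Holm–Bonferroni step-down holds
the family-wise level at α = 0.05 per task family. A rejected condition is
classified `lower`/`higher` by the median fold difference; only `lower`
decisions make a transform contributory. The distilled pipeline orders the
contributory set by transform class — ultrasound intensity (B02–B09 range),
photometric (A02–A05), geometric (B00/B01/B06/B10/B11/A01), crop-and-resize
last — matching the `[B03, A02, B11, A00]` convention; whether directionality
should instead use one-sided tests is genuinely open, and the two-sided +
median-direction choice reproduces the same decisions on unambiguous
effects.

For validation, `planted_embedder(destroy_id)` carries four strongly
class-informative phantom features (brightest lower-half ray, its ratio to
the median ray, anechoic fraction, mean intensity) and replaces them with
pure noise whenever `destroy_id` is missing from the pipeline — the planted
analogue of a transform whose omission ruins the representation. The
harness conditions used by the tests are a 50-patient phantom dataset with
two videos per patient and two frames per video at 64×64, balanced over the
four classes, k = 10: grouped folds then hold 8–12 images with both classes
almost surely present, and the exact Wilcoxon at 9–10 nonzero differences
can clear the Holm-corrected threshold (with ≤ 7 usable folds the smallest
attainable two-sided exact p, `2/2^m`, already exceeds α/4 — a discreteness
floor worth knowing about when choosing fold counts). Under these
conditions the planted transform is recovered as the *exact* contributory
set in well over 90% of replicates, and with exchangeable scores the full
cascade's family-wise false-rejection rate stays below α (the omnibus gate
makes it conservative).

## Numerical choices and degenerate inputs

* Bilinear sampling (one compiled kernel shared by every geometric
  transform) clamps coordinates within 1e-9 of the valid range — polar
  round trips land epsilon outside at boundary pixels.
* Masks re-binarise at 0.5 after any interpolation; empty-mask inputs raise
  domain errors rather than propagating silently.
* `wilcoxon_signed_rank` on all-zero differences returns p = 1 with a
  degeneracy flag; a fully tied Friedman matrix returns statistic 0, p = 1.
* Folds whose test split lacks a class are dropped with a warning (k is
  reduced); a task with fewer than two usable folds is skipped.
* Problem sizes in the test-suite: frequency checks run 10,000 pipeline
  invocations on one 128×128 phantom; geometry round trips use 100 random
  128×128 geometries; the property suite runs 200 cases per operator at
  64×64; calibration uses 1,000 replicates of a 10×5 score matrix; the
  planted-effect check runs 200 replicates on the 50-patient dataset above.

## Package shape

The package's core objects are images with masks and geometry, so the API
is function-over-object in base/S3 style rather than data-frame-first;
tabular surfaces (manifests, fold scores, report summaries) are tibbles,
and the ablation report follows the broom convention (`tidy()`, `glance()`,
`autoplot()`). File formats are plain: PNG for images and masks, YAML for
pipeline configs, CSV for manifests, JSON for provenance and reports. A
thin command-line wrapper (`inst/cli/lusaug`, subcommands `preprocess`,
`augment`, `pairs`, `phantom`, `ablate`, `stats`) exposes the same
functions for shell use; `cli_main()` is the tested entry point.

## Known limitations

* The mask estimator assumes clean backgrounds; it does not reproduce
  commercial ultrasound cleaning software on vendor overlays.
* The speckle transform is a visual-statistics model, not an RF simulation.
* The exact parameter settings of the original pipelines' appendices are
  not public; the defaults here are documented stand-ins and configurable.
* `embed_fn` is pluggable precisely because the packaged embedders are
  handcrafted features, not trained encoders; conclusions about *real*
  encoders require plugging one in.
* Whether the final resize should precede or follow augmentation is
  ambiguous in the source protocol; the package resizes last, and the
  choice is configurable via each pipeline's `out_size`.
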