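---
title: "histostack: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{histostack: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histostack)
```

This vignette is the package's own account of its methods: what is modeled,
which conventions are fixed, where the design was genuinely open and what was
decided, and what the synthetic experiments do and do not demonstrate.

## 1. The synthetic serial-section phantom

Whole-eye serial histology of treated animals is not publicly deposited, so
every stage of the pipeline is exercised on a synthetic phantom with exact
ground truth (`phantom_params()`, `generate_stack()`).

**Geometry.** An eye cross-section is modeled as a circular annulus: a
purple-ish retinal band (default 200 μm thick, centerline radius 460 μm)
inside a pink scleral band (120 μm), around a pale lightly-stained interior,
on a bright background (intensity 245/255) — an HE-like palette chosen so
that the tissue grays cluster well below the background and a global bimodal
threshold lands between tissue and background. This is deliberately *not* an
anatomical eye: the downstream methods act on band geometry (thickness,
arcs, silhouettes), not anatomy. Two intentional asymmetries exist:

* a **coagulation-lesion sector** (default 60°) in which the retina is
  thinned from the inner side to `lesion_thinning_ratio` ρ times its nominal
  thickness — the quantity biometry must recover; and
* a **20°/100 μm optic-nerve stub** opposite the lesion. Real sagittal eye
  sections are not rotationally symmetric; without some silhouette
  asymmetry, rotation would be unidentifiable from a binary mask and
  mask-based registration could not be tested at all.

The band radius tapers weakly along z as a sphere section (sub-pixel at the
default 40 × 3 μm stack depth). Section thickness follows the species
presets: 3 μm for mouse and rat, 6 μm for rabbit. The default raster is
192 × 192 px at 10 μm/px — small enough that the full four-strategy
comparison over tens of seeded stacks runs on a desk machine, large enough
that the retina spans 20 px and sub-degree/sub-pixel registration errors are
measurable.

**Perturbations and artifacts.** Each slice is drawn in its own RNG stream
split deterministically from the master seed (so extending `n_slices` never
reshuffles earlier slices) with:

* **rigid jitter** — rotation ~ Normal(0, 4°), translation ~ Normal(0,
  60 μm) per axis, clamped at 2.5 SD (±10°, ±150 μm = ±15 px). The
  literature gives no distributional statement for section-to-section
  misalignment; clamped Normal jitter is a modeling choice. The jitter is
  applied *analytically* (the band is rendered displaced and rotated), so
  the recorded ground-truth transform — mapping the unperturbed slice onto
  the stored slice, about the image center — is exact, not an interpolated
  approximation.
* **damage events** (probability `crack_probability` per slice): a
  background-colored crack wedge (5–20°) through the section plus an
  overlap fold — a 20–60° arc of the band rendered at 0.55× intensity,
  emulating doubled-over tissue. The fold changes intensities only, never
  the masks: binarized registration is immune to it by construction, which
  is precisely the robustness mechanism the strategy comparison probes.
* **debris** (`debris_density` blobs per slice): small stained specks
  anywhere in the frame, and every fifth blob a large (80–150 μm) detached
  tissue fragment placed in the open background. Fragments are disconnected
  from the section, so prompt-based component selection removes them from
  masks while raw-intensity registration still sees them.

What passing tests on this phantom *do not* show: performance on real HE
texture (nuclear layers, staining gradients), non-rigid tissue distortion,
out-of-frame content, or anatomical structures other than a band. The
phantom validates the algorithmic contracts, not histological generality.

## 2. Segmentation and prompt semantics

`segment_foreground()` is a deterministic classical pipeline: luminance
conversion with fixed weights 0.299/0.587/0.114, Otsu threshold (tissue is
the dark class), morphological closing with a 3 px disc (configurable),
hole filling, connected-component labeling. `apply_prompts()` then keeps
exactly the components containing a positive point and discards components
containing a negative point (default: center positive, four corners
negative); a component containing both is discarded with a prompt-conflict
warning, and a positive prompt on background is an error. `segment_slice()`
adds one pragmatic fallback: if the center prompt lands on background (a
crack or strong jitter), the prompt is re-placed at the centroid of the
largest component — the automated analogue of supplying an additional
manual prompt when the default is unsatisfactory.

The pipeline only ever consumes the resulting binary mask, so any segmenter
honoring the same prompt contract could be substituted.

## 3. Rigid registration

Only rigid 2D transforms are estimated — rotation plus translation about
the image center, parameterized by (θ, tx, ty) and never by a free 2 × 2
matrix, so orthogonality and det = +1 hold to machine precision. Elastic
registration is deliberately out of scope: it would deform the structures
the reconstruction is meant to preserve.

**Metric.** Mean squared pixel difference on grayscale, full frame, with
out-of-frame lookups filled by the moving image's border median. MSE
matches the single-modality setting; mutual information is intentionally
not implemented.

**Optimization.** Nelder-Mead over a 3-level pyramid (block-mean
downsampling by 2). Initialization is by image moments — translation from
the content-centroid difference, rotation from the principal-axis angle
difference (axes are defined mod π; the smaller-magnitude resolution is
used) — with ±90° and 180° restarts competing at the coarsest level; the
restart with the lowest metric wins. One caution discovered during
development and worth recording: R's Nelder-Mead builds its initial simplex
with steps proportional to `parscale`, and with a naive scale the angle
dimension is explored in steps of ~0.1°, far too small to escape a bad
initialization — the restarts and the coarse-level competition are what
make the estimator reliable. For heavily corrupted or nearly symmetric
content an optional exhaustive coarse angle sweep (`init = "sweep"`,
2.5° steps, centroid-induced translations per angle) is available; it is
slower and is not the default.

**Convergence.** Relative tolerance 10⁻⁶ on the objective, iteration cap
200 per start (half that at refinement levels); hitting the cap at the
finest level returns the best-so-far transform with a flagged warning.

**Chaining.** Pairwise transforms (slice i+1 onto slice i) are composed to
absolute transforms about the *middle* reference slice, chaining in both
directions — the source procedure does not state a chaining convention, and
the middle reference halves worst-case drift accumulation. Estimated
transforms are always applied to the original RGB slices with bilinear
resampling.

**Strategies.** `unregistered` (passthrough), `r_original` (estimate on raw
grayscale), `r_segmented` (estimate on grayscale with background set to the
border level via the mask), `r_binary` (estimate on the 0/1 mask). On clean
phantoms all converge; under corruption their robustness separates, because
folds and background fragments pollute the raw-intensity content (moments
and metric) but not the prompted masks.

## 4. Stack-coherence metrics

"Moving average of four adjacent slices" admits two readings; the default
is the symmetric, self-excluding window {i−2, i−1, i+1, i+2} (truncated at
the stack ends, minimum two neighbors), with the causal 4-slice window
available as `window_mode = "causal"`. Metrics are computed on grayscale —
whether the original analysis used grayscale or per-channel averages is
unstated, so the convention is fixed and declared here — over the
intersection of the slice's mask with the union of the comparator masks.

Masked SSIM treats the whole mask as a single window (means, variances with
n−1 normalization, covariance over the mask pixels; C1 = (0.01 L)²,
C2 = (0.03 L)², L = 1): the masks are irregular, and a sliding window would
mix tissue and blanked background at every edge. A 7 × 7 uniform-window
variant averaged over the erosion-safe interior is available
(`ssim_mode = "windowed"`). For constant images the global form reduces to
the luminance term exactly, which the tests pin against the closed form.

`compare_strategies()` re-segments each registered stack before evaluation
(segmentation follows registration, as the strategy definitions state). A
grossly misregistered slice can leave the frame entirely; it then has no
segmentable foreground and is excluded from evaluation rather than aborting
the comparison.

## 5. Volume assembly and sectional views

`assemble_volume()` stacks slices into a (z, y, x, channel) array with
voxel calibration (z from the species section thickness); no z-interpolation
is applied. `orthogonal_section()` returns axial/sagittal/coronal planes
with the anisotropic aspect (z voxel / xy voxel) attached for display.
Export is an uncompressed 8-bit multi-page TIFF plus a JSON calibration
sidecar (baseline TIFF tags cannot carry anisotropic z spacing); because
slices are quantized to k/255, the round trip is bit-exact. Surface meshing
and rendering are out of scope — the package stops at the voxel volume.

## 6. Biometry protocol

`thickness_profile()` operationalizes "evenly spaced cuts through the
retina": the band center is the centroid of the hole-filled retina mask
(exact for a band whose outer boundary is circular, as thinning acts from
the inner side), and thickness at each of 360 sampled angles is the chord
through the band along the radial ray — the local normal of a circular
band — measured by sub-pixel (0.25 px) bilinear sampling of the mask.

`detect_lesion()` needs a computable stand-in for the histological lesion
criterion ("aberrant outer nuclear layer"), which does not exist on a
synthetic band: the lesion is the maximal contiguous arc (wraparound-aware)
with thickness below **0.75 ×** a robust baseline (median of the upper half
of the profile), the threshold being configurable. Equal-length candidates
fall to the lower mean thickness, deterministically. Edge coordinates are
placed at the robust mid-radius of the thinned band (the boundary rays
straddle full and thinned band and are not trusted individually).

`sample_thickness()` takes six scar samples at arc fractions 1/12, 3/12, …,
11/12 of the lesion extent and six baseline samples in the 600 μm band
adjoining the lesion edges — three per side when both flanks offer the full
window, else all six on the available flank (side allocation is not
specified by the source protocol; 3 + 3 is the declared choice). Diameters
divide by the species *axial* shrinkage factor, thicknesses by the
*thickness* factor (shrinkage = post-processing/in-vivo, so correction is
division); the ratio of corrected means equals the ratio of raw means to
machine precision, which the tests assert. Given a list of masks (a stack),
the slice with the largest lesion diameter is selected automatically.

## 7. Group statistics

All summary-level formulas (pooled-variance Student, Welch-Satterthwaite,
Hedge's g with J = 1 − 3/(4 df − 1), Holm-Šídák step-down) are implemented
directly and cross-checked in the tests against `t.test` on constructed
samples with exact summaries, against hand-enumerated adjustments, and
against the closed-form balanced ANOVA decomposition. The approximate J
reproduces all six published effect sizes at two decimals; the exact
gamma-function correction is available behind `exact = TRUE`. `auto` test
selection uses a two-sided F-test of the variance ratio at α = 0.05 — the
source states only "when variances were unequal". The two-way ANOVA uses
type III sums of squares with sum-to-zero contrasts (the source names its
software but not the SS type; type III matches that software's convention),
with per-species contrasts on the pooled residual variance and Holm-Šídák
adjustment.

Two reporting caveats are deliberate. First, the published table's SEM/CI/p
columns are not reproducible from its printed SDs and group sizes under
either Student or Welch formulas (e.g. mouse lesion SEM prints 41.51;
recomputation gives 36.65 Student / 36.35 Welch); `reproduce_table1()`
therefore reports its own internally consistent SEM/CI/p and matches only
the difference and effect-size columns. Second, simulation at the published
rabbit parameters (n = 3 + 3) puts the power of the adjusted rabbit
post-hoc contrast near 0.84, so "all three species significant" holds in
roughly 83% of simulated cohorts, not near-always; the tests assert the
simulated rates, not an idealized one.

## 8. Numerical conventions and degenerate inputs

* Images are numeric arrays in [0, 1]; slices are quantized to k/255 so
  PNG/TIFF round trips are exact. Pixel coordinates are 1-indexed (x =
  column, y = row); the rotation center is ((w+1)/2, (h+1)/2) and is stored
  in every serialized transform.
* Uniform images raise a "no foreground" error; zero-variance moving images
  are rejected by the registration; an empty mask is an error for the
  metrics; SSIM of constant pairs is stabilized by C1/C2 (no division by
  zero); a profile with no sub-threshold arc is a "no lesion" result, not
  an error; ANOVA cells with fewer than two observations are refused by
  name.
* Problem sizes used by the shipped experiments: 40-slice clean stacks
  (10 seeds) for registration recovery, 20-slice corrupted stacks
  (10 seeds) for the strategy ordering, 20 phantoms per thinning ratio for
  biometry recovery, 2000 simulations for CI coverage — sizes chosen so the
  full suite runs in minutes on a single desk-class core while keeping
  Monte-Carlo noise well inside the asserted tolerances.

## 9. Known limitations

* The phantom's convex silhouette anchors the translation component of any
  mean-square rigid registration; gross translation failures ("content
  transcending the border") that degrade raw-image registration below the
  unregistered baseline on real, irregular sections are underrepresented —
  on the phantom, `r_original` degrades markedly (rotation failures, lower
  SSIM, occasional off-frame slices) but rarely falls below unregistered in
  aggregate MSE.
* Thickness is measured along radial rays; for strongly non-circular bands
  the local normal and the radial direction diverge and a centerline-based
  normal would be needed.
* The statistics layer treats printed summaries as exact; two-decimal SDs
  limit how precisely small-ratio effect sizes can be recovered.
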