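---
title: "Building whole-brain training label maps from single-hemisphere MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building whole-brain training label maps from single-hemisphere MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemilabel)
```

## The problem

Ultra-high-resolution ex vivo MRI of fixed brain hemispheres is the best
substrate for manually delineating small, low-contrast structures such as
the hypothalamus and its five subregions (anterior superior/inferior,
tuberal superior/inferior, posterior). But such collections are small
(typically ~10 specimens), cover only one hemisphere each, and carry a
contrast that no in vivo scan ever shows. Modern segmentation networks
bridge that gap by training on *synthetic* images generated from label
maps: if each label's appearance is randomised at train time, the network
becomes agnostic to contrast and resolution. That strategy needs label
maps that (a) label *all* tissue around the target structure, not just the
target, and (b) look like whole brains, because test-time scans are whole
brains.

`hemilabel` turns one hemisphere scan plus its manual subregion labels
into such whole-brain training label maps, and generates the synthetic
images to train on. Every stage is testable without any external data via
a deterministic hemisphere phantom generator.

## Pipeline and models

### Preprocessing

`run_preprocess()` standardises a scan in four fixed stages: reorientation
to canonical RAS+ (no resampling, just axis permutation/flips — every
voxel keeps its world coordinate), background masking, isotropic
resampling, bias-field correction.

*Masking.* Otsu's threshold is applied to log-intensities. MR magnitudes
are multiplicative, and in the log domain the air/tissue separation dwarfs
inter-tissue contrast, so the cut does not hinge on small dark tissue
classes. The largest 6-connected component is kept (detached objects such
as the packing bag around a specimen disappear here) and fully-enclosed
cavities are filled.

*Resampling.* The working resolution is 0.3 mm isotropic — fine enough for
subregion boundaries, small enough for network training. The output grid
keeps the input origin and covers the input field of view
(`shape = ceiling(extent/target)`), so anatomy is never cropped.
Intensities are interpolated linearly; label maps always use
nearest-neighbour, here and everywhere else in the package, because ids
are categorical. The interpolation kernel for intensities is a choice this
package fixes as trilinear.

*Bias field.* A smooth multiplicative field is estimated in the log
domain, adaptively to contrast: in-mask intensities are provisionally
classified into `bias_classes` (default 4) intensity classes by a
deterministic, density-mode-seeded k-means; the per-voxel residual to its
class mean is smoothed by a Gaussian of FWHM `bias_fwhm_mm`; and
classification and estimation alternate for `bias_iters` (default 10)
iterations. Removing class means before smoothing keeps tissue contrast
out of the field estimate — the step that plain log-smoothing misses.
The field is normalised to mean 1 inside the mask, preserving global
brightness, then divided out. `bias_fwhm_mm` defaults to 60 mm, suited to
whole-hemisphere fields of view; for small test volumes a value around
half the field of view behaves equivalently.

### Context labeling

The non-hypothalamic tissue only has to *condition image synthesis*; it is
never a segmentation target. Unsupervised k-means on the bias-corrected
in-mask grayscale values therefore suffices, and deliberately noisy
partitions are acceptable. To diversify synthetic contrast,
`generate_context_set()` produces one label map per k in 4..9 — six maps
per volume, sixty for a ten-subject cohort. Determinism matters more than
optimality here: initialisation is k-means++ with a per-(volume, k) seed
(`seed + k`), best of three restarts, and cluster ids are re-assigned in
ascending order of cluster mean so that id `offset+1` is always the
darkest class. Context ids start at `offset = 100`, which can never
collide with subregion ids 1–10.

### Label fusion

`merge_labels()` overlays the manual subregion labels (ids 1–5) onto a
context map; manual always wins. Overlay leaves inconsistent voxels along
structure boundaries (e.g. around the fornix and the third-ventricle
area), so `refine_with_closing()` applies morphological closing to the
union hypothalamus mask with a spherical structuring element of radius
1.2 mm — 4 voxels at the working resolution. The closing is computed
exactly through the Euclidean distance transform (dilation = distance to
the set ≤ r; erosion = distance to the complement > r), so it agrees with
a literal dilate-then-erode with a discrete Euclidean ball. Voxels the
closing adds are given the subregion id of their nearest pre-existing
subregion voxel, ties resolved toward the lowest id — a deterministic,
local rule the closing operator itself does not specify. Whether closing
should target the whole-hypothalamus mask or individual label pairs is
genuinely open; this package closes the whole mask, which repairs the
boundary inconsistencies without editing interior subregion borders.

### Hemisphere mirroring

A virtual mirror sits on the mid-sagittal plane x = 0. The hemisphere is
placed by a rigid transform T minimising

$$\widehat{T} = \arg\min_T \sum_{i\in\Omega} \delta[x(v_i;T)>0]\,x(v_i;T)
\;-\; \alpha \sum_{i\in\Omega} x(v_i;T),$$

where $\Omega$ is the brain mask, $x(v_i;T)$ the world x-coordinate of
mask voxel $v_i$ after T, $\delta$ Kronecker's delta, and $\alpha$ the
trade-off between not crossing the mirror (first term; crossing would make
the hemispheres overlap) and staying close to it (second term; distance
would leave a seam of background between them).

Three numerical facts shape the implementation:

1. **$\alpha$ must be image-adaptive.** For a translation t the cost
   derivative is $N^+(t) - \alpha N$: the stationary point has a fraction
   $\alpha$ of the mask *across* the mirror. A fixed $\alpha$ therefore
   either tolerates crossing (too large) or barely rewards proximity (too
   small), depending on the mask's face geometry. By default
   $\alpha$ is chosen per image as half the voxel fraction of the
   medial-most layer (strict half-voxel window), which makes the flush,
   non-crossing placement the minimiser whenever the medial face is the
   widest layer. A numeric `alpha` in `mirror_config()` overrides this.
2. **Feasibility is projected, not hoped for.** The crossing term softens
   what is really a hard requirement — the hemisphere must not surpass the
   mirror. For sharp-cornered masks the soft cost can prefer a slight
   tilt-and-cross. Every optimizer candidate is therefore projected back
   onto the non-crossing half-space by a pure x-shift before comparison.
3. **y/z translations and plateau rotations are fixed by convention.** The
   cost depends only on post-transform x, so ty and tz are undetermined;
   the returned transform sets them to 0 (minimum-norm). At the flush
   optimum the cost is first-order flat in rotation, so the simplex can
   drift on that plateau; on a (projected) cost tie the translation-only
   solution wins.

The search itself is derivative-free (Nelder–Mead over the three Euler
angles and the x-shift, or a deterministic Powell-style coordinate
descent), started flush (identity rotation, x-shift placing the medial
face at x = 0) and finished with a fine 1-D grid polish of the x-shift
down to 0.001 mm, since the minimum sits on a kink that a simplex can
straddle. The cost is evaluated on a deterministic stride subsample of at
most `max_subsample` (default 50 000) mask voxels, keeping the whole
optimisation deterministic — the `seed` in `mirror_config()` exists only
for interface stability.

`compose_full_brain()` then samples the placed hemisphere onto a grid
symmetric about x = 0 (voxel centers at ±0.5, ±1.5, ... spacings, so no
center lies on the plane), builds the mirrored hemisphere as the exact
grid-mirror of those samples, relabels its subregions 1–5 → 6–10 (ten
subregions total, five per hemisphere), and keeps context ids unchanged —
tissue appearance is lateral-symmetric for synthesis purposes. Each
half-space belongs to one hemisphere: the original claims x < 0, the
mirror claims x > 0. Outside the tolerated band around the plane
(`crossing_tolerance_mm`, default 0.5 mm) only one hemisphere can claim a
voxel anyway, and any overlap beyond the band is an error, not a warning.
By construction the composition is exactly mirror-symmetric under the id
swap 1↔6, ..., 5↔10.

### Synthetic image generation

`generate_training_pair()` implements the generative model used to train
contrast-agnostic segmenters:

1. **Geometric augmentation** (`augment_labels()`): a random affine —
   rotation ±15°, scale 0.85–1.15, shear ±0.012, translation ±10 mm, all
   uniform, about the volume center — composed with a smooth random
   elastic field (peak 3 mm, FWHM 20 mm), applied as a backward warp with
   nearest-neighbour sampling. The drawn transform and displacement fields
   are attached to the output for auditing.
2. **Per-label Gaussians** (`sample_gmm_image()`): each label id (including
   background) draws a mean from U(25, 225) and a standard deviation from
   U(5, 25); voxels are sampled i.i.d. conditionally on their label, and
   the image is min-max normalised to [0, 1]. The drawn (μ, σ) pairs are
   attached to the image so statistical tests can check the sampler
   against its own parameters.
3. **Resolution simulation** (`simulate_resolution()`): per-axis slice
   thickness drawn from U(1, 9) mm; the image is blurred with
   σ = 0.85·thickness/(2·spacing) voxels per axis, downsampled to the
   simulated spacing and linearly resampled back. Thickness equal to the
   native spacing is an exact pass-through.

The target map is the *same* deformed label map with context ids collapsed
to background — context classes exist only to give the synthetic image
realistic surroundings, never as training targets — so image and target
share the deformation exactly. None of these ranges is prescribed by the
data source; they follow the public conventions of generative
contrast-randomisation training and live in `synth_config()`, not in code
constants. Optional bias-field and gamma augmentations are deliberately
not enabled by default (the generative model here is GMM + blur).

### Agreement metrics

`dice_coefficient()` is 2|A∩B|/(|A|+|B|) over the voxel sets carrying the
requested ids; two empty sets agree on absence (Dice 1), empty versus
non-empty is 0. `average_hausdorff_distance()` is the symmetric mean
nearest-neighbour distance in world mm, over **all** labeled voxels (not
surface voxels — tools using surface point sets report different values),
computed exactly via the distance transform and undefined (an error) for
empty sets. `intra_rater_report()` evaluates the four standard groups:
Whole (1–5), Anterior (1–2), Tuberal (3–4), Posterior (5); groups missing
from both inputs are reported as `NA`, not zero. The published intra-rater
figures for real re-segmentations are human-reliability numbers and are
not reproducible computationally; this module guarantees metric
correctness, verified against brute-force all-pairs oracles.

## The phantom generator

`make_phantom_hemisphere()` emulates the pipeline's inputs: a
half-ellipsoid "hemisphere" entirely at x < 0, flat medial face a
configurable gap from the mirror plane, `n_shells` concentric
constant-intensity shells (means 80–220 over an exact-zero background, so
the background-tissue step dominates inter-shell steps, as in ex vivo
acquisitions), optional Gaussian noise and an optional multiplicative
linear bias ramp; plus a five-label medial block laid out
anterior/tuberal/posterior along y with superior/inferior splits along z,
abutting the medial face. `make_phantom_cohort()` varies seed, grid size,
gap and side; the default ten-member cohort has four right-sided members,
exercising the left-right flip exactly as a mixed collection would.

Phantoms are geometric, not anatomical. Passing tests on them
demonstrates the pipeline's *structural* guarantees — orientation and
world-coordinate handling, determinism, exact morphology, metric
correctness, flush non-crossing mirroring — not segmentation quality on
real tissue, which depends on manual labels and scanner physics the
phantom does not model (fixation effects, FLASH contrast, partial
voluming).

## Numerical choices and degenerate inputs

- Distances, closings and AHD use an exact separable squared Euclidean
  distance transform (compiled); morphology with a radius-r ball is
  defined on the discrete Euclidean ball {d : |d|² ≤ r²}. Out-of-grid
  positions are ignored by both dilation and erosion.
- A closing radius below one voxel warns and uses one voxel.
- Reorientation refuses oblique affines where no voxel axis dominates a
  world axis, naming the ambiguous axis.
- Label reading refuses non-integer data rather than rounding silently;
  label maps are written as int32, never float.
- NIfTI affines are written as the sform (code 2) and read with
  sform-first precedence; sform rows are float32 in the header, which
  bounds affine round-trip precision at ~1e-7.
- `resample_isotropic()` at the native spacing returns its input
  unchanged (grid-identical shortcut), and `simulate_resolution()` at the
  native thickness likewise.
- k-means requires k not to exceed the number of distinct in-mask values;
  constant volumes cannot be thresholded; empty masks are errors
  everywhere.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run the full pipeline on 48³–64³
phantom grids (14–19 mm fields of view at 0.3 mm), ten-member cohorts for
the context-set counts, twenty phantoms for the mirror-oracle comparison,
and ten seeds for the synthesis statistics. These sizes were chosen so
every structural property of the method is exercised end-to-end — the
guarantees checked (counts, exactness, determinism, oracle agreement) are
size-independent.

## Known limitations

- The background/bias stages are a documented, desk-scale substitute for
  contrast-adaptive Bayesian segmentation pipelines; they share the
  contract (clean background, flat field) but not the model.
- Mirroring assumes the anatomy is approximately lateral-symmetric; no
  asymmetric hemisphere synthesis is attempted.
- Only 3-D scalar NIfTI volumes are supported: no DICOM, no 4-D series,
  no oblique-preserving resampling.
- The manual segmentation protocol itself (landmark rules on coronal
  slices) is a human task; the phantom only encodes its five-label layout
  loosely, enough to exercise grouping logic in the metrics.
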