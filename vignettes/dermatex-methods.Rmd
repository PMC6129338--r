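---
title: "Texture and lesion-area based skin disease recognition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture and lesion-area based skin disease recognition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model behind
each stage, the tunable parameters and why their defaults are what they
are, what the synthetic generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The recognition problem

Herpes, paederus dermatitis and psoriasis differ along two image cues
that are individually ambiguous but jointly discriminative:

* **Surface texture.** Herpes lesions carry high-contrast vesicular
  speckle; paederus dermatitis a dense fine irritant grain; psoriasis
  coarse plaque-and-scale patches of low local contrast. Gray-level
  co-occurrence statistics summarise these differences.
* **Lesion extent.** Psoriasis plaques are typically the largest,
  herpes intermediate, paederus lesions the smallest. The lesion's pixel
  area captures this — but a severe herpes outbreak can rival a plaque in
  area, which is exactly why area alone misclassifies and the two cues
  are combined.

## Preprocessing

**Median filter.** Window 3×3 by default (configurable, odd), border
rule edge replication. The filter is the standard remedy for
salt-and-pepper acquisition noise because it preserves edges; a 3×3
window removes isolated impulses without blurring the 1–2 px vesicle
texture that the GLCM stage must still see. The 3×3 path is a vectorised
19-exchange sorting network; other windows fall back to per-pixel
selection.

**Rotation to the horizontal.** The orientation of the epithelium is
estimated as the principal-axis angle of the binarized foreground's
second-order central moments — the image itself carries no orientation
metadata, and the moment estimate is exact for elliptical shapes and
within 1° on the generator's super-ellipses. The rotated canvas is the
tight bounding box `⌈w|cosθ|+h|sinθ|⌉ × ⌈h|cosθ|+w|sinθ|⌉` (with a 1e-9
tolerance before the ceiling so right angles do not round up), and
sampling is nearest-neighbour about the two image centres at
`((h−1)/2, (w−1)/2)`, so rotations by multiples of 90° are exact pixel
bijections. Intensities are never interpolated — interpolation would
smooth precisely the texture the next stage measures.

**Binarization and the working foreground.** Otsu's threshold on a
256-bin histogram. The composed pipeline then keeps the largest
connected component and fills its holes: dark intra-lesion structure
(herpes vesicles) otherwise punches holes in the mask that distort the
distance transform. A constant image yields an all-background mask plus
a warning rather than an error, since downstream stages can report an
empty result meaningfully.

**Medial axis.** The Euclidean distance transform is exact (verified
against an exhaustive nearest-background search in the test suite), and
the axis is the per-column argmax of the distance map within the
foreground's bounding rectangle, smoothed by a running median of window
5 and snapped back to the mask where smoothing leaves it. One design
point deserves emphasis: at the blunt ends of an elongated shape the
distance ridge plateaus across many rows (every row of the cap is
equidistant from the lateral boundary). Resolving argmax ties to the
*middle* of the maximal plateau keeps the axis on the shape's midline
there; resolving to the uppermost row — the obvious convention — drags
the axis toward the shape corner by 10+ px. We measured both and chose
the plateau middle.

**Ten vertical regions.** The axis polyline's arclength is divided into
ten equal spans and every boxed foreground pixel is assigned to the span
of its nearest axis vertex (ties to the lower span index). For a
straight horizontal axis this reduces to ten equal column bands, and a
105-column axis yields bands differing by at most one column. Ten
regions give the classifier localized texture: a lesion occupying three
central regions raises the per-statistic maxima while the flanking plain
skin sets the minima, and that (min, max) contrast is the signature the
SVM consumes.

## GLCM texture statistics

Defaults: `L = 64` quantization levels of [0, 255] (enough resolution to
keep speckle and grain distinguishable, coarse enough that a 2000-px
segment still populates the table), distance-1 offsets at 0°, 45°, 90°
and 135° accumulated into one symmetric matrix (the standard
orientation-averaging choice; the rotation stage has already removed
gross orientation anyway), probability normalization, entropy in bits.

Two degenerate-input conventions: `0·log 0 = 0` in the entropy, so a
constant region has exactly zero entropy (no texture); and correlation
of a zero-spread table is defined as 0 with a warning rather than an
error, because perfectly constant segments genuinely occur on normal
skin. Energy on the probability-normalized table lies in (0, 1]; tables
built with `normalize = FALSE` give the raw-count variant whose
magnitudes run into the hundreds, matching how this statistic is
sometimes reported.

Every statistic is validated against an independent double-loop oracle
to 1e-9 on random tables, and against analytic limits (diagonal table →
contrast 0, correlation 1; anti-diagonal → correlation −1; uniform over
k cells → entropy log₂ k, energy 1/k).

## Lesion segmentation

The watershed relief is the smoothed gradient magnitude of the image's
*chroma* (saturation-scaled hue) and value planes, not of RGB. The
motivation is the same as for HSV-based erythema work: lesion tissue
differs from surrounding skin chromatically even where luminance
matches, and intra-lesion texture (vesicles, scale) modulates brightness
at constant hue — so chroma gradients ridge at tissue boundaries and
stay flat inside them. Gaussian pre-smoothing uses σ = 1.5 px with
forward differences: at σ = 2 the boundary ridge of a small
low-amplitude lesion falls to within the h-minima threshold and the
lesion merges into skin. The h-minima depth default is h = 10 gray
levels; basins shallower than that are noise.

Watershed zones are clustered by k-means (k = 4) on four features per
zone: hue-weighted chroma (×2), value and log-size. Initialisation is
deterministic farthest-point seeding, Lloyd iterations until centres are
stationary (≤ 300). Role mapping: darkest cluster → background; most
populous remaining cluster → normal skin (the zone median of the whole
image would be background-dominated, since the epithelium covers only
~28% of the frame); remaining cluster chromatically farthest from skin →
lesion, but only if that distance exceeds `min_chroma_dist = 0.08` —
sub-clusters of plain skin differ in brightness, not chroma, and sit an
order of magnitude below this gate, so lesion-free images correctly
yield no lesion. The fourth cluster is "mis-segmented" and its zones are
reassigned to lesion or skin by chroma distance.

Cleanup is a closing followed by an opening with a disk of radius 3.
Closing first fills pinholes and black flecks smaller than the element;
opening then removes isolated specks and smooths the boundary. The
reverse order (opening first) erodes each pinhole into a radius-3 hole
before the closing can act — on a test disk with 50 single-pixel holes
it loses 25% of the area where closing-first loses none — which is why
this order was chosen. The operator is idempotent.

## Classification

The feature vector is 11-dimensional: (min, max) over the ten regions of
each of the five statistics, plus the lesion area fraction. Features are
rescaled to [0, 1] per dimension from the training data (the RBF
distance is only meaningful on commensurate scales); zero-spread
dimensions are dropped with a warning.

The binary dual problems are solved by an SMO-style solver: deterministic
second-index choice by maximal `|E_i − E_j|`, KKT tolerance 1e-3, the
pairwise update preserving `Σ aⱼyⱼ = 0` exactly and the box
`0 ≤ aⱼ ≤ C` by clipping. `C = 50` is the default penalty; at the
problem sizes here (20–60 training points) the solver converges in a
handful of sweeps. Multi-class is one-vs-one with majority vote, ties to
the first class in training order. The kernel width default is the
median heuristic — the median pairwise distance between scaled training
points — which is scale-free and deterministic. The integrated
(texture + area) SVM produces the final label; the texture-only SVM1 and
area-only SVM2 are trained as diagnostics of what each cue contributes.

## The synthetic generator

Each image is an elongated super-ellipse (`|u/a|⁴ + |v/b|⁴ ≤ 1`,
a = 0.41 w, b = 0.19 h) of skin-toned pixels (luminance ~130–150, RGB
hue (1, 0.82, 0.70)) at a requested orientation on a dark background
(~10), with an optional lesion disk painted at the epithelium centre in
an erythematous hue (1, 0.55, 0.50) and a class-specific luminance
texture:

* herpes — dark circular speckles (radius 1–2 px, covering ~30% of the
  lesion, 90 gray levels deep) on the erythematous base;
* paederus dermatitis — iid fine grain, ±40 gray levels;
* psoriasis — two-tone patches (±28 gray levels) from median-thresholded
  Gaussian-smoothed noise at scale σ = 6 px.

These amplitudes were chosen once so that the per-class lesion GLCM
contrast intervals are pairwise disjoint (psoriasis ≈ 8–10, paederus
≈ 63–71, herpes ≈ 105–120 over seeds), the qualitative analogue of
published per-disease feature ranges, with the class ordering of those
tables preserved in which feature separates which pair. Default lesion
radii 60 / 40 / 25 px (psoriasis / herpes / paederus, ±10% jitter in
datasets) reproduce the clinical area ordering. Scenes are drawn
analytically in rotated coordinates — no resampling — so the lesion mask
is an exact pixel disk and `lesion_area_px` is its exact count.
Salt-and-pepper noise (default 2% of pixels to 0 or 255) is applied
last. Every image is drawn under its spec's seed through a local RNG
scope, so identical specs are bit-identical and dataset generation is
reproducible from one master seed.

What the generator does **not** emulate: illumination gradients and
colour casts of real photography, hair and specular occlusions,
irregular lesion outlines, multi-lesion presentations, inter-patient
skin-tone variation, and the overlap of real class feature
distributions. Passing tests therefore demonstrate that the pipeline's
stages are correct and that the classifier resolves class structure of
this separability; they do not certify clinical accuracy.

## Problem sizes and determinism

The standard experiment uses 30 images per class at 256×256 (the package
default resolution; 8-bit RGB), split 10 train / 20 test per class —
90 images in total. A full single-image pass (filter, rotate, EDT, ten
GLCMs, watershed, clustering) takes well under a second on one CPU, the
full experiment about a minute. All randomness flows from one master
seed via derived stage seeds; library functions never touch the global
RNG state.

## Known limitations

* The foreground is assumed to be a single dominant component; multiple
  disjoint epithelium regions are reduced to the largest.
* The medial axis is pixel-resolution; no sub-pixel refinement.
* The lesion role is a single cluster: multiple chromatically distinct
  lesions in one image would be merged or partially missed.
* The classifier is a small-sample method by design; no probability
  calibration or grid search beyond the median σ heuristic is provided.
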