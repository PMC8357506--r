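---
title: "Methods: SIFT features and weighted pyramid Lucas-Kanade for speckle tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SIFT features and weighted pyramid Lucas-Kanade for speckle tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Two-dimensional speckle tracking follows material points of the myocardium
through a B-mode echocardiographic cine loop. The speckle pattern — the
granular interference texture of coherent ultrasound — moves with the tissue,
so it can serve as a trackable signature; it is at the same time a noise
source that defeats naive frame differencing. echotrack implements a
tracking pipeline built from four stages:

1. **Despeckling** by a linear mean filter,
2. **Feature extraction** with a SIFT-style detector and 128-dimensional
   descriptor,
3. **Matching** by Euclidean nearest neighbors under the ratio test,
   searched with a K-D tree and Best-Bin-First (BBF),
4. **Displacement refinement** with a weighted iterative Lucas–Kanade (LK)
   scheme run coarse-to-fine over an image pyramid, gated by a per-frame
   displacement tolerance.

Because clinical recordings cannot ship with a package, every stage is
validated on synthetic speckle phantoms whose motion is known exactly.

## Synthetic phantoms: what they emulate, and what they do not

`make_speckle_frame()` renders a field of uniformly random bright scatterers
(density `speckle_density`, default 0.15) smoothed by an isotropic Gaussian
point-spread (`blur_sigma`, default 1.2 px) and contrast-stretched to the
display range, emulating the grain size and full dynamic range of a displayed
B-mode frame. `motion_model()` supplies translation, rotation about a
center, and a periodic radial contraction
`s(t) = 1 - (A/\rho)(1 - \cos(2\pi t/P))/2` — zero displacement at `t = 0`
and `t = P`, peak contraction of `A` pixels (at the inscribed-circle radius)
at `t = P/2` — a coarse stand-in for the systole–diastole cycle. Noise
options cover additive Gaussian, salt-and-pepper, and multiplicative
speckle noise.

The phantom deliberately omits: anisotropic, depth-dependent point spread;
log compression; attenuation and shadowing; out-of-plane motion and speckle
decorrelation over time. Passing tests on phantoms therefore demonstrate
the *algorithmic* correctness and the geometric robustness of the pipeline,
not clinical accuracy on real recordings.

Two rendering paths exist on purpose. `warp_frame()` resamples a frame
bilinearly through a dense displacement field (general motion, used by
`make_sequence()`), which adds a small interpolation blur.
`make_speckle_frame(spec, offset = )` instead re-renders the same scatterers
with the Gaussian point-spread centers translated, producing an exactly
shifted image; sub-pixel flow oracles use this path so the measured error is
the estimator's, not the renderer's.

## Despeckling

`mean_filter()` computes a weighted neighborhood average over an odd
`m x n` mask (uniform `1/(mn)` by default, 3 x 3); borders are handled by
edge replication so output size equals input size. Uniform weights make each
output pixel the plain mean of its `D = mn` neighbors, which suppresses
isolated salt-and-pepper and impulse outliers at the cost of a slight blur.
The filter is deliberately linear and non-adaptive; median and Wiener
variants are out of scope.

## Detector

The Gaussian scale space uses `sigma0 = 1.6`, `scales = 3` per octave
(`k = 2^(1/3)`), `s + 3` Gaussian layers per octave so that `s` DoG layers
have both neighbors, and octaves derived from the image size (stopping at
16 px). These are the canonical settings for this construction. The input
is not pre-doubled by default (`double_input` flag exists); an
`assumed_blur` of 0.5 px is removed when reaching `sigma0`.

Candidate keypoints are strict extrema over the 26-neighborhood of the DoG
stack, pre-filtered at half the contrast threshold (scaling with the
threshold keeps the contrast-monotonicity property: lowering the threshold
can only add keypoints). Each candidate is refined by the fitted quadratic
`xhat = -H^{-1} g` with up to 5 grid re-centerings; the refined response
`D(xhat) = D + g' xhat / 2` is gated at `|D| >= 0.03` (inclusive). The
absolute value is the default because DoG minima (dark blobs) are equally
valid speckle features; a flag restores the literal one-sided reading.
Intensities live in [0, 1], which is what an absolute threshold of 0.03
presumes — the phantom generator's contrast stretch keeps that premise true.

Edge-like points localize poorly along the edge and are rejected by the
standard curvature-ratio test `tr(H)^2/det(H) < (r+1)^2/r` with `r = 10`
on the 2 x 2 spatial Hessian.

Orientation uses the gradient magnitude/angle formulas
`m = sqrt((L(r+1,c)-L(r-1,c))^2 + (L(r,c+1)-L(r,c-1))^2)`,
`theta = atan2(L(r+1,c)-L(r-1,c), L(r,c+1)-L(r,c-1))` over a
Gaussian-weighted circular window of radius `3 * 1.5 * sigma`, a 36-bin
histogram, parabolic peak refinement, and extra keypoints for secondary
peaks at 80% of the maximum. With the first image index read as the row,
this is the conventional image-gradient angle with the column axis as
abscissa; one convention serves the whole pipeline (orientation, descriptor
rotation, plotting).

## Descriptor

Gradients are sampled on the circular window of radius
`R = (3 sigma sqrt(2)(d+1) + 1)/2` (`d = 4` subregions per side), offsets
are rotated by minus the keypoint orientation (standard 2-D rotation
matrix), and magnitudes are
accumulated into a `4 x 4 x 8` histogram with trilinear interpolation and a
spatial Gaussian of `d/2` subregion widths. Entries are clamped at 0.2 and
renormalized (the clamp is standard illumination robustness; `clamp_value =
NULL` restores the unclamped pipeline). Normalization is Euclidean by
default because Euclidean matching presumes unit-norm comparability;
`normalization = "sum"` gives the plain-sum form `l_j = w_j / sum w_i`
instead. Keypoints whose window exits the image are skipped rather than
padded, so no descriptor contains fabricated gradients.

## Matching

For each descriptor in A the two nearest neighbors in B are found (exact
brute force by default, or K-D tree + BBF) and the pair is accepted iff
`r = d_min/d_min2 < 0.44`. Many-to-one collisions on a target keypoint are
resolved by keeping the smallest distance (disable with `mutual = FALSE`
for the literal one-directional flow). Ties are broken by lower keypoint id
for determinism. The K-D tree splits on the highest-variance dimension at
the median; BBF visits bins in order of the accumulated distance from the
query to the bin's bounding box and stops after `max_checks` *leaf-bin*
examinations (200 by default), so any budget of at least the leaf count
reproduces brute force exactly.

## Weighted iterative Lucas-Kanade and the pyramid

For a patch of half-width `S = 7` centered on the point, the displacement
`b` (mapping positions in F to positions in G) is iterated with per-pixel
weights `w(x) = 1/max(|residual|, eps)`, `eps = 1e-3` intensity units. The
weight formula is the inverse absolute temporal difference; it is evaluated
at the *current* estimate — the same residual that drives the update — so
the scheme is an iteratively reweighted (L1-flavored) least squares whose
weights flatten as the estimate converges. Evaluating the weights once at
zero displacement instead measurably biases the estimate toward zero motion
(pixels that happen to look unchanged get enormous weight); the package's
own oracle puts that bias at ~0.08 px on a 0.5 px shift, versus ~0.005 px
for the adopted reading. The update itself is the standard LK weighted
least-squares normal equation in 2-D, solved through an eigendecomposition
pseudo-inverse so that patches with one-dimensional gradient structure
(ramps, straight edges) still solve along the informative direction instead
of failing on a singular matrix. Iterations stop at `|delta| <
convergence_tol` (0.01 px) or `max_iterations` (20).

The pyramid reduces each level with the 1/4, 1/8, 1/16 stencil centered on
odd coordinates — the center, edge-neighbor and diagonal weights sum to 1,
so constant images are preserved; borders replicate edges.
`pyramid_flow()` starts at the coarsest of 3 levels with `b = b0 / 2^(L-1)`
and doubles each level's result into the next; a failed level falls back to
the doubled coarser estimate and flags the result. The package's acceptance
checks demonstrate the pyramid's purpose directly: an 8 px shift on
fine-grained speckle is recovered to well under 0.5 px with 3 levels and
missed by several pixels with 1 level and the same window.

## Tracking loop

For each consecutive frame pair the pipeline despeckles, extracts and
matches features (features are recomputed per pair; no caching across the
sequence), then moves every tracked point by the displacement of the
accepted match nearest its current position (ties by smaller ratio). The
displacement — not the matched keypoint's own position — is transferred, so
a point between keypoints inherits its neighborhood's motion instead of
snapping onto the keypoint. With `refine_with_lk` (default) that match
displacement only seeds `pyramid_flow()` at the point itself.

The tolerance gate accepts a per-frame displacement of at most `tolerance`
pixels (inclusive; range 1-20) and otherwise records the sentinel `(0, 0)`
with the lost flag — the trajectory-table convention in which lost frames
print zero coordinates. With `reacquire = TRUE` (default) a lost point keeps
its last known position as the search anchor and may resume in a later
frame, which reproduces trajectory tables that resume after zero rows; with
`FALSE` a loss is permanent. `contraction_curve()` summarizes surviving
trajectories as the mean distance from a reference (per-frame centroid by
default) normalized to frame 1 — a shrinkage-per-frame summary. There is no
single agreed definition of such a curve; this one is the package's own,
chosen because it is unitless, robust to losing individual points, and dips
exactly when the tracked region contracts.

## Numerical choices and degenerate inputs

- Coordinates are 1-based `(row, col)`, origin top-left, matching R matrix
  indexing; keypoints are reported at base-image scale.
- Gaussian kernels are truncated at `4 sigma` (capped to the frame size)
  and renormalized; convolution is FFT-based with edge replication, which
  leaves ~1e-16 residue — zero-gradient guards therefore use a 1e-12
  tolerance rather than exact zero.
- Brute-force match distances are computed per-row as
  `sqrt(sum((a-b)^2))`; the `|a|^2+|b|^2-2ab` identity loses ~1e-8 of
  precision on near-duplicate descriptors, enough to disagree with the
  K-D-tree path.
- Degenerate cases reject rather than fabricate: singular refinement
  Hessians, non-positive edge-filter determinants, all-zero descriptors,
  flat LK patches (flagged unconverged), duplicate matches with
  `d_min = d_min2 = 0` (ambiguous, reported as failure).
- Seeds: every stochastic function takes an explicit seed; identical seeds
  give bit-identical outputs.

## Problem sizes used in tests

The test suite and acceptance script run on 96-256 px phantoms, 2-20 frame
sequences, and feature sets of tens to low hundreds of keypoints — sizes at
which a 160 px frame yields roughly 25-45 descriptors and a frame pair
roughly 15-30 accepted matches, comfortably exercising every code path
while keeping a full run to a few minutes. Repeatability, precision,
symmetry and tracking-error checks are computed on these conditions by
`tests/testthat/test-acceptance.R` and recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

- The descriptor border policy discards keypoints near frame edges; on
  small frames (under ~128 px) this substantially reduces descriptor yield,
  especially in higher octaves.
- The detector is tuned for blob-like speckle; elongated anatomical
  structures are deliberately rejected by the curvature-ratio test.
- The tracker assigns motion from the single nearest accepted match; in
  regions with no accepted matches within the tolerance the point is lost
  rather than interpolated.
- No geometric verification (e.g. RANSAC) is applied after the ratio test;
  outlier matches are handled only by the tolerance gate.
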