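---
title: "Ripple pond networks: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ripple pond networks: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripplepond)
```

## The model

A ripple pond network (RPN) is a feed-forward spiking network that converts
a centered 2-D image into a 1-D temporal pattern (TP) that a downstream
time-warp-invariant temporal-coding memory could learn and recognize. The
network is a disc of Φ spiral arms with N binary relay neurons per arm
(the innermost neuron, ring n = 0, is shared by all arms). Each neuron has
one outbound connection to its inward neighbour on the same arm with a
fixed unit delay Δt:

    a[n-1, φ](t) = a[n, φ](t − Δt),   n = 1 … N−1.

A projected image activates a subset of neurons; the activation then
"ripples" inward, one ring per step, and a summing neuron at the center
counts the activations arriving each step. An activation starting on ring
n exits at step n + 1 and the central neuron's activation at step 1, so
TP(t) is an integer series of length N whose total equals the initial
activation count m. Because the disc is rotationally symmetric by arms,
permuting arm indices leaves TP unchanged — the network-level source of
its rotation tolerance. Because the neuron density is uniform in area, a
rescaled object yields a TP that is a time- and magnitude-scaled copy of
the original's, which a time-warp-invariant memory absorbs.

An inhibitory neuron carries the total activity remaining on the disc,
Inh(t) = m − Σ_{s≤t} TP(s). It acts as an asynchronous shutter: while
Inh > 0 the input pathway is blocked; when the disc clears, the next
frame is admitted. Small objects clear early, so the effective frame rate
adapts to image size (`stream_run(mode = "gated")`); a periodic enable
signal every N steps (`mode = "periodic"`) is the simpler, slower
alternative.

One printed form of the summing rule counts activations passing through
ring 1 twice (once via the relay into the center and once directly) and
sums the central neuron over arms although it is a single shared unit. We
resolve this so that every initial activation is counted exactly once:
arms terminate at ring 1 into the summing neuron, and the central neuron
carries only the image's central sample. This is the only reading under
which Σ TP = m holds, which the shutter logic requires (Inh must reach 0
exactly when the pattern ends).

## Disc geometry

Ring n sits at radius √n (normalized by √(N−1)). A disc of uniform areal
density requires radius ∝ √(ring index); we adopt this reading and verify
it empirically: equal-area annuli of the 200 × 200 disc hold neuron counts
within ~3% of each other. Arms spiral: ring n is offset from ring n−1 by
an angle β_n found by a randomized max-min search — `trials` candidate
offsets are drawn uniformly from [0, 2π/Φ) (a larger range is redundant by
arm symmetry), each scored by the minimum distance from the candidate ring
to all placed neurons, and the best is kept, ties to the first candidate.
Offsets accumulate, which produces the characteristic spiral appearance;
an absolute per-ring offset would not.

The implementation scores one candidate arm against nearby rings only;
both the candidate ring and the placed set are exactly Φ-fold symmetric,
and rings radially farther than an upper bound on the achievable score
cannot attain the minimum, so this is algebraically identical to the
brute-force all-pairs search (the test-suite checks agreement against a
naive reference).

Two caveats worth knowing:

* Nearest-neighbour distances are *not* radially constant: every ring
  carries all Φ neurons, so within-ring spacing shrinks toward the
  center even though per-area counts stay uniform.
  `nn_distance_profile()` therefore defaults to equal-area bands — the
  partition appropriate for validating areal density; with equal-width
  bands the innermost band's mean nearest-neighbour distance is roughly
  half the outer bands'.
* For ring 1 every candidate offset ties exactly (the only placed neuron
  is the center), so β_1 is simply the first candidate drawn.

## Feature maps

Images are high-pass filtered with a difference of Gaussians (DoG) before
projection. Defaults σ_center = 1 px, σ_surround = 2 px suit 200 × 200
rasters of glyph-scale objects; both are exposed. Kernels are truncated at
3σ and normalized, convolution is separable with reflective boundaries, so
constant regions map to (numerically) zero and the filter is exactly
linear.

Orientation-sensitive features need care: a Cartesian Gabor map rotates
its *content* but not its orientation selectivity when the image rotates,
which would destroy the disc's rotation tolerance. The radial Gabor
filter instead orients its kernel at θ = α + β, where β is the position
angle of the pixel about the disc center and α a fixed radial offset, so
the response map co-rotates with the image. (A printed form of this
relation reads θ = 2α + β; the accompanying definition of β as the
position angle fixes θ = α + β, which we implement.) The per-pixel
orientation cosine and sine are taken directly as x/r and y/r rather than
through `atan2`, which makes the equivariance exact (to machine epsilon)
under lossless 90° grid rotations; the test-suite asserts both this and
the *failure* of the Cartesian control under the same test. Feature maps
are rectified before projection because disc neurons are binary: a strong
response of either sign should activate.

Gabor wavelength (8 px), envelope σ (3 px), aspect (0.8) and phase (0) are
engineering defaults — the operation's contracts (equivariance, linearity)
hold for any values.

## Projection and thresholds

The unit disc is inscribed in the square map; each neuron samples its
nearest pixel (+y up; bilinear sampling is available but unused by the
tests) and fires iff the sample exceeds the threshold. The default
threshold 1e−6 on rectified maps realizes "any positive response
activates" while ignoring floating-point residue in flat regions —
separable convolution leaves ~1e−17-scale dust where a constant region
should cancel exactly. The threshold is deliberately *not* adaptive;
adapting it per image would reintroduce a global operation the
architecture is designed to avoid.

## Temporal-pattern comparison

Patterns are magnitude-normalized by m — the cue the inhibitory neuron
delivers before the pattern itself arrives — and brought to a fixed
length (default 200). Two alignments exist:

* **Time-warp (support) alignment** (`normalize_tp()`): the span from the
  first to the last nonzero step is resampled linearly onto the full
  axis. This is the memory network's time-warp invariance made explicit,
  and it is what makes a half-scale object's pattern nearly collinear
  with the original's (mean cosine ≥ 0.9 at 0.5×).
* **Native-axis comparison**: the full N-point series is compared as-is
  (resampled only if the target length differs). Rotation and
  translation do not change object scale, and support-stretching would
  partially mask the radial redistribution a shift causes, so
  `invariance_sweep(time_warp = "auto")` uses the native axis for
  rotation/translation and the warp for scale. Cosine similarity is
  scale-free, so dividing by m affects stored values, not metrics.

Spearman's ρ uses mean ranks for ties (`stats::cor`); a constant sequence
has no defined rank correlation and errors rather than returning NA.

## The invariance sweeps

For each image and each grid point the sweep transforms the raster
(rotation about the center, then scale, then shift; nearest-neighbour
resampling by default, matching the resizing family used for the original
experiments), filters both versions, projects, ripples, normalizes and
records both metrics; per-grid-point means are arithmetic, and images
whose transformed pattern is empty are excluded from that point with the
retained count reported.

The rotation-similarity curve repeats every 2π/Φ — rotating the image by
one arm spacing maps the disc onto itself. With raster images the
repetition is only near-exact: the transformed raster is resampled twice
(once by the transform, once by projection), which adds a slow drift of
comparable size to the periodic component (~5e−5 cosine units on the full
disc). `estimate_period()` therefore detrends linearly and reads the
dominant frequency off the periodogram; autocorrelation peak spacing,
the more obvious estimator, mis-reads the period by more than a grid
step on exactly this kind of weak-signal curve.

## The synthetic image generator

Experiments run on a generated, centered 200 × 200 corpus of six kinds in
equal numbers: single letters and digits (an embedded stroke-vector font —
no system-font dependency, so rasters are reproducible across platforms),
3–4 letter words, geometric shapes (circle, ring, rectangle, polygon,
star), radial-harmonic blobs with interior features (standing in for face
photographs) and fish-like silhouettes (ellipse body, triangle tail, eye;
standing in for fish photographs). Photographic faces and fish from the
original corpus are not redistributable, so results tied to corpus
composition are approximate reproductions, not exact ones. All images are
binary-ish with ~1 px anti-aliased edges, deterministic given their seed,
re-centered to put the foreground centroid within 2 px of the image
center, and sized to cover 10–80% of the inscribed disc.

What the generator does *not* emulate: photographic texture and grayscale
interiors, clutter, occlusion, or imperfect centering beyond the
transforms explicitly applied. Passing sweeps therefore demonstrate the
transform behaviour of the architecture on well-centered binary-ish
objects, not photographic-recognition performance.

## Problem sizes and determinism

The test-suite exercises full-scale conditions where the claims demand
them — the Φ = 200, N = 200 disc (39,801 neurons), 200 × 200 rasters, 100
images for the translation experiment, 30 images × 65 angles for the
periodicity experiment — and desk-scale discs (Φ ≤ 32) elsewhere; the
property suites use 200–1000 random frames. Every stochastic component
(placement search, image generation) takes an explicit seed, restores the
caller's RNG state, and derives per-image sub-seeds arithmetically, so
identical configurations reproduce bit-identical layouts, images and
tables.

## Known limitations

* Translation tolerance is explicitly *not* provided: the transform is a
  global polar one, and a 10% shift costs ~0.1–0.2 in similarity. The
  architecture assumes an upstream salience system delivers centered
  inputs.
* Very small scales degrade through raster resampling before they degrade
  through the network: a nearest-neighbour downscale below ~0.3× thins
  strokes below the pixel grid.
* The shutter model is idealized (exact zero-activity admission); a
  biological implementation would gate on a low-activity threshold with
  lateral-inhibition wavefronts, which is out of scope here.
* The downstream memory network is emulated only through its two relevant
  properties (time-warp invariance and the m-cue normalization), never
  simulated.
```{r}
sessionInfo()
```
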