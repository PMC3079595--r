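---
title: "Methods: a supervised visual-attention model for histopathology RoIs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a supervised visual-attention model for histopathology RoIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(historoi)
```

## The model

`historoi` detects diagnostic Regions of Interest (RoIs) in
haematoxylin–eosin fields by emulating the first, low-magnification phase
of a pathologist's examination. Three stages cooperate:

1. **Bottom-up conspicuity (V1).** For the intensity channel
   I = (R+G+B)/3, the colour double-opponency axes RG and BY of broadly
   tuned channels, and Gabor orientation energy at four angles, we build
   dyadic pyramids (binomial [1,4,6,4,1] smoothing, decimation by two)
   and form centre–surround maps |center − upsample(surround)| between
   pyramid levels. Each map passes through the peak-promoting
   normalization N(m) = (m / max m) · (1 − m̄)², where m̄ is the mean of
   the local maxima other than the global one; maps with one dominant
   peak survive, maps of diffuse activity are suppressed. Normalized maps
   are summed across scales and rescaled to [0, 1].
2. **Texture conspicuity (V4).** The per-pixel Shannon entropy (bits) of
   the windowed intensity histogram (default window 9 px, 32 bins,
   mirrored borders), divided by log2(bins). Tumour islets are cluttered
   and score high; stroma is quiet and scores low.
3. **Grouping and integration (V2).** The intensity channel is
   partitioned by the graph-based merge rule: edges (absolute intensity
   differences on the 0–255 scale) are processed in nondecreasing order
   and two components merge when the connecting weight does not exceed
   min(Int(c) + k/|c|) over both sides, Int(c) being the largest merge
   weight inside c. Each conspicuity map is averaged inside each region;
   the four indices are combined as a weighted mean with learned
   non-negative channel weights, min–max normalized across regions, and
   every region whose saliency strictly exceeds the unweighted mean of
   region saliencies enters the RoI mask.

The model assumes that diagnostic relevance is a *regional* property
visible at low magnification — darker, texturally disordered islets with
smooth closed contours — and that one global linear weighting of four
channels suffices per corpus. It does not model nucleus-level morphology,
stain variation, or inter-observer disagreement.

## The perceptual energy

Supervision compares a candidate partition C with an expert partition G.
Every ground-truth region is paired with the segmentation region of
maximal pixel overlap; pairs are made unique greedily in descending
overlap, losers stay uncoupled. For a matched pair, missing-foreground
pixels (in g, not in c) are weighted by w(i) = offset + slope·min(i,
d_max) of their Euclidean distance i to c, and added-background pixels
(in c, not in g) by their distance to g; the pairwise sums form the
boundary inaccuracy e_bl. Uncoupled segmentation regions are charged as
false foreground against an empty reference — every pixel at the capped
weight w(d_max) — giving the over-segmentation error e_ov; uncoupled
ground-truth regions symmetrically give e_un. The training energy is the
unweighted sum E = e_bl + e_ov + e_un, and reports also carry decibel
scores 10·log10(error / (area · w(d_max)) + 1e-7), floored at −70 dB for
a perfect match and capped at 0.

Defaults: slope 1, offset 1, d_max 20 px. These are conventions, not
corpus calibrations: only comparisons under a fixed weighting are
meaningful, and the dB values are on the scale of the package's own
normalization.

Degenerate inputs are defined, not rejected: an empty prediction weights
every missing pixel at w(d_max) (and symmetrically for an empty ground
truth), which keeps the energy finite and monotone as masks degrade.

## Learning

Both stages use a generalized pattern search (GPS): from the current
point, poll x ± Δ·s_i·ê_i coordinate by coordinate (declared order, +
before −), accept the first strict improvement keeping Δ, otherwise halve
Δ; stop after a fixed number of refinements (default 8). Objective values
are cached on the parameter tuple; non-finite values are treated as +∞;
integer-valued coordinates are rounded at evaluation time only, so the
search itself stays real-valued. Opportunistic polling was chosen over
complete polling for determinism and speed; with caching the two visit
nearly the same points on the landscapes at hand.

**Stage 1 (segmentation).** Minimizes the mean energy over the training
samples with respect to (k, smooth_sigma, min_size), bounds k ∈ [10,
5000] (start 500), sigma ∈ [0, 2] px (start 0.8), min_size ∈ [1, 500] px
(start 20). Two numerical choices matter here:

* k is polled on the log10 scale through the per-coordinate scale s_i.
  k is a scale factor spanning more than two decades; linear polling from
  k = 500 repeatedly stalled on a ridge far above the optimum, while
  log-scale polling descends into the correct basin.
* Before polling, a *search step* sweeps a coarse factorial grid of mesh
  points around the start (six log-k offsets × three sigma offsets) and
  begins the poll from its best point, the start winning ties. The energy
  is piecewise constant in the segmentation parameters (finitely many
  distinct segmentations), so a pure single-start poll can be trapped on
  a plateau; the sweep is deterministic and stays on the mesh.

**Stage 2 (channel weights).** With the segmentation fixed, minimizes the
mean normalized foreground–background quality of the extracted mask with
respect to the four weights in [0, 1] (start 0.25 each). Conspicuity
maps, segmentations and per-region indices are precomputed once per
sample, so each poll only recombines and rethresholds. An all-zero poll
is evaluated with uniform weights; the returned weights are renormalized
to sum 1.

An 11-fold cross-validation harness (`crossvalidate`) repeats the
two-stage learning on the training folds and reports per-fold energies
and pixel/region metrics on the held-out fold, with a deterministic fold
assignment from a seed.

## The entropy channel is used unnormalized

The detector deliberately does *not* pass the entropy map through N(·).
N(·) promotes maps with one isolated peak and cancels maps with many
comparable maxima — but a textured region is exactly a plateau of
comparable local maxima. Under N(·) the entropy channel's between-region
spread collapses far below the other channels', leaving the stage-2
objective flat in the entropy weight and the V4 channel useless; on its
absolute
[0, 1] scale (entropy / log2 bins) the channel separates textured islets
from smooth stroma cleanly. The entropy map is also computed single-scale:
whether the texture channel should receive multiscale treatment is left
open, and both window and bin count are exposed as parameters.

## Synthetic fixtures: what they emulate and what they do not

Real annotated slides cannot ship with the package, so `generate_fixture`
synthesizes the study conditions: pale eosin-like stroma (230, 200, 210)
carrying darker haematoxylin-like islets (120, 90, 160) with smooth
closed contours — discs deformed by low-frequency radial harmonics of
amplitude at most a quarter radius — strong intensity speckle inside
islets (sd 40/255) and weak speckle outside (sd 4/255), softened by a
1 px Gaussian blur. The mask is exactly the union of islet supports, so
ground truth is known analytically; placement is by rejection sampling
with a bounded retry budget, and identical (spec, seed) pairs are
bit-identical. The quantitative texture statistics of carcinoma versus
stroma are not published for any corpus; these parameters are a
realistic-looking stand-in chosen once, not a calibration.

Two *channel-discriminative* variants support the weight-learning
experiments; each plants distractor islets excluded from the ground
truth, so that the wrong channel actively misleads the detector:

* `entropy_only`: true islets have the background colour and differ only
  by speckle; distractors are dark but texture-quiet. Intensity points at
  the distractors, entropy at the truth.
* `color_only`: true islets are a strong hue shift with only a mild
  darkening (enough intensity contrast — about 23 of 255 units — for the
  intensity-based still-segmentation to isolate them), with
  background-level speckle; distractors are dark and hue-neutral.

In these experiments the still-segmentation is fixed per suite (k = 800
for the textured suite, k = 400 for the weak-contrast hue suite, sigma
0.8, min_size 30): stage 2 presupposes a segmentation whose regions
isolate both the true and the distractor structures, and the two stimuli
need different merge scales for that premise to hold.

Passing tests on fixtures demonstrates that the machinery behaves as
specified — it does not demonstrate performance on real slides, where
stain variability, touching islets, out-of-focus regions and annotation
ambiguity all appear and none is emulated here.

## Numerical choices

* **Tie-breaking.** Segmentation edges are sorted by (weight, column-major
  index of the first endpoint, then second), so results are
  platform-deterministic; region labels are renumbered 1..K by first
  occurrence in column-major order (1-based, the R convention).
* **Local maxima in N(·).** Only strictly positive plateaus count, each
  connected plateau once; otherwise the zero background of a two-peak map
  would enter the mean and break the two-equal-peaks ⇒ zero-map identity.
  Constant maps return zero: a constant carries no localized information.
* **Entropy windows.** Odd windows are centred; even windows (allowed
  from width 2) take the extra row/column towards the bottom-right, with
  mirror (no edge repeat) padding. An even window makes the analytic
  half/half-histogram case (entropy exactly 1 bit) realizable, which an
  odd pixel count cannot produce.
* **Pyramids.** Reduction is binomial smoothing plus decimation to
  ceil(n/2); expansion is pixel-centre-aligned bilinear resampling. Both
  are written plainly in-package so a naive loop reference can verify
  them to 1e-9. Images below 256 px use a reduced 5-level pyramid
  (centres 1–2, deltas 1–2) so small fields remain analysable; Gabor
  filtering falls back to reducing the previous level's response when a
  pyramid level is smaller than the 9×9 kernel.
* **Thresholding.** Strict ">" against the mean region saliency; if all
  regions tie (uniform images) the mask is empty — the conservative
  reading for a detector. Min–max normalization of the combined saliency
  maps a constant column to 0.5.
* **Label maps on disk.** Region ids are split across two 8-bit PNG
  channels (low byte red, high byte green) with a JSON sidecar, giving an
  exact round-trip to 65535 regions with plain 8-bit PNG I/O.

## Problem sizes

The test-suite study conditions are 80 × 80 px fixtures with two islets
of radius 9–14 px: 20 training and 20 held-out fields for the end-to-end
checks, 100 random parameter draws as the stage-1 baseline, six-fixture
discriminative suites at 96 × 96 px, and 500 random 3 × 3 images against
the exhaustive segmentation reference. These sizes keep every region
large relative to the entropy window while the full suite runs in a few
minutes on one CPU; the pipeline itself is resolution-independent and
runs on 1280 × 1024 fields unchanged (the segmentation core and entropy
scan are compiled).

## Known limitations

* The still-segmentation weighs intensity only (the package's default and
  the behaviour the energy is learned against); isoluminant structure is
  invisible to stage 1 even though the colour channel sees it at stage 3.
* N(·)'s plateau handling and the greedy tie rule in region matching are
  documented conventions; other resolutions of the same ambiguities are
  defensible and would change scores slightly.
* The dB scale is normalized by image area and maximal pixel weight, so
  absolute dB values are not comparable across metrics with different
  weighting constants — only within a fixed configuration.
* Learned weights are corpus-global; a per-magnification or per-stain
  weighting would require grouped training data.
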