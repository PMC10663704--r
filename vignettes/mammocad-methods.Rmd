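---
title: "Methods: phantom-scale mammographic mass detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-scale mammographic mass detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and the numerical choices behind
`mammocad`, in the spirit of a methods section: what each stage assumes,
which knobs matter, what the synthetic phantoms do and do not emulate,
and where the design was genuinely open.

## The synthetic phantoms

Every quantitative statement the package's tests make is made on
synthetic phantoms, because they come with exact ground truth (the mass
mask is *defined* as the set of pixels the mass painter incremented) and
because they make every experiment reproducible from a seed.

A phantom is an ellipse of breast tissue (base level 152 with a gentle
radial falloff of 16 gray levels, plus smooth Gaussian-blurred texture,
`texture_sd = 6`) over a background near level 10, an optional pectoral
wedge (+20) in the top-left corner, and an optional mass. Benign masses
are discs with full contrast (default +70 gray levels) inside 80% of the
radius and a linear taper that reaches zero *exactly at* the radius, so
the rasterized mask area stays within a percent of `pi r^2`. Malignant
masses modulate the radius with `n` angular lobes
(`r(theta) = r (0.65 + 0.35 max(0, cos(n theta + phi))^3)`), giving the
spiculated star margin that distinguishes the malignant class in the
standard metadata taxonomy. Clean phantoms are clamped to `[2, 250]`:
real uncorrupted tissue does not sit at the saturated extremes 0/255,
and keeping the extremes free makes them an unambiguous signature of
impulse corruption. Each case also carries nine cytology-style
attributes on a 1--10 scale drawn from label-conditional Gaussians
(means 2.8 benign / 7.2 malignant / 1.5 normal, sd 1.2) — roughly the
separation seen in the classic Wisconsin cytology attributes — so the
metadata-aware classifier head is exercised.

What the phantoms deliberately do **not** emulate: calcification
clusters, architectural distortion, asymmetry, overlapping
fibroglandular texture, scanner artifacts, and the heavy-tailed
intensity statistics of real film digitization. Passing tests therefore
demonstrate the machinery is correct and well-calibrated at desk scale,
not that the pipeline reaches clinical performance on real archives.

Default phantom size is 256 x 256 (the classic archive images are
1024 x 1024; the pipeline resizes its classifier input anyway, so the
phantom size mainly sets segmentation scale). The packaged experiment
uses 128 x 128 phantoms and 200 cases — sizes chosen so a full
experiment runs in minutes on a laptop core while every stage still
operates far from degenerate regimes.

## Denoising

The stage assumes additive or impulsive noise on an otherwise piecewise
smooth image. It minimizes

    E(I) = sum_px [ 1 + alpha^2 |grad I|^2 + gamma^2 (I - I0)^2 ]

with forward-difference gradients and replicate boundary (the boundary
rule is fixed so energies are bit-stable). `alpha` (default 1) weighs
total variation; `gamma` (default 1.5) anchors the estimate to the
observed image `I0`. The defaults were chosen so that removing an
isolated impulse (a large local TV gain against a bounded fidelity
cost) is always accepted while wholesale blurring of true edges is not;
they are ordinary tuning parameters, not fitted quantities.

The search starts from a soft-thresholded wavelet reconstruction.
The wavelet transform is a periodized orthonormal separable 2-D DWT
written in this package (Haar default, 4-tap Daubechies available):
periodization keeps the transform exactly orthogonal, which the tests
exploit (perfect reconstruction to 1e-6 RMS, Parseval to 1e-4
relative). The default threshold is the universal rule
`sigma_hat sqrt(2 log N)` with the robust noise scale
`sigma_hat = median |diagonal coefficients| / 0.6745`; a BayesShrink
style per-band rule and a fixed threshold are available. A deterministic
default threshold was preferred over manual tuning for
reproducibility.

Local-search operators: Gaussian blur (sigma 1), 3x3 mean filter, a
global intensity scale drawn uniformly from [0.7, 1.3], re-thresholding
one randomly chosen detail band, and 3x3 median replacement restricted
to the pixels flagged by the four-level quantization (below). One
operator is proposed per iteration with probability `local_search_rate`
(default 0.8); acceptance requires a strict energy decrease, ties
reject, so the accepted-energy trace is non-increasing by construction.
The stop rule is `max_iterations` (default 30) or ten consecutive
rejections.

Noisy-pixel flagging quantizes the image onto four equal-width
brightness levels and flags a pixel whose level differs from at least
six of its eight neighbours (rows, columns and diagonals; replicate
boundary). The 6-of-8 rule is the documented tie-break: a checkerboard
flags nothing, an isolated impulse is always flagged.

Noise profiling reports total variation, an impulse fraction, and the
3x3-median residual variance. Two details matter. First, the impulse
fraction counts only saturated pixels that deviate from their local
median by more than 100 gray levels: clipped Gaussian noise on a dark
background also saturates pixels at 0, but those agree with their
neighbourhood and are not impulses. Second, the Gaussian/Poisson
decision uses the correlation, across 16 x 16 tiles, of local residual
variance with local mean intensity — Poisson variance scales with
intensity — evaluated only on flat, mid-intensity tiles (tile mean in
[40, 215], tile gradient below the 70th percentile), because clipping
and structural edges both induce spurious mean-variance correlation.
The decision order is: impulse gate first, then the variance floor,
then Poisson iff the correlation exceeds 0.5, else Gaussian.

## Segmentation

Per-pixel features are brightness and Sobel edge magnitude, each
min-max scaled to [0, 1] (no weighting between the two: the scaling is
the only normalization). A K-segment Lloyd iteration (assign to nearest
center in Euclidean distance, recompute centers as means) minimizes the
within-segment sum of squared distances; the fitness trace is
non-increasing and iteration stops at an assignment fixpoint. Centers
are initialized deterministically at the feature rows of K brightness
quantiles spanning the full range *including both extremes* — a small
bright mass occupies the top percent of the brightness distribution and
never seeds a center under midpoint quantiles.

ROI extraction embodies one empirical fact about this feature space: on
realistic images the converged clusters are typically {background,
edges, tissue-plus-mass} — the edge feature always wins a center — so
"the brightest cluster" is frequently the whole breast. The extractor
therefore applies a bounded refinement: while the brightest candidate
exceeds `max_area_frac` (default 0.15) of the frame, it is split by a
deterministic 1-D two-means on brightness and the brighter half kept,
at most three rounds. Gates: the candidate must be separated from the
rest by `min_contrast = 0.15` scaled-brightness units (normal images
fail here), a disc opening of radius `se_radius = 2` removes specks
(anti-extensive, never grows the mask), and the largest connected
component is kept with its internal boundary `M \ (M erosion N)`. An
empty or non-focal outcome is a flagged "no mass" result, not an error.

Morphology lives on a finite frame: translations that leave the frame
fail the containment test, so erosion shrinks at borders. This matches
the array implementation, keeps the exhaustive test oracle finite, and
is the documented reason erosion/dilation duality is asserted on
interior pixels only.

## Classification

The feature stack is frozen at construction from a seed: zero-mean
random 9x9 kernels (4 filters per layer) with replicate boundary
handling (as everywhere else in the package, so zero-mean kernels stay
exactly zero on constant images), sigmoid activations, 7x7
stochastic pooling (sampling proportional to activation magnitude at
training time, its magnitude-weighted expectation at inference — the
"random pooling" reading of stochastic pooling), a second 9x9
convolution, 5x5 sliding max pooling, then the atrous pyramid: the same
9x9 bank at dilation rates {1, 2, 3, 4, 6, 9, 12}. The rates were
chosen once to span fine-to-coarse context and to include the identity
rate, which the tests exploit (the rate-1 branch must equal direct
convolution exactly). Images are resized to 64 x 64 before the stack —
the classifier's "predefined size" — so receptive fields at the larger
rates still cover a meaningful image fraction. The feature vector is
the per-channel mean and standard deviation of the 28 atrous channels
(56 features), optionally concatenated with the nine tabular
attributes.

Training is a single linear solve. Features are standardized (training
statistics stored on the model), pushed through a frozen random dense
layer into the hidden design matrix `G` (intercept column appended),
and the output weights are `beta = pinv(G) targets`, the minimum-norm
least-squares solution via SVD with a relative cutoff of 1e-10; a
degenerate `G` falls back to a ridge solve (lambda 1e-6) with a
warning. Refitting identical data reproduces `beta` bit-identically.

The hidden architecture was a genuinely open design point. A stack of
two narrow random layers (10 then 2 units) was considered and rejected:
a 2-unit final layer caps `G` at rank 3, and measured hold-out accuracy
collapsed toward chance with most cases labeled suspicious. The default
is the standard extreme-learning-machine shape — one wide random layer
(256 units) — whose width gives the closed-form solve its capacity and
keeps hold-out accuracy comfortably above the experiment's 0.9 floor
across weight seeds. Multi-layer shapes remain available through
`hidden_units`.

Decisions are three-way: softmax over benign/malignant scores, and
"suspicious" whenever the top probability is below `tau` (default 0.6).
The suspicious rate is monotone non-decreasing in `tau` by
construction. For binary bookkeeping (ROC, sensitivity), suspicious
collapses to the positive side — an unclear case is never reported as
clean — and the full three-way confusion matrix is always emitted.

## CRF refinement

The dense CRF couples every pixel pair with a Potts compatibility times
two Gaussian kernels: appearance (positions at `theta_alpha = 8` px,
intensities at `theta_beta = 25` gray levels) and smoothness
(`theta_gamma = 3` px). Kernels are evaluated exactly — no
high-dimensional filtering approximation — which is intended for
instances up to roughly 96 x 96; the pipeline crops a window around the
detected ROI and downsamples it to at most 48 px a side. Each kernel
matrix is scaled by the reciprocal of its mean row sum (a global
scalar, preserving symmetry) so message magnitudes are O(1) regardless
of instance size; with that normalization the default weights are 1
(appearance) and 0.3 (smoothness), five mean-field iterations.

The unary seed blends an intensity likelihood with the segmentation
mask prior (0.6 / 0.4): the likelihood is a tanh ramp centered between
the mean mass and mean background intensity of the crop, so rim and
spicule pixels — whose gray level sits between the two — get
intermediate probabilities that the pairwise kernels can resolve. On a
small phantom calibration set this measurably raised refined-mask Dice
while keeping the argmax-energy trace non-increasing; a pure
mask-confidence unary either left the labels unchanged (small weights)
or destroyed spiculated margins (large weights). Mean-field iteration
does not guarantee monotone energy in general; the packaged tests
assert the property that matters — final energy at or below the initial
argmax energy — on the instances the pipeline actually produces.

## Particle filter

Localization treats the detection score map as observation evidence for
a static (or slowly moving) mass center. Particles are initialized by
sampling pixels proportional to the first score map (uniform fallback
when it is all zero), propagated by a Gaussian random walk
(`process_sd = 2` px/frame), weighted by the score map correlated with
a two-dimensional Gaussian observation kernel (`sigma1 = sigma2 = 3`
px), normalized, summarized by their weighted mean, and systematically
resampled. Everything is seeded; a degenerate point-mass observation
with zero process noise recovers the center exactly after one step.

## Evaluation conventions

PSNR uses the 8-bit peak (255); identical images report `Inf` (and the
JSON report serializes that as null). Dice of two empty masks is 1 by
convention. The ROC sweeps unique score thresholds with ties entering
together, and AUC is the trapezoidal area — equal to the
concordant-pair statistic, which the tests assert against a naive
pair-counting oracle. Splits are stratified per class; folds are dealt
round-robin after a seeded shuffle so fold sizes differ by at most one
case. Both accuracy and positive predictive value are reported, under
those names, to avoid the common conflation of the two.

## Problem sizes and determinism

The packaged experiment: 200 phantoms at 128 x 128, stratified 70/30
split plus 5-fold CV, CRF refinement on test cases (crops at most
48 px), particle filter on ten test cases with ten frames each. The
acceptance script additionally denoises 20 phantoms at 256 x 256 per
noise family. All stage seeds derive from one master seed; report JSON
excludes timings so reruns are byte-identical.

## Known limitations

- The exact dense CRF is quadratic in pixels; refining beyond ~96 x 96
  crops requires the usual filtering approximations, which are out of
  scope here.
- The stochastic-pooling training path consumes the RNG stream, so
  training-time features are only reproducible through the seeded
  wrapper; the packaged pipeline uses the deterministic expectation
  mode.
- Image-stack features alone separate the phantom classes only weakly
  (the spiculation signal survives global pooling only partially); the
  packaged experiment's headline accuracy rests on the stack plus the
  tabular attributes, mirroring metadata-aware CAD practice.
- The periodized DWT requires dimensions divisible by `2^levels`.
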