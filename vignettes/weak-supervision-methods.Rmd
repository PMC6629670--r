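---
title: "Weak supervision for aortic valve classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weak supervision for aortic valve classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Bicuspid aortic valve (BAV) is a congenital malformation — two valve
leaflets instead of three — visible in phase-contrast cardiac MRI as a flow
region that is more eccentric and more irregular than the near-circular
flow of a normal tricuspid valve (TAV). Large imaging biobanks contain
thousands of such sequences but essentially no labels, and BAV prevalence
is low (on the order of 6 per 100 in labeled subsets), so hand-labeling
enough positives for supervised learning is impractical.

`valveweak` implements a weak-supervision pipeline for this setting: noisy
threshold heuristics (labeling functions) vote on unlabeled frames; a
generative factor-graph label model estimates each heuristic's reliability
without ground truth and converts the votes into per-frame probabilistic
labels; those are aggregated into per-patient soft labels; and a
noise-aware sequence classifier is trained on the soft labels. Because the
real MRI data are access-restricted, the package ships a synthetic phantom
generator that reproduces the statistical structure the pipeline relies
on, and the entire system is developed and tested against phantoms.

# The phantom generator

`render_sequence()` draws a three-channel, 30-frame, 192x192 sequence per
patient (floating-point intensities in [0, 1]; a 12-bit quantized export is
available in the I/O layer):

* **MAG** — a bright quasi-elliptical flow region over Gaussian background
  noise (sd 0.05, background level 0.08). The region's intensity follows a
  raised-cosine temporal bump of half-width 8 frames, maximal at the
  planted peak frame; multiplicative texture (sd 0.08) refreshed per frame
  emulates turbulence. The bump is smooth and unimodal, and with peak
  frames drawn uniformly from 5–14 most temporal variation falls in the
  first 15 frames, as in real acquisitions.
* **CINE** — time-constant anatomy (vessel wall, smooth blobs, frozen
  noise).
* **VENC** — MAG re-centered on mid-gray with the sign flipped in a random
  half-plane. Only MAG feeds the default pipeline, so VENC fidelity is
  deliberately low-stakes.

The flow-region boundary is an ellipse (eccentricity is the planted shape
parameter) perturbed by random angular harmonics k = 2–4 whose total
amplitude is the `irregularity` parameter. Cohort defaults
(`sample_cohort_specs()`) plant the class contrast: TAV regions are larger
(radius 12 px), rounder (eccentricity 0.40 ± 0.10), smoother
(irregularity 0.10) and brighter (amplitude 0.78); BAV regions are
slightly smaller (11.5 px), eccentric (0.72 ± 0.10), irregular (0.32) and
dimmer (0.70). Radius scales by sex (F 0.93 / M 1.07) so that
sex-stratified normalization matters. These numbers were chosen once so
that the classes are *hard but learnable* — every labeling function is
better than chance but far from perfect, mirroring the reliability range
reported for real heuristics — and frozen; they are study conditions, not
tuning knobs.

What the phantoms do **not** emulate: cardiac anatomy other than the valve
region, regurgitation and turbulent-flow confounds (the dominant real
failure mode), k-space/phase-wrapping physics, scanner variation, and
patient motion. Passing tests therefore demonstrate that the pipeline's
machinery is correct and that the weak-supervision logic works when its
statistical assumptions hold; they say nothing about clinical performance.

# Preprocessing

The aorta has the most blood flow, so the per-pixel temporal standard
deviation of MAG (`pixel_variation_map()`) is maximal inside the valve
region. `localize_aorta()` slides a 32x32 window over the map (summed-area
table; exactly equivalent to exhaustive search) and returns the
maximum-sum window, ties broken by the smallest (top, left). We interpret
"pixel region of maximum variation" as the window-sum maximizer rather
than the argmax pixel because the localization target is a crop, and a
window statistic is robust to single-pixel noise. `find_peak_frame()`
returns the frame of maximal spatial standard deviation (ties to the
lowest index); `crop_and_align()` keeps the ±7-frame window around the
peak (boundary-clipped rather than padded — padding would invent data) and
copies pixels exactly. All public pixel and frame indices are 0-based.

# Shape primitives

Each aligned MAG frame is Otsu-binarized (`binarize()`; a constant frame
has no valid threshold and yields an empty, `defined = FALSE` mask), and
reduced to its largest 8-connected component. Five primitives are
computed: area (pixel count), perimeter (boundary contour length, diagonal
steps weighted sqrt(2) to reduce rasterization bias), eccentricity (from
normalized second central moments, with the 1/12 single-pixel moment so
thin shapes stay strictly below 1), mean intensity over the mask on the
raw frame, and ratio = area/perimeter^2 (bounded by the isoperimetric
1/(4*pi) up to rasterization error). Degeneracies (empty mask, zero
perimeter) set per-primitive `defined` flags, and every labeling function
abstains on undefined inputs. Primitives are normalized by sex-stratified
population means computed on the unlabeled cohort; unknown sex falls back
to the pooled mean (the least-assumption choice with only two strata).

# Labeling functions

Five threshold labeling functions vote {-1 = TAV, 0 = abstain, +1 = BAV}
on normalized primitives: LF_Area (small area -> BAV, large -> TAV),
LF_Perimeter (high perimeter -> BAV; positive-leaning), LF_Eccentricity
(high -> BAV, low -> TAV), LF_Intensity (high mean flow intensity -> TAV;
negative-leaning), and LF_Ratio (low ratio -> BAV, high -> TAV; its inputs
are area and perimeter, which drives dependency inference). Votes are
collected over the t-frame window centered on the peak frame (t = 6, an
inclusive window of 7 frames).

Thresholds live in a YAML config; the packaged defaults were calibrated
once from quantiles of a seeded 400-patient development cohort at 6%
prevalence (area q15/q70, perimeter q90, eccentricity q45/q88, intensity
q60, ratio q10/q55), mimicking how thresholds would be set from
distributional statistics of an expert-labeled development set. A note on
"better than random chance": at 6% prevalence a positive-only heuristic
cannot have majority-correct votes no matter how good it is (most items
are negative), so the better-than-chance requirement is checked as
class-balanced accuracy — evaluated on a balanced cohort normalized with
deployment population means — which is exactly the quantity the label
model's accuracy factor parameterizes. All five defaults score 0.68–0.96
on that check.

# The generative label model

`label_model()` fits a factor graph over the label matrix Lambda and the
latent frame labels y in {-1, +1}:

    p(Lambda, Y) ~ exp( sum_i [ theta0 y_i
                     + sum_j thetaAcc_j y_i Lambda_ij
                     + sum_j thetaLab_j 1(Lambda_ij != 0)
                     + sum_(j,k) theta_jk 1(Lambda_ij = Lambda_ik) ] )

* **Accuracy factors** couple votes to the latent label; thetaAcc_j maps
  to an implied class-balanced accuracy logistic(2 thetaAcc_j).
* **Labeling-propensity factors** absorb each function's abstain rate.
  Without them the accuracy weight is forced to reproduce the abstain
  rate, and with heterogeneous propensities the recovered ordering tracks
  propensity instead of accuracy (we verified this failure directly in
  simulation before adding the factor, which is standard in the
  data-programming model family).
* **Dependency factors** are pairwise agreement indicators for functions
  sharing input primitives (`infer_dependencies()`; e.g., the ratio
  function depends on the area and perimeter functions). Agreement
  factors capture shared-primitive redundancy while keeping the
  y-conditional closed-form, since they do not involve y.
* **Class prior** theta0 y: fitted by default. At 6% prevalence the
  symmetric model compresses the accuracy weights (ordering recovery in
  simulation went from 0/10 to 10/10 when the prior was fitted); it can
  be fixed to 0 or set from a prevalence estimate.

Weights are estimated by persistent contrastive divergence: full-batch
gradient steps whose expectations come from Gibbs sampling (positive phase
clamps Lambda and samples y from its closed-form conditional; the negative
phase advances a persistent chain over both Lambda and y by two
column-wise sweeps per update). Defaults: 250 updates, step size 0.05,
accuracy-weight init 0.7, final weights tail-averaged over the last 40% of
the trajectory. The init encodes the data-programming assumption that
labeling functions beat chance; a symmetric init at 0 sits on the
y <-> -y saddle, and the sign of the solution it falls into is a coin
flip. Zero-coverage functions are dropped (their weights are
unidentifiable), and a single function's accuracy weight is only
identifiable relative to an ensemble. Fits are deterministic under a
seed.

Posterior marginals are exact by two-state enumeration:
P(y = 1 | Lambda_i) = logistic(2 (theta0 + sum_j thetaAcc_j Lambda_ij));
propensity and dependency factors cancel. For patient aggregation the
class-prior term is **excluded** (`marginals(use_prior = FALSE)`): the
mean > 0.9 / min < 0.5 aggregation thresholds are calibrated for the
symmetric-model conditional (with a 6%-prevalence prior of about -1.2 no
marginal can reach 0.9 at all), and since theta0 shifts every score
equally, rankings and AUROC are unaffected either way. Patients whose
7-frame window satisfies neither rule are discarded; the discard fraction
is recorded in every run manifest.

# The noise-aware classifier

The sequence classifier follows the frame-encoder / sequence-encoder
design: a small convolutional network (default: one block of 6 filters,
5x5, stride 3, ReLU, global average pooling) encodes each 32x32 MAG frame;
a bidirectional tanh recurrent encoder (hidden 8 per direction) consumes
the frame features; soft attention (projection 6) pools the recurrent
states into a weighted mean embedding; and a logistic head classifies. Two
engineering choices matter at this scale: frame features are standardized
by a fixed affine computed from the training set at initialization (the
raw pooled features span two orders of magnitude, which cripples the
recurrent stack), and the head also receives the plain mean of the frame
features as a skip connection, so the attention path refines rather than
gates the frame-level signal. Architecture sizes are package defaults, not
reference values.

Rendering and the convolution data movement are implemented as small
C++ kernels (Rcpp) that consume R's RNG stream in a fixed draw order, so
all results remain reproducible under a single seed on one CPU.

Training minimizes the noise-aware loss — the expectation of binary
cross-entropy over each patient's probabilistic label, with predictions
clipped at 1e-7 — with Adam (lr 0.01, batch 16, L2 1e-3) and validation-based early
stopping on F1 with a 20-epoch burn-in and patience 15; the scale-up
experiment additionally caps every run at the same 3000-gradient-step
budget so that training cost is comparable across training-set sizes. The stopping F1 is computed at the best threshold on the
validation set rather than at 0.5: the decision threshold is tuned per run
anyway, and fixed-0.5 F1 is maximized by degenerate all-positive states on
balanced validation sets. The final decision threshold
(`tune_threshold()`) scans midpoints of sorted unique validation
probabilities and takes the lowest maximizer. Training is deterministic
under a seed in single-thread mode.

`build_training_set()` implements the two training-set constructions:
balanced sampling with replacement from the positive/negative
probabilistic-label bins (threshold 0.5, strict for the positive side),
and the hand-labeled baseline that oversamples positives to parity.
`augment_training_set()` enlarges a training set with label-invariant
affine copies (translation ±2 px, rotation ±10 degrees, scale 0.9–1.1; one
transform per sequence applied to every frame; integer translations are
exact pixel copies); the scale-up experiment adds two augmented copies per
sequence, matching the protocol in which augmented models performed best.

# The scale-up experiment

`scaleup_experiment()` reproduces the central claim at phantom scale: a
1200-patient cohort at 6% prevalence is split into a 700-patient unlabeled
weak pool, a 100-patient hand-labeled split (expected ~6 positives,
matching the 6:100 development sets used in practice), and
natural-prevalence validation (100) and test (300) splits — all splits
random, as in the study protocol; the split sizes were fixed in advance so
the test split carries roughly 18 positives. Weak training sets of sizes
50, 250, and 1000 and the hand-labeled oversampled baseline are trained
with identical architectures across 5 seeds each; every run early-stops
and tunes its threshold on the validation split and is scored on the test
split. The expected picture mirrors the reference findings qualitatively:
mean F1 grows with weak-set size, and the size-1000 weak model overtakes
the 100-example hand-labeled baseline. Absolute numbers are phantom-scale
and are not comparable to results on real MRIs.

Problem sizes throughout the package (cohort 1200, m = 10,000 rows and 20
fits for label-model recovery, 100 phantoms for preprocessing recovery,
500 masks for the isoperimetric property) are the package's chosen test
conditions, balancing statistical resolution against a single-CPU
workstation run.

# Numerical and degenerate-input choices

* Window/argmax ties: lowest (top, left) lexicographic; lowest frame
  index.
* Constant frames yield empty masks, not errors; empty masks propagate
  `defined = FALSE` and force abstains.
* Eccentricity is clamped strictly below 1; single pixels have
  eccentricity 0.
* Aggregation evaluates the mean rule before the min rule (their stated
  order); every input lands in exactly one of mean/min/discard.
* Probability ties in rankings are resolved by stable input order, and
  NDCG flags ties in an attribute.
* Confidence intervals over seeds use a Student-t interval (n = 5 is
  small; the interval method is otherwise unspecified in the reference
  protocol).
* The per-patient RNG is derived from one master seed, so cohorts are
  byte-reproducible and individual patients can be re-rendered in
  isolation.

# Known limitations

* The phantom class contrast is a modeling choice; real BAV/TAV shape
  overlap is unknown, so absolute metric values carry no clinical meaning.
* The classifier is deliberately small; with ~6 validation positives at
  natural prevalence, early stopping and threshold tuning remain noisy
  across seeds, which is visible as run-to-run F1 spread (the reference
  results show the same wide confidence intervals).
* Persistent contrastive divergence gives consistent orderings and useful
  marginals but is a biased likelihood optimizer; weights should be read
  comparatively, not as calibrated accuracies.
* The CINE and VENC channels exist for interface completeness; only MAG
  is validated end to end.
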