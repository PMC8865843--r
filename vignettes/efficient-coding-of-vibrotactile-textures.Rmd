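---
title: "Efficient coding of vibrotactile texture signals: models and methods"
author: "hapticAE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Efficient coding of vibrotactile texture signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

When a tool is slid over a textured surface, the surface's spatial
micro-structure becomes a vibration, and that vibration is what the haptic
system actually receives. `hapticAE` implements an analysis chain built
around one idea from efficient-coding theory: if a perceptual system's
representation arises from compressing its input as losslessly as possible,
then an artificial network trained only to compress and reconstruct those
inputs — with no access to labels — should end up organising them the way
perception does.

The chain is: simulate (or ingest) per-(participant, material) acceleration
recordings; band-pass and window them; train a 1-D convolutional
autoencoder with a small bottleneck; and then interrogate the learned code
three ways — linear decodability of material categories, agreement between
latent category geometry and rating-derived perceptual geometry, and the
temporal-frequency tuning of the latent dimensions against the two
canonical tactile afferent classes (RA, tuned near 40–60 Hz, and PC, tuned
near 250–300 Hz).

# The autoencoder

The encoder applies four 1-D convolutions (kernel 5 samples, same padding,
ReLU), each followed by a factor-4 max pool, so a 256-sample window (80 ms
at 3200 Hz) is reduced along time as 256 → 64 → 16 → 4 → 1 while feature
counts run 64, 32, 16, `latentDim`. The bottleneck is therefore one time
step of `latentDim` features — the *code*. The decoder mirrors this with
step-repetition upsampling (each time step repeated four times) through
feature counts 16, 16, 32, 64 and a final sigmoid convolution back to one
256-sample channel. Training minimizes mean absolute error for 50 epochs
in the canonical configuration. For wider bottlenecks (the compression
sweep) every intermediate feature count is clamped to at least
`latentDim`, so no layer is narrower than the code.

The compression sweep takes an explicit list of bottleneck sizes; the
defaults — 16, 64, 128, 192, 256 — step the compression rate through
6.25, 25, 50, 75 and 100 %.

No deep-learning framework is available to R in this project's
environment, and the autoencoder is the central instrument rather than a
standard step, so it is implemented natively (RcppArmadillo): im2col/GEMM
convolutions, max-pool argmax bookkeeping for exact gradients, Adam
(learning rate 1e-3, batch 128 — conventional defaults for this model
family; the optimizer is not part of the scientific claim), single
(float32) precision as is conventional for such models. Weight initialisation is
Glorot-uniform from R's RNG; batch order comes from a C++ Mersenne Twister
seeded from the `seed` argument, so a (spec, data, seed) triple reproduces
the loss curve bit-for-bit.

# The synthetic-data generator

The generator exists so that every stage is testable without the archived
recordings. It emulates the study conditions: 81 material samples in 7
categories (12, 12, 12, 12, 11, 11, 11 — the per-category breakdown is not
recorded anywhere, so an even split is used), 11 participants, 10 s
recordings at 3200 Hz, and rating tables with 7 descriptor and 7
category-similarity scales.

Per category, a base spectral envelope is a mixture of 2–4 Gaussian bumps
between 20 and 700 Hz (inside the 10–800 Hz analysis band); categories are
redrawn until all pairwise envelope correlations fall below 0.8. Each
material then perturbs its category envelope (lognormal bump-amplitude
jitter, SD 0.4; 3% centre jitter) and — crucially — blends it with the base
envelope of one random other category by a weight drawn from [0, 0.8].
This mixing models a well-documented feature of everyday materials: some
samples of one material are systematically perceived as being made of
another. Recordings
are Gaussian noise spectrally shaped by the material envelope, with the
frequency axis scaled by a per-participant exploration-speed factor
(log-uniform in [0.8, 1.25]; free exploration leaves stroke speed
uncontrolled), plus a sub-10 Hz hand-movement drift band, a >800 Hz sensor-noise
band (both there for the band-pass stage to remove), and an in-band
broadband noise floor (gain 0.35) standing in for contact/sensor noise
that filtering cannot remove.

Ratings: each material's 7 latent haptic attributes are projections of its
full envelope (level included — vibration intensity co-determines percepts
such as roughness) onto smooth random frequency profiles; descriptor
ratings add participant noise (SD 0.8). Category-similarity ratings peak
at the true category via an additive truth bonus, except that with
probability 0.45 a rating follows the signal instead: its peak moves to
the category whose base envelope the material's own envelope resembles
most. Drifted materials are thereby relabelled consistently across
participants — the mechanism that lets perceptual labels align better with
the codes than ground-truth labels do.

These free parameters were calibrated once against the behavioral
anchors of the experimental setting the generator emulates —
between-participant agreement near 44% and linear-classification
accuracies in the mid-30s to mid-40s percent — and then frozen. With the defaults the synthetic study lands at roughly 47%
agreement and 35–45% accuracy. What the generator does *not* model:
contact biomechanics, accelerometer transfer functions, non-stationary
exploration within a trial, and rating-scale discreteness. Passing tests
on this data therefore demonstrate the correctness and internal coherence
of the pipeline, not that real recordings would reproduce any particular
laboratory experiment's numeric results.

# Preprocessing choices

Filtering uses a 4th-order Butterworth band-pass (10–800 Hz) applied
forward–backward for zero phase; the band is dictated by the analysis,
the filter design is this package's choice. Filtering precedes segmentation (the alternative order would let
boundary transients dominate 256-sample windows). Windows tile the
recording without overlap; 10 s at 3200 Hz gives 125 windows of 256
samples. Normalization is one global affine map to [0, 1] from the
training set's min/max — per-segment scaling would erase amplitude
differences between materials that the code must represent; test data uses
the training constants and clips. The train/test split (95/5) is random at
the segment level with `floor` rounding; windows of one material can
land in both sets (the split is not grouped).

# Latent-space analyses

PCA is fitted on the codes of the full data set (train plus test); the
retained dimensionality `k` is the smallest number of components reaching
95% cumulative explained variance, and all category geometry (embeddings,
centroids, distances) lives in that k-D *latent PCs space* rather than in
the raw codes. Material embeddings average
the projected codes of all windows of a material. Category distances are Euclidean between centroids. The perceptual
distance between categories is `delta = 2 * (1 - rho)` by default, with
`rho` the mean pairwise correlation of material descriptor vectors; the
conventional correlation distance `sqrt(2 * (1 - rho))` is available
behind a switch. Both are strictly decreasing in `rho`, and the choice
only mildly affects correlations between distance matrices. Distance matrices are compared by Pearson correlation over the
21 category pairs.

The 2-D t-SNE view is a visualization aid only. No t-SNE implementation
for R exists in this project's dependency set, so the package carries a
compact exact (non-Barnes–Hut) implementation — affinities with perplexity
calibration by bisection, early exaggeration, adaptive gains — which is
entirely adequate for 81 points (perplexity 10 by default).

# Classification and its null

Classification is linear discriminant analysis (`MASS::lda`) on the
per-material embeddings; LDA is the minimal-assumption linear choice and
is swappable. The folds leave out one material per category at a time:
the fold count is the largest category size and each category cycles its
materials (sorted by id) through folds, so every material is tested at
least once.
Embedding columns are standardized first — a discriminant is
affine-invariant, and this keeps tiny-scale PC columns clear of `lda`'s
absolute constant-variable guard. The null distribution re-runs the whole
scheme 5000 times with labels shuffled over materials; the mean is the
empirical chance level and the 2.5th/97.5th percentiles give the CI.
Argmax and majority-vote ties break to the lowest category index, with a
log message.

# Temporal tuning probe

The probe bank holds 830 frequencies uniformly spanning 0–800 Hz (the 0 Hz
endpoint is replaced by the first positive grid frequency; a true DC probe
is the baseline itself), each at 8 phases, amplitude 0.25 around the 0.5
mid-range. The
response of a latent dimension at a frequency is the phase-averaged
absolute deviation of its projection from the baseline response to the
constant-0.5 signal — an operational definition this package supplies,
since a non-spiking model has no ready-made notion of response
sensitivity.
Curves are min–max normalized per dimension; flat dimensions are flagged
degenerate and excluded from clustering. The tuning summary is the
sensitivity-weighted mean frequency; 1-D k-means (k = 2, 25 restarts)
orders the groups as low/high. The bundled afferent reference table is a
constructed stand-in — log-Gaussian curves peaking inside the canonical RA
(40–60 Hz) and PC (250–300 Hz) bands, labelled synthetic in its filename —
not digitized physiology; users can supply their own table.

# Problem sizes used by the test-suite

The packaged tests run the full scientific chain at reduced scale, chosen
so the suite completes comfortably on a single CPU while leaving the
qualitative structure intact: a 3-participant x 81-material corpus of 2 s
recordings (6,075 windows), training subsets of 2,000 windows, and 10
epochs for the compression-monotonicity checks (2 seeds per bottleneck
size); the bootstrap-null check uses 1,000 label shuffles (the canonical
analysis uses 5,000, as does the acceptance script). At this scale
reconstruction R-squared is far below the values a 50-epoch run on the
full 111,375-window corpus reaches; the tests therefore assert directions,
invariants and exact bookkeeping, not absolute performance.

# Known limitations

* Reduced-scale training leaves all models far from convergence; metrics
  that depend on converged representations (distance-matrix correlations
  in particular) are noisy across seeds at test scale.
* The native autoencoder is single-threaded; a 256-feature model on the
  full corpus is a long run (hours, not minutes).
* Real-data ingestion assumes recordings are already the clean 10 s
  window; no trimming or artifact rejection is implemented.
* The exact t-SNE is quadratic in the number of points; it is meant for
  material-level maps (dozens of points), not segment-level ones.
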