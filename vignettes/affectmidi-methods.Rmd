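---
title: "Decoding affect from EEG and generating MIDI: models and design choices"
author: "affectmidi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding affect from EEG and generating MIDI: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Brain--computer interfaces can read out a listener's affective state --
summarized as *arousal* (calm to excited) and *valence* (negative to
positive), each self-rated on a 1--9 scale in DEAP-style studies -- while the
listener hears music. `affectmidi` implements a three-stage pipeline that
turns such EEG readouts into symbolic music:

1. **EEG conditioning.** Polyphase downsampling (e.g. 512 to 128 Hz),
   zero-phase 4--45 Hz band-pass, common average reference, and
   segmentation of each one-minute trial into ten non-overlapping 6-s
   windows aligned with the music.
2. **Supervised feature extraction.** A compact convolutional network
   (EEGNet) regresses normalized arousal/valence from each EEG window
   through two sigmoid heads; in parallel, a residual convolutional
   autoencoder compresses each 6-s binary piano-roll window into a latent
   code, optionally supervised by a Centered Kernel Alignment (CKA) loss
   that pulls the code geometry toward the affective-label geometry.
3. **Affect-driven retrieval.** An EEG window's predicted
   (arousal, valence) point retrieves the k = 5 nearest training windows in
   label space, weights them by a softmax over negative distances, forms the
   convex combination of their latent codes, and decodes it back to a
   piano-roll / MIDI clip.

Every stage is testable offline because the package ships a synthetic-data
generator emulating the structure of the DEAP recordings.

# Models

## EEG conditioning

*Filter.* The band of interest is 4--45 Hz. The paper-style conditioning
chain does not pin a filter family, so we use the standard EEG choice: a
4th-order Butterworth applied forward and backward (`signal::filtfilt`),
which is zero-phase and has a testable magnitude response (a 2 Hz sine is
attenuated below 10% RMS; a 20 Hz sine passes within 10%).

*Reference.* "Common-reference spatial filtering" is read as the common
average reference: the per-sample channel mean is subtracted, so every
output column sums to zero. Since both CAR and the band-pass are linear and
time-invariant they commute, which the suite verifies to 1e-8.

*Labels.* Raw 1--9 ratings are normalized as `(raw - 1) / 8`, matching the
sigmoid output range of the regression heads; binarization uses
`raw > 5`. Quadrants of the arousal x valence plane are numbered 1 = HA/HV,
2 = HA/LV, 3 = LA/LV, 4 = LA/HV.

*Fade-out exclusion.* The published stimulus set drops 9 of 400 windows with
fade-out endings; which ones is data-dependent and unrecoverable, so only
the rule's shape is implemented: a window is excluded when its final-second
note activity falls below a configurable fraction (default 5%) of its mean
activity.

## EEGNet

The architecture is the printed configuration: a temporal convolution
(F1 = 4 filters, kernel 1 x 4, no bias) learning frequency filters, a
depthwise spatial convolution over the full montage (kernel Nc x 1, depth
multiplier 2), ELU, average pooling 1 x 4, dropout 0.6, a separable
convolution (F2 = 32, kernel 1 x 16), ELU, average pooling 1 x 8, dropout,
flatten, dense head. Batch normalization follows each convolution.

The printed table's concrete pooled shapes presuppose Nt = 128 input
samples, while 6-s windows at 128 Hz give Nt = 768; shapes are therefore
computed dynamically from Nt, and the tests pin both cases (flatten length
128 at Nt = 128; 768 at Nt = 768, both `F2 * floor(floor(Nt/4)/8)`).

Two heads are provided. The regression head (two sigmoid units, summed
mean-squared error) is the pipeline's default; a K-class softmax head with
categorical cross-entropy (K defaulting to the 4 quadrants) supports the
classification experiments. Optimization is Adam with optional L2 weight
decay; classification loss/optimizer are unspecified upstream, so the
conventional categorical cross-entropy + Adam is used.

The per-segment validation scoring used for ranking subjects is the mean
binarized accuracy of the two heads on the held-out windows; the upstream
"dimensionality reduction to identify the optimal temporal segments" is
under-specified, and we deliberately implement only this transparent
variant.

## Piano-rolls and NMF transcription

A piano-roll is a binary pitch x time mask at a fixed frame rate (default
16 frames/s, so a 6-s window is 96 frames -- divisible by 8, which the
autoencoder's three stride-2 stages require). MIDI-to-roll conversion marks
frames `floor(onset*fs) <= t < ceil(offset*fs)`; roll-to-MIDI recovers
maximal runs per pitch row, dropping runs shorter than `min_frames`
(default 11, mirroring the transcription tool's "minimum note length 11",
whose unit we read as frames) at 120 BPM.

For raw audio, transcription is non-negative matrix factorization of the
magnitude spectrogram: `Z ~ D A` with both factors nonnegative, fitted by
multiplicative updates. The distance is not pinned upstream, so the default
is the Frobenius (Euclidean) cost with Lee--Seung updates -- the simplest
rule with a provable non-increasing objective, which the tests assert on
every input -- with generalized Kullback--Leibler as an option. Matrix
orientation is standardized internally to frequency x time (the printed
dimensions are inconsistent between `Z` and `DA`; we transpose at I/O).
Because the factorization alone does not say which template is which note,
the transcription path fixes the dictionary to idealized harmonic templates
(Gaussian bumps at the first harmonics of each MIDI pitch) and updates only
the activations, making the template-to-pitch mapping well-defined. A cell
is active when its template's activation reaches a threshold fraction
(default 0.3 in transcription) of that template's maximum.

## The piano-roll autoencoder

The encoder follows the printed residual configuration: a 1 x 1 stride-2
convolution to F1 = 32 channels, then two residual blocks (F2 = 64,
F3 = 128), each adding a main path -- two separable 3 x 3 convolutions with
batch normalization and a 3 x 3 stride-2 max-pool -- to a projection
shortcut (3 x 3 stride-2 convolution, dropout 0.5, ReLU). Three stride-2
stages map `Np x Nt x 1` to `(Np/8) x (Nt/8) x 128`; the flattened
bottleneck is the window's latent code (24 576 dimensions at the full
128 x 96 roll). The printed shortcut kernel size 3 (where 1 is conventional)
is followed as printed.

The decoder is not specified upstream. It mirrors the encoder with
nearest-neighbour upsampling and separable convolutions, ending in a
per-pixel sigmoid -- and deliberately has **no** encoder-to-decoder skip
connections: the retrieval stage decodes codes that never passed through
the encoder, so the bottleneck must suffice on its own. This is the reason
a U-Net-style decoder was rejected.

The loss is per-pixel binary cross-entropy (the roll is a two-label
segmentation target). With `cka_weight > 0` the batch loss adds
`cka_weight * (1 - rho_CKA(K_code, K_target))`, computed per mini-batch
(alignment is batch-estimable; batches of at least 8 are enforced). The
target kernel defaults to the linear kernel on the (arousal01, valence01)
pairs; a kernel on externally supplied features (e.g. EEGNet penultimate
features) is the alternative -- the upstream description supports both
readings, and the label target was chosen as the default because it is
self-contained and directly testable.

## Centered kernel alignment

For two sample-aligned feature sets, CKA is the normalized Frobenius inner
product of doubly-centered kernel matrices

$$\rho(K_a, K_b) = \frac{\langle \bar K_a, \bar K_b\rangle_F}
  {\lVert \bar K_a\rVert_F \lVert \bar K_b\rVert_F},
  \qquad \bar K = H K H,\; H = I - \tfrac1n \mathbf{1}\mathbf{1}^\top,$$

bounded in [0, 1], symmetric, and (for the linear kernel) invariant to
rotation and isotropic scaling of the features. The self-referential
notation of the centering step in the source description is implemented as
the standard `HKH`. The kernel family is not pinned; the linear kernel is
the default for the loss (cheap, smooth), with an RBF option using the
median-distance bandwidth. Constant features make the expression 0/0 and
raise an error rather than returning 0 or 1. The loss term `1 - rho` has an
analytic gradient in the features (used to supervise the bottleneck), which
a finite-difference check verifies to 1e-4 relative error.

## Affect-driven retrieval

For each query, Euclidean distances from the predicted (arousal, valence)
point to all training labels are passed through a softmax over **negative**
distances, truncated to the k = 5 largest weights, and renormalized to sum
to one. Two upstream ambiguities are resolved here and flagged:

* the printed softmax formula weights *larger* distances more, but the
  accompanying algorithm selects `Top5Indices(-distances)`; nearest-neighbour
  semantics and the algorithm win, so near neighbours dominate;
* whether weights are renormalized after top-5 truncation is unstated;
  renormalization was chosen so predicted codes are exactly convex
  combinations of the selected codes -- a contract the tests assert
  coordinate-wise;
* the squared-distance notation surrounding the word "Euclidean" is read as
  the plain Euclidean distance (a squared option exists and affects only
  weight sharpness).

Predicted codes are decoded and binarized at threshold 0.5.

# The synthetic cohort

The generator emulates the *structure* of the DEAP study -- per subject, 40
one-minute trials of 32-channel EEG at 128 Hz with a paired one-minute music
clip and a 1--9 arousal/valence rating -- with monotone, single-parameter
couplings chosen for testability:

* **EEG**: pink (1/f) noise of configurable standard deviation (default 1),
  plus a 10 Hz component whose amplitude decreases with arousal, a 30 Hz
  component whose amplitude increases with arousal, and a 20 Hz left/right
  amplitude asymmetry tracking valence. Effect sizes default to 1, giving
  oscillation amplitudes of the same order as the noise -- an alpha-band
  signal-to-noise a practitioner would call favourable but not absurd.
* **MIDI**: note rate rising from about 2 to 3.5 notes/s with arousal
  (at unit effect), register centre and interval set (major-like vs
  minor-like) shifting with valence, onsets on a jittered grid so that
  roll conversion is exactly invertible at the frame level.
* **Ratings**: quadrant-balanced, drawn uniformly from the low ([1, 4.5])
  or high ([5.5, 9]) half of the scale so binarization is never ambiguous.

Trial stimuli are MIDI clips directly (no video, no audio synthesis): the
pipeline consumes piano-rolls, so transcribing synthesized audio first would
only add a tested-elsewhere step. Ratings stay on the 1--9 scale so the real
dataset can be swapped in unchanged.

**What the simulator does not capture** -- and therefore what green tests do
and do not show: real EEG is nonstationary, artifact-laden and spatially
correlated in ways pink noise plus three sinusoids is not; which EEG
features actually carry emotion information in DEAP is an open question,
and the simulator's spectral couplings are a stand-in, not a
neurophysiological claim; real music has long-range structure the
first-order note process lacks. Passing tests demonstrate that the
*pipeline machinery* behaves as specified and that the *couplings it
assumes* are recoverable end to end -- not that the published
human-data accuracies would be reproduced.

# Numerical choices and problem sizes

* All training is seeded; batch-norm running statistics, dropout masks and
  shuffles derive from the seed, so reruns are bit-identical on a single
  thread.
* Adam (1e-3 to 1e-2 depending on model size), BCE probabilities clamped to
  [1e-7, 1 - 1e-7], NMF denominators guarded by 1e-12, histogram KL
  smoothed by eps = 1e-10 on 30 shared bins (this estimator gives exactly 0
  for identical samples, matching the baseline row of the published
  comparison table).
* The stratified 80/20 split takes `floor(0.8 n)` training items, allocating
  per-quadrant counts by largest remainder (ties to the lower quadrant id):
  391 segments give 312 training items, and quadrant proportions stay
  within one item of the global ones. "Cross-validation" is read as
  repeated seeded holdout; the fold count is configurable because the
  upstream description names none.
* The test suite and the acceptance script run at desk scale, a deliberate
  package choice so the whole evaluation re-runs quickly on one CPU:
  16-pitch x 24-frame rolls (4 frames/s over the two-octave window 48--63),
  6-channel EEG, 12--24 trials per subject, cohorts of two subjects with the
  degraded subject's couplings halved, three seeds per stochastic claim with
  the median compared. The architecture code is size-generic; the full
  128 x 96 configuration is exercised for shape and parameter-count
  correctness.
* Dice between two empty masks is defined as 1 (identity of equals). The
  scalar used to compare pitch-class histograms across groups is their
  Shannon entropy (tonal concentration); the upstream table's absolute
  magnitudes are not reproducible because its normalization is unstated, so
  group comparisons anchor on the exact self-comparison identities
  (KL = 0, overlap = 1) and on ordering claims.
* Group "mean/std" columns report the mean and standard deviation of
  absolute rank-paired differences (values sorted within group, paired up
  to the shorter length) -- one reading of an ambiguous upstream summary;
  self-comparison then gives exactly 0.

# Known limitations

* Decoding a convex combination of latent codes is conservative: averaged
  codes decode to lower per-pixel probabilities than any single code, so
  generated rolls are sparser than training rolls at threshold 0.5. The
  subject-comparison experiment relies on the *relative* overlap ordering
  (intact coupling above degraded coupling), which is robust to this, and
  the effect is strongest at desk scale where the autoencoder sees tens of
  windows rather than hundreds.
* The layer engine is plain R matrix algebra; it is exact (finite-difference
  verified) but not fast. Paper-scale training (24 576-dimensional codes,
  hundreds of epochs) is out of reach of this implementation on one CPU and
  is not attempted anywhere in the suite.
* Only mono audio and single-instrument binary rolls are supported; no
  onset/velocity modelling beyond the mask, and no multi-instrument
  separation.
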