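# affectmidi

Decoding a listener's affective state from EEG and turning it into symbolic
music. `affectmidi` is an R implementation of an EEG-to-MIDI pipeline for
researchers in affective computing and brain--computer interfacing: it
conditions multichannel EEG, regresses continuous valence/arousal from each
window with a compact convolutional network (EEGNet), compresses paired
piano-roll music windows with a residual convolutional autoencoder whose
bottleneck can be supervised by a Centered Kernel Alignment (CKA) loss on
the affective labels, and generates music for unseen EEG by softmax-weighted
nearest-neighbour retrieval of latent piano-roll codes.

## The model in brief

**EEG branch.** Windows `X ∈ R^{C×T}` (C channels, T samples; 4–45 Hz
band-passed, common-average-referenced, 6 s at 128 Hz) pass through EEGNet —
temporal convolution (F1 = 4, kernel 1×4), depthwise spatial convolution
(kernel C×1, depth 2), separable convolution (F2 = 32, kernel 1×16), average
pooling 1×4 and 1×8, dropout 0.6 — into two sigmoid heads trained with MSE
against the normalized ratings `(raw − 1)/8 ∈ [0, 1]`.

**Music branch.** Each 6-s window of a binary piano-roll `M ∈ {0,1}^{Np×Nt}`
(from MIDI directly, or from audio via NMF transcription `Z ≈ DA` with
multiplicative updates against harmonic templates) is compressed by three
stride-2 residual stages to a latent code of dimension `(Np/8)(Nt/8)·128`,
trained with per-pixel binary cross-entropy plus an optional alignment term

```
L = BCE(M, M̂) + λ · (1 − ρ_CKA(K_code, K_label)),
ρ_CKA(Ka, Kb) = ⟨H Ka H, H Kb H⟩_F / (‖H Ka H‖_F ‖H Kb H‖_F)
```

**Retrieval.** A query's predicted (arousal, valence) point is compared with
all training labels by Euclidean distance `d`; weights `w ∝ exp(−d)` are
truncated to the top k = 5 and renormalized; the convex combination
`x_code = w · Y_code` of the training codes is decoded and binarized to a
piano-roll/MIDI clip. Generated and training groups are compared with
symbolic-music metrics — pitch-class count (PC), pitch range (PR), mean
inter-onset interval (IOI), pitch-class histogram (PCH) — via histogram KL
divergence and overlap area, plus the Dice coefficient for mask agreement.

A synthetic cohort generator emulates the DEAP study structure (per subject,
40 one-minute trials, 32-channel EEG at 128 Hz, 1–9 ratings, paired
one-minute clips whose note rate, register and mode covary with the
ratings), so the entire pipeline is testable without the external dataset.

## Worked example

One simulated subject, 16 twelve-second trials, 6-channel EEG, two-octave
rolls at 4 frames/s:

```r
library(affectmidi)

cfg <- sim_config(n_subjects = 1, n_trials = 16, trial_seconds = 12,
                  n_channels = 6, fs_roll = 4, pitch_lo = 48, pitch_hi = 63,
                  seed = 7)
sub <- simulate_dataset(cfg)$subjects[[1]]
res <- run_subject_pipeline(sub, cfg, window_s = 6,
                            eegnet_epochs = 25, eegnet_lr = 3e-3,
                            ae_epochs = 120, ae_lr = 1e-2,
                            ae_filters = c(8, 16, 32), ae_dropout = 0.2,
                            cka_weight = 0.5, k = 5, seed = 7)

res$n_segments; res$n_train; res$n_test
#> [1] 32
#> [1] 25
#> [1] 7
res$val_accuracy        # binarized test accuracy, mean of the two heads
#> [1] 0.8571429
tail(res$ae_history, 1) # reconstruction loss and batch CKA after training
#>     epoch  rec_loss       cka
#> 120   120 0.1429656 0.9800586
print(res$report, digits = 3)
#>   metric  mean   std   kl overlap
#> 1     pc 2.000 0.816 20.2    0.04
#> 2     pr 9.857 5.305 21.3    0.04
#> 3    ioi 0.626 0.775 21.1    0.00
#> 4    pch 0.862 0.456 19.7    0.04
```

Reading the output: the 16 trials give 32 aligned 6-s EEG/roll windows,
split 25/7 stratified by emotion quadrant. EEGNet classifies the held-out
windows' high/low arousal and valence at 86% after binarization. The
autoencoder reaches a per-pixel reconstruction loss of 0.14 while the
bottleneck kernel aligns with the label kernel at ρ ≈ 0.98 (the CKA term at
work). The report compares the seven generated piano-rolls with the 25
training rolls per metric: at this desk scale, decoded convex combinations
of codes are much sparser than real windows, so absolute overlaps are small
— the meaningful signal, exercised by the cohort experiment below, is the
*ordering* of overlaps between subjects with intact versus degraded
EEG-label coupling. `subject_report()` on a multi-subject `run_pipeline()`
manifest ranks subjects by validation accuracy and emits the
training-vs-training (identity: KL 0, overlap 1), training-vs-worst and
training-vs-best comparisons.

A thin command-line front end over the same functions is installed at
`inst/cli/affectmidi.R` (subcommands `simulate`, `midi2roll`, `roll2midi`,
`cka`, `evaluate`, `pipeline`).

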