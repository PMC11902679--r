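Package: affectmidi
Title: EEG Affect Decoding and Emotion-Conditioned MIDI Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline that couples EEG-based emotion decoding with symbolic
    music generation. EEG epochs are conditioned (polyphase resampling,
    zero-phase band-pass filtering, common average referencing, non-overlapping
    windowing) and fed to a compact convolutional network (EEGNet) that
    regresses valence and arousal through dual sigmoid heads. Music clips are
    represented as binary piano-roll masks, obtained either from MIDI files or
    from audio via non-negative matrix factorization transcription, and
    compressed by a residual convolutional autoencoder whose bottleneck can be
    supervised with a Centered Kernel Alignment loss against the affective
    labels. EEG-predicted emotion coordinates retrieve latent piano-roll codes
    by softmax-weighted nearest neighbours, which are decoded back to MIDI.
    Includes a synthetic cohort generator emulating DEAP-style recordings,
    symbolic-music evaluation metrics (pitch class count, pitch range,
    inter-onset interval, pitch-class histogram, Dice), and distribution
    comparison via histogram KL divergence and overlap area.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
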