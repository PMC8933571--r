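Package: alarmsieve
Title: Contrastive Siamese Deep Learning for ICU False Arrhythmia Alarm Reduction
Version: 0.1.0
Authors@R:
    person("Alarmsieve", "Developers", email = "alarmsieve@example.org",
           role = c("aut", "cre"))
Description: Discriminates true from false ICU arrhythmia alarms
    (asystole, extreme bradycardia, extreme tachycardia, ventricular
    tachycardia, ventricular flutter/fibrillation) from multi-channel
    bedside-monitor waveforms. Implements a parallel multi-kernel 1-D
    convolutional signal encoder trained as a Siamese network with a
    pair-wise discriminative constraint between the 10-s alarm segment
    and a randomly sampled pre-alarm baseline segment, fused with a
    learned alarm-type embedding and an embedding of a rule-based
    verifier score, and evaluated with the PhysioNet/CinC Challenge
    2015 score. Ships a WFDB reader/writer, a synthetic alarm-record
    simulator with per-type rhythm signatures and artifact-driven
    false alarms, a reference QRS-detection rule scorer, fivefold
    cross-validation, an ablation grid, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
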