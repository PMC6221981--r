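Package: execrt
Title: Simulation and ERP Analysis Pipeline for a Go/NoGo Executive
    Reaction Time Task with Emotional Distractors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse a Go/NoGo executive reaction time
    experiment with task-irrelevant emotional distractors, as used in
    EEG studies of emotion-attention interaction.  Includes a seeded task
    scheduler with exact 50:50 counterbalancing, generators for trial-level
    behaviour and continuous multichannel EEG with injected event-related
    potential (ERP) components and realistic artifacts, a preprocessing chain
    (downsampling, zero-phase IIR band-pass filtering, ocular-artifact
    regression, voltage-jump rejection, linked-earlobe re-referencing,
    segmentation and baseline correction), ERP feature extraction (windowed
    N2/P3 peaks, N2P3 peak-to-peak amplitudes, emotional-minus-neutral
    difference waveforms and late-positive-potential window means), behavioural
    scoring with error taxonomies, quality-control rules and odds ratios, and
    a mixed between/within repeated-measures ANOVA engine with
    Greenhouse-Geisser correction and generalized eta squared.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
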