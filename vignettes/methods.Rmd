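---
title: "Methods: simulating and analysing a Go/NoGo executive RT task with emotional distractors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a Go/NoGo executive RT task with emotional distractors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(execrt)
```

## The task and its measurement model

`execrt` implements an end-to-end analysis pipeline for a Go/NoGo visual
reaction-time paradigm with task-irrelevant emotional distractors. Each trial
begins with a white triangle (0--150 ms from trial onset) whose orientation
must be held in working memory; 150 ms after its offset (i.e. 300 ms from
onset) a traffic-light cue signals Go or NoGo, with the colour-to-meaning
rule reversed in half of the blocks. On Go trials the response button encodes
the memorized orientation (up = middle finger, down = index finger). A
distractor — a threat-related or a neutral figure composed of identical line
elements — appears with the cue. Three error types exist: misses and
incorrect button presses on Go trials, commission errors on NoGo trials.

The electrophysiological read-outs are event-related potentials (ERPs)
time-locked to trial onset: the N2 (most negative peak in 450--670 ms, i.e.
150--370 ms after the cue), the P3 (most positive peak in 600--900 ms), the
N2P3 peak-to-peak amplitude (P3 minus N2, a robust index of attention
allocation that cancels slow baseline shifts), and the late positive
potential (LPP) quantified as mean amplitudes of emotional-minus-neutral
difference waveforms in fixed 100-ms windows (600--700, 700--800,
800--900 ms).

## Synthetic data as a stated world

The original study's recordings are not public, so every downstream stage is
exercised on synthetic data with known ground truth. The generator is
first-class, tested code, and its defaults encode the published design:

* 16 blocks x 64 trials = 1,024 trials, with Go:NoGo, emotional:neutral and
  up:down each balanced exactly 50:50 (the cue x distractor crossing balances
  exactly as well), half of the blocks with the reversed rule, half performed
  with the left hand.
* Inter-trial onset interval 2,600 ms. The interval is not printed in the
  source description; 2,600 ms accommodates the 2,000-ms epoch plus margin
  and is configurable. Cue/distractor duration defaults to 300 ms for the
  same reason.
* Error-rate presets. The published per-category rates (miss 0.2% vs 0.9%,
  incorrect 1.2% vs 2.9% for control vs lesion groups) are read as
  proportions of *all* trials, which makes the printed totals (2.1% vs 4.7%)
  the exact sums once commission errors (0.7% vs 0.9% of all trials) are
  included — and implies commission rates that barely differ between groups,
  matching the published null result for commissions. Per-eligible-trial
  probabilities are twice the all-trials rates (half the trials are Go).
  One uniform draw per Go trial partitions miss / incorrect / correct, so
  simulated frequencies converge to the stated rates exactly.
* Reaction times are log-normal (median ~430--450 ms, sdlog 0.37,
  reproducing the published means of ~460--480 ms with SD ~180 ms), so
  log-RT is normal by construction, matching the analysis-side log
  transformation.
* ERP components are Gaussian bumps in time, with amplitude x topography
  per channel: N2 (-4.5 uV, 530 ms, SD 65 ms, fronto-central), P3 (+5 uV,
  760 ms, SD 80 ms, centro-parietal), LPP (+2 uV, 840 ms, SD 110 ms,
  parietal). Gaussians were chosen for a smooth, unambiguous peak; widths
  are broad enough that the 11-sample peak mean (below) sits within ~2% of
  the true extremum, so the noiseless pipeline check isolates filter
  fidelity rather than estimator bias.
* Group presets encode the published findings qualitatively: the
  control-like profile adds +0.6 uV of Go-condition N2P3 modulation by
  emotion over the right hemisphere (F4/C4/P4, implemented on the P3
  component); the lesion-like profile instead adds +0.6 uV of Go LPP
  modulation at the left parietal site and -0.45 uV (an increase) of NoGo
  N2 modulation.
* Background noise is white plus 1/f (spectral shaping with exponent 1, the
  standard EEG surrogate); blinks are 400-ms half-sines (150 uV at an
  EOG-proxy channel, frontally weighted on scalp channels); step artifacts
  exceed the 100-uV rejection rule at a configurable rate. Earlobe channels
  A1/A2 carry attenuated noise only, so linked-earlobe re-referencing is
  exercised without injecting signal.

What the generator does *not* emulate: volume conduction from realistic
sources, heteroscedastic or non-stationary noise, latency jitter across
trials, eye movements other than blinks, and channel-specific drifts. A
green recovery test therefore establishes that the pipeline's arithmetic is
faithful, not that it would be robust to every pathology of real EEG.

Each simulated recording carries a ground-truth sidecar: the injected
amplitude of every component per condition and channel, the artifact
injection log, and the *expected feature values* — the N2/P3 peak means and
difference-window means of the injected clean waveform evaluated on the
250-Hz analysis grid. Because the reported peak amplitude is a mean around
the extremum and components overlap in time, the expected feature is a
deterministic functional of the injected waveform rather than the raw peak
parameter; recovery is assessed against these expectations (and against the
raw injected deltas for modulation effects, where shape biases cancel).

## Preprocessing

The chain runs in a fixed, asserted order: downsample to 250 Hz →
0.01--70 Hz band-pass → blink removal → >100 uV artifact rejection →
linked-earlobe re-reference → 0.01--30 Hz band-pass → segmentation
(-200..+1800 ms; 501 samples at 4-ms steps) with baseline correction over
the closed interval [-200, 0] ms.

Numerical choices worth recording:

* **Filters.** The band edges are implemented as 4th-order Butterworth
  low-/high-pass pairs applied forward-backward (zero net phase shift). At
  the extreme 0.01-Hz high-pass corner, time-domain recursions are
  numerically unusable — the double pole sits ~1e-4 inside the unit circle
  and start-up transients decay over roughly an hour of signal; reference
  implementations (e.g. `scipy.signal.filtfilt`) show passband errors of
  40--100% on this corner. The package therefore applies the *exact*
  forward-backward response spectrally: the signal is reflection-padded,
  evenly extended (continuous and periodic), multiplied by the
  bilinear-warped Butterworth magnitude-squared response, and transformed
  back. Passband gain and zero phase are exact by construction; tests verify
  both against analytic sinusoids.
* **Anti-aliasing.** Downsampling by an integer ratio is preceded by an
  8th-order zero-phase low-pass at 80% of the target Nyquist; markers remap
  by index arithmetic.
* **Blink removal.** The published analysis used semi-automatic ICA; that
  involves component-selection heuristics that cannot be reproduced
  deterministically, so the default stage regresses each channel on the
  EOG-proxy channel (least squares) and subtracts the projection, with a
  `passthrough` hook for plugging in alternatives. On the generator's blink
  model this removes >95% of blink amplitude.
* **The 100-uV rule.** "More than 100 uV difference to the surrounding
  signal" is operationalized as the peak-to-peak range (max minus min)
  within a sliding 200-ms window — the maximal-difference-in-interval check
  of standard ERP software. A running-median deviation rule was considered
  and rejected: a median tracks any step longer than half its window, so
  plateau artifacts would pass unflagged. Flagged windows get a ±200-ms
  guard band and merge into bad intervals; epochs overlapping a bad interval
  are dropped, and kept + dropped always equals the number of markers.
* **Minimum segments.** A subject enters ERP analysis only if all four
  conditions (Go/NoGo x emotional/neutral) retain at least 50 artifact-free
  epochs (boundary inclusive).

## Feature extraction

Condition ERPs are pointwise means of kept epochs. Peaks are detected by
windowed argmin/argmax (N2: 450--670 ms; P3: 600--900 ms) with ties broken
toward the earlier latency; the reported amplitude is the mean over the
extremum ±5 time points (±20 ms at 250 Hz; "±5 time points" is interpreted
at the analysis rate since peaks are exported after downsampling), truncated
at epoch edges. N2P3 = P3 amplitude - N2 amplitude per electrode. Difference
waves are per-subject emotional-minus-neutral subtractions; window means are
closed-interval averages, so a sample on a shared boundary (e.g. 700 ms)
belongs to both adjacent windows, mirroring the published window lists. The
six statistical electrodes map to a fixed laterality x region design:
F3/F4 (frontal), C3/C4 (central), P3/P4 (parietal), left/right.

## Statistics

The inferential layer mirrors the published analysis:

* **Mixed ANOVA.** Group (between) x Emotion x Laterality x Region (within)
  on N2P3 amplitudes, and Group x Laterality x Region on difference-window
  means. Sums of squares and F tests use the standard univariate
  multistratum decomposition; on top, the package computes Mauchly's
  sphericity test from the pooled within-group covariance of orthonormal
  effect contrasts, Greenhouse-Geisser epsilon, and generalized eta squared
  defined as SS_effect / (SS_effect + sum of all subject-level error SS).
  The correction is applied when Mauchly's test rejects at 0.05 (the source
  says only "whenever non-spherical data was encountered"; 0.05 is this
  package's choice), and both corrected and uncorrected p-values are always
  reported. The test suite checks the full table against an independent
  definitional computation built from cell means (inclusion-exclusion over
  balanced margins) to 1e-8.
* **Interaction decomposition.** Significant interactions are decomposed by
  stratifying on one factor and re-running the ANOVA per stratum, declaring
  significance only at the Bonferroni-adjusted final level p < 0.017.
* **Trial-level error models.** Dichotomized outcomes (incorrect-vs-other
  and miss-vs-other on Go trials, commission-vs-correct on NoGo, any-error
  on all trials) are fitted with binomial mixed models (Group + Emotion
  fixed, Subject random intercept) via `lme4::glmer` — the backend the
  original analysis used. Singular (zero-variance) random effects are kept
  as boundary fits; outright non-convergence falls back to the marginal
  odds ratio with a leave-one-subject-out jackknife CI. Marginal odds
  ratios from two rates are computed as odds(a)/odds(b); degenerate rates
  (0 or 1) are refused rather than continuity-corrected.
* **QC rules.** Outlier subjects: error count in any category strictly more
  than 2.5 group SDs above the group mean ("more than" reads as a strict
  inequality, so identical subjects are never flagged). Wrong-rule blocks:
  at least 75% of answers are commissions plus misses (inclusive, per "if
  75% of the answers were"). Outlier blocks: block error rate strictly more
  than 3 SDs above the subject's own mean. The package reports flags; the
  published re-run-without-outliers policy is the caller's decision, since
  it requires comparing conclusions across runs.
* **Questionnaires.** Scale scores are compared with two-sided Wilcoxon
  rank-sum tests (exact for combined n <= 20 without ties, normal
  approximation with tie and continuity correction otherwise). BRIEF-A is
  consumed at scale/t-score level (item-level scoring is proprietary). The
  RPQ item-to-category mapping ships as an editable default that is a
  *reconstruction* of the cited three-factor schemes, not a verbatim copy —
  the source does not print item lists.

### Open choices resolved here

* RTs enter analysis only from correct Go responses; the natural log is
  used (base unspecified in the source; monotone-equivalent for rank tests,
  and base only rescales the ANOVA).
* Late presses beyond the next trial's onset are not modelled; the
  generator's response window closes at the following onset.
* The ±5-sample peak mean is applied uniformly, including the NoGo N2
  re-analysis, since no separate rule is printed.
* Distractor onset is modelled as simultaneous with the cue (it appears "in
  the middle position of the traffic light"), sharing its duration.

## Reproducibility

`run_study()` derives per-subject, per-stage RNG substreams from one master
seed (all derived seeds stay below 2^31), so identical configurations
reproduce every number bit-for-bit regardless of cohort size, and any
subject can be regenerated in isolation. Output directories carry a
manifest with MD5 checksums of every exported file.

## Known limitations

* The synthetic world is stationary and Gaussian; power estimates derived
  from it do not transfer to real recordings.
* Mauchly/GG machinery assumes multivariate normality of the within-subject
  contrasts; with 11--12 subjects per group the sphericity test itself has
  little power, as in the original design.
* The EOG-regression blink stage removes any signal genuinely correlated
  with the EOG proxy; with real data this can bleed frontal neural signal,
  which is why the stage is pluggable.
* BrainVision I/O covers the subset of the format the pipeline writes
  (multiplexed IEEE float32 / INT_16, stimulus markers); EDF is not
  implemented.
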