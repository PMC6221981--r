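# execrt

Simulation and ERP analysis of a Go/NoGo executive reaction time task with
emotional distractors.

## The problem

In studies of emotion–attention interaction, participants perform a Go/NoGo
visual RT task whose targets are emotionally neutral while task-irrelevant
threat-related or neutral distractors appear with the response cue. The
electrophysiological read-outs are event-related potentials time-locked to
trial onset:

* **N2** — most negative peak in 450–670 ms (150–370 ms after the cue),
* **P3** — most positive peak in 600–900 ms,
* **N2P3 peak-to-peak amplitude** = P3 − N2, a robust index of attention
  allocation that cancels slow baseline shifts,
* **LPP** — late positivity quantified as mean amplitudes of
  emotional-minus-neutral difference waveforms in fixed 100 ms windows
  (600–700, 700–800, 800–900 ms).

Peak amplitudes are means around the detected extremum ±5 time points at
250 Hz. ERP features per subject × condition × electrode (F3/F4, C3/C4,
P3/P4) enter a mixed ANOVA, Group × Emotion × Laterality × Region, with
Greenhouse–Geisser correction under Mauchly non-sphericity, generalized eta
squared (SS_effect / (SS_effect + ΣSS_error)) as effect size, and post-hoc
decomposition at a Bonferroni-adjusted level of p < 0.017. Behavioural
errors (miss, incorrect button, commission) are dichotomized and fitted with
binomial mixed models (Group + Emotion fixed, Subject random); marginal odds
ratios derive from rates as OR = odds(a)/odds(b).

Because the original recordings are not public, the package ships a
first-class synthetic-data module: seeded schedules with exact 50:50
counterbalancing (16 blocks × 64 trials = 1,024 trials), trial-level
behaviour with preset group error rates, and continuous multichannel EEG
with injected Gaussian ERP components, 1/f + white noise, blinks, >100 µV
step artifacts, near-silent earlobe reference channels and sample-exact
markers — plus a ground-truth sidecar for parameter-recovery tests. The
preprocessing chain (250 Hz downsampling, zero-phase 0.01–70 and 0.01–30 Hz
Butterworth band-passes, EOG-regression blink removal, 100 µV jump
rejection, linked-earlobe re-referencing, −200..+1800 ms segmentation with
baseline correction, ≥50 segments per condition) reproduces the published
pipeline stage for stage. See the methods vignette
(`vignettes/methods.Rmd`) for every modelling choice and its rationale.

## Worked example

```r
library(execrt)

sched <- generate_schedule(16, 64, seed = 1)   # 1,024 trials, exact 50:50
prof  <- subject_profile("control_like")
beh   <- simulate_behavior(sched, prof, seed = 1)
table(beh$outcome)
#>       commission          correct incorrect_button
#>               12             1003                9

rec <- simulate_eeg(sched, prof, noise_model(white_sd = 5), seed = 1)
pp  <- preprocess_recording(rec)    # blinks removed, jump intervals dropped
enforce_min_segments(pp$epochs)$counts
#>   GoEmotional     GoNeutral NoGoEmotional   NoGoNeutral
#>           249           254           253           250

erp <- average_condition(pp$epochs, "GoEmotional")
n2  <- detect_peak(erp, "F4", "N2")
p3  <- detect_peak(erp, "F4", "P3")
round(c(n2 = n2$amplitude, p3 = p3$amplitude,
        n2p3 = n2p3_amplitude(n2, p3)), 2)
#>    n2    p3  n2p3
#> -4.70  3.83  8.53
```

The N2 is the (negative) early cognitive-control deflection, the P3 the
attention-related positivity (here riding on the simulated LPP), and `n2p3`
their peak-to-peak difference in µV. A full cohort run —
`run_study(study_config(master_seed = 1))` — adds behavioural QC,
trial-level odds-ratio models, and the Go/NoGo mixed ANOVAs with sphericity
handling, and writes checksummed output tables. A command-line wrapper is
provided at `inst/scripts/run_study.R`.

Published group-level reference values are available for consistency checks:

```r
marginal_odds_ratio(0.021, 0.047)$or   # 0.4349 -> 0.43: control vs lesion error odds
head(reference_peak_table(), 2)        # published N2/P3/N2P3 group means
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance quantities from
scratch — the peak-to-peak amplitudes obtained by applying the package's
N2P3 definition to the published group-mean N2 and P3 peak values (Go /
Control / Emotional / F3, and NoGo / OFC / Emotional / F3) — and writes them
as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
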