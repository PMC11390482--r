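# oddball2p

Analysis of sensory prediction-error signals in two-photon calcium imaging
from virtual-corridor oddball experiments.

## What this is for

In an oddball paradigm, a mouse learns a fixed sequence of grating stimuli
along a virtual corridor (A–B–A–B over four positions). In the probe
session, a conditioning block (160 trials) replaces the stimulus at
position 4 with an oddball — a novel grating, the familiar grating A, or an
omission — on a random 10% of trials; a second block (40 trials) shows the
oddball on every trial. Visual-cortex neurons respond far more strongly to
the oddball while it is *unexpected* than once it has become expected, and
this prediction-error amplification is concentrated in cells highly
selective for the oddball stimulus and decays over repeated exposures.

`oddball2p` provides, for anyone analyzing such recordings (or building on
their analysis):

* **Preprocessing** — phase-correlation motion registration with
  large-motion flagging, ROI trace extraction, robust neuropil
  decontamination by an asymmetric Student-t residual model, baseline
  F0 from a two-component Gaussian mixture, ΔF/F and per-cell session
  z-scoring.
* **Event-aligned analysis** — responses as baseline-subtracted window
  means (0.4–2 s after onset), stimulus-responsiveness thresholds,
  prediction-error classification (t-test at α = 0.05 plus a 0.5-z minimum
  difference against late-block-2 expected responses), selectivity
  `(R_target − R_ref)/(R_target + R_ref)` with the 0.6/0.8 class cutoffs,
  the pooled-SD selectivity index, and the optogenetic recruitment rule.
* **Statistics for nested data** — a hierarchical bootstrap test
  (animals, then cells, then a within-pair condition shuffle),
  randomization tests, BCa bootstrap confidence intervals, Cohen's d,
  Bonferroni adjustment.
* **Behavioral controls** — fast/slow running splits, running–activity
  correlation (R²), pupil detection and Hampel-style trace filtering.
* **A synthetic-session generator** — trial structure, behavior, and
  forward-modeled fluorescence with per-cell ground truth (tuning,
  prediction-error gain, exposure decay, neuropil coefficient, baseline,
  noise), so the entire pipeline is verifiable against planted parameters.

## Worked example

```r
library(oddball2p)

cfg <- session_config(seed = 7)      # 160 + 40 trials, 6 animals x 40 cells
ses <- run_simulate(cfg)             # trial table, events, behavior, traces
rb  <- run_analyze(ses, n_boot = 1000, seed = 8)
print(rb)
```

```
Oddball session report
  240 cells classified; config 5d42918b, seed 8
  selectivity_class n_cells mean_unexpected mean_expected  mean_diff
1  highly-selective      57     3.515023229   2.348922980 1.16610025
2      intermediate       7     3.290700317   2.277031066 1.01366925
3     non-selective     127     0.879188523   0.861298806 0.01788972
4      unresponsive      49     0.003801392  -0.008482111 0.01228350
  selectivity_class n_cells n_animals  statistic     p_value    cohens_d
1  highly-selective      57         6 1.16610025 0.000999001 14.77504087
2      intermediate       7         2 1.01366925 0.003996004  7.68412128
3     non-selective     127         6 0.01788972 0.030969031  0.08215513
       ci_low    ci_high n_boot seed  p_adjusted
1 1.144745097 1.18662965   1000    8 0.002997003
2 0.953215085 1.05290750   1000    8 0.011988012
3 0.003006287 0.03476838   1000    8 0.092907093
```

Reading the output: cells highly selective for the oddball grating respond
about 1.2 z-scored ΔF/F more strongly when the oddball is unexpected than
when it has become expected (hierarchical bootstrap p at the Monte-Carlo
floor for 1,000 resamples), while the non-selective contrast is 0.018 z —
two orders of magnitude below the 0.5-z criterion that defines real
amplification, and not significant after Bonferroni adjustment. That is
the planted ground-truth structure, recovered by the full chain from raw
contaminated fluorescence to class-wise statistics.

The `analysis/` directory holds the same workflow as numbered driver
scripts (simulate → preprocess → classify → statistics → calibration),
writing their tables under `results/`.

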