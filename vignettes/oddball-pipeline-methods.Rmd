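---
title: "Methods: detecting sensory prediction-error signals in virtual-corridor oddball imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting sensory prediction-error signals in virtual-corridor oddball imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In a virtual-corridor oddball paradigm, a head-fixed mouse runs through a
corridor in which four grating stimuli appear in a trained sequence
(A–B–A–B). After several conditioning sessions, the stimulus at one position
is occasionally replaced: in a 160-trial first block, a randomly chosen 10%
of traversals carry an oddball (a novel grating C or D, the familiar grating
A, or an omission) at position 4; in a 40-trial second block every traversal
carries it. Layer 2/3 neurons in primary visual cortex respond much more
strongly to the oddball when it is unexpected (block 1) than when it has
become expected (late block 2), and this amplification is largely restricted
to cells that are highly selective for the oddball stimulus and decays over
repeated exposures.

`oddball2p` implements the complete analysis chain for such recordings —
preprocessing, event-aligned response quantification, classification,
behavior-conditioned controls, and nesting-aware resampling statistics —
together with a forward model that generates synthetic sessions with known
ground truth, so that every stage can be verified quantitatively without
animal data.

## Preprocessing model

**Registration.** Frames are registered to a reference built from 30 evenly
spaced batches of 40 frames (1,200 frames) when available, otherwise the
stack mean, by phase correlation with integer-pixel displacements. Because
each frame contributes a small share of the reference, its self-term places
a competing correlation peak at zero lag; with references built from tens of
frames or more the true peak dominates, and on textured synthetic stacks
recovery of planted shifts within ±8 px is exact. Frames whose displacement
magnitude exceeds 10 px, or the session mean + 3 SD, are flagged and
excluded from all downstream trace statistics; events that lose more than
half of their response window to flagged frames are dropped.

**Neuropil decontamination.** The measured ROI trace is modeled as
\(F_\mathrm{meas} = F_\mathrm{cell} + r\,F_\mathrm{np}\). We estimate \(r\)
by maximizing an asymmetric Student-\(t\) likelihood of the residuals
\(F_\mathrm{meas} - a - r\,F_\mathrm{np}\): degrees of freedom \(\nu = 5\),
with the scale multiplied by an asymmetry factor of 3 for positive
residuals, fitted by coordinate ascent over \((r, a, s)\) and clipped to
\([0, 1)\). Positive excursions — calcium transients — are therefore
tolerated by the residual model rather than pulled into the regression
slope, which is what biases ordinary least squares upward whenever cell
transients co-occur with stimulus-locked neuropil signal. On transient-free
traces the estimator agrees with least squares; on transient-rich traces its
absolute bias is at most that of least squares (both properties are tested).
\(\nu\), the asymmetry factor, and the iteration caps are configurable.

**Baseline and normalization.** \(F_0\) is the mean of the lower component
of a two-component Gaussian mixture fitted to the distribution of trace
values by EM — deterministic initialization at the 25th/90th percentiles of
the trace, at most 50 iterations, log-likelihood tolerance \(10^{-6}\),
single run, so the estimate is reproducible without a random restart.
\(\Delta F/F = (F - F_0)/F_0\), and the z-scored trace subtracts the
session mean of \(\Delta F/F\) and divides by its SD (motion-flagged frames
excluded from both statistics). A useful identity: because
\(\Delta F/F\) is affine in the underlying signal for any positive baseline
estimate, the z-scored trace is *exactly* invariant to multiplicative
baseline error — classification operates on z-scored responses and is
therefore insensitive to the few-percent \(F_0\) bias that dense transients
induce in any mixture-based baseline.

By default the baseline is estimated on the decontaminated trace; an
`f0_on_raw` flag estimates it on the raw measured trace instead, preserving
the alternative ordering in which the mixture is fitted before neuropil
subtraction. The ordering is not identified by the data; we default to
subtract-first because the decontaminated trace is the quantity whose
baseline the \(\Delta F/F\) definition needs.

## Event-aligned responses and classification

The response to one stimulus presentation is the mean z-scored
\(\Delta F/F\) over \([0.4, 2.0)\) s after onset minus the mean over the
\([-0.5, 0)\) s baseline. Both windows are half-open on the right so that no
frame is double-counted; at 7.5 Hz the response window holds 12 frames and
the baseline 3–4 depending on frame phase.

Classification rules, each a strict inequality at its printed threshold:

* **Stimulus-responsive**: mean response > 0.5 z (variants: 0.2 for raw
  \(\Delta F/F\), 0.1 for axonal boutons).
* **Prediction-error-responsive**: unexpected (block-1 oddball) vs expected
  (second half of block 2) responses differ by a two-sided two-sample
  t-test at \(\alpha = 0.05\) *and* the mean difference exceeds 0.5 z
  (0.3-z variant available). The equal-variance Student test is the
  default, Welch by flag; the choice is not identified by the rules
  themselves, and both are exposed.
* **Selectivity** \(= (R_\mathrm{target} - R_\mathrm{ref}) /
  (R_\mathrm{target} + R_\mathrm{ref})\), clipped to \([-1, 1]\), from
  late-block-2 mean responses (target = the oddball stimulus at its
  position; reference = the trained gratings at the non-oddball positions).
  Cells with a zero denominator are excluded; cells whose denominator is
  negative but whose raw ratio is within the clip range are retained.
  Responsive cells are **non-selective** below 0.6, **highly selective**
  above 0.8, intermediate in the deliberate gap between the cutoffs.
* **SI** = mean difference over pooled SD (\(n-1\) weights), the variant
  robust enough for noisy bouton traces.
* **Recruited** (optogenetic sessions): LED-on vs LED-off responses differ
  at \(\alpha = 0.016\) with a difference above 0.3 z in at least one
  stimulus condition.

"Second half of block 2" is the last \(\lfloor n_2/2 \rfloor\) trials: the
design names the epoch ("late block 2") without a count, and half the block
is the natural reading. Figure-variant trial subsets (pooled LED trials for
responsiveness, LED-off-only for selectivity) are selected by
`select_classification_trials()` so variants are switches, not code forks.

## Resampling statistics

Comparisons across cells respect the nesting of cells within animals.
`hierarchical_bootstrap_test()` resamples animals with replacement, then
cells with replacement within each drawn animal (to the animal's original
cell count), then shuffles the paired data by independently swapping the
two condition values of each resampled pair with probability ½, and records
the statistic (default: mean paired difference); 10,000 iterations in the
analysis scripts. The two-sided p-value compares the original-sample
statistic against this null with a +1 correction, so p is never exactly 0
and is floored at \(1/(n_\mathrm{boot}+1)\). Two design points deserve
note:

* The comparison point is the original-sample statistic, not a
  recomputation on resampled-but-unshuffled data; the latter would conflate
  resampling noise with the null.
* The within-pair swap assumes that, under the null, the paired difference
  is symmetric around zero and free of animal-level mean structure. That
  holds by construction when the animal-level effect is shared by both
  conditions of the same cell — which is how paired conditions arise here
  (the same cell is measured in both) and how the generator plants animal
  effects. The calibration study (`run_calibrate()`) verifies a type-I
  error within [0.03, 0.07] at intraclass correlations 0 and 0.2 of the
  condition values, and power above 0.8 for a planted paired shift of one
  value-SD with 5 animals × 40 cells — 1,000 datasets at 1,000 resamples,
  a problem size chosen so the whole grid runs in well under a minute.

`randomization_test()` permutes condition labels (or swaps within pairs),
`bootstrap_ci()` gives BCa intervals for the mean (percentile by flag) via
the `boot` package, `cohens_d()` uses the pooled SD with \(n-1\) weights,
and `bonferroni()` is the standard \(\min(1, m p)\) adjustment. With one
cell per animal the hierarchical bootstrap reduces to the flat paired
permutation test up to Monte-Carlo error, which is tested.

## Behavior-conditioned controls

Fast/slow trial splits use the median of event-window mean running speeds
(same \([0.4, 2.0)\) s window), ties broken by event order, the extra event
of an odd count going to the fast set, so the two sets always partition the
events. Running modulation per cell is the Pearson correlation across
trials between window-mean response and window-mean speed, reported as
\(R^2\). Pupil frames are thresholded (dark pupil), the largest connected
region's centroid and pixel area taken; area traces pass through a
Hampel-style filter (moving median, window 11; outliers beyond 3 scaled
MADs replaced by linear interpolation). The window and MAD multiplier are
the common defaults of this filter family and are configurable — the
upstream description names the filter but not its parameters.

## The synthetic-session generator

The generator is first-class, tested code; its defaults are the study
conditions. Per cell, each stimulus event contributes an amplitude

\[ A = T(\mathrm{id}) \cdot \bigl(1 + g\,\mathbb{1}\{\mathrm{oddball}\}\,
  \lambda^{k-1}\bigr) + \beta_\mathrm{run}\, v(t_\mathrm{onset}) + u_a , \]

where \(T\) is the cell's tuning amplitude for the stimulus identity,
\(g\) the prediction-error gain (default 1, planted only in cells whose
ground-truth selectivity exceeds 0.8), \(\lambda\) the per-exposure decay
(default 0.9; the exposure counter \(k\) increments on every presentation
of the oddball identity at the oddball position and never resets, so late
block 2 is unamplified by construction), \(\beta_\mathrm{run}\) a running
gain (default 0.002 per cm/s — weak modulation, about 1% of a responsive
cell's amplitude per 4-cm/s speed excursion), and \(u_a\) an additive
animal-level offset
(SD 0.15) shared by all of an animal's cells and by both conditions.
Amplitudes are convolved with a double-exponential calcium kernel (rise
0.05 s, decay 0.6 s, GCaMP6f-scale — the analysis never assumes the
kernel); the cell trace is \(F_0 (1 + s(t))\) plus Gaussian frame noise
(default SD 5 on baselines of 80–120 a.u.), and the measured trace adds
\(r_\mathrm{np} F_\mathrm{np}\) with \(r_\mathrm{np} \sim U(0.4, 0.8)\).
The neuropil trace mixes a slow animal-shared fluctuation (15% of its
baseline) with a weak (5%-weight) stimulus-locked population drive — slow
diffuse signal dominates real neuropil, and the weak locked component is
what makes least squares overestimate \(r\).

Populations default to 25% oddball-selective cells (tuning ≈ 1.5 to the
oddball identity, ≈ 0.05 to the trained gratings), 45% non-selective
responsive cells (tuning ≈ 0.8 to all gratings), and 30% unresponsive
cells; 6 animals × 40 cells, 7.5 Hz, 13.2-s traversals with onsets every
3 s. The traversal duration is chosen so stimulus onsets keep a constant
(half-frame) offset from the imaging frame grid: with a duration that
frame-locks alternate trials, the discrete sampling of the calcium kernel
aliases into a small systematic response difference between trial subsets,
which a sensitive across-cell test then detects as a spurious condition
effect.
Omission events carry no stimulus drive unless a cell has positive omission
tuning. Oddball counts are exact (`round(p n)`) rather than Bernoulli — the
design states a fraction over a fixed block, and the exact count makes
trial bookkeeping reproducible; this is an assumption, flagged here.

What the generator does *not* emulate: trial-to-trial amplitude
variability beyond running and noise, adaptation within block 1 outside
the oddball pathway, nonlinear calcium indicator saturation, slow drift in
\(F_0\), correlated noise across cells, or realistic pupil video. Passing
tests therefore certify the analysis logic under the stated statistical
structure, not robustness to every property of real recordings.

## Numerical choices and degenerate inputs

* Windows are half-open; events with empty windows yield NA responses and
  are dropped.
* Zero-variance traces: flagged cells are excluded from classification;
  constant neuropil gives \(\hat r = 0\) with a warning; constant input to
  the bootstrap CI gives a zero-width interval; zero pooled SD gives SI 0
  (equal means) or a flagged infinity.
* The mixture EM floors component SDs at \(10^{-4}\) of the trace SD to
  avoid collapse onto a single value.
* The exposure-decay recovery fit is robust nonlinear least squares
  (Levenberg–Marquardt) of \(a(1 + g\lambda^{k-1})\) with \(\lambda\)
  bounded in \((0, 1]\).
* All randomness flows from integer seeds; sub-seeds are small fixed
  offsets of the session seed, kept below \(2^{31}\).

## Problem sizes

The bundled analysis scripts and tests use a full default session
(200 trials, 240 cells, ≈19,500 frames, ≈2 min end to end on one CPU), a
1,000-dataset × 1,000-resample calibration grid (≈30 s), and 50-seed
estimator-bias comparisons — sizes chosen so the complete verification
suite runs comfortably on a laptop while leaving every statistical check
enough resolution to be meaningful.

## Known limitations

* Integer-pixel registration only; subpixel motion appears as residual
  jitter the trace statistics must absorb.
* The asymmetric-t neuropil model is this package's own concrete robust
  estimator; it is validated against its stated properties (least-squares
  agreement without transients, smaller bias with them), not against any
  external implementation.
* ROI segmentation is out of scope; masks are inputs.
* The hierarchical bootstrap's within-pair swap is anti-conservative if
  true animal-level structure survives in the paired *difference* (e.g.
  genuinely heterogeneous per-animal effects); its calibration is
  guaranteed only under the shared-animal-effect structure described
  above.
* The oddball design compares 16 block-1 presentations against 20
  late-block-2 presentations per session, so any covariate that varies
  across trials — chiefly running speed — leaves a residual condition
  difference of order 0.01 z per animal that is shared across that
  animal's cells. A sensitive across-cell test can flag this residual as
  nominally significant even though it is two orders of magnitude below
  real amplification; this is why every decision rule here pairs
  significance with a magnitude criterion (class-level amplification is
  read as p < 0.05 *and* a contrast above 0.5 z, mirroring the
  cell-level rule), and why the fast/slow running split exists as an
  explicit control. Each animal gets its own independent behavior trace,
  so these residuals average out across animals rather than acting as one
  session-wide offset.
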