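---
title: "Closed-loop TMR: models, design choices and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop TMR: models, design choices and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tmrtools)
```

This vignette documents the scientific models behind `tmrtools`, the
parameters that matter, the numerical decisions taken where the design was
genuinely open, and what the synthetic-data validation does and does not
establish about real recordings.

## The closed-loop stimulation model

During N3 sleep the scalp EEG is dominated by slow oscillations (SOs):
high-amplitude waves in the 0.5–1.5 Hz band whose surface-negative trough
corresponds to the cortical down-state and whose positive peak to the
depolarised up-state. Closed-loop TMR delivers an auditory cue at a chosen
SO phase. The replayed online system here follows the standard
trough-locked design:

1. the detection channel (F3, where SOs are maximal) is band-pass filtered
   **causally** in the slow-wave range (0.5–4 Hz);
2. when the filtered amplitude crosses **−80 µV**, the running minimum is
   tracked until the derivative has been positive for a 20 ms confirmation
   window; the sample of the minimum is the detected trough;
3. the cue (200 ms sound) is scheduled at **trough + 500 ms**, which for a
   ~1 Hz SO is half a period, i.e. the next up-state;
4. delivery is vetoed unless the hypnogram epoch containing the onset is
   N3, the onset is outside every arousal interval, and at least **4 s**
   have elapsed since the previous sound ended (so onset-to-onset gaps are
   ≥ 4.2 s);
5. down-state targeting runs the identical detector on the
   polarity-inverted signal, so "trough + 500 ms" lands on the true trough.

Cueing follows a block schedule: each block contains four six-sound sets
(Experimental-Up, Novel-Up, Experimental-Down, Novel-Down) in an order
randomised per block and counterbalanced across blocks by Latin squares;
within a set sounds always run in hierarchy order A…F. Twelve blocks plan
288 cues. Sets are delivered sequentially on consecutive qualifying SOs
and never interleave.

### The causal online filter

The only genuinely open element of the online path is the filter, and it
matters: any causal filter delays or advances the apparent trough, and the
fixed 500 ms delay converts that timing error directly into a phase error
at the cue. We measured the trough-timing bias of candidate causal designs
on a 1 Hz oscillation before choosing:

| design                               | bias at 1 Hz |
|--------------------------------------|--------------|
| Butterworth band-pass, 2 poles       | −15.8°       |
| Butterworth band-pass, 4 poles       | −23.8°       |
| 1st-order HP (0.5 Hz) + 2nd-order LP (4 Hz) | −5.8° |

A symmetric band-pass is centred near √(0.5·4) ≈ 1.4 Hz and therefore
*leads* at 1 Hz, pushing cues ~16–24° before the up-state peak — outside
the ±15° landing tolerance this package holds itself to. The asymmetric
high-pass/low-pass cascade keeps the phase response near zero across the
SO band and is what `run_closed_loop()` uses. Residual bias is frequency
dependent (larger for slower SOs), which is one mechanism behind the
dispersion of landing phases on broadband SO activity — and a plausible
reason real down-state landings average past 180°.

The trough-to-onset delay is exact by construction
(`onset = detected_trough_time + delay`), so the elapsed time reported per
cue is always the configured 500 ms; the phase accuracy question is
whether the *detected* trough is the true one.

## Offline phase validation

Landing phases are verified offline: zero-phase (two-pass, order-2-per-pass
Butterworth) 0.5–2 Hz filtering, analytic-signal phase via the Hilbert
transform, with the convention 0° = positive peak, 180° = trough. Reports
are in degrees in [0, 360); the circular SD √(−2 ln R) is reported in
**radians** (an SD of ~0.5 rad ≈ 29° is a plausible landing spread; 0.5°
would not be). The Up-vs-Down comparison uses the Watson–Williams test
when the pooled resultant length is ≥ 0.45 and both samples have n ≥ 5;
otherwise it falls back to a label-permutation test on the absolute
circular mean difference and flags the fallback. The von Mises sampler
(Best–Fisher) exists purely so these routines can be calibrated by
simulation.

## EEG analysis chain

Offline preprocessing is 0.5–30 Hz zero-phase Butterworth (low-pass order
4 per pass; the high-pass stays at order 2 because high-order IIR designs
at a normalised corner of 0.002 are numerically fragile), linked-mastoid
re-referencing when a mastoid pair exists (the operation is idempotent;
without mastoids the data are left as-is with a warning), and
neighbour-average interpolation for user-declared bad channels. ICA and
manual artifact rejection are out of scope: the synthetic data are clean,
and the bad-channel hook stands in for that stage of a real pipeline.

Cue-locked epochs span −1…3 s. Time–frequency power uses complex Morlet
wavelets, 4–20 Hz in 0.5 Hz steps on a −1…2.4 s grid in 50 ms steps, with
`n_cycles = max(4, f/2)` (at least 4 cycles everywhere, growing with
frequency so temporal smoothing narrows at higher frequencies). The output
grid stops at 2.4 s precisely so the 1 s wavelet at 4 Hz never runs past
the 3 s epoch tail; bins whose wavelet support would leave the epoch are
flagged in an `edge_mask` rather than silently returned. Baseline
normalisation is the relative change (P − B)/B against the −1…0 s mean per
channel and frequency; zero baseline power is an error, not a NaN.

## Cluster-based permutation inference

Per-bin statistics are one-sample t values (paired comparisons enter as
within-subject differences). Bins exceeding the two-tailed t quantile at
df = n−1 are clustered — contiguously in time (and frequency), across
channels via a distance-thresholded adjacency graph — and each cluster's
mass is the sum of its t values. The null distribution of the maximum
absolute cluster mass is built by random sign flipping of subject
deviations (equivalently condition swapping), giving family-wise control;
p-values are (1 + #{null ≥ observed})/(n_perm + 1), so the floor is
1/(n_perm+1). Defaults mirror common practice: 2000 permutations, both
alphas 0.05, two-tailed. Sign-flip t values are computed in closed form
(the column sum of squares is invariant under sign flips), which is what
makes the 500-dataset calibration suite affordable.

## Per-timepoint decoding

At each time sample the feature vector is the (4–20 Hz filtered) channel
values of each trial. Stratified 5-fold cross-validation with 2
repetitions; within each training fold the z-scoring parameters and the
PCA basis (20 components by default) are estimated on training trials only
and applied to the held-out fold — PCA per fold rather than globally,
because a global basis would leak test-set covariance into training.
Classifiers are LDA and a linear SVM; ACC is the native decision rule
averaged over held-out trials, AUC is the rank (Mann–Whitney) statistic on
pooled held-out decision scores per repetition. Group inference delegates
to the time-course cluster test with a null value of 0.5.

## The transitive-inference task

Six-item hierarchies A>B>…>F yield 5 premise pairs, inference pairs B>D
and C>E (first degree of separation: one intervening item), B>E (second
degree), and the anchor A>F — so second-degree instances are necessarily
half as frequent as first-degree ones. Learning blocks present each
premise pair twice (orientations counterbalanced), 10 trials per
hierarchy, hierarchies as contiguous sub-blocks, and consecutive trials
never share an item so the ordering never reveals the hierarchy; the
scheduler uses greedy random construction with restarts because plain
rejection shuffling succeeds too rarely on 5-pair sets. The exit criterion
evaluates only the middle pairs (B-C, C-D, D-E): feedback for a hierarchy
switches off — permanently — once accuracy exceeded 66% (strictly; a
configuration flag relaxes to ≥) in at least 2 of the last 3 recorded
blocks, evaluation starting after block 3, with a hard stop at 10 blocks.
Whether blocks 1–2 count toward "the last three" is ambiguous in the
source protocol; this implementation counts all recorded blocks from
block 1 and exposes `window_from_start = FALSE` for the other reading.

Behavioural accuracy is scored per subject × condition × session × pair
class with premise/inference roll-ups; empty cells are NA with n = 0,
never 0%.

## The synthetic-data generator

The generator is the package's study population; its defaults are fixed
once and the validation suites run against them.

* **SO waveform**: one period of a raised-cosine biphasic template (trough
  half-wave then peak half-wave), frequency drawn uniformly from
  0.5–1.5 Hz per event. A template rather than filtered noise so trough
  and peak times are *exact* oracles for the detector. Up/down asymmetry
  (`so_asym`) and peak/trough amplitude ratio are options, both defaulting
  to symmetric.
* **Amplitude convention**: the trough amplitude (default −100 ± 10 µV at
  F3) is the event's depth in the zero-phase 0.5–4 Hz band — the
  convention under which sleep-scoring amplitude criteria such as the
  −80 µV detection threshold are stated. Each template is scaled so its
  band-filtered minimum equals the drawn amplitude; without this an
  isolated −100 µV template filters to ~−70 µV and the detector misses
  most events by construction rather than by physiology.
* **Topography**: a fixed frontal-maximal mixing vector (normalised to 1
  at F3) applied to a single SO source; spindles use a central vector.
  This is deliberately not a forward model — it provides just enough
  spatial structure for adjacency-aware cluster tests and frontal-maximal
  ERPs.
* **SO density**: `so_rate` (default 8/min in N3) via a renewal process
  whose mean gap matches the configured rate; `so_spacing` switches to a
  regular grid for densely packed trains with known timing. Events are
  placed only in N3 segments of the stage plan.
* **Spindles**: with probability `spindle_prob_per_so`, a 9–16 Hz burst
  (0.5–1 s, squared-sine envelope, ~20 µV) centred on the SO positive
  peak.
* **Background**: per-channel 1/f noise (exponent 1, SD 10 µV) by
  spectral shaping. Arousals are metadata intervals only (they gate
  stimulation but carry no waveform).
* **Evoked effects**: `inject_condition_effects()` adds a squared-sine
  (optionally oscillatory) deflection with a chosen topography to selected
  events — purely additive, so ground truth stays recoverable.
* **Behaviour**: per-cell Bernoulli trials with
  `plogis(qlogis(p) + b_subject)`, `b ~ N(0, 0.3)` on the logit scale
  shared across cells. The bundled `default_accuracy_table()` encodes a
  plausible next-morning pattern (premise ~75–80%, a second-degree
  up-state benefit at session 2, a below-chance down-state dip recovering
  by session 3, near-ceiling anchors).

What the generator does **not** emulate: realistic head geometry or
volume conduction, N1/N2/REM microstructure, K-complexes, EMG/EOG
channels, reaction times, or any mechanistic link between cueing and
behaviour. Consequently, passing validation demonstrates that the
*machinery* is correct and calibrated — detector causality and phase
accuracy, statistical error control, absence of decoding leakage,
parameter recovery — not that any scientific effect exists in real data.

## Validation strategy and problem sizes

The acceptance suite pins down, at sizes chosen to run comfortably on a
single CPU:

* **Protocol arithmetic** — pair and schedule counts are forced by the
  design (5/2/1/1 pair classes, 30-trial blocks, 288 cues in 12 blocks).
* **Phase targeting** — on 150 s, 1 Hz SO trains (~150 SOs): Up landings
  within ±15° of 0°, Down within ±15° of 180°, resultant length > 0.9.
* **Cluster-test calibration** — 500 null datasets (12 subjects × 200
  bins, 500 permutations each): family-wise false-positive rate in
  0.05 ± 0.02.
* **Decoding** — null cohorts decode at AUC 0.5 ± 0.03 (100 trials per
  class); 20 cohorts of 8 subjects with a 20 µV evoked difference planted
  at 1.2–1.3 s (100 Hz recordings, 16 channels, 30 trials/class, 50 ms
  decoding grid) must show a significant group cluster overlapping the
  planted window in ≥ 90% of cohorts.
* **Behavioural calibration** — 200 subjects, 8 trials/cell: cell means
  within 2 Monte-Carlo SEs of their configured probabilities at the
  nominal ~95% rate (binomial allowance across the ~30 cells, none beyond
  4 SEs). With ~30 cells, demanding *every* cell within 2 SEs would fail
  a perfectly calibrated generator about 80% of the time, so the check is
  formulated as a proper calibration test.
* **Bootstrap coverage** — 500 independent-data simulations at n = 17:
  the 95% percentile CI covers zero in 95 ± 3% of runs.

## Known limitations

* The online detector is a replay simulation; real-time audio latency and
  hardware jitter are not modelled.
* The Watson–Williams route assumes von Mises-like concentration; very
  diffuse samples silently (but flaggedly) switch to the permutation
  route, which tests a slightly different null.
* `cluster_test_tfr` permutes at the subject level only; trial-level
  permutation is not implemented.
* The Holm bound reported by `correlate_decoding_behaviour()` is the
  conservative single-p form (`p × family_size`); use `correct_family()`
  across the full p-vector when all family members have been computed.
* External formats are plain-text TSV/YAML; EDF/BrainVision readers are
  not bundled.
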