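# tmrtools

Simulation and analysis toolkit for **closed-loop targeted memory
reactivation (TMR)** experiments in slow-wave sleep.

In closed-loop TMR, sounds that were paired with learning material are
replayed during non-REM sleep, phase-locked to ongoing slow oscillations
(SOs, 0.5–1.5 Hz): an online detector tracks the EEG at a frontal channel,
finds the negative half-wave peak (trough) of each SO, and plays a 200 ms
cue a fixed 500 ms later so it lands on the depolarised **up-state**
(or, with polarity inversion, on the **down-state**). The scientific
questions — did cues really land on the intended phase? do cued sounds
evoke classifiable memory reactivation? does reactivation predict next-day
behaviour on a transitive-inference task? — all require a chain of
signal-processing and statistical machinery that this package implements
end to end, together with a synthetic-data generator so the whole chain is
testable without any sleep recordings.

## What is implemented

* **Synthetic sleep EEG** (`sim_config()`, `generate_sleep_eeg()`):
  frontally dominant SOs as one-period raised-cosine biphasic waves with
  analytically known trough/peak times, spindle bursts (9–16 Hz) coupled
  to the SO up-phase, 1/f background noise, hypnogram and arousal
  intervals; plus condition-specific evoked effects
  (`inject_condition_effects()`) and a behavioural cohort generator
  (`generate_behaviour()`).
* **Closed-loop replay** (`detector_config()`, `run_closed_loop()`):
  causal slow-wave filtering (0.5–4 Hz), −80 µV threshold, trough
  confirmation, cue at trough + 500 ms, ≥4 s pause after each sound,
  N3/arousal gating, and the block schedule (each block = Experimental-Up,
  Novel-Up, Experimental-Down, Novel-Down × items A…F; 12 blocks = 288
  cues).
* **Phase validation** (`instantaneous_phase()`, `circular_summary()`,
  `circular_difference_test()`): zero-phase 0.5–2 Hz filtering, analytic-
  signal phase (0° = SO positive peak, 180° = trough), circular mean,
  resultant length R, circular SD = √(−2 ln R), Watson–Williams test with
  a permutation fallback.
* **ERP / time–frequency analysis** (`preprocess()`, `epoch_recording()`,
  `compute_erp()`, `morlet_tfr()`, `baseline_normalize()`): 0.5–30 Hz
  zero-phase filtering, linked-mastoid re-referencing, −1…3 s cue-locked
  epochs, Morlet wavelets 4–20 Hz (0.5 Hz steps, ≥4 cycles) on a
  −1…2.4 s / 50 ms grid, relative-change baseline.
* **Cluster-based permutation statistics** (`cluster_test_timecourse()`,
  `cluster_test_tfr()`, `channel_adjacency()`): per-bin t statistics,
  cluster mass, sign-flip / condition-swap permutation null with
  max-statistic family-wise correction (defaults: 2000 permutations,
  cluster-forming p < 0.05, cluster p < 0.05, two-tailed).
* **Per-timepoint decoding** (`decode_timecourse()`,
  `group_decoding_test()`): LDA and linear SVM on the channel vector at
  each time point, 5-fold × 2-repetition stratified cross-validation,
  within-fold z-scoring and PCA (20 components), ACC and rank-based AUC,
  and a between-subject cluster test against the 0.5 chance level.
* **Transitive-inference task** (`hierarchy()`, `build_premise_pairs()`,
  `build_late_test_pairs()`, `schedule_learning_block()`,
  `update_exit_criterion()`, `score_behaviour()`): 6-item hierarchies
  A>B>…>F, the 5 premise pairs, inference pairs B>D/C>E (1st degree) and
  B>E (2nd degree), anchor A>F, 30-trial learning blocks with the
  no-shared-item constraint, the >66%-in-2-of-last-3-blocks exit
  criterion, and accuracy scoring.
* **Brain–behaviour correlation** (`chance_level_test()`,
  `correlate_decoding_behaviour()`): normality-gated chance tests,
  Pearson correlation with percentile-bootstrap CI, permutation p and a
  Holm family bound.

## Worked example

```r
library(tmrtools)

cfg <- sim_config(duration = 600, n_channels = 16, so_rate = 10,
                  so_trough_amp_mean = -100, seed = 1)
sim <- generate_sleep_eeg(cfg)
sim$recording
#> <sleep_recording> 16 channels x 300000 samples @ 500 Hz (600.0 s)
#>   hypnogram: 20 x 30-s epochs (N3); 0 arousal interval(s)

sched <- make_tmr_schedule(2, seed = 1)      # 2 blocks = 48 planned cues
res <- run_closed_loop(sim$recording, sched)
summarize_delivery(res$events)$counts
#>      Experimental Novel
#> Up             12    12
#> Down           12    12

ps <- instantaneous_phase(sim$recording$data["F3", ], 500)
up <- res$events$condition == "Up"
circular_summary(phase_at_events(ps, res$events$onset[up]))
#> circular mean 340.50 deg (R = 0.585, SD = 1.036 rad, n = 24)
circular_summary(phase_at_events(ps, res$events$onset[!up]))
#> circular mean 167.31 deg (R = 0.910, SD = 0.434 rad, n = 24)
```

All 48 cues were delivered (12 per condition × sound-type cell, every
block complete). Up-targeted cues concentrate near 0° (the SO positive
peak) and Down-targeted cues near 180° (the trough). The spread reflects
the simulated SO frequency range: a fixed 500 ms delay is exactly half a
period only for a 1 Hz oscillation, so faster/slower SOs land slightly
off-phase — the same dispersion mechanism seen in real recordings. On
single-frequency 1 Hz SO trains the landing concentrates within a few
degrees of the target (resultant length > 0.9; see the test suite).

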