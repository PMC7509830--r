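# ssvepr

Frequency-domain analysis of steady-state visual evoked potentials
(SSVEPs) with Reliable Components Analysis, built around the paradigm
used to separate and time the neural sources of letter and Vernier
acuity: a stimulus alternating between two states at 3 Hz drives EEG
responses at exact harmonics (1F = 3 Hz for configural processing,
2F = 6 Hz for transient responses), whose amplitude and phase are tracked
across five stimulus sizes (logMAR 0.15–0.75 for Vernier offsets,
0.15–1.06 for letters).

The package is for researchers who want this analysis chain as tested,
reusable code — together with a forward simulator of 128-channel sessions
with known ground truth, so every stage can be validated by parameter
recovery.

## What it computes

* **Stimulus design** — logMAR conversions, graded acuity series,
  Vernier-grating and phase-scrambled letter-array frames, and the
  8-block x 20-trial randomized schedule (16 twelve-second trials per
  condition).
* **Preprocessing** — resampling 500 → 420 Hz (an integer 140 samples per
  3 Hz cycle), zero-phase 0.3–50 Hz band-pass, bad-channel replacement by
  the 6 nearest neighbors, common average reference, and threshold
  artifact rejection (30–80 µV range), in an enforced order.
* **Bin-centered spectra** — 2-s epochs (6 whole cycles) after a 1-s
  discard, DFT at 0.5 Hz resolution with single-sided ASD scaling, and
  *coherent* (complex) averaging with a neighbor-bin noise floor
  (2.5/3.5 Hz around 1F), giving SNR in dB as `10 log10` of the power
  ratio.
* **Reliable Components Analysis** — spatial filters maximizing
  trial-to-trial reliability of the complex harmonic coefficients via the
  generalized eigenproblem `R_between w = λ R_within w` on cross-trial
  covariances (same-condition trial pairs, whitened reduced subspace),
  with forward topographies, reliability spectra, and projections of the
  per-condition coherent averages into component space.
* **Dynamics and statistics** — amplitude/phase tuning curves per
  component, phase-difference latency estimation with the full
  wrap-around candidate family (at 3 Hz a 180° shift is 167 ms and the
  period is 333 ms), the paired signal-vs-noise-floor t test, and the
  two-factor repeated-measures ANOVA (component × logMAR) fitted as a
  linear mixed model.
* **Synthetic sessions** — two ground-truth sources per task (letters:
  left-lateral occipital leading medial-posterior by 100 → 40 ms;
  Vernier: medial occipital leading right-lateral by a constant 90 ms)
  with 1/f background noise and blink artifacts; `recovery_study()` runs
  a pooled multi-subject study end to end and scores recovery.

## Worked example

A reduced session (2 blocks, low noise) simulated and analyzed end to
end:

```r
library(ssvepr)

montage <- load_montage()
gt <- list(vernier = default_ground_truth("vernier", montage),
           letter  = default_ground_truth("letter", montage))

schedule <- build_schedule(n_blocks = 2, per_block_per_cond = 1, seed = 19)
raw <- simulate_session(schedule, gt, noise_spec(noise_rms_uv = 0.5),
                        seed = 19, montage = montage)
raw
#> <raw_session> 128 channels x 120000 samples @ 500 Hz, 20 trials

analysis <- analyze_session(raw, montage)
subset(analysis$tasks$vernier$tuning, harmonic == "1F" & component == "RC1",
       select = c(logmar, amplitude, phase_deg, snr_db))
#>   logmar amplitude phase_deg snr_db
#> 1   0.15     0.608      225.   29.8
#> 2   0.3      1.02       239.   32.9
#> 3   0.45     1.39       249.   33.4
#> 4   0.6      1.71       252.   36.0
#> 5   0.75     2.12       259.   43.7
```

RC1's amplitude grows linearly with log offset (the generating source
runs 0.7 → 2.2 µV) and its SNR sits ~30–44 dB above the neighbor-bin
noise floor. The RC1–RC2 latency lag per level:

```r
analysis$tasks$vernier$latency[, c("level", "logmar", "delta_phase_deg",
                                   "latency_ms")]
#>   level logmar delta_phase_deg latency_ms
#> 1     1   0.15            78.3       72.5
#> 2     2   0.3             91.6       84.8
#> 3     3   0.45            94.3       87.4
#> 4     4   0.6             94.2       87.2
#> 5     5   0.75            93.9       86.9
```

— the medial component leads the lateral one by roughly the generated
90 ms at all offsets (positive = second component later; estimates
tighten further at the full study size). Recovery scoring matches fitted
components to the generating topographies:

```r
evaluate_recovery(analysis, gt)$match
#>   task    component source     r
#> 1 vernier RC1            1 0.979
#> 2 vernier RC2            2 0.938
#> 3 letter  RC1            1 0.954
#> 4 letter  RC2            2 0.838
```

`plot_topography()`, `autoplot()` (montages, RCA models), `plot_tuning()`
and `plot_latency()` provide ggplot2 graphics; `tidy()`/`glance()`
methods summarize fitted RCA models.

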