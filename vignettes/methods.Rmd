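---
title: "Methods: evoked flow-velocity responses from functional TCD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evoked flow-velocity responses from functional TCD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vefr)
```

## The measurement model

Functional TCD probes neurovascular coupling by insonating the posterior
cerebral artery (PCA) during a block-design visual task: 10 cycles of 20 s
eyes-closed rest (OFF) followed by 30 s of checkerboard stimulation (ON),
with the middle cerebral artery (MCA) recorded as a control for systemic
effects, plus arterial pressure and a capnogram. The analysis chain in this
package assumes:

1. **Beat-resolved envelopes.** The velocity envelope is pulsatile; per beat
   we take the systolic peak $s$, the end diastolic value $d$ (the envelope
   minimum preceding the systolic upstroke) and the mean velocity
   $(s + 2d)/3$. The valley-before-peak convention is a deliberate choice:
   end diastole physiologically precedes the upstroke, and the alternative
   (valley after the peak) differs only in beat labelling, not in window
   averages.
2. **A stereotyped evoked response.** Stimulation raises velocity after an
   onset delay of about 1 s, the response peaks 5–10 s in, relaxes to a
   plateau, and decays back to baseline after stimulus offset. Only the
   plateau enters the headline statistic.
3. **The plateau contrast.** Per cycle and velocity index,
   $\mathrm{VEFR} = (v_\mathrm{stimul} - v_\mathrm{rest})/v_\mathrm{rest}
   \times 100\%$, where $v_\mathrm{stimul}$ averages the index over the last
   10 s of ON and $v_\mathrm{rest}$ over the last 5 s of OFF. Averages are
   taken over *beat-level* index values, not raw samples, because the
   systolic and diastolic indices only exist per beat; for the mean index a
   sample-wise average would differ only through beat-weighting and is not
   provided as a default. All windows are half-open $[start, end)$ seconds
   from recording start — stated once, used everywhere (beats on a boundary
   belong to the later window and are never double-counted).
4. **Per-cycle exclusion, per-subject averaging.** Artifact-contaminated
   cycles are excluded individually (never whole subjects, unless no cycle
   survives); the subject's response is the unweighted mean over included
   cycles.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `off_duration`, `on_duration`, `n_cycles` | 20, 30, 10 | s, s, count | the block design of the emulated study |
| rest / stimulation analysis windows | 5, 10 | s | plateau-contrast definition; on toy protocols shorter than the windows, the whole phase is used with a warning |
| `hr_bounds` | [40, 150] | beats/min | plausible cardiac range; sets the minimum peak separation 60/150 s |
| `min_amplitude_frac` | 0.3 | — | adaptive beat-amplitude gate, relative to the windowed (±5 s) median amplitude, iterated to a fixed point (see below) |
| `rr_bounds` | [6, 30] | breaths/min | breath-peak separation for end-tidal CO₂ |
| `snr_min` | 3 | — | cycle SNR: median beat amplitude over a windowed robust noise estimate |
| `max_missing_frac` | 0.10 | — | tolerated fraction of expected beats missing per cycle |
| `dropout_floor_frac`, `dropout_min_s` | 0.10, 1 | —, s | envelope below 10% of its median for >1 s counts as dropout |
| onset threshold (early phase) | 2 SD, floor 0.1 pp | — | threshold crossing of the smoothed (2 s) relative mean-velocity trace, sustained ≥1 s |

Statistical options: Student's pooled-variance t-test by default (Welch by
flag); Pearson's χ² without continuity correction; mixed-design ANOVA with
the `"cellmeans"` missing-cycle policy (subject cell means over available
cycles — the between-group F then equals a one-way ANOVA on subject means)
or `"complete"` (complete cases); confounders for the habituation regression
default to age, BMI, sex and smoking status. No multiplicity adjustment is
applied across the three indices, matching the emulated analysis; this is
deliberately reported rather than corrected.

## The synthetic-data generator

The generator *states* the world the pipeline assumes; its defaults are the
published group tables of the emulated study (`default_groups()`): baseline
mean PCA velocity 32.4 ± 7.8 vs 31.4 ± 6.0 cm/s, heart rate 71 vs 66 /min,
MAP 93 vs 113 mmHg, end-tidal CO₂ 36 vs 37 mmHg, per-index responses
12.9/14.4/16.7% (stenosis) and 10.5/12.2/14.4% (control) with the published
between-subject SDs.

**What it emulates.** Pulsatile envelopes (diastolic floor plus a
stereotyped pulse: 0.1 s half-sine-squared upstroke, then an asymptotically
exponential decay whose curvature is matched at the peak — envelope peaks
are rounded, and an unrounded kink would bias sub-sample peak
interpolation); an evoked-response curve that is zero before the onset
delay, rises as a smoothstep to the peak at `time_to_peak`, relaxes
exponentially (τ = 3 s) to the plateau and decays exponentially (τ = 3 s)
after stimulus offset; a +1 beats/min heart-rate increment during ON (the
reported non-significant tendency); breath-by-breath capnogram whose cyclic
maxima equal the programmed end-tidal value; pressure pulsatile around MAP;
additive Gaussian measurement noise; two artifact families — dropout
(envelope to ~2% for 1–3 s) and broadband spike bursts — drawn per cycle
with a configured probability and recorded in a ledger; and an optional
linear habituation slope. One root seed derives per-subject seeds, so a
cohort is reproducible byte for byte.

**Index coupling.** The three index responses cannot vary independently on
one heart: the mean-velocity response is the pulsatility-weighted
combination of the systolic and diastolic responses with weight
$w = s_0/(s_0 + 2 d_0)$. The generator therefore derives $w$ from the three
programmed response means, $w = (V_d - V_m)/(V_d - V_s)$, which fixes the
baseline pulsatility (stenosis: $s_0/d_0 \approx 3.1$, i.e. ≈59/19 cm/s at
baseline 32.4 — physiologically plausible) so that *all three* programmed
group-mean responses are attained exactly. Per subject, systolic and
diastolic targets are drawn independently with the between-subject SD and
the mean-index target follows with the group weight; the mean index
consequently has slightly smaller between-subject variance than its two
parents, a documented simplification. The within-subject cycle-to-cycle SD
(default 4 percentage points) is **an assumption** — the emulated study does
not report it; it was chosen once as consistent with the visual spread of
published per-cycle error bars and is not revisited.

**What it does not emulate** (so what a green test does *not* establish):
raw audio-band Doppler, probe repositioning drift, autoregulatory or
CO₂-reactivity dynamics, correlated systemic fluctuations (pressure and
velocity noise are independent), non-Gaussian measurement noise, and any
cognitive covariate structure. Group comparisons on synthetic cohorts
validate the *pipeline*, not the physiology.

## Numerical choices

- **Peak detection** collects local maxima, keeps the tallest subject to a
  minimum separation of 60/`hr_bounds[2]` s, then applies the adaptive
  amplitude gate. The gate is iterated to a fixed point because in noisy,
  slow-rate recordings spurious noise peaks can outnumber real beats and
  drag the windowed median amplitude down; re-estimating the median from
  survivors restores the intended threshold. Peak times are refined by
  3-point parabolic interpolation (sub-sample accuracy makes beat-to-beat
  heart rate stable to <0.1 beats/min on clean signals).
- **Cycle SNR** uses the MAD of second differences (which annihilates slow
  beat morphology) scaled by $\sqrt 6$, taken as the *worst* 1-s bin of the
  cycle so that short spike bursts cannot hide behind a long clean cycle.
- **Dropout runs** are detected on the raw envelope with sub-0.1 s
  interruptions merged, so isolated noise samples above the floor do not
  split a run.
- **Beat-level dropout** (no envelope available) uses inter-beat gaps with
  threshold `max(1 s, 1.6 × median inter-beat interval)`: clean gaps equal
  one interval, so the factor 1.6 separates deterministic beat trains from
  deleted spans at any plausible heart rate.
- **Onset detection** needs an absolute floor (0.1 percentage points)
  because on noiseless data the baseline SD vanishes and any positive
  residual would count as onset.
- **Sample size** is the smallest integer n whose exact noncentral-t power
  reaches the target. At Δ = 3, SD = 5, 80% power, two-sided α = 0.05 this
  is **45** (the normal approximation gives 43.6 → 44, but the t-based power
  at 44 is 0.795); the widely quoted "40 per group" for this design is
  analytically optimistic, and the package reports the formula-correct
  value.
- **Degenerate inputs**: flat signals yield empty, flagged series rather
  than errors; cycles whose analysis windows contain no beats are demoted to
  excluded with reason `beat_failure`; subjects with no included cycles are
  dropped from cohort statistics and logged.

## Design decisions that were genuinely open

- *Averaging domain for the plateau windows* (samples vs beat values):
  beat-level, for index consistency (above).
- *"Response onset" for the early-phase estimate* is not standardized;
  threshold-crossing with a sustain requirement was chosen, with every
  parameter exposed, because it is monotone and auditable.
- *Missing cycles in the repeated-measures comparison*: available-case
  subject cell means by default (keeps subjects with excluded cycles,
  weights their remaining cycles equally), complete-case as the strict
  alternative. The Greenhouse–Geisser correction is computed for the
  within-subject effects, but the between-group effect — the headline
  comparison — does not need a sphericity correction.
- *Recovery checks compare against realized draws.* The parameter-recovery
  acceptance test compares pipeline output with the cohort's *drawn*
  per-subject programmed targets rather than the population means: with a
  between-subject SD of 5 and n = 40, the sample mean itself wanders ±0.8
  points around the population value, which is sampling error, not
  measurement error.

## Known limitations

Beat detection assumes envelope SNR well above 3 for unbiased systolic
values (the maximum of a noisy signal is upward-biased; the VEFR ratio
cancels most, but not all, of this). The breath detector assumes a
reasonably periodic capnogram and will under-count during apnea. The
mixed-ANOVA within-subject table is only produced for balanced common-cycle
sets. The CLI is intentionally minimal (simulate / run); vendor formats
(EDF, DICOM) are out of scope, as is any raw Doppler audio processing.
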