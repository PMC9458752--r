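---
title: "Models and conventions behind CircuitPlasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind CircuitPlasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CircuitPlasticity)
```

CircuitPlasticity implements the standard quantification chain of a
critical-period plasticity study — ocular-dominance scoring, LSPS input
maps, intracellular and miniature-PSC metrics, fEPSP/LTP scoring, and the
accompanying group statistics — together with seeded generators that stand
in for raw recordings. This vignette is the package's account of the
underlying models, of the conventions we had to fix where the protocols
leave details open, and of what the synthetic benchmarks do and do not
demonstrate. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Ocular-dominance scoring

Units are scored from per-trial spike counts recorded while drifting
gratings (twelve equally spaced orientations, 2 s of stimulus in 4-s
trials, three repeats per eye and orientation, blank trials interleaved)
are shown to each eye in turn. Per unit:

1. **Tuning.** Mean stimulus-window firing rate per eye × orientation; the
   blank-trial mean is the baseline; evoked rate = raw − baseline. The
   preferred orientation is the argmax of the evoked rate. *Convention:*
   ties break toward the lowest orientation value, so the mapping is
   deterministic.
2. **Inclusion.** A unit is kept when its *raw* rate at the preferred
   orientation of its best eye is ≥ 1.5 × the blank rate. The rule is
   stated as a comparison of firing frequencies against blank, so it must
   use raw rates: on baseline-subtracted rates any positive response
   whatsoever would pass and the criterion would be vacuous. When the blank
   rate is zero, any positive response passes.
3. **ODI.** CE and IE are the baseline-subtracted responses through the
   contralateral and ipsilateral eye, rectified at zero (a negative evoked
   rate is no response, and rectification keeps the index inside [−1, 1]);
   ODI = (IE − CE)/(IE + CE). *Convention:* both responses are read at the
   unit's **global** preferred orientation (best over both eyes);
   `responseAt = "pereye"` switches to each eye's own preferred
   orientation. The source protocols do not say which was used; the global
   variant compares the two eyes at the same stimulus and is the default.
   Units with CE + IE = 0 after rectification have no defined ODI and are
   excluded (counted and reported).
4. **Categories and CBI.** ODI maps to seven categories with edges −1,
   −0.75, −0.45, −0.15, 0.15, 0.45, 0.75, 1. The printed edges touch, so a
   closure convention is required: bins are half-open [lower, upper), the
   last closed at 1. Per mouse, CBI = [(n1 − n7) + (2/3)(n2 − n6) +
   (1/3)(n3 − n5) + N]/2N, which is equivalently the mean over units of
   (w + 1)/2 with per-category weights 1, 2/3, 1/3, 0, −1/3, −2/3, −1 —
   the test suite checks the closed form against that independent
   per-unit sum.
5. **Group comparison.** Per-unit ODIs pool within condition for a
   two-sample Kolmogorov–Smirnov test; per-mouse CBIs compare by pooled
   two-sample t. Mice whose units are all excluded are dropped with a
   warning and recorded in the result.

### The OD generator

`genODDataset()` simulates Poisson-spiking units: spike counts are Poisson
with rate = baseline + eye drive × tuning over the 2-s stimulus window
(a constant-rate Poisson count is distributionally identical to summing
1-ms Poisson bins, so rates are all that matter downstream). Tuning is a
von Mises-shaped profile exp(κ(cos(θ − θpref) − 1)) over direction, with
the preferred direction shared across eyes. Defaults define the simulated
study conditions:

- baseline 2 Hz; mean contra drive 10 Hz, ipsi 5 Hz, with lognormal
  across-unit spread (sdlog 0.35). These place the expected non-deprived
  CBI near 0.67 — a normally contra-dominated binocular zone — and a
  halved contra drive near 0.5.
- κ = 4, i.e. a half-width at half height of ≈ 34°, the typical width of
  mouse V1 orientation tuning. A much broader profile would make adjacent
  orientations 30° apart statistically indistinguishable from three
  repeats, which no orientation-tuning experiment with this design would
  tolerate.
- monocular deprivation multiplies the deprived (contralateral) eye's
  drive by (1 − `mdShift`): a one-parameter effect the pipeline must
  detect. The deprived eye is contralateral because the sutured eye is
  contralateral to the recorded hemisphere.
- sample sizes for recovery studies: 7 mice × 30 units per condition,
  matching the 25–45 units/mouse yield of the emulated recordings.

Trial ordering and inter-trial randomization are not modelled (the
analysis is order-blind); the generator emits rows in a fixed design
order. What passing recovery tests shows: the chain detects a halved
deprived-eye drive in essentially every replicate at these sizes, with the
CBI t test holding its nominal 5% size under the null. What it does not
show: robustness to non-Poisson firing, eye-position artifacts, sorting
errors, or drift — none of which the generator emulates.

## LSPS input maps

Per stimulation site, classification works on the baseline-subtracted
sweep: the site is **direct** if the first deflection exceeding threshold
begins within the direct window after the laser, **synaptic** if it begins
within the synaptic window, **none** otherwise; saturated sweeps are
**excluded**. Direct sites are dropped from all synaptic statistics — the
glutamate acting on the recorded cell itself says nothing about
connectivity. Conventions the protocols leave open, all configurable:

- windows: direct 0–7 ms, synaptic 7–50 ms post-laser (standard for
  uncaging maps at these laser powers);
- threshold: 3 × the robust RMS (1.4826·MAD) of the pre-laser baseline;
- detection runs on a 1-ms **causal** boxcar of the trace. Causality
  matters: a centered filter smears a synaptic onset backwards in time and
  can push it across the direct-window boundary, misclassifying the site;
  a causal filter can only delay onsets.
- amplitude: baseline-subtracted **mean** current over the synaptic window
  (the quantity behind "averaged strength of synaptic inputs");
  `estimator = "peak"` is available;
- layer bounds from the pia: L1 0–100, L2/3 100–350, L4 350–450, L5
  450–650, L6 650–900 µm, plus a white-matter bin to 1200 µm so the
  16 × 75 µm grid is covered. These are mouse-V1 approximations and fully
  configurable.
- averaging across cells is per-site over maps where the site is synaptic
  or none (excluded/direct sites do not contribute to that site's n);
  alignment is by pia row by default, with soma-centred shifting offered.

The generator plants, per connected site, a current that steps to the
site's layer mean (times a lognormal factor, CV 0.1) at an onset drawn
uniformly 7–10 ms post-laser, holds through the synaptic window, then
decays (τ 20 ms); direct sites add a large fast-decaying response at
0.5–3 ms. The plateau-through-the-window shape is deliberately idealized so
that the window-mean estimator is unbiased up to the onset jitter (≈ 4%);
real synaptic currents decay within the window and their window-mean
underestimates the peak — recovered profile values are estimator-defined,
not absolute conductances. Recovery runs (10 cells, 2 pA noise) in the
test suite verify the planted L2/3 −50 pA / L5 −20 pA profile within 10%
and ≥ 95% site-class agreement.

## Intracellular metrics

- **Passive properties** from a −5 mV voltage step: Rin = step /
  steady-state current change, with steady state the mean over the final
  20% of the step; τ from a single-exponential fit of the capacitive
  transient (nonlinear least squares, started from — and, when the data are
  noiseless and nls cannot iterate on a zero-residual problem, replaced
  by — a log-linear fit over the top 98% of the decay); Cm = τ/Rin. The
  charge-integral Cm estimator was considered and not used: τ/Rin is the
  estimator consistent with reading both Rin and τ from the same step.
- **Spikes**: upward 0-mV crossings merged within 2 ms; per-spike
  threshold = voltage at the first dV/dt ≥ 20 V/s before the peak (the
  criterion value is a convention, configurable); half-width = width at
  half of (peak − threshold) with linear interpolation on both flanks.
- **F-I**: spike counts over the 1-s step window of the −100…+500 pA
  ladder. **SFA** = ISI3/ISI5, scored on the smallest step evoking ≥ 8
  spikes (≈ 10 Hz); at least 7 spikes are required for ISI5 to exist.
- **Minis**: amplitude-threshold detection with merging, validated against
  planted truth. The trace is median-baselined and polarity-rectified;
  the noise RMS is estimated robustly (MAD) on the raw trace; detection
  runs on a 0.5-ms boxcar-smoothed copy against 3 × that raw-trace RMS;
  suprathreshold excursions closer than 5 ms merge. Estimating the RMS on
  the *unsmoothed* trace is what makes a 3-SD threshold usable at 20 kHz:
  relative to the smoothed noise the threshold is ≈ 9 SD, so chance
  crossings are negligible while 20-pA events at SNR 5 still clear it.
  Event amplitude is read from the raw trace near the smoothed-trace peak;
  at noise levels around SNR 5 this peak-reading carries a positive bias
  of order the noise SD — a known limitation of threshold detectors,
  shared by the interactive tools this one stands in for. Template
  matching was deliberately not used: a threshold detector is verifiable
  against planted truth without circular assumptions about event shape.

The integrate-and-fire generator behind the current-clamp fixtures is a
forward-Euler leaky IF with spike-triggered adaptation (dt 0.05 ms, error
far below measurement granularity); spikes render as stereotyped 1-ms
waveforms so detectors see realistic depolarizations, and the closed-form
rheobase (Vth − Vrest)/R anchors the F-I tests.

## Field potentials and LTP

The fEPSP slope is the least-squares line over the 1-ms window after the
fiber volley. "After the fiber volley" does not pin down the volley's end,
so the window is anchored at the volley trough + 0.5 ms (configurable).
The volley itself is the *first* local trough in the 1–4 ms post-stimulus
search window that exceeds both 3 × the baseline RMS and 10% of the
deepest in-window deflection — first, not deepest, because the fEPSP
usually dips lower than the volley within the same window. The stimulus
artifact is blanked for 1 ms. Paired-pulse ratios measure each pulse with
a short local pre-pulse baseline so the first response cannot contaminate
the second's. Theta-burst timing is generated by closed form and checked
against a literal nested-loop enumeration (5 trains × 10 bursts × 4
pulses = 200 pulses; last at 41.83 s). LTP magnitude normalizes every
sweep to the mean over the 10 min preceding induction (×100) and averages
the final 10 min; the LTP generator samples every 20 s (the 0.05-Hz
baseline stimulation rate) with multiplicative noise.

## Statistics

The pooled-variance two-sample t is the default (the emulated reports use
integer df = n1 + n2 − 2); Welch is available. Summary mode reconstructs
sd = SEM·√n from printed summaries and agrees with raw mode to numerical
precision when the summaries come from the raw data — this is what lets
published group summaries be re-tested without raw traces, up to the
rounding of the printed values. K-S and Mann–Whitney delegate to
`stats::ks.test`/`stats::wilcox.test` (with brute-force oracles in the
tests); repeated-measures two-way ANOVA uses the subject-within-group
error stratum via `stats::aov`, reporting an explicit infinite-F flag when
an error stratum is numerically zero; Šidák is 1 − (1 − p)^m; the outlier
rule is a single, non-iterated pass at |z| > 2.5 because it is stated as
an a-priori criterion. All p values are two-sided.

## Problem sizes and determinism

Every generator is a pure function of its arguments and seed (the global
RNG state is saved and restored). The test suite and acceptance script use
the study-condition sizes where the quantity demands them — 200 replicate
experiments for deprivation detection, 1000 for the null rejection rate,
10 cells for LSPS recovery, 60-s sweeps at 20 kHz for mini detection —
which keeps the full suite in the low minutes on one CPU while leaving the
Monte-Carlo error well below the tested tolerances.

## Known limitations

- Generators emulate the *statistical* structure the analyses assume, not
  biophysics: no conductances, no correlated noise, no electrode or sorting
  artifacts.
- Mini amplitudes from the threshold detector are noise-biased upward at
  low SNR (see above); frequency and detection performance are unbiased.
- The LSPS laminar profile is estimator-defined (window-mean); compare
  groups with the same estimator settings only.
- The KS p-value is asymptotic in the presence of ties, as in the standard
  implementation.
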