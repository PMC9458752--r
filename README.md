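# CircuitPlasticity

Quantification pipelines for electrophysiological assays of developmental
cortical-circuit plasticity, written for slice and in-vivo physiologists who
need the standard readouts of a critical-period study as tested, scriptable
code rather than one-off analysis scripts:

- **Ocular-dominance plasticity** from single-unit recordings: orientation
  tuning from drifting-grating trial tables, the 50% responsiveness
  inclusion rule, the ocular dominance index
  ODI = (IE − CE)/(IE + CE) (CE/IE = contralateral/ipsilateral-eye
  response), the seven-category scheme with edges
  −1, −0.75, −0.45, −0.15, 0.15, 0.45, 0.75, 1, and the per-mouse
  contralateral bias index
  CBI = [(n1 − n7) + (2/3)(n2 − n6) + (1/3)(n3 − n5) + N] / 2N.
- **LSPS input mapping**: per-site response classification (direct vs
  synaptic vs none) on a 16 × 16, 75-µm uncaging grid aligned to the pia,
  direct-response exclusion, map averaging across cells, and laminar input
  profiles (per-layer mean input in pA; combined L2/3 and L2/3+L5).
- **Intracellular metrics**: input resistance and capacitance from −5 mV
  voltage steps (Rin = ΔV/ΔI, Cm = τ/Rin), spike detection with threshold
  and half-width, F-I curves over the −100…+500 pA step ladder,
  spike-frequency adaptation (ISI3/ISI5), and miniature-PSC detection with
  1-pA amplitude histograms and empirical CDFs.
- **Field-potential scoring**: fiber-volley detection, the fEPSP slope over
  the first 1 ms after the volley, input–output curves, paired-pulse ratios
  (20–200 ms), theta-burst induction timing (5 trains of 2-s 5-Hz bursts,
  4 pulses at 100 Hz, 10 s apart), and LTP magnitude as the mean
  baseline-normalized slope over the last 10 min.
- **Group statistics** as used with such data: pooled/Welch two-sample t
  from raw values *or* printed mean ± SEM/n summaries, two-sample
  Kolmogorov–Smirnov, (repeated-measures) two-way ANOVA, Šidák adjustment,
  Mann–Whitney U, and the a-priori 2.5-SD outlier rule.
- **Seeded synthetic generators** for every input modality — Poisson-spiking
  orientation-tuned units with eye-specific drive, an adaptive
  integrate-and-fire neuron, biexponential mini trains, layer-structured
  LSPS maps, and LTP slope series — each returning ground-truth labels so
  that every pipeline is validated by parameter recovery.

The data containers are S4 classes with validity checks (`TraceSweep`,
`LSPSRecording`, `InputMap`, `LTPTimecourse`, …); analyses are plain
functions over them.

## Worked example

Simulate a monocular-deprivation experiment (7 mice × 30 units per
condition; deprivation halves the deprived contralateral eye's drive) and
run the full analysis chain:

```r
library(CircuitPlasticity)

p  <- stimProtocol()                       # 12 orientations, 2 s / 4 s, 3 reps
nd <- genODDataset(p, odGroundTruth(),              30, 7, seed = 1)
md <- genODDataset(p, odGroundTruth(mdShift = 0.5), 30, 7, seed = 2)
odGroupAnalysis(nd$trials, md$trials, p)
```

```
  ND: 7 mice, mean CBI 0.686 +/- 0.008
  MD: 7 mice, mean CBI 0.490 +/- 0.016
  ODI K-S: D = 0.500, p = 0; CBI t(12) = 11.1, p = 1.18e-07
```

The non-deprived mice sit at a contralateral bias of about 0.67; four-day
deprivation shifts units toward the open (ipsilateral) eye, dropping the CBI
to about 0.5, and both the pooled-ODI K-S test and the per-mouse CBI t test
detect the shift. `runPipeline()` wraps the same chain behind a declarative
YAML configuration and writes per-unit, per-mouse and group outputs as
CSV/JSON.

A slice-side example — scoring LTP from a slope time course sampled every
20 s:

```r
tc <- genLTPSession(-0.25, potentiationFactor = 1.65, noiseCv = 0)
ltpMagnitude(tc)
#> [1] 165
```

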