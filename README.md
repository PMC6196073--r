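# oppkin

Kinematic analysis of thumb–finger opposition movements.

In an opposition task the thumb tip and one phalanx of a target finger move
towards each other until they touch — the building block of precision grip.
Given 3D trajectories of 15 digit sensors plus a wrist reference (100 Hz,
3-s trials; 12 tasks = 4 fingers × 3 phalanges), `oppkin` answers two
questions per trial:

- **How much does each effector contribute?** The displacement ratio
  `D_T = |d_thumb| / (|d_thumb| + |d_finger|)` (and `D_F = 1 − D_T`), where
  each displacement is the change in resultant displacement
  `RD(t) = √((x−x₀)² + (y−y₀)² + (z−z₀)²)` over the onward movement, in the
  wrist frame. `D` is Fisher z-transformed
  (`z = ½ ln((1+D)/(1−D))`) before testing.
- **How smooth is each movement?** The spectral arc length (SAL): the
  negative arc length of the amplitude- and frequency-normalized Fourier
  magnitude spectrum of the segmented speed profile. Values closer to zero =
  smoother movement.

The processing chain: wrist-reference subtraction → second-order zero-lag
low-pass Butterworth at 5 Hz per axis → five-point-stencil speed → onward
movement segmented at 5% of peak speed (with an automatic, flagged rescue
for degenerate trials) → per-trial metrics → repeated-measures ANOVAs
(finger × phalanx, Huynh-Feldt adjusted) plus twelve per-task effector
ANOVAs and Bonferroni post-hocs.

Because no raw recordings are distributed, the package ships a synthetic
session generator (`sim_config()`, `simulate_session()`) that emulates the
protocol — paired minimum-jerk thumb/finger movements with configurable
amplitude split, submovement count (roughness), sensor noise and onset
jitter — and records ground truth for every trial.

## Worked example

The `analysis/` scripts run the full workflow; `03_stats.R` simulates a
default session (8 participants × 12 tasks × 15 trials) and runs the
statistical battery:

```sh
Rscript analysis/01_simulate.R   # small demo session to TSV
Rscript analysis/02_analyze.R    # read back, analyze, check vs ground truth
Rscript analysis/03_stats.R      # full session + RM-ANOVAs
Rscript analysis/04_report.R     # means ± SEM tables
```

Output of `03_stats.R` and `04_report.R` (seed 200):

```
Two-way RM-ANOVA on the thumb's Fisher-z displacement ratio:
  finger           F(2.84, 19.90) =  2870.25, HF eps = 0.95, p = 3e-26
  phalanx          F(2.00, 14.00) = 52874.54, HF eps = 1.00, p = 7.1e-28
  finger:phalanx   F(6.00, 42.00) =     0.56, HF eps = 1.00, p = 0.76
Thumb contribution significantly exceeds the finger's in 10 of 12 tasks.
Tasks with statistically comparable contributions: ID, MD
Mean thumb displacement ratio D_T by target phalanx:
  distal   middle proximal
   0.576    0.727    0.917
Mean D_T by target finger:
 index middle   ring little
 0.659  0.718  0.771  0.813
Thumb movements are smoother than finger movements in 12 of 12 tasks
(mean SAL thumb -1.91 vs finger -2.17; closer to zero = smoother).
```

Reading: the thumb's share of the approach rises from distal to proximal
targets (0.58 → 0.92) and from index to little finger (0.66 → 0.81), both
main effects are significant with no finger × phalanx interaction, the thumb
out-contributes the finger in every task except the distal phalanx of index
and middle fingers, and thumb movements are smoother than finger movements
everywhere — the qualitative fingerprint of the original study.

In code, the same pipeline is three calls:

```r
library(oppkin)
ses <- simulate_and_analyze(sim_config(seed = 200))  # simulate + analyze
st  <- run_stats(ses$results)                        # ANOVAs + post-hocs
rep <- run_report(ses$results)                       # means ± SEM per task
```

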