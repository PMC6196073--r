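---
title: "Quantifying thumb and finger contributions to opposition movements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying thumb and finger contributions to opposition movements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oppkin)
```

## The problem

In a thumb–finger opposition movement the thumb tip and one phalanx of a
finger travel towards each other until they touch. Two questions drive this
package: *how much does each effector contribute* to the approach, and *how
smooth is each effector's movement*? Both are answered per trial from 3D
position recordings of 15 digit sensors plus a wrist reference sensor
(100 Hz, 3-s trials; 12 tasks = 4 target fingers × 3 target phalanges, 15
repetitions each per participant).

The contribution index is the **displacement ratio**. With resultant
displacements $RD(t) = \sqrt{(x-x_0)^2 + (y-y_0)^2 + (z-z_0)^2}$ measured in
the wrist frame, each effector's displacement is
$RD(\mathrm{end}) - RD(\mathrm{onset})$ over its onward movement, and

$$D_T = \frac{|d_{thumb}|}{|d_{thumb}| + |d_{finger}|},
  \qquad D_F = 1 - D_T .$$

$D$ is bounded in $[0,1]$, so the Fisher z-transform
$z = \tfrac12 \ln\frac{1+D}{1-D}$ maps it to an unbounded scale before
parametric testing.

Smoothness is the **spectral arc length (SAL)**: the negative arc length of
the amplitude- and frequency-normalized Fourier magnitude spectrum of the
segmented speed profile. Smooth bell-like movements concentrate their
spectrum near 0 Hz and give values close to $-1$; rough, multi-peaked
profiles spread spectral content and push SAL more negative.

## Processing chain and its assumptions

1. **Wrist frame.** All positions have the simultaneous wrist-reference
   position subtracted (`to_wrist_frame()`), removing rigid hand/arm
   translation. Assumption: the wrist sensor is rigid with the hand frame of
   interest.
2. **Filtering.** Each axis is low-pass filtered with a second-order
   Butterworth applied forward and backward (`lowpass()`): zero phase lag at
   every frequency, DC gain exactly 1, squared magnitude response. Cutoff
   5 Hz — voluntary reaching content lives well below it. Edges use
   reflective (odd) padding of 3 × order samples, and each causal pass
   removes the series' first value before filtering (the trials start at
   rest, so zero initial filter state is then nearly steady state).
3. **Differentiation.** Speed comes from the five-point central stencil
   $f'(t) = \frac{-f_{+2} + 8f_{+1} - 8f_{-1} + f_{-2}}{12h}$, exact for
   polynomials up to degree 4. The two samples at each edge use one-sided
   4-point and 3-point differences so the output keeps the input length;
   trials begin and end at rest, so segment bounds never depend on edge
   samples in practice.
4. **Rest position.** $(x_0, y_0, z_0)$ is the mean of the first 20 filtered
   samples (0.2 s), not the single first sample, for noise robustness. The
   generator never starts a movement before 0.25 s.
5. **Segmentation.** The onward movement is bounded by 5%-of-peak-speed
   crossings: walking back from the (first) global speed peak, the onset is
   the sample after the first sub-threshold sample; walking forward, the end
   is the last supra-threshold sample before the first sub-threshold one.
   The threshold is relative, so segmentation is invariant to speed scaling.
6. **Fallback.** If the segment is implausible — shorter than 100 ms, or
   carrying less than half of the trial's RD range — the longest contiguous
   supra-threshold run is used instead; if that also fails the gates (speed
   buried in noise), the whole trial is used, which is unbiased for the
   displacement because trials begin and end at rest. Rescued trials are
   flagged and counted. The 50% displacement gate separates the regimes
   cleanly: a genuine onward segment carries more than 95% of the RD range
   on clean data, while noise-truncated segments scatter well below half.
   This rescue exists because, when an effector contributes very little
   (e.g. the finger in proximal-target tasks under heavy sensor noise), its
   peak speed approaches the velocity noise floor and a random sub-threshold
   dip can truncate the primary segment; RD itself remains high-SNR, so any
   segment spanning the movement recovers the displacement.
7. **Metrics.** Displacement ratio with $D_F = 1 - D_T$ by construction
   (the identity then holds exactly in floating point); Fisher z with the
   ratio clamped to $1 - 10^{-9}$ so a zero finger displacement yields a
   finite, order-preserving value; SAL per effector from its own segmented
   speed profile.

Thumb and target phalanx are segmented independently, each from its own
speed profile.

## Tunable parameters

| Key | Default | Units | Why |
|---|---|---|---|
| `cutoff_hz` | 5 | Hz | movement band of voluntary reaches |
| `filter_order` | 2 | — | per pass; squared by the double pass |
| `threshold_frac` | 0.05 | of peak speed | onset/end crossings |
| `min_duration_s` | 0.1 | s | fallback gate: implausibly short segment |
| `min_displacement_frac` | 0.5 | of RD range | fallback gate: truncated/empty segment |
| `rest_samples` | 20 | samples | rest-position averaging window |
| `sal_f_max_hz` | 10 | Hz | spectral window; all movement content is below it after the 5 Hz filter |
| `sal_pad_factor` | 16 | — | zero-padding density; controls arc-length discretization error |
| `adaptive_cutoff` | FALSE | — | fixed-band SAL by default; the adaptive amplitude-threshold variant is available |

The SAL parameterization (10 Hz window, ×16 padding) is a package choice:
the published description of the metric does not pin these down, so absolute
SAL magnitudes are comparable *within* this package but not bit-for-bit with
other implementations. All orderings and invariances tested here (scale
invariance, monotone decrease with submovement count) are insensitive to
these two knobs.

## The synthetic generator

`sim_config()` / `simulate_session()` emulate the study conditions: 8
participants × 12 tasks × 15 trials, 3-s trials at 100 Hz, one sensor per
phalanx plus a wrist reference resting at fixed anatomically plausible
offsets of a supinated hand.

Per trial, the thumb tip and the target phalanx move towards each other
along the line joining their rest positions, covering a share $r$ and
$1 - r$ of the total amplitude (8 cm by default). Each effector's path is a
superposition of minimum-jerk submovements
$x(\tau) = 10\tau^3 - 15\tau^4 + 6\tau^5$ over a 1.2-s movement span with
onset jittered uniformly in [0.6, 0.8] s. Submovements are staggered by
span/(count + 1), so each overlaps its neighbour by half its duration:
the speed profile undulates but remains contiguous, and SAL decreases
strictly with the count.

- **Ratio map.** The default task → $r$ map is anchored on the reported
  group means of the z-transformed ratios (fingers: 0.87 at index to 1.23 at
  little; phalanges: 0.62 distal, 0.89 middle, 1.54 proximal) and combined
  *additively on the z scale*, then mapped back through $\tanh$. The design
  therefore carries finger and phalanx main effects but no interaction —
  matching the reported null interaction — and the recovered marginal means
  land near the published values (e.g. $D_T \approx$ 0.54/0.68/0.88 across
  phalanges).
- **Smoothness map.** The thumb always moves as a single submovement; finger
  effectors get 1 + phalanx index (+1 for ring/little) submovements, capped
  at 4. This encodes the reported asymmetry: thumb movements smoother
  everywhere, finger smoothness degrading towards proximal targets.
- **Variability.** A participant-level offset (SD 0.1) and a trial-level
  jitter (SD 0.05) perturb the ratio on the z scale; sensor noise is
  isotropic Gaussian per axis per sample on every sensor including the
  reference (default SD 0.005 cm; the tracker's static accuracy, 0.076 cm,
  is the hardware-scale upper bound, and recovery studies here use 0.05 cm).
- **Ground truth** (true onset/end, displacements, ratio, submovement
  counts) is recorded before noise for every trial.

What the generator does **not** emulate: finger curling geometry (paths are
straight lines), orientation data, anticipatory or corrective submovement
timing, return movements, inter-trial drift of the rest posture, and any
participant-specific hand geometry. Passing recovery tests on this generator
therefore demonstrates the pipeline's correctness under the stated noise and
trajectory model, not performance on real recordings.

## Statistics

Trials are averaged within participant × task first; all tests are
within-participant on those means, matching the degrees of freedom reported
for 8 participants. Fisher z values (transformed per trial, then averaged)
enter the ANOVAs, not raw ratios.

`rm_anova_2way()` partitions the balanced 4 × 3 within-participant design
with the participant as block; each effect is tested against its own
participant × effect interaction. Sphericity is handled by the Huynh-Feldt
epsilon estimated from the covariance of orthonormal condition contrasts,
clipped to 1; adjusted p-values use epsilon-shrunk degrees of freedom. With
two levels (the effector factor) the epsilon is exactly 1 and the F equals
the squared paired t statistic — both facts are exercised as oracles in the
test suite, alongside agreement with `stats::aov` sums of squares and
`car::Anova` epsilons on random data. Post-hoc pairwise comparisons are
paired t-tests with Bonferroni correction (Holm available); the correction
is a package choice, as the original analysis does not name one.

## Replication studies shipped with the package

The test suite runs, among unit oracles:

- **Segmentation recovery:** 1,000 single-effector minimum-jerk reaches
  (amplitude 9–14 cm, duration 0.5–0.8 s — comfortable fast reaches whose
  5% threshold sits well above the speed-noise floor). Noise-free detection
  must match a brute-force threshold scan within ±1 sample; with 0.05 cm
  sensor noise, within ±2 samples in ≥95% of trials.
- **Ratio recovery:** a 15-trial session per task at 0.05 cm noise, with
  participant- and trial-level ratio variability disabled so the trial mean
  is compared against the *configured* $r$ (tolerance 0.02).
- **Qualitative reproduction:** 100 seeded full sessions through the entire
  pipeline; in at least 90% the finger and phalanx main effects on $z_{D_T}$
  must be significant at 0.01, the interaction must not be significant, and
  the thumb's mean SAL must exceed the finger's in all 12 tasks.
- **Type-I control:** 200 seeded sessions from a null generator ($r = 0.5$,
  single submovements, no participant-level ratio offset) must reject in
  5% ± 3% of the 2,400 effector tests. The participant offset is removed
  here deliberately: a shared offset makes the twelve per-task tests
  near-perfectly correlated copies of one test, which leaves the nominal
  level intact but would reduce the study to ~200 effective samples.

Problem sizes (replicate counts, trial counts, noise levels) are the
package's chosen study conditions and are stated in the tests themselves.

## Numerical choices and edge cases

- Peak ties: the earliest global speed maximum is the peak.
- A speed profile that is identically zero raises an explicit
  "no movement detected" error; the pipeline records such trials in an
  exclusion table rather than aborting, so every manifest trial is accounted
  for (conservation is tested).
- `resample_100()` interpolates linearly — the profiles are already low-pass
  filtered at 5 Hz, so higher-order interpolants add nothing testable —
  and preserves endpoint values exactly.
- Zero-variance ANOVA cells give F = 0, p = 1 rather than NaN.
- The Huynh-Feldt estimate warns (but proceeds) when participants are too
  few for a full-rank contrast covariance.
- Time stamps in files are derived from the integer sample index
  (`time_s = index / fs`); the index is authoritative, avoiding float-equality
  joins, and write→read→write round trips are byte-identical.

## Limitations

- Absolute SAL values depend on the chosen spectral window and padding;
  compare them only within a fixed configuration.
- The effector ANOVA equals a paired t-test; with 8 participants its power
  profile is narrow, exactly as in the original design.
- The fallback segmentation is a declared convention for automatic rescue
  of degenerate trials, not a reconstruction of the original study's manual
  procedure.
- Straight-line synthetic trajectories mean the generator cannot probe
  errors specific to curved real paths (e.g. RD non-monotonicity within a
  movement); the displacement ratio is defined on RD differences and is
  exact for the generator's geometry.
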