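---
title: "Model- and data-driven directed connectivity for SSVEP: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model- and data-driven directed connectivity for SSVEP: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ssvepflow)
```

## The problem

A flickering visual stimulus at certain frequencies (classically below ~30 Hz)
evokes a steady-state visual evoked potential (SSVEP): an oscillation at the
stimulus frequency, strongest over visual cortex but detectable in frontal
areas. ssvepflow quantifies the *directed* interaction between visual cortex
and frontal area under different flicker frequencies along two independent
routes:

1. **Model-driven.** A coupled double-column neural mass model is fitted to a
   two-channel (occipital, frontal) recording by particle swarm optimization
   (PSO). The estimated inter-column gains K1 (occipital → frontal) and K2
   (frontal → occipital), and the intra-column connectivities C1 and C2, are
   the effective-connectivity readout.
2. **Data-driven.** Partial directed coherence (PDC) over a multivariate
   autoregressive (MVAR) fit of a multi-electrode montage, band-averaged and
   aggregated into four area-level flows: VC→FA, FA→VC, within-VC, within-FA.

Both readouts feed the same group-level inference: one-way repeated-measures
ANOVA across stimulus conditions with Greenhouse–Geisser (GG) correction and
Bonferroni-corrected paired t post-hoc tests.

## The double-column model

Each column is a Jansen–Rit cortical column: a pyramidal population receiving
excitatory and inhibitory feedback from local interneurons. Population
potential-to-rate conversion uses the sigmoid

$$\mathrm{Sigm}(v) = \frac{2 e_0}{1 + e^{r (v_0 - v)}},$$

with half-maximum rate $e_0$ = 2.5 s⁻¹ at threshold $v_0$ = 6 mV and
steepness $r$ = 0.56 mV⁻¹. Synaptic dynamics are second-order linear kernels
with gains $A$ = 3.25 mV (EPSP), $B$ = 22 mV (IPSP) and rate constants
$a$ = 100 s⁻¹, $b$ = 50 s⁻¹. These are the standard literature values
(`column_constants()`), exposed in configuration but treated as fixed
physiology, not estimated.

A column's four internal synapse counts derive from one global connectivity
constant $C$ as $(C,\, 0.8C,\, 0.25C,\, 0.25C)$. We interpret the estimated
C1, C2 as this global constant per column; the estimation box 60–120 sits
below the canonical 135 and is treated as a restricted search range. This
interpretation is a design choice: the alternative reading (C as a single
sub-constant) is not compatible with one constant per column controlling the
whole intra-column loop.

Columns are coupled bidirectionally: the pyramidal firing rate of the source
column, scaled by the gain (K1 for column 1 → 2, K2 for 2 → 1), enters the
target column through an additional second-order kernel with rate constant
$a_d$, modelling inter-area conduction delay. We use $a_d$ = 33 s⁻¹, the
literature value for the coupled two-column model; it is a configuration
constant. The recorded output per column is the pyramidal membrane potential
(excitatory feedback PSP + coupling PSP − inhibitory PSP).

The external drive $p(t)$ (occipital) and $p'(t)$ (frontal) is pulse-density
noise, uniform in [120, 320] s⁻¹ per 1-ms sample. Stimulus conditions add a
square pulse train at the flicker frequency (amplitude 7.0 drive units, 50%
duty cycle) to $p(t)$ only; the control condition is pure noise. The pulse
shape and duty cycle are configurable: only the amplitude (7.0) and the noise
range are fixed by the study design, the wave form of an LED flicker drive is
not, and a square wave is the closest idealization. The "7.0 V" drive
increment is treated as dimensionless pulse density; its physical units are
not interpretable in this drive scale, and we deliberately do not rescale it.

### Operating regime

With the literature constants and the study's coupling box (K1 ∈
[1500, 3000], K2 ∈ [100, 600]), the coupling input $A/a_d \cdot K \cdot
\mathrm{Sigm}(v)$ is large relative to the sigmoid's dynamic range, so each
column drives its partner onto the upper shoulder of the sigmoid. In this
regime the inter-column gains act chiefly as a tonic depolarization of the
partner column plus a scaled transfer of its fluctuations, which makes K1 and
K2 strongly identifiable from the waveform (they set the offset and gain of
the transferred signal). The stimulus-frequency asymmetry that defines SSVEP
— a clear spectral response for 8 Hz flicker, none for 44 or 84 Hz — arises
here from the synaptic kernels' low-pass characteristics: the second-order
EPSP kernel attenuates at −40 dB/decade above ~16 Hz, so the 44/84 Hz drives
reach the output with negligible absolute power (the test suite verifies a
>10× power ratio). Limit-cycle alpha dynamics, by contrast, require the
canonical C = 135 and are reproduced by `simulate_single_column(135, ...)`,
outside the inversion box.

### Integration

Fixed-step 4th-order Runge–Kutta at dt = 1 ms (matching the 1000 Hz
recording rate), inputs held constant within each sample, all-zero initial
state, and a discarded 1 s burn-in ahead of the 3 s analysis window.
A finer dt is available through an integer substep factor. Fixed-step
integration was chosen over adaptive stepping for bit-level reproducibility:
identical (parameters, inputs) give identical trajectories, which the
shared-noise inversion protocol relies on. Divergence (non-finite or
>10⁸ mV states) raises an error naming the parameter set; inside the search
box the system is dissipative and divergence does not occur in practice.

## PSO inversion

`invert_segment()` estimates (C1, C2, K1, K2) by global-best PSO on the box
C1, C2 ∈ [60, 120], K1 ∈ [1500, 3000], K2 ∈ [100, 600], with swarm size
Q = 60, G_max = 100 generations, attraction constants t1 = t2 = 2, stagnation
window D = 20 at tolerance δ = 10⁻⁶.

Choices made where the procedure was genuinely open:

* **Fitness.** The default objective is the sum of per-channel relative
  errors, RE(u1, U1) + RE(u2, U2) with RE = ‖X − Y‖/‖X‖ — the relative error
  is the method's fit-quality measure, and summing the two channels is its
  simplest two-channel extension. Sum-of-squared-errors and a spectral RE
  variant are selectable (`rule` argument).
* **Shared noise.** During inversion every candidate simulation reuses one
  fixed noise realization (a fixture's stored drive, or a seeded realization
  for real recordings). Waveform-level RE below 0.01 is unattainable if each
  candidate draws fresh noise, so a common drive is a structural requirement
  of the fit-quality target, not an optimization trick.
* **Inertia.** Linear decay from 0.9 to 0.4 over G_max — the canonical
  schedule of inertia-weight PSO.
* **Bounds.** After each velocity update, positions are clamped to the box
  and the violating velocity component zeroed. Velocities initialize
  uniformly in ±(upper − lower) per dimension.
* **Ties.** Personal and global bests keep the incumbent on exact ties, so a
  run is a deterministic function of (objective, config, seed).
* **Failures.** A failed or diverged candidate simulation scores a large
  finite penalty (10⁶) instead of raising, so the swarm continues.

Per-subject estimates average the recovered couplings across the five
segments of each condition (`average_segment_results()`).

In recovery experiments on shared-noise fixtures the swarm at full budget
(Q = 60, G_max = 100) reaches per-channel REs of order 10⁻⁴ and recovers K1
within a few units; C1/C2 are the least identifiable directions because the
sigmoid compresses their influence at the driven operating point (their
group-level contrast is also null in the emulated study, matching the
original design).

## PDC analysis

`fit_mvar()` fits x(n) = Σ A_r x(n−r) + w(n) by per-segment ordinary least
squares on the stacked regression after channel-mean removal; no
cross-segment pooling, matching a 3 s analysis unit. The innovation
covariance uses maximum-likelihood scaling. Order selection
(`select_order_aic()`) minimizes ln det Σ̂ + 2pN²/T over p ∈ [5, 20]; ties
take the smallest order.

PDC is computed from Ā(f) = I − Σ_r A_r e^(−i2πfr/fs) as
π_ij(f) = |Ā_ij(f)| / ‖ā_j(f)‖ with the **column** (source) normalization of
the standard definition, so Σ_i |π_ij(f)|² = 1 per source j and frequency.
Two deliberate readings are documented because misreading either silently
flips the headline result:

* π_ij(f) quantifies flow **j → i** (source column, target row); the flow
  matrix is stored target-by-source.
* The normalization uses the column of Ā(f), even where descriptions call
  ā_j a "row vector": only the column normalization yields the unit
  source-power identity above, which the test suite enforces to 10⁻¹⁰.

Directed flow strength between two electrodes is the average PDC magnitude
(not squared PDC; a squared variant is available) over 6–92 Hz on a 1 Hz
grid (87 grid points; grid configurable). Area aggregation sums ordered
electrode pairs: VC→FA and FA→VC over 4 × 2 = 8 pairs each, within-FA over
2, within-VC over 12, self-loops excluded. The FA→VC definition mirrors
VC→FA with the roles swapped — the transposed block of the flow matrix —
which is the only logically consistent reading. Electrode groups are
user-supplied configuration (default: V1_L, V1_R, V2_L, V2_R vs FrA_L,
FrA_R); a reference electrode such as Cb is excluded simply by leaving it
out of the montage passed to analysis (`select_channels()`).

No significance thresholding is applied to PDC edges before averaging, and
no DTF/Granger variants are provided.

## Group statistics

`rm_anova_gg()` implements the one-way within-subject ANOVA from textbook
sums of squares: F = MS_condition/MS_error on ((k−1), (k−1)(n−1)) degrees of
freedom — (3, 27) for the 10-subject, 4-condition design. GG epsilon comes
from the double-centered condition covariance, ε = tr(C̃)²/((k−1)ΣC̃²),
clamped to [1/(k−1), 1]; a numerically singular covariance returns the lower
bound with a warning. The GG p value scales both degrees of freedom by ε.
Post-hoc tests are two-sided paired t tests of the reference condition
(default 8 Hz) against each other condition, Bonferroni-corrected with
m = 3; sidedness is a package choice since the original analysis does not
state it. All-zero difference vectors report t = 0, p = 1; constant non-zero
differences are flagged undefined rather than reporting an infinite t.

Because ε is estimated, the GG-corrected test is conservative under a
spherical null (measured rejection ≈ 0.02 at α = 0.05 over 1000 null
tables); the uncorrected F test sits at the nominal level. The test suite
asserts exactly these two properties.

## The synthetic study generator

Real multi-subject recordings are not redistributable, so
`generate_study_fixture()` emulates the study design: 10 subjects × 4
conditions (control, 8, 44, 84 Hz) × 5 segments of 3 s at 1000 Hz. Per
subject × condition cell it draws

* a true double-column parameter set around mid-box values (C1 = C2 = 90,
  K1 = 2000, K2 = 350) with per-subject jitter (SD 5/5/120/40 for
  C1/C2/K1/K2) and per-cell jitter (SD 3/3/60/20), truncated to the box,
  with **K1 elevated by 500 in the 8 Hz condition** — the planted
  model-driven effect;
* a 6-channel VAR(1) generator over the VC/FA montage with a baseline
  VC→FA coupling of 0.03 raised by 0.12 in the 8 Hz condition (±0.01
  per-cell jitter) — the planted data-driven effect.

Mid-box centring avoids asserting unavailable population means; the jitter
SDs produce between-subject spread comparable to the planted effect, and the
effect sizes are large enough that the repeated-measures design detects them
with power near 1 — the generator plants a qualitative contrast, not a
calibrated effect size from data. These defaults were fixed once and are the
study conditions of the package's tests.

Every artifact is a deterministic function of (spec, seed): the master seed
expands into a per-segment seed table recorded in the manifest, from which
each segment regenerates bit-identically (`load_study_fixture()` does exactly
this). The generator makes no attempt to model line noise, movement
artifacts, volume conduction or reference effects — the emulated study
corresponds to pre-cleaned, artifact-free segments, so passing tests say
nothing about robustness to such contamination in real data. The VAR montage
fixtures share no generative mechanism with the double-column fixtures; the
two branches validate independently.

## Problem sizes in the shipped tests

The test suite and acceptance script choose sizes that keep a full run on one
CPU within minutes while leaving every statistical margin wide: the
fit-quality experiment runs the full swarm (Q = 60, G_max = 100) on one
segment per condition; the end-to-end study runs the full 10 × 4 × 5 design
with a reduced swarm (Q = 16, G_max = 20), which recovers K1 to ~±25 against
a planted effect of 500; the ANOVA power loop uses 20 single-segment
replicates at Q = 12, G_max = 10. Direction-recovery and null-calibration
properties use 100 and 1000 replicates respectively at n = 3000 samples.

## Known limitations

* Two columns only; no spatially extended networks, no volume conduction.
* The coupling box places the model in the driven (shoulder) regime
  described above; conclusions about limit-cycle dynamics require other
  parameter ranges.
* PDC captures only direct linear lagged dependencies among the modelled
  channels; flow through unmodelled relays (e.g. parietal or motor nodes) is
  not attributed.
* The native I/O format is delimited text with a JSON sidecar; EDF import is
  not provided.
* C1/C2 are weakly identifiable at the driven operating point; their
  estimates should be interpreted as box-constrained nuisance parameters.
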