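# ssvepflow

Directed connectivity analysis for steady-state visual evoked potential
(SSVEP) experiments, along two independent routes:

* **Model-driven:** inversion of a coupled double-column Jansen–Rit neural
  mass model — column 1 representing occipital (visual) cortex, column 2 the
  frontal area — by particle swarm optimization (PSO), estimating the
  intra-column connectivities C₁, C₂ and the directed inter-column coupling
  gains K₁ (occipital → frontal) and K₂ (frontal → occipital) from a
  two-channel recording.
* **Data-driven:** partial directed coherence (PDC) over a multivariate
  autoregressive (MVAR) fit of a multi-electrode montage, with AIC order
  selection (order 5–20), band-averaged flow strengths (6–92 Hz), and
  aggregation into four area-level flows: VC→FA, FA→VC, within-VC,
  within-FA.

Both readouts feed one-way repeated-measures ANOVA with Greenhouse–Geisser
correction and Bonferroni-corrected paired t post-hoc tests across stimulus
conditions (control, 8, 44, 84 Hz flicker).

The package is aimed at electrophysiologists comparing effective-connectivity
readouts across stimulation conditions, and at methodologists who need a
fully synthetic, seed-reproducible test bed: a generator emulating a complete
multi-subject study (10 subjects × 4 conditions × 5 segments of 3 s at
1000 Hz) with planted, recoverable effects is included and is itself tested
code.

## The core quantities

Model inversion minimizes the summed per-channel relative error

    RE = ‖X − Y‖ / ‖X‖

between recorded (U₁, U₂) and simulated (u₁, u₂) waveforms over the box
C₁, C₂ ∈ [60, 120], K₁ ∈ [1500, 3000], K₂ ∈ [100, 600], with candidate
simulations driven by a fixed (shared) noise realization. PDC is the
column-normalized spectral measure

    π_ij(f) = |Ā_ij(f)| / ‖ā_j(f)‖,   Ā(f) = I − Σ_r A_r e^(−i2πfr/fs)

so that Σ_i |π_ij(f)|² = 1 for every source j: π_ij quantifies directed
influence j → i.

## Worked example

Generate a synthetic 8 Hz segment with known parameters, invert it, and run
the data-driven chain:

```r
library(ssvepflow)

truth <- double_column_params(C1 = 85, C2 = 95, K1 = 2200, K2 = 300)
fix <- generate_inversion_fixture(truth, stimulus_spec("8"), seed = 11)
res <- invert_segment(fixture = fix,
                      config = pso_config(Q = 30, G_max = 40), seed = 99)
res$params
#> <double_column_params> C1 = 109.361, C2 = 60.000, K1 = 2191.967, K2 = 311.020
round(res$relative_error, 6)
#>       u1       u2
#> 0.000205 0.001044
```

Both channels are fitted to a relative error of ~10⁻³–10⁻⁴ (the full-budget
swarm, Q = 60 and G_max = 100, reaches ~10⁻⁴), and the directed gain K₁ is
recovered within 0.4% of the generating value; C₁/C₂ are only weakly
identifiable at this operating point, which mirrors their null group-level
role. The data-driven branch on a montage segment with a planted VC→FA
coupling:

```r
seg <- generate_var_fixture(ssvepflow:::study_var_coefficients(0.15),
                            innovation_sd = 1, n_samples = 3000, seed = 3)
fl <- segment_flows(seg)   # AIC order selection, MVAR, PDC, band average
fl$order
#> [1] 5
unlist(fl$flows)
#>  vc_to_fa  fa_to_vc within_vc within_fa
#>     1.812     0.474     0.740     0.178
```

The planted VC→FA direction dominates its reverse. Group-level inference on
a 10-subject × 4-condition table of K₁ estimates:

```r
res <- rm_anova_gg(tab)    # tab: condition_table, subjects x conditions
res
#> F(3, 27) = 49.040, p = 0.0000 (GG eps = 0.668, p_GG = 0.0000)
posthoc_paired_bonferroni(tab, reference = "8")
```

`run_study()` chains everything: fixture generation (or a directory of
recorded segments), per-segment PSO inversion with per-subject averaging,
per-segment PDC flows, and the ANOVA + post-hoc layer for all eight measures,
deterministically from one seed.

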