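# mdximmune

Deterministic ODE model of the interplay between the immune response and
skeletal-muscle fiber turnover in the dystrophin-deficient **mdx mouse**,
the standard animal model of early-onset Duchenne muscular dystrophy
(DMD).  The package is aimed at systems-biology and disease-modelling work
where one needs to (a) simulate immune-driven degeneration/regeneration
cycles, (b) run in-silico immune-cell depletion experiments, (c) calibrate
the model against heterogeneous literature-style time courses, and (d) map
the model's long-run regimes by parameter sweeps and ensembles.

## The model

Six state variables: immune-cell counts per mm³ of muscle — CD4⁺ helper
T cells *H*, CD8⁺ cytotoxic T cells *C*, macrophages *M* — and fiber-state
percentages of the tissue — normal *N*, damaged *D*, regenerating *R*
(with *N* + *D* + *R* = 100 conserved):

```
dH/dt = b_H + k1·D·M − d_H·H
dC/dt = b_C + k2·D·H − d_C·C
dM/dt = b_M + k3·M·D − d_M·M
dN/dt = k4·R − k5·C·N − α(t)·N
dD/dt = k5·C·N + α(t)·N − k6·D·M − d_D·D
dR/dt = k6·D·M + d_D·D − k4·R
```

Mechanical damage enters as a lognormal time-to-failure hazard
α(t) = h/(t·σ·√2π)·exp(−(ln t − m)²/2σ²) — the hazard shape that arises
when fiber failure is the endpoint of accumulated multiplicative
micro-damage.  The immune source terms are derived, not free:
b_X = d_X·X₀, so the wild-type baselines (H₀, C₀, M₀) are a fixed point of
the immune block whenever no damage is present.  The wild-type (disease
free) configuration is identical to the mdx one except that the damage
amplitude *h* is one tenth of the mdx value.  Time is measured in weeks;
ages given in days are converted on ingest.

Defaults throughout are the published calibrated values for the mdx mouse
(`mdx_parameters()`).

## Worked example

```r
library(mdximmune)

p  <- mdx_parameters()                                   # calibrated mdx values
tr <- simulate_mdx(p, cfg = simulation_settings(t_end = 12))

peak_value(tr, "M")   # macrophage peak: 104206 cells/mm^3 at week 3.95
peak_value(tr, "C")   # CD8+ peak:          433 cells/mm^3 at week 3.75
tail(tr, 1)           # week 12: N = 40.9%, D = 1.2%, R = 57.9%

# in-silico antibody-mediated macrophage depletion over the whole run
res <- run_depletion_experiment(
  p, depletion_schedule("macrophages", t_start = 0, t_end = 12))
res$summary
#>        arm    N    D    R
#> 1 depleted 84.8 1.36 13.9
#> 2  control 40.9 1.19 57.9
```

The simulated mdx course shows the massive early macrophage infiltration
(about 10⁵ cells/mm³ peaking near week 4) and the ensuing conversion of
normal tissue to regenerating fibers: by week 12 only ~41 % of fibers are
morphologically normal.  Clamping macrophages to zero for the whole run
leaves ~85 % of fibers normal at week 12, while the damaged percentage
(1.36 %) is barely below the undepleted run (1.19 %): without macrophage
antigen presentation there are few cytotoxic CD8⁺ cells making new damage,
but also no macrophage clearing driving the repair loop.

Long-run behavior is summarized over a late window and classified:

```r
tr50 <- simulate_mdx(p, cfg = simulation_settings(t_end = 50, output_step = 0.1))
tail_statistics(tr50, c(40, 50))["N", ]   # mean 31.5 %, amplitude 0.80 pp
classify_mode(tr50)                       # "quiescent_low"
```

Calibration, synthetic data and sensitivity analyses follow the same
pattern; see `?fit_global`, `?generate_observations`,
`?factorial_ensemble`, `?find_optimal_k4` and the methods vignette
(`vignettes/mdx-immune-model.Rmd`).  A command-line wrapper around every
experiment ships at `inst/cli/mdxsim.R`.

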