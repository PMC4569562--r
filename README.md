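# divwave

Collapse-driven population dynamics and diversity waves.

`divwave` simulates communities of `N` species that share a single
saturated carrying capacity (`P_tot = 1`) and whose composition changes
not by incremental birth–death drift but by **episodic whole-population
collapses**: at each discrete step one population is wiped out (think of a
bacterial strain decimated by a lytic phage), a new species is seeded at a
tiny fraction `γ` of the capacity, and the freed-up resources are
instantaneously redistributed among the survivors. Each population obeys

    dP_i/dt = Ω_i · P_i · (1 − Σ_j P_j) − η_i(t) · P_i

with `η_i(t)` zero for survivors and large for the collapsing species;
since regrowth is fast relative to the interval between collapses, the
simulation advances in discrete collapse events (one collapse = one time
unit).

The emergent dynamics is rich: cyclic **diversity waves** punctuated by
collapses of dominating species (`P_max > 1 − 1/N`), wave durations of
order `N·ln N`, a **bimodal time-aggregated species abundance
distribution** whose upper tail is scale-free with
`dProb(P_i > P)/dP ∝ P^(−τ)`, `τ ≈ 1.7`, and long-term memory of the
abundance hierarchy transmitted across waves. In the simplified
history-free limit (all abundances reset to `1/N` at each wave start) the
tail exponent is exactly 2.

The package is aimed at theoretical ecologists and microbiome researchers
who want a fast, reproducible reference implementation of the model, its
seven published variants (neutral drift, exponential fluctuations,
interconnected environments, Kill-the-Winner, Kill-the-Loser,
heterogeneous fitness, resilience), and the estimators for its emergent
observables.

## Worked example

```r
library(divwave)

params <- model_params(N = 1000, gamma = 1e-9)
run <- simulate_community(params, 1e6, seed = 42)
run
#> divwave run: variant 'basic', N = 1000, gamma = 1e-09
#>   1000000 collapse steps (burn-in 10000), seed 42, engine cpp
#>   125 wave boundaries

w <- detect_waves(run$events, N = 1000)
ws <- wave_statistics(w, run$diversity, run$events)
ws$mean_duration          # 7974 steps; N log N = 6908
1 / ws$survivor_rate      # 1001; uniform-kill prediction is N = 1000

fit_powerlaw_tail(run$sad, fit_range = c(1/1000, 1))
#> tail_fit (logbin_ls): tau = 1.614 (slope -0.614, se 0.0167) on [0.001, 1], n = 15
```

The run detects 125 diversity waves whose mean duration (7974 collapse
steps) is close to the `N·ln N ≈ 6908` prediction; the survivor curve
within waves decays at the exact uniform-kill rate `1/N`; and the
least-squares fit of the log-binned abundance density over `[1/N, 1]`
gives a tail exponent `τ ≈ 1.61` for this single seed (pooling three
seeds gives 1.63–1.65, inside the universal `1.7 ± 0.1` band). The
companion estimators — `snapshot_sad()` for the wave-boundary ("green" /
"red") distributions, `interpeak_slope()` for the region connecting the
two distribution peaks, `jump_series()` for the cross-wave memory
observable, and `fitness_population_map()` for the trait heatmaps of the
heterogeneous variants — are documented in the methods vignette
(`vignettes/collapse-driven-dynamics.Rmd`).

## Command line

A thin CLI wrapper ships in `inst/cli/divwave`:

```sh
divwave simulate --variant basic --N 1000 --gamma 1e-9 \
        --steps 1000000 --seed 42 --out runs/basic
divwave analyze  --in runs/basic
divwave fit-tail --sad runs/basic/sad.tsv --range-low 1e-3
divwave reproduce --seed 1 --out headline.json
```

`simulate` writes `events.tsv`, `diversity.tsv`, `sad.tsv`,
`sad_green.tsv`, `sad_red.tsv` and a `manifest.json` that suffices to
reproduce every output byte-identically; `analyze` adds `waves.tsv`,
`jumps.tsv` and `summary.json`. YAML configuration files are supported via
`--config` (see `?load_config`).

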