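---
title: "Collapse-driven community dynamics: model, estimators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collapse-driven community dynamics: model, estimators, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divwave)
```

## The model

`divwave` simulates `N` species competing for one shared carrying capacity,
normalised to `P_tot = 1`. Between collapses the community sits saturated:
the populations `P_i` sum to 1 and nothing moves. All dynamics is driven by
episodic, whole-population collapses — the picture relevant to, e.g.,
bacterial strains decimated by lytic phages while the community as a whole
remains at nutrient saturation. Formally each population obeys a logistic
competition `dP_i/dt = Ω_i P_i (1 − Σ_j P_j) − η_i(t) P_i`, where `η_i(t)`
is zero for survivors and large for the species collapsing at time `t`.

Because repopulation of freed-up resources is fast compared to the interval
between collapses, the continuous dynamics is replaced by a discrete
event scheme; **one collapse = one time step** throughout the package:

1. a victim is selected (uniformly in the basic model — extinction risk
   independent of abundance);
2. the victim's population is removed and a brand-new species is seeded in
   its slot at a small fraction `gamma` of the carrying capacity (the
   fixed-`N` bookkeeping: richness never changes, species identities do);
3. all populations, the newcomer included, are multiplied by the common
   factor `1/Σ P_i` that restores `Σ P_i = 1` exactly — the instantaneous
   equivalent of the shared logistic regrowth.

The newcomer is inserted *before* the rescale and participates in it. This
ordering is what places the pre-rescale ("green") snapshot populations
between `gamma` and `gamma·N` and the post-rescale ("red") ones between
`~N·gamma` and 1 after a dominant collapse, which is how the bimodal
time-aggregated abundance distribution arises. The victim is chosen before
the newcomer exists, so a newcomer can never be the victim of its own birth
step.

The emergent behaviour is cyclic **diversity waves**: random extinctions
thin the community until a single species dominates (`P_max > 1 − 1/N`);
its eventual collapse frees almost the whole capacity, the survivors and
recent newcomers are boosted by the large factor `1/(1 − P_max)`, diversity
jumps up abruptly, and the cycle restarts. Waves last about `N·ln N` steps
— the time for `N` species to be eliminated one-by-one at rate `1/N`.

## Variants

Seven published variants are layered on the same stepper
(`make_variant()` composes the policy):

* **neutral_drift** — between consecutive collapses each population takes
  one drift step `P_i → P_i ± r·P_i(1−P_i)` with independent equiprobable
  signs, then the community is renormalised. The printed drift rule is
  linear in `P(1−P)`; classical demographic noise would scale as its
  square root. Both are implemented behind `drift_law`; the default is the
  printed linear rule, because that is the stated update, and the square
  root is available for users who want the classical scaling.
* **exp_fluct** — multiplicative fluctuations `P_i → P_i(1 ± n·Ω_i)`,
  renormalised. The basic variant defines no per-species rates, so
  `Ω_i = 1` unless the state carries trait vectors. We renormalise after
  *every* update (not only when `ΣP > 1`): the model lives in the
  saturated steady state, and a one-sided rule would let the total drift
  persistently below capacity, which contradicts saturation. A downward
  fluctuation can make a victim smaller than `gamma`; its replacement then
  pushes the total slightly above 1 and the rescale *contracts* — exactly
  what the logistic term does when `1 − ΣP < 0`. `saturate()` permits this
  only for the fluctuation variants (`allow_excess`), and still rejects
  over-capacity states elsewhere.
* **interconnected** — spatially separated sub-populations of one species
  coupled by slow diffusion: a collapsed local population is re-seeded by
  an influx `gamma` from the other environments. The update rule coincides
  with the basic model, so it is an interface alias, documented rather
  than duplicated.
* **ktw / ktl** — Kill-the-Winner / Kill-the-Loser: victim weights
  `∝ P_i^σ` with `σ > 0` (phages preying on abundant strains; published
  values 0.01, 0.2, 1) or `σ = −0.2` (company-volatility scaling). KtL
  weights are finite because populations never fall below `gamma > 0`.
* **fitness** — per-species growth rate `Ω_i` and collapse weight `c_i`,
  both log-uniform on `[0.1, 1]`. Saturation with heterogeneous rates is
  the exact logistic endpoint: `P_i → P_i e^{Ω_i A}` with the scalar
  `A ≥ 0` solving `Σ P_i e^{Ω_i A} = 1`. Whether a replacement species
  inherits the victim's traits or draws fresh ones is not specified by the
  variant description; we default to fresh draws
  (`resample_on_replace = TRUE`, configurable), since a *new* species has
  no mechanistic reason to inherit its predecessor's phenotype.
* **resilience** — collapses are not extinctions: the victim shrinks to
  `γ_i P_i` with a per-species survivor ratio `γ_i` log-uniform on
  `[1e-9, 1e-2]`, plus per-species `Ω_i`. Species identities are permanent
  in this variant.

## Numerical choices

* **Exact saturation, no ODE error.** The per-species growth scalar `A` is
  bracketed by `[0, ln(1/ΣP)/min Ω_i]` (the excess `Σ P_i e^{Ω_i A} − 1`
  is monotone in `A`) and solved by safeguarded Newton/bisection to
  relative tolerance 1e-12, with an overflow guard for deep brackets.
* **Renormalisation every step.** The total is recomputed from scratch
  each step and divided out, so floating-point drift never accumulates;
  the saturation invariant `|ΣP − 1| ≤ 1e-9` is asserted per-step in the
  tests.
* **Reference equality.** The compiled stepper accumulates sums in long
  double, matching base R's `sum()`/`cumsum()`, so the pure-R reference
  stepper (`engine = "r"`) produces *bit-identical* trajectories for every
  variant under the same seed. The RNG consumption order is fixed and
  documented: (1) drift/fluctuation sign draws, slot order; (2) one
  uniform for victim selection; (3) trait resampling draws. Victim
  selection consumes exactly one uniform: `floor(u·N)` for the uniform
  policy, first cumulative weight exceeding `u·Σw` for weighted policies —
  the two rules coincide exactly for equal weights, making the
  `σ = 0 ≡ uniform` and equal-trait degeneracies exact, not approximate.
* **Log-binned histograms.** Default 5 bins per decade over
  `[gamma/10, 1]` (the resilience variant extends the support below
  `min γ_i` because repeated shrinkage can stack). Out-of-support values
  are clamped into edge bins so the conservation invariant
  `Σ counts = snapshots × N` always holds. Tail fits are stable to ±0.02
  under 3 vs 10 bins per decade (tested).
* **Burn-in.** The uniform initial condition is not the steady state;
  aggregated recorders discard `min(10·N, n_steps/2)` initial steps.
  Per-step recorders (events, diversity) keep everything so transients
  remain inspectable.

## Estimators

**Tail exponent.** `fit_powerlaw_tail()` reports `τ` of
`dProb(P_i > P)/dP ∝ P^{−τ}`; on the log-binned density the slope is
`−(τ−1)`. The default window `[1/N, 1]` is the scaling window between the
upper peak and the capacity. A truncated-Pareto maximum-likelihood
estimator on raw samples is provided as an independent cross-check; the
two agree within 0.1 on synthetic samples of 1e5+ (tested, including
recovery of `τ = 2.00 ± 0.05` and `τ = 1.7 ± 0.05` from known-exponent
samples).

**Wave segmentation.** A boundary is a collapse with pre-collapse size
above `1 − 1/N` (configurable: small-`N` waves are visually rather than
threshold defined). Durations are differences of boundary steps.

**Diversity decay.** Within each wave, `ln D(t)` is fitted by least
squares over the wave interior, trimming 5% at each end (configurable)
to avoid boundary transients; the median of `1/|slope|` across waves is
reported.

**Inter-peak slope.** Between the two modes of the bimodal distribution
the density passes through a minimum. A fit spanning that dip would mix
the lower peak's falling flank with the rising connector and average two
opposite slopes away, so `interpeak_slope()` locates the two modes *and*
the dip, and fits only the rising connector from the dip to the upper
peak (trimming 2 bins at each end against curvature). It reports the dip
and both peak locations so the window is auditable.

**Survivor curve.** Incumbents of a wave (species born at or before the
boundary) are hit at rate exactly `1/N` under uniform selection, so
`N_surv(t) = N e^{−t/N}`; the pooled curve's fitted rate is within 10% of
`1/N` (tested), which also validates the decay-constant estimator.

## What the package reproduces, and where the idealised laws bend

The package's own experiments (`reproduce_headline()`, the acceptance
tests) reproduce at desk scale — 3 pooled seeds × 1e6 collapses against
the published 2e7:

* the universal tail exponent: `τ ≈ 1.63–1.65` for `N = 1000` and
  `gamma` from 1e-9 down to 1e-12 (the `1.7 ± 0.1` band);
* the history-free limit: equalizing all abundances to `1/N` at wave
  starts gives `τ ≈ 1.98` (the closed-form `τ = 2`);
* wave durations within ~10% of `N ln N` at `N = 100` and `N = 1000`;
* KtW flatness: with `σ = 1` the species counts per decade are equal to
  within `|slope| < 0.02` across three decades below the
  winner-suppression cutoff at `~1/N`;
* KtL robustness, the trait-fitness monotonicity (mean population
  increasing in both `Ω_i` and `γ_i`, Spearman p < 0.01), and the
  snapshot-phase structure of the green/red distributions.

Three idealised quantitative laws hold exactly only in the equalized-start
(history-free) limit and bend in the full model; the package measures and
reports the faithful values rather than the idealised ones:

* **Diversity decay `∝ exp(−t/N)`.** In the equalized model
  `D = N_surv(t)` and the measured median decay constant is ~1020 at
  `N = 1000`. In the full model wave-start diversity is far below `N`
  (median `D₀ ≈ 0.02·N` at `gamma = 1e-12`, because the redistributed
  populations are broadly distributed, not near-equal), the effective
  e-folding constant is ~1.3–1.8·N, and the late-wave monodominant
  plateau (`D ≈ 1` while the dominant waits to be hit) inflates the
  interior fit further, to ~1800–2500.
* **Jump growth `−ln(1−P_collapsed) ≃ e^{t/N}/N`.** Exact in the
  equalized model (measured rate `1/109–1/113` at `N = 100`, absolute
  level within 1%); in the full model the growth is still exponential but
  with the same slowed effective rate as the diversity decay.
* **Inter-peak slope `= τ − 1`.** The magnitude symmetry holds
  approximately for the lower peak's falling flank (−0.76 at
  `gamma = 1e-12`, pooled 2e7 steps) and the tail (−0.62 to −0.67), but
  the rising connector converges to ~0.4, and single desk-scale runs
  scatter widely (~0.2–0.6) because the connector is populated by rare
  large-boost waves.

## What the synthetic data does and does not emulate

All inputs are generated by the simulator itself; there is no external
data. The model deliberately omits pairwise species interactions, neutral
drift between collapses (available as a variant), mechanistic
phage–bacteria coupling, spatially explicit environments, and any
correlation between growth rate and collapse risk — in real communities
fast growth and fragility are usually coupled through trade-offs. Passing
tests therefore demonstrate the internal consistency of the collapse-
redistribution mechanism and its estimators, not agreement with any
empirical abundance data set.

## Problem sizes

Aggregated-distribution experiments pool 3 independent seeds of 1e6
collapse steps each at `N = 1000` (the published aggregations used 2e7
collapses; the tail window `[1/N, 1]` is well populated at a tenth of
that). Wave-level experiments use single runs of 2.5e5–4e5 steps, giving
30–50 complete waves. Property checks use `N = 10–200` and 1e3–2e5 steps.
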