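# methanokin

Kinetic analysis of closed-batch gas fermentation by hydrogenotrophic
methanogens.

## The problem

Hydrogenotrophic methanogens convert H₂ and CO₂ to methane:

    4 H₂ + CO₂ → CH₄ + 2 H₂O

Grown in a sealed vessel ("closed batch") on a pressurized 4:1 H₂:CO₂
headspace, every mole of CH₄ formed removes a net four moles of gas (the
product water condenses into the medium), so the headspace pressure decay is
a quantitative, online record of methanogenesis. `methanokin` turns logged
pressure traces into the standard kinetic read-outs used to screen and rank
CH₄-producing strains:

- **MER** — methane evolution rate, MER(t) = −(dp/dt)·V_gas/(4·R·T·V_liquid),
  in mmol L⁻¹ h⁻¹; with **MER_max** (peak), **MER_global** (mean over the
  active conversion window) and **MER_total** (whole-run mean). The
  stoichiometric companions are CUR = MER (CO₂ uptake) and HUR = 4·MER
  (H₂ uptake).
- **Turnover** — the fraction of supplied substrate converted. For the 4:1
  feed, complete conversion leaves exactly one-fifth of the initial
  pressure (2 bar from 10 bar, 10 bar from 50 bar), so
  X = (p₀ − p)/(0.8·p₀).
- **k_min** — the most negative pressure slope (bar h⁻¹), marking the moment
  of fastest conversion.
- **Biomass increase rate** — a growth-homogeneity index from OD₅₇₈ series,
  the per-interval average of OD_max·μᵢ/(ODᵢ·μ_average).

It also handles **repetitive closed batch (RCB)** operation — successive
conversion cycles created by venting and repressurizing the same culture —
by segmenting multi-cycle logs at repressurization jumps and evaluating each
cycle, including the one-fifth full-conversion verdict.

Two companion stages support strain screening campaigns: a multivariate
module (regularized iterative-PCA imputation of missing entries,
standardized PCA, k-means on the first two components, between-SS/total-SS
quality) and an MCR motif scanner that reports, for every sequence in an
MCRα protein alignment, the residues at reference positions 444–446 — the
Tyr⁴⁴⁴-Gly⁴⁴⁵-Tyr⁴⁴⁶ motif associated with high-performance (Class I)
methanogens, and its Y→F variants.

A built-in simulator (gas-limited Monod growth integrated with fixed-step
RK4, seeded sensor noise, RCB repressurization scheduling) generates
pressure/OD traces, screening matrices and alignments with known ground
truth, so the whole pipeline is testable without experimental data.

## Worked example

Simulate a 4-cycle RCB run at 10 bar (160-mL vessel, 60 mL medium, 65 °C),
segment it, and evaluate every cycle:

```r
library(methanokin)

params <- SimParams(seed = 42)            # 10 bar, 4:1 H2:CO2, 5-min logging
sim    <- simulateRCB(params, nCycles = 4, duration = 120)
cycles <- evaluateCycles(segmentCycles(sim$pressure))
cycles[, c("cycle", "p0", "mer_max", "mer_global", "k_min",
           "turnover_max_pct", "time_to_full_conversion", "full_conversion")]
```

```
  cycle    p0 mer_max mer_global  k_min turnover_max_pct time_to_full_conversion full_conversion
1  RCB1 10.03    6.98       2.74 -0.542            100.0                    42.7            TRUE
2  RCB2  9.98   15.06      12.15 -1.033             99.9                    52.9            TRUE
3  RCB3  9.99   23.99      19.41 -1.680             99.8                    58.9            TRUE
4  RCB4  9.90   32.81       1.92 -2.291            100.0                    63.5            TRUE
```

Each row is one conversion cycle: `mer_max` is the peak volumetric CH₄
production rate (mmol L⁻¹ h⁻¹), `k_min` the steepest pressure drop
(bar h⁻¹), and `full_conversion` confirms the cycle reached the one-fifth
residual. Biomass carried across cycles makes successive cycles faster —
the peak rate climbs from 7.0 to 32.8 mmol L⁻¹ h⁻¹ while the conversion
time per cycle shrinks (the `time_to_full_conversion` column is cumulative
run time). The deflated `mer_global` of RCB4 is an instructive artifact:
that cycle converts in under five hours and then idles for two days, and
occasional sensor-noise excursions above the 0.1 mmol L⁻¹ h⁻¹ activity
threshold stretch its integration window into the idle tail — raise
`threshold` (or shorten the run) when cycles finish long before the log
ends.

Growth statistics from an OD₅₇₈ series:

```r
g <- growthStats(ODSeries(c(0, 12, 24, 36, 48), c(0.02, 0.05, 0.21, 0.48, 0.50)))
sprintf("mu_max = %.3f /h, OD_max = %.2f, biomass increase rate = %.1f",
        g@muMax, g@odMax, g@biomassIncreaseRate)
#> mu_max = 0.120 /h, OD_max = 0.50, biomass increase rate = 12.2
```

A command-line front end over the same functions lives in
`inst/cli/methanokin.R` (subcommands `simulate`, `kinetics`, `rcb`,
`screen`, `motif`).

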