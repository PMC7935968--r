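---
title: "Closed-batch methanogenesis kinetics: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-batch methanogenesis kinetics: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methanokin)
```

# The measurement model

Hydrogenotrophic methanogenesis, 4 H₂ + CO₂ → CH₄ + 2 H₂O, shrinks the gas
phase: five moles of substrate gas become one mole of CH₄, and the product
water condenses into the medium at cultivation temperatures, so each mole
of CH₄ removes a net four moles of headspace gas. In a sealed vessel of
fixed headspace volume $V_g$ at temperature $T$, the ideal gas law converts
a logged pressure $p(t)$ into total gas moles $n = pV_g/RT$, and the
methane evolution rate per litre of liquid follows directly:

$$\mathrm{MER}(t) = -\frac{dp}{dt}\cdot\frac{V_g}{4\,R\,T\,V_l}$$

with CUR = MER and HUR = 4·MER fixed by stoichiometry. For the standard
4:1 H₂:CO₂ feed, the limiting-reagent balance says complete conversion
leaves exactly one fifth of the initial pressure; the substrate turnover at
pressure $p$ is therefore $X = (p_0 - p)/(0.8\,p_0)$, clipped to $[0,1]$
against sensor noise. Non-stoichiometric feeds are handled by the general
species balance (the H₂-poor branch limits on H₂/4, the H₂-rich branch on
CO₂).

Assumptions worth stating:

* **Ideal gas everywhere.** At 50 bar the H₂-rich mixture's
  compressibility factor is ≈ 1.02; we document rather than model it.
* **Pressure convention.** Screening reports conventionally apply the
  one-fifth rule to *relative* (gauge) readings; the default
  `paper_gauge` convention uses logged values as-is. An
  `absolute_corrected` mode (+1.013 bar) exists for physically exact mole
  bookkeeping. The two differ by a constant offset that cancels in
  pressure *drops* but not in absolute mole counts.
* **Water vapour neglected.** At 80–98 °C cultivation the vapour partial
  pressure is non-trivial, but the conventional arithmetic ignores it and
  so does the default here.
* **Biomass and dissolved-gas carbon sinks neglected** in MER, as is
  standard for headspace balances.
* **Temperatures.** Online reactor traces are converted at the incubation
  temperature; end-point serum-bottle/GC measurements at the measurement
  temperature (default 298.15 K, vessels equilibrated to room temperature).

# The analysis chain and its tunables

`summarizeKinetics()` runs: resample → differentiate → smooth → window →
integrate.

| parameter | default | units | why |
|---|---|---|---|
| `interval` | 0.5 | h | analysis grid; 5-min raw logs are differentiated on a 30-min grid so finite differences are not noise-dominated |
| `window` | 5 | points | centred moving average on the rate curve; shrinks at edges, preserves length |
| `threshold` | 0.1 | mmol L⁻¹ h⁻¹ | horizontal cut defining the active window; `xStart`/`xEnd` are the first/last threshold crossings, located by linear interpolation |
| `fullConversionTol` | 0.02 | relative | slack on the one-fifth residual when declaring full conversion |
| `noiseTol` | 0.3 | bar | largest sample-to-sample rise attributed to sensor noise; larger rises abort single-segment analysis and point to RCB segmentation |

Derivatives are central differences (one-sided at the ends); the estimator
is deliberately simple and configurable rather than model-based.
`MER_global` divides the trapezoid integral of the smoothed rate over
`[xStart, xEnd]` by Δt; `MER_total` averages over the whole record.
`turnover_max` is computed from raw pressure extrema on purpose — it is a
state quantity, not a rate, and must not depend on smoothing. Extremum
ties break to the earliest timestamp. The maximum turnover *rate* is
reported as max d(turnover %)/dt with the percentage treated as
dimensionless; its product with the time to full conversion is ≈ 100 by
construction, which reproduces the customary magnitude of "turnover rate"
values (a few per hour for two-day conversions).

Two readings of the activity threshold were possible ("shifting the x-axis
to low points of the curve" conflates axes); we implement a horizontal cut
on the smoothed rate at 0.1 and expose it as a parameter. Likewise the
biomass increase rate OD_max·μ/(OD·μ_average) does not pin down how OD and
μ are paired; the default pairs them per log-linear interval and averages
(`mode = "interval"`), a single-point variant evaluated at the fastest
interval is available (`mode = "single"`). With two OD points both
collapse to OD_max/OD₁.

A trace whose smoothed rate never crosses the threshold is *flagged*
(`noGrowth`), not errored, so screening runs report non-growers (a real
outcome at 50 bar for pressure-sensitive strains) alongside performers.

# RCB segmentation

Repetitive closed batch runs vent and repressurize the same culture, so
the log is a sawtooth. A new cycle starts wherever pressure rises by more
than `jumpFraction` (default 0.2) of the trace maximum between consecutive
samples — a relative rule that works unchanged from 2 to 50 bar. Runs of
consecutive jump samples (multi-sample repressurization ramps) open a
single segment. Each cycle is summarized independently; the
full-conversion verdict compares the cycle's minimum pressure against
p₀/5·(1 + 0.02). The tolerance is our choice; no standard value exists for
declaring "total gas conversion" before re-pressurizing.

# The simulator

The generator integrates gas-limited Monod growth in the closed headspace:

$$\frac{d\xi}{dt} = \begin{cases} 0 & t < t_{lag} \\ q_{max} X V_l
\dfrac{p_{H_2}}{K_p + p_{H_2}} & t \ge t_{lag}\end{cases} \qquad
\frac{dX}{dt} = Y_x \frac{d\xi/dt}{V_l}$$

with $p_{H_2}$ from the species balance and gas law, and ξ clipped at the
CO₂-limited maximum. The Monod dependence is on the H₂ *partial pressure*
rather than the dissolved concentration — this keeps the model closed
without a gas–liquid mass-transfer (k~L~a) submodel and is the main
deliberate simplification. Defaults emulate a pressurized 160-mL stirred
reactor with 60 mL medium at 65 °C and 10 bar of 4:1 feed, logged every
5 min: q_max = 60 mmol g⁻¹ h⁻¹, K_p = 0.5 bar, X₀ = 0.01 g L⁻¹,
Y_x = 1.5 g CDW per mol CH₄, t_lag = 5 h, σ_noise = 0.02 bar,
OD/CDW = 2.5 L g⁻¹. These give conversion times of ~40 h and peak rates of
~7 mmol L⁻¹ h⁻¹ in the first cycle — the magnitudes typical of competent
thermophilic methanogens at 10 bar.

Numerics: fixed-step RK4 at dt = 0.01 h, chosen over an adaptive solver
for bit-reproducibility across platforms; a Richardson full-step versus
two-half-steps comparison is sampled every 20th step and aborts if the
local error exceeds 10⁻⁶ bar (the check skips the two intentional
discontinuities — the lag switch and the stoichiometric clip). The logger
samples the nearest solver state rather than interpolating, so
repressurization jumps occupy exactly one logging interval. Before each
flush the converged residual pressure is held for one logging interval
(gas release is not instantaneous), which guarantees the recorded trace
contains the sub-residual reading the full-conversion verdict needs; the
operator trigger (1% above residual) is deliberately tighter than the
analysis verdict (2%). Carried-over biomass is active immediately, so
cycles after the first skip the lag phase and successive cycles convert
faster — the adaptation signature seen in real RCB campaigns.

What the simulator does *not* emulate: thermodynamic limitation near
equilibrium, product inhibition, pH/carbonate dynamics, gas–liquid
transfer limitation, drift or autocorrelated sensor error. Passing
recovery tests on these traces therefore demonstrates the *analysis
machinery* (differentiation, smoothing, windowing, segmentation) under
known kinetics and i.i.d. Gaussian noise — not robustness to every failure
mode of real logs.

One visible interaction deserves a note: with σ_noise = 0.02 bar, the
smoothed-rate noise floor is of the same order as the 0.1 mmol L⁻¹ h⁻¹
activity threshold, so a cycle that converts quickly and then idles for
tens of hours can have its active window stretched by noise excursions,
deflating `mer_global`. Raising the threshold or trimming idle tails
resolves it; we left the defaults alone because the effect is itself
instructive.

# Screening stage

Missing entries are imputed by iterative PCA: initialize with column
means, alternate a rank-2 reconstruction with re-substitution into the
missing cells, stop when the imputed cells move less than 10⁻⁹ RMS. The
reconstruction is *regularized* by default — singular values are shrunk by
the residual variance estimated from trailing components. On exactly
low-rank matrices the shrinkage vanishes and imputation is exact (tested
to < 10⁻⁴); on noisy matrices it prevents the fixed point from chasing
noise directions, where the plain iteration converges geometrically with
ratio ≈ 1 and would otherwise stall against any practical iteration cap.
Observed cells are never modified.

PCA is a plain SVD of the column-centred, standardized matrix with a
deterministic sign convention (dominant loading positive per component).
k-means runs on PC1–PC2 with 25 seeded restarts (Lloyd via `stats::kmeans`,
best within-SS kept) and reports between-SS/total-SS as a percentage; k
defaults to 4, matching the customary cluster numbering of such screens,
but is configurable since no canonical k exists. The degenerate boundary
k = number of distinct points is handled directly (within-SS = 0). Cluster
summaries are per-cluster medians plus metadata composition — tidy tables
rather than biplots.

# Motif scan

Residue numbering follows the ungapped coordinates of a designated
reference sequence (canonically the MCR I alpha subunit of
*Methanothermobacter marburgensis*): the k-th non-gap reference character
defines residue k, and every sequence is read at the alignment columns
mapped by residues 444–446. Classes are the motif itself (YGY), the
single substitutions FGY (Y444F, the Class II signature) and YGF (Y446F,
typical of Methanosarcinaceae), FGF, and `other/gapped` for anything else
— gaps, ambiguity codes (X), or non-canonical residues. Comparison is
case-insensitive. For sequences with long indels relative to the
reference, only the reference-mapped columns are reported; no attempt is
made to renumber such sequences in their own coordinates.

# Problem sizes used in the checks

The recovery suites run 20 seeded closed-batch traces per noise level
(σ = 0 and 0.05 bar, 80 h at 5-min logging), ten 4-cycle RCB traces for
segmentation, 60 × 6 screening matrices with 10% missingness, 40 × 8
rank-2 imputation fixtures, and 25–30-sequence alignments of length ~520
with 30 inserted gap columns. These sizes were chosen as the smallest at
which the asserted tolerances are meaningful statements about the method
rather than about luck; all fixtures are generated in code from fixed
seeds.

# Known limitations

* No compressibility or vapour-pressure corrections by default (documented
  switches or conventions cover the exact cases).
* The MER estimator is finite-difference + moving average; traces with
  strongly non-uniform sampling should be resampled with care, and rates
  near record boundaries use one-sided differences.
* `k_min`'s timestamp is noise-dominated at realistic sensor noise; it
  coincides with the MER peak only on clean traces (asserted noise-free).
* The screening stage reproduces machinery, not published memberships: the
  original screening matrix behind such analyses is typically not
  deposited, so only generative ground truth is testable.
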