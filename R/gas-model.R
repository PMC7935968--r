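## Stoichiometric and ideal-gas bookkeeping for 4 H2 + CO2 -> CH4 + 2 H2O in
## a fixed headspace. Product water is assumed to condense into the medium,
## so each mole of CH4 formed removes a net 4 moles of gas (5 in, 1 out).

.effectivePressure <- function(p, vessel) {
    p <- p + if (vessel@pressureConvention == "absolute_corrected") .ATM_BAR else 0
    if (any(p < 0))
        stop(sprintf(
            "negative pressure after applying the '%s' convention",
            vessel@pressureConvention))
    p
}

#' Moles of headspace gas from a pressure reading
#'
#' Ideal-gas conversion n = P V_gas / (R T). Under the default
#' `"paper_gauge"` convention the logged value is used as-is (this is how
#' gauge-pressure screening data are conventionally analysed); under
#' `"absolute_corrected"` 1.013 bar is added first.
#'
#' @param p pressure in bar (vectorised).
#' @param vessel a [VesselSpec-class]; supplies headspace volume and the
#'   pressure convention.
#' @param temperature temperature in K; defaults to the vessel's incubation
#'   temperature.
#' @return Amount of gas in mol.
#' @examples
#' v <- VesselSpec(vTotal = 0.12, vLiquid = 0.05)
#' molesFromPressure(1, v, temperature = 298.15)   # ~2.82e-3 mol
#' @export
molesFromPressure <- function(p, vessel, temperature = vessel@tIncubation) {
    stopifnot(temperature > 0)
    pEff <- .effectivePressure(p, vessel)
    pEff * .BAR_PA * (vGas(vessel) / 1000) / (.R_GAS * temperature)
}

#' Pressure from an amount of headspace gas
#'
#' Inverse of [molesFromPressure()] (same convention handling, so the two
#' round-trip exactly).
#'
#' @param n amount of gas in mol.
#' @inheritParams molesFromPressure
#' @return Pressure in bar, on the vessel's convention.
#' @export
pressureFromMoles <- function(n, vessel, temperature = vessel@tIncubation) {
    stopifnot(temperature > 0, all(n >= 0))
    pAbs <- n * .R_GAS * temperature / (vGas(vessel) / 1000) / .BAR_PA
    pAbs - if (vessel@pressureConvention == "absolute_corrected") .ATM_BAR else 0
}

#' Reaction extent from a pressure drop
#'
#' Converts a headspace pressure drop into moles of CH4 formed. The net gas
#' consumption is 4 mol per mol CH4 (4 H2 + 1 CO2 consumed, 1 CH4 formed,
#' water condensed), so xi = (n(p0) - n(p)) / 4.
#'
#' @param p0 initial pressure, bar.
#' @param p current pressure, bar; must not exceed `p0` beyond `tol`.
#' @inheritParams molesFromPressure
#' @param tol noise tolerance in bar for small apparent pressure rises.
#' @return Moles of CH4 formed.
#' @export
extentFromPressureDrop <- function(p0, p, vessel,
                                   temperature = vessel@tIncubation,
                                   tol = 1e-6) {
    if (any(p > p0 + tol))
        stop("pressure increase inside a conversion segment; ",
             "use segmentCycles() for repressurized (RCB) traces")
    pmax(0, (molesFromPressure(p0, vessel, temperature) -
             molesFromPressure(p, vessel, temperature)) / 4)
}

## Stoichiometric extent at exhaustion of the limiting reagent, as a
## fraction of the initial total moles.
.xiMaxFraction <- function(composition) {
    min(composition@xH2 / 4, composition@xCO2)
}

#' Substrate turnover from pressures
#'
#' Fraction of the initially supplied headspace substrate that has been
#' converted, from the species mole balance. For the standard 4:1 H2:CO2
#' mixture this reduces to (p0 - p) / (0.8 p0): the pressure drop at full
#' conversion is four-fifths of the initial pressure. Results are clipped to
#' \[0, 1\] so sensor noise cannot produce impossible fractions.
#'
#' @param p0 initial pressure, bar, > 0.
#' @param p current pressure(s), bar.
#' @param composition initial [GasComposition-class].
#' @return Turnover fraction(s) in \[0, 1\].
#' @examples
#' turnoverFraction(10, 6)   # 0.5
#' turnoverFraction(10, 2)   # 1: full conversion leaves one-fifth of p0
#' @export
turnoverFraction <- function(p0, p, composition = GasComposition()) {
    if (!is.finite(p0) || p0 <= 0)
        stop("turnover is undefined for p0 <= 0")
    dropFracMax <- 4 * .xiMaxFraction(composition)
    if (dropFracMax <= 0)
        stop("composition contains no convertible H2/CO2 substrate")
    pmin(1, pmax(0, (p0 - p) / (dropFracMax * p0)))
}

#' Residual pressure at full conversion
#'
#' Headspace pressure left after complete conversion of the limiting
#' substrate, with product water condensed. For a stoichiometric 4:1
#' H2:CO2 mixture this is exactly one-fifth of the initial pressure
#' (2 bar from 10 bar, 10 bar from 50 bar); other mixtures follow
#' limiting-reagent logic on the species balance.
#'
#' @param p0 initial pressure, bar.
#' @param composition initial [GasComposition-class].
#' @return Residual pressure in bar, on the same convention as `p0`.
#' @examples
#' residualPressureFullConversion(10)  # 2
#' residualPressureFullConversion(50)  # 10
#' @export
residualPressureFullConversion <- function(p0, composition = GasComposition()) {
    p0 * (1 - 4 * .xiMaxFraction(composition))
}

#' Dissolved-H2 availability ratio between two pressures
#'
#' Henry's-law proportionality: at equal temperature and composition the
#' equilibrium dissolved H2 concentration scales with its partial pressure,
#' so cultivation at `pA` offers `pA / pB` times the dissolved substrate of
#' cultivation at `pB` (e.g. 5x for 10 vs 2 bar, 25x for 50 vs 2 bar).
#'
#' @param pA,pB total pressures in bar; `pB` must be positive.
#' @return The fold-increase `pA / pB`.
#' @export
dissolvedH2Ratio <- function(pA, pB) {
    if (any(pB <= 0)) stop("reference pressure pB must be positive")
    pA / pB
}

## Species table at reaction extent xi (mol CH4 formed) starting from n0
## total moles of `composition`. Used by tests as an elemental-balance
## oracle and by the simulator for partial pressures.
.speciesTable <- function(n0, xi, composition) {
    data.frame(
        H2  = n0 * composition@xH2 - 4 * xi,
        CO2 = n0 * composition@xCO2 - xi,
        CH4 = n0 * composition@xCH4 + xi,
        H2O = 2 * xi,
        other = n0 * composition@xOther)
}
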