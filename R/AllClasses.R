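#' @import methods
NULL

## Physical constants used throughout: ideal-gas R in J mol^-1 K^-1 and the
## bar -> Pa conversion. Volumes are litres, pressures bar, times hours.
.R_GAS <- 8.314
.BAR_PA <- 1e5
.ATM_BAR <- 1.013

#' Headspace gas composition
#'
#' Mole fractions of the four species tracked in the headspace of a sealed
#' cultivation vessel. The default is the standard methanogen feed gas,
#' 80 vol-% H2 and 20 vol-% CO2 (a 4:1 H2:CO2 mixture matching the
#' stoichiometry of hydrogenotrophic methanogenesis,
#' 4 H2 + CO2 -> CH4 + 2 H2O).
#'
#' @slot xH2 numeric(1), mole fraction of H2.
#' @slot xCO2 numeric(1), mole fraction of CO2.
#' @slot xCH4 numeric(1), mole fraction of CH4.
#' @slot xOther numeric(1), mole fraction of inert/other gas.
#'
#' @examples
#' GasComposition()              # 4:1 H2:CO2
#' GasComposition(xH2 = 0.75, xCO2 = 0.25)
#' @export
setClass("GasComposition",
    representation(xH2 = "numeric", xCO2 = "numeric",
                   xCH4 = "numeric", xOther = "numeric"),
    prototype(xH2 = 0.8, xCO2 = 0.2, xCH4 = 0, xOther = 0))

setValidity("GasComposition", function(object) {
    x <- c(object@xH2, object@xCO2, object@xCH4, object@xOther)
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
        return("all mole fractions must be finite and in [0, 1]")
    if (abs(sum(x) - 1) > 1e-9)
        return(sprintf("mole fractions must sum to 1 (got %.12g)", sum(x)))
    TRUE
})

#' Constructor for GasComposition
#'
#' @param xH2,xCO2,xCH4,xOther mole fractions; must sum to 1.
#' @return A [GasComposition-class] object.
#' @export
GasComposition <- function(xH2 = 0.8, xCO2 = 0.2, xCH4 = 0, xOther = 0) {
    new("GasComposition", xH2 = xH2, xCO2 = xCO2, xCH4 = xCH4,
        xOther = xOther)
}

#' Cultivation vessel geometry and temperatures
#'
#' Geometry and thermal state needed to convert a headspace pressure into an
#' amount of gas. `pressureConvention` selects how logged pressures are
#' interpreted: `"paper_gauge"` uses the recorded (relative/gauge) value
#' as-is, which is how screening results are conventionally reported;
#' `"absolute_corrected"` adds 1.013 bar for physically exact mole
#' bookkeeping.
#'
#' @slot vTotal numeric(1), total vessel volume in L.
#' @slot vLiquid numeric(1), liquid (medium) volume in L.
#' @slot tIncubation numeric(1), incubation temperature in K.
#' @slot tMeasurement numeric(1), temperature at which point measurements
#'   (serum-bottle manometry, GC sampling) are taken, in K.
#' @slot pressureConvention character(1), `"paper_gauge"` or
#'   `"absolute_corrected"`.
#'
#' @examples
#' # 120-mL serum bottle with 50 mL medium
#' serumBottle <- VesselSpec(vTotal = 0.12, vLiquid = 0.05)
#' # 160-mL stirred bioreactor with 60 mL medium at 65 degrees C
#' sbrs <- VesselSpec(vTotal = 0.16, vLiquid = 0.06, tIncubation = 338.15)
#' vGas(sbrs)
#' @export
setClass("VesselSpec",
    representation(vTotal = "numeric", vLiquid = "numeric",
                   tIncubation = "numeric", tMeasurement = "numeric",
                   pressureConvention = "character"),
    prototype(vTotal = 0.12, vLiquid = 0.05, tIncubation = 310.15,
              tMeasurement = 298.15, pressureConvention = "paper_gauge"))

setValidity("VesselSpec", function(object) {
    if (!(object@vLiquid > 0 && object@vLiquid < object@vTotal))
        return("need 0 < vLiquid < vTotal")
    if (object@tIncubation <= 273 || object@tMeasurement <= 273)
        return("temperatures must exceed 273 K")
    if (!object@pressureConvention %in% c("paper_gauge", "absolute_corrected"))
        return("pressureConvention must be 'paper_gauge' or 'absolute_corrected'")
    TRUE
})

#' Constructor for VesselSpec
#'
#' @param vTotal,vLiquid volumes in L.
#' @param tIncubation,tMeasurement temperatures in K.
#' @param pressureConvention `"paper_gauge"` (default) or
#'   `"absolute_corrected"`.
#' @return A [VesselSpec-class] object.
#' @export
VesselSpec <- function(vTotal = 0.12, vLiquid = 0.05, tIncubation = 310.15,
                       tMeasurement = 298.15,
                       pressureConvention = "paper_gauge") {
    new("VesselSpec", vTotal = vTotal, vLiquid = vLiquid,
        tIncubation = tIncubation, tMeasurement = tMeasurement,
        pressureConvention = pressureConvention)
}

#' Headspace gas volume of a vessel
#' @param vessel A [VesselSpec-class].
#' @return Gas volume in L.
#' @export
vGas <- function(vessel) vessel@vTotal - vessel@vLiquid

#' Logged headspace pressure trace for one vessel
#'
#' @slot vesselId character(1) vessel identifier.
#' @slot times numeric, strictly increasing, in hours.
#' @slot pressures numeric, gauge pressure in bar (per the vessel's
#'   convention).
#' @slot vessel the [VesselSpec-class] the trace was recorded in.
#' @export
setClass("PressureSeries",
    representation(vesselId = "character", times = "numeric",
                   pressures = "numeric", vessel = "VesselSpec"))

setValidity("PressureSeries", function(object) {
    n <- length(object@times)
    if (n < 2) return("a pressure series needs at least 2 points")
    if (length(object@pressures) != n)
        return("times and pressures must have equal length")
    if (anyNA(object@pressures) || anyNA(object@times))
        return("missing values are not allowed in a loaded series")
    if (any(diff(object@times) <= 0))
        return("times must be strictly increasing")
    TRUE
})

#' Constructor for PressureSeries
#' @param times hours, strictly increasing.
#' @param pressures bar.
#' @param vessel a [VesselSpec-class].
#' @param vesselId vessel identifier.
#' @return A [PressureSeries-class] object.
#' @export
PressureSeries <- function(times, pressures, vessel = VesselSpec(),
                           vesselId = "R1") {
    new("PressureSeries", vesselId = vesselId, times = as.numeric(times),
        pressures = as.numeric(pressures), vessel = vessel)
}

#' Optical density (OD578) time series
#'
#' @slot times numeric, hours.
#' @slot od numeric, absorbance at 578 nm, non-negative.
#' @export
setClass("ODSeries",
    representation(times = "numeric", od = "numeric"))

setValidity("ODSeries", function(object) {
    if (length(object@times) != length(object@od))
        return("times and od must have equal length")
    if (any(!is.finite(object@od)) || any(object@od < 0))
        return("OD values must be finite and >= 0")
    if (length(object@times) > 1 && any(diff(object@times) <= 0))
        return("times must be strictly increasing")
    TRUE
})

#' Constructor for ODSeries
#' @param times hours.
#' @param od absorbance units, >= 0.
#' @return An [ODSeries-class] object.
#' @export
ODSeries <- function(times, od) {
    new("ODSeries", times = as.numeric(times), od = as.numeric(od))
}

#' End-point GC off-gas measurement
#'
#' @slot vesselId character(1).
#' @slot yCH4 numeric(1), CH4 volume fraction in the headspace, in [0, 1].
#' @slot sampledAt numeric(1), sampling time in hours.
#' @export
setClass("GCResult",
    representation(vesselId = "character", yCH4 = "numeric",
                   sampledAt = "numeric"))

setValidity("GCResult", function(object) {
    if (object@yCH4 < 0 || object@yCH4 > 1)
        return("yCH4 must lie in [0, 1]")
    TRUE
})

#' Constructor for GCResult
#' @param yCH4 CH4 volume fraction in the headspace, in \[0, 1\].
#' @param sampledAt hours.
#' @param vesselId vessel identifier.
#' @return A [GCResult-class] object.
#' @export
GCResult <- function(yCH4, sampledAt = NA_real_, vesselId = "R1") {
    new("GCResult", vesselId = vesselId, yCH4 = yCH4, sampledAt = sampledAt)
}

#' Volumetric gas conversion rates over time
#'
#' MER is the methane evolution rate per litre of liquid. CUR and HUR follow
#' from the fixed stoichiometry of hydrogenotrophic methanogenesis:
#' one CO2 and four H2 are consumed per CH4 formed, so CUR = MER and
#' HUR = 4 MER at every time point.
#'
#' @slot times numeric, hours.
#' @slot mer numeric, mmol CH4 L^-1 h^-1.
#' @export
setClass("RateSeries",
    representation(times = "numeric", mer = "numeric"))

setValidity("RateSeries", function(object) {
    if (length(object@times) != length(object@mer))
        return("times and mer must have equal length")
    if (any(!is.finite(object@mer)))
        return("rates must be finite")
    TRUE
})

#' Carbon-dioxide uptake rate of a RateSeries
#' @param rates a [RateSeries-class].
#' @return numeric vector, mmol L^-1 h^-1 (equal to MER).
#' @export
cur <- function(rates) rates@mer

#' Hydrogen uptake rate of a RateSeries
#' @param rates a [RateSeries-class].
#' @return numeric vector, mmol L^-1 h^-1 (4 times MER).
#' @export
hur <- function(rates) 4 * rates@mer

#' Kinetic summary of one closed-batch conversion run
#'
#' @slot merMax peak smoothed MER, mmol L^-1 h^-1.
#' @slot tMerMax time of the peak, h.
#' @slot merGlobal active-window mean MER (integral over
#'   \[xStart, xEnd\] divided by deltaT), mmol L^-1 h^-1.
#' @slot merTotal whole-run mean MER, mmol L^-1 h^-1.
#' @slot kMin most negative pressure slope, bar h^-1 (signed).
#' @slot tKMin time of kMin, h.
#' @slot turnoverMax maximum substrate conversion, percent.
#' @slot turnoverRateMax peak d(turnover percent)/dt, h^-1.
#' @slot timeToFullConversion first time the trace reaches the
#'   full-conversion residual pressure, h; NA if never reached.
#' @slot xStart,xEnd active-window boundaries, h.
#' @slot deltaT xEnd - xStart, h.
#' @slot noGrowth logical flag: the smoothed MER never exceeded the active
#'   threshold.
#' @export
setClass("KineticsResult",
    representation(vesselId = "character", merMax = "numeric",
                   tMerMax = "numeric", merGlobal = "numeric",
                   merTotal = "numeric", kMin = "numeric", tKMin = "numeric",
                   turnoverMax = "numeric", turnoverRateMax = "numeric",
                   timeToFullConversion = "numeric", xStart = "numeric",
                   xEnd = "numeric", deltaT = "numeric",
                   noGrowth = "logical"))

setValidity("KineticsResult", function(object) {
    if (!object@noGrowth) {
        if (is.finite(object@merGlobal) && is.finite(object@merMax) &&
            object@merGlobal > object@merMax + 1e-9)
            return("merGlobal cannot exceed merMax")
        if (is.finite(object@xStart) && is.finite(object@xEnd) &&
            object@xStart >= object@xEnd)
            return("xStart must precede xEnd")
    }
    TRUE
})

#' Growth statistics from an OD series
#'
#' @slot muSeries per-interval specific growth rates, h^-1.
#' @slot muMax maximum interval growth rate, h^-1.
#' @slot muAverage arithmetic mean of `muSeries`, h^-1.
#' @slot odMax maximum OD observed.
#' @slot biomassIncreaseRate dimensionless homogeneity-of-growth index
#'   (NA when the culture did not grow).
#' @export
setClass("GrowthResult",
    representation(muSeries = "numeric", muMax = "numeric",
                   muAverage = "numeric", odMax = "numeric",
                   biomassIncreaseRate = "numeric"))

#' One conversion cycle of a repetitive closed batch run
#'
#' @slot index 1-based cycle index (RCB1, RCB2, ...).
#' @slot series the [PressureSeries-class] restricted to this cycle.
#' @slot p0 initial pressure of the cycle, bar.
#' @export
setClass("CycleSegment",
    representation(index = "integer", series = "PressureSeries",
                   p0 = "numeric"))

#' Strains-by-variables screening matrix
#'
#' Numeric responses (odMax, turnoverMax, merMax) and medium covariates per
#' strain-by-medium observation, with per-row metadata and possibly missing
#' entries (NA).
#'
#' @slot data numeric matrix, rows = observations, columns = variables.
#' @slot rowData data.frame of per-row metadata (taxonomy, temperature
#'   group, medium id, ...), `nrow(rowData) == nrow(data)`.
#' @export
setClass("ScreeningMatrix",
    representation(data = "matrix", rowData = "data.frame"))

setValidity("ScreeningMatrix", function(object) {
    if (!is.numeric(object@data)) return("data must be a numeric matrix")
    if (nrow(object@rowData) != nrow(object@data))
        return("rowData must have one row per observation")
    fracMissing <- colMeans(is.na(object@data))
    if (sum(fracMissing <= 0.5) < 2)
        return("need at least 2 columns with <= 50% missing entries")
    TRUE
})

#' Constructor for ScreeningMatrix
#' @param data numeric matrix (NAs mark missing entries).
#' @param rowData per-row metadata data.frame; defaults to row indices.
#' @return A [ScreeningMatrix-class] object.
#' @export
ScreeningMatrix <- function(data, rowData = NULL) {
    data <- as.matrix(data)
    if (is.null(rowData))
        rowData <- data.frame(row = seq_len(nrow(data)))
    new("ScreeningMatrix", data = data, rowData = rowData)
}

#' Clustering result of the screening stage
#'
#' @slot labels integer cluster label per row.
#' @slot centroids k-by-2 matrix of centroids on PC1-PC2.
#' @slot betweenSSPct between-cluster sum of squares as a percentage of the
#'   total sum of squares.
#' @slot pcVarFrac variance fraction per principal component; sums to 1.
#' @slot imputation list with elements `iterations` and `converged`
#'   describing the preceding missing-value imputation (empty when nothing
#'   was imputed).
#' @export
setClass("ClusterResult",
    representation(labels = "integer", centroids = "matrix",
                   betweenSSPct = "numeric", pcVarFrac = "numeric",
                   imputation = "list"))

setValidity("ClusterResult", function(object) {
    if (object@betweenSSPct < -1e-9 || object@betweenSSPct > 100 + 1e-9)
        return("betweenSSPct must lie in [0, 100]")
    if (length(object@pcVarFrac) &&
        abs(sum(object@pcVarFrac) - 1) > 1e-9)
        return("pcVarFrac must sum to 1")
    TRUE
})

## ---- show methods ---------------------------------------------------------

setMethod("show", "GasComposition", function(object) {
    cat(sprintf("GasComposition: H2 %.3f | CO2 %.3f | CH4 %.3f | other %.3f\n",
                object@xH2, object@xCO2, object@xCH4, object@xOther))
})

setMethod("show", "VesselSpec", function(object) {
    cat(sprintf(
        "VesselSpec: %.0f mL total, %.0f mL liquid (%.0f mL headspace)\n",
        1000 * object@vTotal, 1000 * object@vLiquid, 1000 * vGas(object)))
    cat(sprintf("  T(incubation) %.2f K, T(measurement) %.2f K, convention '%s'\n",
                object@tIncubation, object@tMeasurement,
                object@pressureConvention))
})

setMethod("show", "PressureSeries", function(object) {
    cat(sprintf(
        "PressureSeries '%s': %d points, %.2f-%.2f h, %.3f-%.3f bar\n",
        object@vesselId, length(object@times), min(object@times),
        max(object@times), min(object@pressures), max(object@pressures)))
})

setMethod("show", "KineticsResult", function(object) {
    if (object@noGrowth) {
        cat(sprintf("KineticsResult '%s': no active phase detected\n",
                    object@vesselId))
        return(invisible(NULL))
    }
    cat(sprintf("KineticsResult '%s':\n", object@vesselId))
    cat(sprintf("  MER_max    %8.3f mmol/L/h at %.2f h\n",
                object@merMax, object@tMerMax))
    cat(sprintf("  MER_global %8.3f mmol/L/h  (window %.2f-%.2f h)\n",
                object@merGlobal, object@xStart, object@xEnd))
    cat(sprintf("  MER_total  %8.3f mmol/L/h\n", object@merTotal))
    cat(sprintf("  k_min      %8.3f bar/h at %.2f h\n",
                object@kMin, object@tKMin))
    cat(sprintf("  turnover_max %.1f %%, max turnover rate %.2f /h\n",
                object@turnoverMax, object@turnoverRateMax))
    if (is.finite(object@timeToFullConversion))
        cat(sprintf("  full conversion reached at %.2f h\n",
                    object@timeToFullConversion))
})

setMethod("show", "ScreeningMatrix", function(object) {
    cat(sprintf("ScreeningMatrix: %d observations x %d variables (%.1f%% missing)\n",
                nrow(object@data), ncol(object@data),
                100 * mean(is.na(object@data))))
})

setMethod("show", "ClusterResult", function(object) {
    cat(sprintf("ClusterResult: k = %d, between_SS/total_SS = %.1f%%\n",
                nrow(object@centroids), object@betweenSSPct))
})
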