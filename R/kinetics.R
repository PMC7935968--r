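## Pressure-trace -> kinetics pipeline: resampling, MER/CUR/HUR, smoothing,
## k_min, active-window integration, turnover, and OD growth statistics.

## central differences, one-sided at the ends
.slope <- function(t, y) {
    n <- length(t)
    if (n < 3) stop("need at least 3 points for slope estimation")
    d <- numeric(n)
    d[1] <- (y[2] - y[1]) / (t[2] - t[1])
    d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
    i <- 2:(n - 1)
    d[i] <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
    d
}

.trapz <- function(t, y) sum(diff(t) * (y[-length(y)] + y[-1]) / 2)

#' Resample a pressure series onto a regular grid
#'
#' Linear interpolation from the first to the last timestamp. Raw logs are
#' typically recorded every 5 min; analysis is done on a coarser regular
#' grid (default 30 min) so that finite-difference rates are not dominated
#' by sensor noise.
#'
#' @param series a [PressureSeries-class].
#' @param interval grid spacing in hours, > 0 (default 0.5).
#' @return A resampled [PressureSeries-class].
#' @export
resampleSeries <- function(series, interval = 0.5) {
    if (interval <= 0) stop("resampling interval must be positive")
    t0 <- series@times[1]
    t1 <- series@times[length(series@times)]
    grid <- seq(t0, t1, by = interval)
    if (grid[length(grid)] < t1 - 1e-9) grid <- c(grid, t1)
    p <- stats::approx(series@times, series@pressures, xout = grid)$y
    PressureSeries(grid, p, vessel = series@vessel,
                   vesselId = series@vesselId)
}

#' Methane evolution rate from a pressure trace
#'
#' Differentiates the headspace pressure and converts the gas-consumption
#' rate into a volumetric methane evolution rate per litre of liquid:
#' MER(t) = -(dp/dt) V_gas / (4 R T V_liquid), since 4 moles of headspace
#' gas vanish per mole of CH4 formed. Biomass and dissolved-gas carbon
#' sinks are neglected. CUR and HUR follow via [cur()] and [hur()].
#'
#' @param series a resampled [PressureSeries-class] covering one conversion
#'   segment (no repressurization jumps).
#' @param vessel a [VesselSpec-class]; defaults to the one attached to the
#'   series. The incubation temperature is used (online traces are logged
#'   at cultivation temperature).
#' @param noiseTol largest pressure rise (bar) between consecutive samples
#'   attributed to sensor noise; larger rises abort with a pointer to RCB
#'   segmentation.
#' @return A [RateSeries-class] (mmol CH4 L^-1 h^-1).
#' @export
merFromPressure <- function(series, vessel = series@vessel, noiseTol = 0.3) {
    rises <- diff(series@pressures)
    if (any(rises > noiseTol))
        stop("pressure rise exceeds the noise tolerance inside a segment; ",
             "run segmentCycles() first for repetitive closed batch traces")
    dpdt <- .slope(series@times, series@pressures)
    molPerBar <- .BAR_PA * (vGas(vessel) / 1000) /
        (.R_GAS * vessel@tIncubation)
    mer <- -dpdt * molPerBar / 4 / vessel@vLiquid * 1000
    new("RateSeries", times = series@times, mer = mer)
}

#' Smooth a rate series with a centred moving average
#'
#' The window shrinks symmetrically at the edges, so the length is
#' preserved and a constant series is unchanged.
#'
#' @param rates a [RateSeries-class].
#' @param window odd number of points >= 1 (default 5 on the 30-min grid).
#' @return A smoothed [RateSeries-class].
#' @export
smoothSeries <- function(rates, window = 5) {
    n <- length(rates@mer)
    if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
    if (window > n) stop("smoothing window exceeds series length")
    half <- (window - 1) / 2
    sm <- vapply(seq_len(n), function(i) {
        h <- min(half, i - 1, n - i)
        mean(rates@mer[(i - h):(i + h)])
    }, numeric(1))
    new("RateSeries", times = rates@times, mer = sm)
}

#' Steepest pressure drop (k_min)
#'
#' The most negative finite-difference slope of the pressure curve and its
#' timestamp. It marks the moment of fastest gas conversion and coincides
#' with the MER peak on clean traces. Ties are broken by the earliest time.
#'
#' @param series a resampled [PressureSeries-class] (>= 3 points).
#' @return A list with `kMin` (bar h^-1, signed, <= 0 for decaying traces)
#'   and `time` (h).
#' @export
kMin <- function(series) {
    dpdt <- .slope(series@times, series@pressures)
    i <- which.min(dpdt)    # which.min returns the first (earliest) minimum
    list(kMin = dpdt[i], time = series@times[i])
}

#' Detect the active conversion window
#'
#' Intersects the smoothed MER curve with a horizontal threshold (default
#' 0.1 mmol L^-1 h^-1): `xStart` is the first up-crossing and `xEnd` the
#' last down-crossing, both located by linear interpolation between grid
#' points. This excises lag and stationary phases before integration.
#'
#' @param rates a smoothed [RateSeries-class].
#' @param threshold positive rate threshold, mmol L^-1 h^-1.
#' @return A list with `xStart` and `xEnd` in hours.
#' @export
detectActiveWindow <- function(rates, threshold = 0.1) {
    if (threshold <= 0) stop("threshold must be positive")
    t <- rates@times; y <- rates@mer
    above <- y >= threshold
    if (!any(above))
        stop("no active phase detected: the rate curve never exceeds the threshold")
    iFirst <- which(above)[1]
    iLast <- which(above)[sum(above)]
    xStart <- if (iFirst == 1) t[1] else {
        # linear interpolation of the up-crossing
        t[iFirst - 1] + (threshold - y[iFirst - 1]) /
            (y[iFirst] - y[iFirst - 1]) * (t[iFirst] - t[iFirst - 1])
    }
    xEnd <- if (iLast == length(t)) t[length(t)] else {
        t[iLast] + (threshold - y[iLast]) /
            (y[iLast + 1] - y[iLast]) * (t[iLast + 1] - t[iLast])
    }
    list(xStart = xStart, xEnd = xEnd)
}

## trapezoid integral of (t, y) restricted to [a, b], with interpolated
## endpoint values
.trapzWindow <- function(t, y, a, b) {
    ya <- stats::approx(t, y, xout = a)$y
    yb <- stats::approx(t, y, xout = b)$y
    inside <- t > a & t < b
    tt <- c(a, t[inside], b)
    yy <- c(ya, y[inside], yb)
    .trapz(tt, yy)
}

#' Summarize the conversion kinetics of one closed-batch run
#'
#' Runs the full analysis chain on a single conversion segment:
#' resampling, MER computation, smoothing, active-window detection, and
#' integration. `merGlobal` is the trapezoid integral of the smoothed MER
#' over the active window divided by its width; `merTotal` the analogous
#' whole-run mean; `turnoverMax` comes from the raw pressure extrema (it is
#' deliberately independent of smoothing); `timeToFullConversion` is the
#' first time the trace reaches the stoichiometric residual pressure
#' (within `fullConversionTol` relative).
#'
#' A trace whose smoothed rate never exceeds `threshold` yields a result
#' flagged `noGrowth` with the rate extrema set to `NA` (turnover is still
#' reported).
#'
#' @param series a [PressureSeries-class] covering one conversion segment.
#' @param vessel a [VesselSpec-class]; defaults to the one on the series.
#' @param threshold active-window threshold, mmol L^-1 h^-1.
#' @param interval resampling interval, h.
#' @param window smoothing window, points.
#' @param composition initial [GasComposition-class].
#' @param fullConversionTol relative tolerance on the full-conversion
#'   residual pressure.
#' @param noiseTol see [merFromPressure()].
#' @return A [KineticsResult-class].
#' @export
summarizeKinetics <- function(series, vessel = series@vessel,
                              threshold = 0.1, interval = 0.5, window = 5,
                              composition = GasComposition(),
                              fullConversionTol = 0.02, noiseTol = 0.3) {
    res <- resampleSeries(series, interval)
    rates <- merFromPressure(res, vessel, noiseTol = noiseTol)
    sm <- smoothSeries(rates, window = min(window, length(rates@mer) -
                                           (1 - length(rates@mer) %% 2)))

    p0 <- series@pressures[1]
    pMin <- min(series@pressures)
    turnoverMax <- 100 * turnoverFraction(p0, pMin, composition)
    turnover <- 100 * turnoverFraction(p0, res@pressures, composition)
    turnoverRateMax <- max(.slope(res@times, turnover))
    pResidual <- residualPressureFullConversion(p0, composition)
    reached <- which(series@pressures <= pResidual * (1 + fullConversionTol))
    timeToFull <- if (length(reached)) series@times[reached[1]] else NA_real_

    km <- kMin(res)

    win <- tryCatch(detectActiveWindow(sm, threshold), error = function(e) e)
    if (inherits(win, "error")) {
        return(new("KineticsResult", vesselId = series@vesselId,
                   merMax = NA_real_, tMerMax = NA_real_,
                   merGlobal = NA_real_, merTotal = NA_real_,
                   kMin = km$kMin, tKMin = km$time,
                   turnoverMax = turnoverMax,
                   turnoverRateMax = turnoverRateMax,
                   timeToFullConversion = timeToFull,
                   xStart = NA_real_, xEnd = NA_real_, deltaT = NA_real_,
                   noGrowth = TRUE))
    }

    iMax <- which.max(sm@mer)
    merMax <- sm@mer[iMax]
    tMerMax <- sm@times[iMax]
    deltaT <- win$xEnd - win$xStart
    merGlobal <- .trapzWindow(sm@times, sm@mer, win$xStart, win$xEnd) / deltaT
    span <- sm@times[length(sm@times)] - sm@times[1]
    merTotal <- .trapz(sm@times, sm@mer) / span

    new("KineticsResult", vesselId = series@vesselId,
        merMax = merMax, tMerMax = tMerMax,
        merGlobal = merGlobal, merTotal = merTotal,
        kMin = km$kMin, tKMin = km$time,
        turnoverMax = turnoverMax, turnoverRateMax = turnoverRateMax,
        timeToFullConversion = timeToFull,
        xStart = win$xStart, xEnd = win$xEnd, deltaT = deltaT,
        noGrowth = FALSE)
}

#' MER from an end-point GC measurement
#'
#' Off-gas chromatography yields the CH4 volume fraction in the final
#' headspace; combined with the final pressure this gives the total CH4
#' formed, and dividing by liquid volume and run duration the average
#' methane evolution rate: MER_GC = y_CH4 n(p_end) / (V_liquid duration).
#' Point measurements are taken after equilibration to the measurement
#' temperature (default 298.15 K on the vessel).
#'
#' @param gc a [GCResult-class].
#' @param pEnd final headspace pressure, bar.
#' @param vessel a [VesselSpec-class].
#' @param duration run duration in hours, > 0.
#' @return MER in mmol L^-1 h^-1.
#' @export
merFromGC <- function(gc, pEnd, vessel, duration) {
    if (duration <= 0) stop("duration must be positive")
    if (pEnd < 0) stop("pEnd must be non-negative")
    nEnd <- molesFromPressure(pEnd, vessel,
                              temperature = vessel@tMeasurement)
    gc@yCH4 * nEnd / (vessel@vLiquid * duration) * 1000
}

#' Growth statistics and biomass increase rate from an OD series
#'
#' Per-interval specific growth rates mu_i = ln(OD_{i+1}/OD_i) / dt_i, their
#' maximum and mean, and the biomass increase rate — a dimensionless
#' homogeneity-of-growth index defined per interval as
#' (OD_max mu_i) / (OD_i mu_average) with OD_i the interval-start OD, and
#' averaged over intervals (`mode = "interval"`, the default). The
#' alternative `mode = "single"` evaluates the index once at the interval
#' of fastest growth, (OD_max mu_max) / (OD@mu_max mu_average).
#'
#' @param od an [ODSeries-class] with >= 2 strictly positive points.
#' @param mode `"interval"` or `"single"`.
#' @return A [GrowthResult-class]. For a culture with zero average growth
#'   the biomass increase rate is `NA` (flagged, not an error).
#' @examples
#' growthStats(ODSeries(c(0, 1, 2), c(0.1, 0.2, 0.4)))  # rate = 3
#' @export
growthStats <- function(od, mode = c("interval", "single")) {
    mode <- match.arg(mode)
    if (length(od@od) < 2) stop("need at least 2 OD points")
    if (any(od@od <= 0))
        stop("growth rates require strictly positive OD values")
    dt <- diff(od@times)
    mu <- log(od@od[-1] / od@od[-length(od@od)]) / dt
    muAvg <- mean(mu)
    odMax <- max(od@od)
    bir <- if (muAvg == 0) {
        NA_real_
    } else if (mode == "interval") {
        mean(odMax * mu / (od@od[-length(od@od)] * muAvg))
    } else {
        i <- which.max(mu)
        odMax * max(mu) / (od@od[i] * muAvg)
    }
    new("GrowthResult", muSeries = mu, muMax = max(mu), muAverage = muAvg,
        odMax = odMax, biomassIncreaseRate = bir)
}
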