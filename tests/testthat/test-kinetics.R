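test_that("resampling puts a 5-min log on a 30-min grid and is exact on lines", {
    v <- sbrsVessel()
    t5 <- seq(0, 10, by = 5 / 60)
    lin <- PressureSeries(t5, 10 - 0.4 * t5, vessel = v)
    res <- resampleSeries(lin, 0.5)
    expect_equal(diff(res@times), rep(0.5, length(res@times) - 1))
    expect_equal(length(res@times), 21)   # 1/6 the points (plus endpoint)
    expect_equal(res@pressures, 10 - 0.4 * res@times, tolerance = 1e-12)
    # interval equal to native spacing: values unchanged
    same <- resampleSeries(lin, 5 / 60)
    expect_equal(same@pressures, lin@pressures, tolerance = 1e-12)
    expect_error(resampleSeries(lin, 0), "positive")
})

test_that("MER from a linear pressure decay matches the mole-balance value", {
    v <- sbrsVessel()   # V_gas 0.1 L, V_liquid 0.06 L, 338.15 K
    t <- seq(0, 5, by = 0.5)
    series <- PressureSeries(t, 10 - t, vessel = v)   # dp/dt = -1 bar/h
    rates <- merFromPressure(series)
    # oracle: 1 bar/h of gas loss -> n/4 mol CH4 per hour into 0.06 L
    merOracle <- oracleMoles(1, 0.1, 338.15) / 4 / 0.06 * 1000
    expect_equal(rates@mer, rep(merOracle, length(t)), tolerance = 1e-12)
    expect_equal(merOracle, 14.8, tolerance = 0.002)
    # constant pressure -> MER identically zero
    flat <- PressureSeries(t, rep(10, length(t)), vessel = v)
    expect_equal(merFromPressure(flat)@mer, rep(0, length(t)))
    # stoichiometric companions
    expect_equal(cur(rates), rates@mer)
    expect_equal(hur(rates), 4 * rates@mer)
})

test_that("a repressurization jump inside a segment is rejected", {
    v <- sbrsVessel()
    series <- PressureSeries(seq(0, 3, 0.5), c(10, 9, 8, 7, 10, 9, 8),
                             vessel = v)
    expect_error(merFromPressure(series), "segmentCycles")
})

test_that("smoothing matches a brute-force moving average", {
    set.seed(1)
    y <- runif(31)
    rates <- new("RateSeries", times = seq_along(y) / 2, mer = y)
    for (w in c(1, 3, 5, 9)) {
        expect_equal(smoothSeries(rates, w)@mer, oracleMovingAverage(y, w),
                     tolerance = 1e-12)
    }
    # window 1 is the identity; constants are unchanged; a unit spike under
    # window 5 flattens to 1/5
    expect_equal(smoothSeries(rates, 1)@mer, y)
    const <- new("RateSeries", times = 1:10, mer = rep(2, 10))
    expect_equal(smoothSeries(const, 5)@mer, rep(2, 10))
    spike <- new("RateSeries", times = 1:11, mer = c(rep(0, 5), 1, rep(0, 5)))
    expect_equal(max(smoothSeries(spike, 5)@mer), 1 / 5)
    expect_error(smoothSeries(const, 4), "odd")
    expect_error(smoothSeries(const, 11), "length")
})

test_that("k_min finds the steepest drop, ties to the earliest time", {
    v <- sbrsVessel()
    t <- seq(0, 10, 0.5)
    lin <- PressureSeries(t, 10 - 0.5 * t, vessel = v)
    km <- kMin(lin)
    expect_equal(km$kMin, -0.5, tolerance = 1e-12)
    expect_equal(km$time, 0)   # all slopes tie; earliest wins
    flat <- PressureSeries(t, rep(10, length(t)), vessel = v)
    expect_equal(kMin(flat)$kMin, 0)
    # sigmoid decay: k_min at the inflection, consistent with the
    # exhaustive pairwise finite-difference oracle within grid resolution
    sig <- PressureSeries(t, 6 + 4 * tanh((5 - t)), vessel = v)
    km <- kMin(sig)
    expect_equal(km$time, 5, tolerance = 0.5)
    expect_equal(km$kMin, oracleMinPairSlope(t, sig@pressures),
                 tolerance = 0.15 * abs(km$kMin))
    expect_error(kMin(PressureSeries(c(0, 1), c(2, 1), vessel = v)),
                 "3 points")
})

test_that("active-window crossings are found by line intersection", {
    tri <- triangularRates(peak = 1, span = 10, by = 0.1)
    win <- detectActiveWindow(tri, threshold = 0.1)
    expect_equal(win$xStart, 0.5, tolerance = 1e-9)  # 1 * t/5 = 0.1
    expect_equal(win$xEnd, 9.5, tolerance = 1e-9)
    low <- new("RateSeries", times = 0:10, mer = rep(0.01, 11))
    expect_error(detectActiveWindow(low, 0.1), "no active phase")
    high <- new("RateSeries", times = 0:10, mer = rep(5, 11))
    win <- detectActiveWindow(high, 0.1)
    expect_equal(c(win$xStart, win$xEnd), c(0, 10))
    expect_error(detectActiveWindow(tri, 0), "positive")
})

test_that("summary of a constant-rate window returns that rate as merGlobal", {
    v <- sbrsVessel()
    t <- seq(0, 20, by = 5 / 60)
    series <- PressureSeries(t, 10 - 0.3 * t, vessel = v)
    k <- summarizeKinetics(series)
    merOracle <- oracleMoles(0.3, 0.1, 338.15) / 4 / 0.06 * 1000
    expect_equal(k@merGlobal, merOracle, tolerance = 1e-6)
    expect_equal(k@merMax, merOracle, tolerance = 1e-6)
    expect_equal(k@merTotal, merOracle, tolerance = 1e-6)
    expect_equal(k@kMin, -0.3, tolerance = 1e-9)
    expect_false(k@noGrowth)
})

test_that("summary flags a flat trace as no growth but keeps turnover", {
    v <- sbrsVessel()
    t <- seq(0, 20, by = 0.5)
    set.seed(3)
    flat <- PressureSeries(t, 10 + rnorm(length(t), 0, 0.002), vessel = v)
    k <- summarizeKinetics(flat)
    expect_true(k@noGrowth)
    expect_true(is.na(k@merMax))
    expect_lt(k@turnoverMax, 2)
})

test_that("MER from GC matches the mole balance at full conversion", {
    v <- sbrsVessel()
    expect_equal(merFromGC(GCResult(0), pEnd = 2, vessel = v, duration = 40), 0)
    # full conversion: all residual gas is CH4 and equals 0.2 n(p0)
    mer <- merFromGC(GCResult(1), pEnd = 2, vessel = v, duration = 40)
    nCH4 <- mer * 40 * 0.06 / 1000
    n0 <- molesFromPressure(10, v, temperature = v@tMeasurement)
    expect_equal(nCH4, 0.2 * n0, tolerance = 1e-12)
    # and agrees with the extent computed from the pressure drop (same T)
    expect_equal(nCH4, extentFromPressureDrop(10, 2, v,
                                              temperature = v@tMeasurement),
                 tolerance = 1e-12)
    # halving duration doubles the rate
    expect_equal(merFromGC(GCResult(1), 2, v, 20), 2 * mer)
    expect_error(merFromGC(GCResult(0.5), 2, v, 0), "duration")
})

test_that("growth statistics implement the per-interval biomass increase rate", {
    # hand evaluation: [0.1, 0.2, 0.4] equally spaced -> mean(4, 2) = 3
    g <- growthStats(ODSeries(c(0, 1, 2), c(0.1, 0.2, 0.4)))
    expect_equal(g@biomassIncreaseRate, 3)
    expect_equal(g@muMax, log(2))
    expect_equal(g@muAverage, log(2))
    expect_equal(g@odMax, 0.4)
    # two points: rate = od_max / od_1 regardless of timing
    g2 <- growthStats(ODSeries(c(0, 7), c(0.05, 0.6)))
    expect_equal(g2@biomassIncreaseRate, 0.6 / 0.05)
    # single-point mode at the fastest interval
    gs <- growthStats(ODSeries(c(0, 1, 2), c(0.1, 0.4, 0.5)),
                      mode = "single")
    muAvg <- mean(c(log(4), log(1.25)))
    expect_equal(gs@biomassIncreaseRate, 0.5 * log(4) / (0.1 * muAvg))
    # degenerate inputs
    expect_error(growthStats(ODSeries(c(0, 1), c(0, 0.1))), "positive")
    gFlat <- growthStats(ODSeries(c(0, 1, 2), c(0.2, 0.2, 0.2)))
    expect_true(is.na(gFlat@biomassIncreaseRate))
})

test_that("merGlobal never exceeds merMax and turnover ignores smoothing", {
    v <- sbrsVessel()
    set.seed(11)
    for (s in 1:5) {
        sim <- simulateClosedBatch(SimParams(sigmaNoise = 0.03, seed = s),
                                   duration = 70)
        k <- summarizeKinetics(sim$pressure)
        expect_lte(k@merGlobal, k@merMax + 1e-9)
        # turnoverMax depends only on raw extrema, not on the smoothing
        k2 <- summarizeKinetics(sim$pressure, window = 9)
        expect_equal(k@turnoverMax, k2@turnoverMax)
    }
})

test_that("integral of MER over a segment equals the endpoint mole balance", {
    sim <- simulateClosedBatch(SimParams(sigmaNoise = 0), duration = 80)
    v <- sim$pressure@vessel
    res <- resampleSeries(sim$pressure, 0.5)
    rates <- merFromPressure(res)
    dt <- diff(res@times)
    integral <- sum(dt * (rates@mer[-length(rates@mer)] + rates@mer[-1]) / 2)
    mmolCH4 <- integral * v@vLiquid
    p <- res@pressures
    truth <- extentFromPressureDrop(p[1], p[length(p)], v) * 1000
    expect_equal(mmolCH4, truth, tolerance = 0.01 * truth)
})

test_that("k_min timestamp matches the MER peak within one grid step, noise-free", {
    for (s in 1:3) {
        sim <- simulateClosedBatch(SimParams(sigmaNoise = 0, seed = s),
                                   duration = 80)
        k <- summarizeKinetics(sim$pressure)
        expect_lte(abs(k@tKMin - k@tMerMax), 0.5 + 1e-9)
    }
})
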