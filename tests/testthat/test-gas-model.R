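test_that("ideal-gas mole conversion matches hand arithmetic and is linear", {
    v <- VesselSpec(vTotal = 0.12, vLiquid = 0.05)  # 70 mL headspace
    expect_equal(molesFromPressure(0, v, 298.15), 0)
    expect_equal(molesFromPressure(1, v, 298.15),
                 oracleMoles(1, 0.07, 298.15), tolerance = 1e-12)
    expect_equal(molesFromPressure(1, v, 298.15), 2.82e-3, tolerance = 2e-3)
    expect_equal(molesFromPressure(2, v, 298.15),
                 2 * molesFromPressure(1, v, 298.15))
})

test_that("pressure convention handling is applied and validated", {
    vAbs <- VesselSpec(pressureConvention = "absolute_corrected")
    vG <- VesselSpec()
    expect_gt(molesFromPressure(0, vAbs), 0)   # 1.013 bar added
    expect_equal(molesFromPressure(0, vG), 0)
    expect_error(molesFromPressure(-2, vAbs), "absolute_corrected")
    expect_error(molesFromPressure(-0.1, vG), "paper_gauge")
})

test_that("moles and pressure round-trip to 1e-12 relative", {
    for (conv in c("paper_gauge", "absolute_corrected")) {
        v <- VesselSpec(vTotal = 0.16, vLiquid = 0.06,
                        pressureConvention = conv)
        p <- c(0.5, 2, 10, 50)
        expect_equal(pressureFromMoles(molesFromPressure(p, v), v), p,
                     tolerance = 1e-12)
    }
})

test_that("reaction extent from pressure drop follows the 4-for-1 balance", {
    v <- sbrsVessel()
    n10 <- molesFromPressure(10, v)
    expect_equal(extentFromPressureDrop(10, 10, v), 0)
    # full conversion: p falls to p0/5, all CO2 (0.2 n0) became CH4
    expect_equal(extentFromPressureDrop(10, 2, v), n10 * 0.2,
                 tolerance = 1e-12)
    # half conversion oracle: xi such that p = 6 means 4 xi = 0.4 n0
    expect_equal(extentFromPressureDrop(10, 6, v), n10 * 0.1,
                 tolerance = 1e-12)
    expect_error(extentFromPressureDrop(10, 10.5, v), "pressure increase")
})

test_that("elemental H and C are conserved at random extents (species oracle)", {
    v <- sbrsVessel()
    n0 <- molesFromPressure(10, v)
    set.seed(42)
    for (xi in runif(25, 0, 0.2 * n0)) {
        sp <- oracleSpecies(n0, xi)
        hAtoms <- 2 * sp$H2 + 4 * sp$CH4 + 2 * sp$H2O
        cAtoms <- sp$CO2 + sp$CH4
        expect_equal(hAtoms, 2 * n0 * 0.8, tolerance = 1e-12)
        expect_equal(cAtoms, n0 * 0.2, tolerance = 1e-12)
        # total gas moles strictly decreasing in xi
        expect_lt(sp$H2 + sp$CO2 + sp$CH4, n0)
        # and the package's pressure at this extent matches the oracle
        p <- pressureFromMoles(n0 - 4 * xi, v)
        expect_equal(p, oraclePressure(n0, xi, 10), tolerance = 1e-12)
    }
})

test_that("turnover fraction reproduces the one-fifth rule and mole balance", {
    expect_equal(turnoverFraction(10, 10), 0)
    expect_equal(turnoverFraction(10, 2), 1)    # residual = p0/5
    expect_equal(turnoverFraction(50, 10), 1)
    expect_equal(turnoverFraction(10, 6), 0.5)  # species mole-balance oracle
    # monotone non-increasing in p, equals 1 exactly at the residual
    p <- seq(10, 2, by = -0.5)
    tf <- turnoverFraction(10, p)
    expect_true(all(diff(tf) >= 0))
    expect_equal(tf[length(tf)], 1)
    expect_error(turnoverFraction(0, 0), "p0")
})

test_that("turnover generalizes to non-4:1 mixtures by limiting reagent", {
    # H2-rich 6:1 -> CO2 limits; full conversion drop = 4 * xCO2 * p0
    rich <- GasComposition(xH2 = 6 / 7, xCO2 = 1 / 7)
    pRes <- residualPressureFullConversion(7, rich)
    expect_equal(pRes, 7 * (1 - 4 / 7))
    expect_equal(turnoverFraction(7, pRes, rich), 1)
    # H2-poor 2:1 -> H2 limits: xiMax = xH2/4
    poor <- GasComposition(xH2 = 2 / 3, xCO2 = 1 / 3)
    expect_equal(residualPressureFullConversion(9, poor),
                 9 * (1 - 4 * (2 / 3) / 4))
})

test_that("residual pressure at full conversion is one-fifth for 4:1 feed", {
    expect_equal(residualPressureFullConversion(10), 2)
    expect_equal(residualPressureFullConversion(50), 10)
    expect_equal(residualPressureFullConversion(0), 0)
})

test_that("Henry's-law availability ratio is a pressure ratio", {
    expect_equal(dissolvedH2Ratio(10, 2), 5)
    expect_equal(dissolvedH2Ratio(50, 2), 25)
    expect_equal(dissolvedH2Ratio(7, 7), 1)
    expect_error(dissolvedH2Ratio(10, 0), "positive")
})

test_that("gas composition and vessel invariants are enforced", {
    expect_error(GasComposition(xH2 = 0.9, xCO2 = 0.2), "sum to 1")
    expect_error(VesselSpec(vTotal = 0.1, vLiquid = 0.1), "vLiquid")
    expect_error(VesselSpec(tIncubation = 200), "273")
    expect_equal(vGas(VesselSpec(vTotal = 0.16, vLiquid = 0.06)), 0.1)
})
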