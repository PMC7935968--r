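# Independent oracles, deliberately naive: direct species-table mole
# bookkeeping and brute-force loops, never the package's own vectorised
# code paths.

# Moles of each species after xi mol CH4 formed from n0 total moles of a
# 4:1-style mixture; direct transcription of 4 H2 + CO2 -> CH4 + 2 H2O.
oracleSpecies <- function(n0, xi, xH2 = 0.8, xCO2 = 0.2) {
    list(H2 = n0 * xH2 - 4 * xi,
         CO2 = n0 * xCO2 - xi,
         CH4 = xi,
         H2O = 2 * xi)
}

# Headspace pressure from the species table (water condensed out).
oraclePressure <- function(n0, xi, p0) {
    nGas <- n0 - 4 * xi   # H2 + CO2 + CH4 remaining in the gas phase
    p0 * nGas / n0
}

# Ideal-gas moles, hand arithmetic (bar, L, K).
oracleMoles <- function(pBar, vLitre, tKelvin) {
    (pBar * 1e5) * (vLitre / 1000) / (8.314 * tKelvin)
}

# Brute-force centred moving average with shrinking edges.
oracleMovingAverage <- function(y, window) {
    half <- (window - 1) / 2
    n <- length(y)
    sapply(seq_len(n), function(i) {
        h <- min(half, i - 1, n - i)
        mean(y[(i - h):(i + h)])
    })
}

# Brute-force minimum finite-difference slope over all adjacent pairs.
oracleMinPairSlope <- function(t, p) {
    slopes <- (p[-1] - p[-length(p)]) / (t[-1] - t[-length(t)])
    min(slopes)
}

# Adjusted Rand index from the contingency table (direct formula).
oracleARI <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    sumij <- sum(choose(tab, 2))
    ai <- sum(choose(rowSums(tab), 2))
    bj <- sum(choose(colSums(tab), 2))
    expected <- ai * bj / choose(n, 2)
    maxidx <- (ai + bj) / 2
    (sumij - expected) / (maxidx - expected)
}

# A clean triangular rate series peaking at `peak` over [0, span].
triangularRates <- function(peak = 1, span = 10, by = 0.1) {
    t <- seq(0, span, by = by)
    y <- peak * (1 - abs(t - span / 2) / (span / 2))
    new("RateSeries", times = t, mer = y)
}

sbrsVessel <- function() {
    VesselSpec(vTotal = 0.16, vLiquid = 0.06, tIncubation = 338.15)
}
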