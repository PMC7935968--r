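## Synthetic closed-batch / RCB methanogenesis, plus screening-matrix and
## MCR-alpha alignment fixtures. The gas model is the same species balance
## used by the analysis side; growth follows Monod kinetics on the H2
## partial pressure, which keeps the system closed without a gas-liquid
## mass-transfer submodel.

#' Simulation parameters for closed-batch methanogenesis
#'
#' Defaults emulate a stirred 160-mL bioreactor (60 mL medium) run at
#' 65 degrees C with 10 bar of 4:1 H2:CO2 — the standard conditions of a
#' pressurized closed-batch conversion run. `qMax` is the maximum
#' biomass-specific CH4 production rate, `Kp` the Monod half-saturation on
#' the H2 partial pressure, `Yx` the biomass yield per mol CH4, and
#' `odPerGcdw` converts cell dry weight to OD578.
#'
#' @slot vessel [VesselSpec-class].
#' @slot composition [GasComposition-class].
#' @slot p0 initial pressure, bar.
#' @slot qMax mmol CH4 (g CDW)^-1 h^-1.
#' @slot Kp bar.
#' @slot X0 inoculum density, g CDW L^-1.
#' @slot Yx g CDW per mol CH4.
#' @slot tLag lag phase, h.
#' @slot sigmaNoise pressure sensor noise sd, bar.
#' @slot dtSim integrator step, h.
#' @slot dtRecord logging interval, h (default 5 min).
#' @slot seed integer; fixes all randomness.
#' @slot odPerGcdw OD units per g CDW L^-1.
#' @export
setClass("SimParams",
    representation(vessel = "VesselSpec", composition = "GasComposition",
                   p0 = "numeric", qMax = "numeric", Kp = "numeric",
                   X0 = "numeric", Yx = "numeric", tLag = "numeric",
                   sigmaNoise = "numeric", dtSim = "numeric",
                   dtRecord = "numeric", seed = "integer",
                   odPerGcdw = "numeric"),
    prototype(vessel = new("VesselSpec", vTotal = 0.16, vLiquid = 0.06,
                           tIncubation = 338.15, tMeasurement = 298.15,
                           pressureConvention = "paper_gauge"),
              composition = new("GasComposition", xH2 = 0.8, xCO2 = 0.2,
                                xCH4 = 0, xOther = 0),
              p0 = 10, qMax = 60, Kp = 0.5, X0 = 0.01, Yx = 1.5,
              tLag = 5, sigmaNoise = 0.02, dtSim = 0.01,
              dtRecord = 1 / 12, seed = 1L, odPerGcdw = 2.5))

setValidity("SimParams", function(object) {
    pos <- c(p0 = object@p0, qMax = object@qMax, Kp = object@Kp,
             Yx = object@Yx, dtSim = object@dtSim,
             dtRecord = object@dtRecord, odPerGcdw = object@odPerGcdw)
    if (any(pos <= 0))
        return(sprintf("parameter(s) must be positive: %s",
                       paste(names(pos)[pos <= 0], collapse = ", ")))
    if (object@X0 < 0 || object@tLag < 0 || object@sigmaNoise < 0)
        return("X0, tLag and sigmaNoise must be non-negative")
    if (object@dtSim > object@dtRecord)
        return("dtSim must not exceed dtRecord")
    TRUE
})

#' Constructor for SimParams
#' @param ... slot values overriding the defaults (see
#'   [SimParams-class]).
#' @return A [SimParams-class] object.
#' @export
SimParams <- function(...) {
    args <- list(...)
    if (!is.null(args$seed)) args$seed <- as.integer(args$seed)
    do.call(new, c("SimParams", args))
}

#' Simulate a repetitive closed batch (RCB) run
#'
#' Integrates gas-limited Monod growth in a sealed headspace with a
#' fixed-step RK4 solver. Whenever the pressure reaches the full-conversion
#' residual (one-fifth of `p0` for the 4:1 feed) and cycles remain, the
#' headspace is flushed and repressurized to `p0` with fresh feed gas while
#' the biomass carries over — exactly the RCB operating scheme. With
#' `nCycles = 1` this is a plain closed-batch simulation.
#'
#' Recorded pressures carry i.i.d. Gaussian sensor noise (`sigmaNoise`,
#' seeded); the returned truth record carries the noise-free per-cycle
#' kinetics for use as an oracle.
#'
#' @param params a [SimParams-class].
#' @param nCycles number of conversion cycles, >= 1.
#' @param duration total simulated time, h.
#' @param fullConversionTol relative tolerance on the residual pressure
#'   used for the truth record's time-to-full-conversion.
#' @param repressurizeTol relative tolerance at which the operator declares
#'   total gas conversion and repressurizes; tighter than the analysis
#'   tolerance so a converged cycle is unambiguous downstream. The residual
#'   pressure is held for one logging interval before the flush (gas
#'   release and repressurization are not instantaneous), so the logged
#'   trace always contains the converged reading.
#' @return A list with `pressure` ([PressureSeries-class] on the
#'   `dtRecord` grid), `od` ([ODSeries-class]), and `truth`, a list holding
#'   `cycles` (data.frame: cycle, start, end, p0, merMaxTrue, tMerMaxTrue,
#'   kMinTrue, tKMinTrue, timeToFullConversion), `boundaries` (h), and the
#'   noise-free fine-grid trace.
#' @export
simulateRCB <- function(params, nCycles = 1L, duration = 120,
                        fullConversionTol = 0.02, repressurizeTol = 0.01) {
    methods::validObject(params)
    if (nCycles < 1) stop("nCycles must be >= 1")
    vessel <- params@vessel
    n0 <- molesFromPressure(params@p0, vessel)
    xiMax <- .xiMaxFraction(params@composition) * n0
    pRes <- residualPressureFullConversion(params@p0, params@composition)
    dt <- params@dtSim
    nSteps <- ceiling(duration / dt)

    tGrid <- numeric(nSteps + 1)
    pGrid <- numeric(nSteps + 1)
    xGrid <- numeric(nSteps + 1)
    rateGrid <- numeric(nSteps + 1)   # mmol CH4 / L liquid / h
    cycleGrid <- integer(nSteps + 1)

    state <- c(0, params@X0)          # (xi within cycle, X)
    cycle <- 1L
    boundaries <- numeric(0)
    tCycleStart <- 0
    pGrid[1] <- params@p0
    xGrid[1] <- params@X0
    cycleGrid[1] <- 1L
    rateGrid[1] <- 0

    # precomputed scalars keep the inner loop cheap
    xH2 <- params@composition@xH2
    barPerMol <- .R_GAS * vessel@tIncubation / (vGas(vessel) / 1000) / .BAR_PA
    gaugeOffset <- if (vessel@pressureConvention == "absolute_corrected")
        .ATM_BAR else 0
    qVl <- params@qMax / 1000 * vessel@vLiquid
    yOverVl <- params@Yx / vessel@vLiquid
    tLag <- params@tLag; Kp <- params@Kp
    deriv <- function(t, st) {
        xi <- st[1]
        if (t < tLag || xi >= xiMax) return(c(0, 0))
        nTot <- n0 - 4 * xi
        pH2 <- max(0, (nTot * barPerMol - gaugeOffset) *
                       (n0 * xH2 - 4 * xi) / nTot)
        dXi <- qVl * st[2] * pH2 / (Kp + pH2)
        c(dXi, yOverVl * dXi)
    }
    rk4 <- function(t, st, h) {
        k1 <- deriv(t, st)
        k2 <- deriv(t + h / 2, st + h / 2 * k1)
        k3 <- deriv(t + h / 2, st + h / 2 * k2)
        k4 <- deriv(t + h, st + h * k3)
        out <- st + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        out[1] <- min(out[1], xiMax)
        out
    }

    # hold the converged residual for a bit more than one logging interval
    # before flushing, so the record grid always captures it
    dwellSteps <- ceiling(params@dtRecord / dt) + 2L
    dwellLeft <- 0L
    pHold <- NA_real_

    for (s in seq_len(nSteps)) {
        t <- (s - 1) * dt
        tGrid[s + 1] <- s * dt
        if (dwellLeft > 0L) {
            dwellLeft <- dwellLeft - 1L
            xGrid[s + 1] <- state[2]
            rateGrid[s + 1] <- 0
            if (dwellLeft == 0L) {
                # flush and repressurize with fresh feed gas
                boundaries <- c(boundaries, s * dt)
                cycle <- cycle + 1L
                tCycleStart <- s * dt
                state[1] <- 0
                pGrid[s + 1] <- params@p0
            } else {
                pGrid[s + 1] <- pHold
            }
            cycleGrid[s + 1] <- cycle
            next
        }
        tc <- t - tCycleStart + if (cycle == 1L) 0 else params@tLag
        # carried-over biomass is active immediately after repressurization,
        # so cycles >= 2 skip the lag term by offsetting the clock
        prev <- state
        state <- rk4(tc, state, dt)
        p <- (n0 - 4 * state[1]) * barPerMol - gaugeOffset
        # Richardson local-error check on smooth steps (the lag switch and
        # the stoichiometric clip are intentional discontinuities), sampled
        # every 20th step to keep the fixed-step loop cheap
        smoothStep <- (tc >= tLag || tc + dt < tLag) && state[1] < xiMax
        if (smoothStep && s %% 20L == 0L) {
            half <- rk4(tc, prev, dt / 2)
            half <- rk4(tc + dt / 2, half, dt / 2)
            pHalf <- (n0 - 4 * half[1]) * barPerMol - gaugeOffset
            if (abs(p - pHalf) > 1e-6)
                stop("integrator step error exceeds 1e-6 bar; reduce dtSim")
        }
        d <- deriv(tc + dt, state)
        rateGrid[s + 1] <- d[1] / vessel@vLiquid * 1000
        if (p <= pRes * (1 + repressurizeTol) && cycle < nCycles) {
            dwellLeft <- dwellSteps
            pHold <- p
            rateGrid[s + 1] <- 0
        }
        pGrid[s + 1] <- p
        xGrid[s + 1] <- state[2]
        cycleGrid[s + 1] <- cycle
    }

    # per-cycle truth
    cycStart <- c(0, boundaries)
    cycEnd <- c(boundaries, tGrid[nSteps + 1])
    truthRows <- lapply(seq_along(cycStart), function(k) {
        idx <- which(cycleGrid == k)
        dpdt <- .slope(tGrid[idx], pGrid[idx])
        iR <- idx[which.max(rateGrid[idx])]
        iK <- which.min(dpdt)
        full <- idx[pGrid[idx] <= pRes * (1 + fullConversionTol)]
        data.frame(cycle = k, start = cycStart[k], end = cycEnd[k],
                   p0 = params@p0,
                   merMaxTrue = max(rateGrid[idx]),
                   tMerMaxTrue = tGrid[iR],
                   kMinTrue = min(dpdt), tKMinTrue = tGrid[idx][iK],
                   timeToFullConversion =
                       if (length(full)) tGrid[full[1]] - cycStart[k]
                       else NA_real_)
    })

    # the logger samples the nearest solver state (no interpolation, so
    # repressurization jumps stay crisp between consecutive log records)
    nominal <- seq(0, tGrid[nSteps + 1], by = params@dtRecord)
    idx <- unique(pmin(nSteps + 1, round(nominal / dt) + 1))
    recTimes <- tGrid[idx]
    pRec <- pGrid[idx]
    xRec <- xGrid[idx]
    set.seed(params@seed)
    pRec <- pRec + stats::rnorm(length(pRec), 0, params@sigmaNoise)

    list(pressure = PressureSeries(recTimes, pRec, vessel = vessel,
                                   vesselId = "SIM"),
         od = ODSeries(recTimes, xRec * params@odPerGcdw),
         truth = list(cycles = do.call(rbind, truthRows),
                      boundaries = boundaries,
                      fine = data.frame(time = tGrid, pressure = pGrid,
                                        biomass = xGrid,
                                        mer = rateGrid)))
}

#' Simulate a single closed-batch conversion run
#'
#' Convenience wrapper for [simulateRCB()] with one cycle; see there for
#' the model.
#'
#' @inheritParams simulateRCB
#' @return As [simulateRCB()], with a single truth row.
#' @export
simulateClosedBatch <- function(params, duration = 120,
                                fullConversionTol = 0.02) {
    simulateRCB(params, nCycles = 1L, duration = duration,
                fullConversionTol = fullConversionTol)
}

#' Synthetic strains-by-variables screening matrix
#'
#' Generates a cluster-structured matrix emulating a strain screening
#' campaign: `k` cluster centroids separated by `separation` noise standard
#' deviations, unit Gaussian noise, and a missing-at-random mask. True
#' labels are returned in the row metadata.
#'
#' @param nObs number of observations (strain-by-medium rows).
#' @param nVars number of numeric variables.
#' @param k number of true clusters.
#' @param separation centroid separation in noise sd units.
#' @param missingFrac fraction of entries masked as missing, in \[0, 1).
#' @param seed integer seed.
#' @return A [ScreeningMatrix-class]; `rowData` carries `true_cluster`,
#'   a taxonomy group and a temperature group per row.
#' @export
screeningFixture <- function(nObs = 60, nVars = 6, k = 2, separation = 5,
                             missingFrac = 0.1, seed = 1) {
    if (missingFrac >= 1 || missingFrac < 0)
        stop("missingFrac must lie in [0, 1)")
    set.seed(seed)
    labels <- rep_len(seq_len(k), nObs)
    centroids <- matrix(0, k, nVars)
    for (j in seq_len(k))
        centroids[j, ((seq_len(nVars) - 1) %% k) + 1 == j] <- separation
    data <- centroids[labels, , drop = FALSE] +
        matrix(stats::rnorm(nObs * nVars), nObs, nVars)
    colnames(data) <- c("od_max", "turnover_max", "mer_max",
                        paste0("covariate_", seq_len(max(0, nVars - 3))))[seq_len(nVars)]
    if (missingFrac > 0) {
        mask <- matrix(stats::runif(nObs * nVars) < missingFrac, nObs, nVars)
        # never blank out a full row or column
        for (i in which(rowSums(!mask) == 0)) mask[i, 1] <- FALSE
        for (j in which(colSums(!mask) == 0)) mask[1, j] <- FALSE
        data[mask] <- NA
    }
    rowData <- data.frame(
        strain = sprintf("strain_%02d", seq_len(nObs)),
        true_cluster = labels,
        taxonomy = c("Methanococci", "Methanobacteria",
                     "Methanomicrobia", "Methanopyri")[((labels - 1) %% 4) + 1],
        temp_group = sample(c("meso", "thermo", "hyper"), nObs,
                            replace = TRUE))
    ScreeningMatrix(data, rowData)
}

#' Exact low-rank matrix with a missing mask
#'
#' Builds a noiseless rank-`rank` matrix (product of Gaussian factors) and
#' masks a fraction of entries, returning both the complete truth and the
#' masked copy — the canonical oracle for low-rank imputation.
#'
#' @param nObs,nVars dimensions.
#' @param rank true rank.
#' @param missingFrac fraction of masked entries.
#' @param seed integer seed.
#' @return list(full, masked) numeric matrices.
#' @export
lowRankFixture <- function(nObs = 40, nVars = 8, rank = 2,
                           missingFrac = 0.1, seed = 1) {
    set.seed(seed)
    full <- matrix(stats::rnorm(nObs * rank), nObs, rank) %*%
        matrix(stats::rnorm(rank * nVars), rank, nVars)
    masked <- full
    mask <- matrix(stats::runif(nObs * nVars) < missingFrac, nObs, nVars)
    for (i in which(rowSums(!mask) == 0)) mask[i, 1] <- FALSE
    for (j in which(colSums(!mask) == 0)) mask[1, j] <- FALSE
    masked[mask] <- NA
    list(full = full, masked = masked)
}

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Synthetic gapped MCR-alpha alignment with motif ground truth
#'
#' Builds a reference-anchored multiple alignment emulating an MCR
#' alpha-subunit protein alignment: a reference sequence carrying the
#' Tyr444-Gly445-Tyr446 motif, variant sequences with prescribed Y->F
#' substitutions at positions 444/446 (classes YGY, FGY, YGF, FGF) or a gap
#' at 445 (class other/gapped), point substitutions elsewhere, and randomly
#' inserted gap columns (which give the reference itself a gapped
#' coordinate system).
#'
#' @param nSeqs number of non-reference sequences.
#' @param seqLength ungapped reference length (>= 446; default 520).
#' @param gapColumns number of all-but-a-few-gap columns inserted.
#' @param substitutionRate per-residue background substitution rate.
#' @param classes character vector recycled over sequences; subset of
#'   c("YGY", "FGY", "YGF", "FGF", "gapped").
#' @param seed integer seed.
#' @return list with `alignment` (a gapped [Biostrings::AAStringSet]),
#'   `referenceId`, and `truth` (data.frame id, class).
#' @export
alignmentFixture <- function(nSeqs = 20, seqLength = 520, gapColumns = 30,
                             substitutionRate = 0.05,
                             classes = c("YGY", "FGY", "YGF", "FGF", "gapped"),
                             seed = 1) {
    if (seqLength < 446) stop("reference must have at least 446 residues")
    set.seed(seed)
    ref <- sample(.AA20, seqLength, replace = TRUE)
    ref[444:446] <- c("Y", "G", "Y")
    cls <- rep_len(classes, nSeqs)
    seqs <- lapply(seq_len(nSeqs), function(i) {
        s <- ref
        mut <- stats::runif(seqLength) < substitutionRate
        mut[444:446] <- FALSE
        s[mut] <- sample(.AA20, sum(mut), replace = TRUE)
        s[444] <- substr(cls[i], 1, 1)
        s[446] <- substr(cls[i], 3, 3)
        if (cls[i] == "gapped") {
            s[444:446] <- c("Y", "-", "Y")
        }
        s
    })
    mat <- do.call(rbind, c(list(ref), seqs))
    # insert gap columns: each inserted column holds a residue in a random
    # minority of the variant sequences and '-' elsewhere; the reference is
    # always gapped there, so its residue numbering is exercised against
    # gaps without shifting the motif coordinates
    for (g in seq_len(gapColumns)) {
        pos <- sample(ncol(mat) + 1, 1)
        col <- rep("-", nrow(mat))
        lucky <- 1 + sample(nrow(mat) - 1,
                            max(1, stats::rbinom(1, nrow(mat) - 1, 0.15)))
        col[lucky] <- sample(.AA20, length(lucky), replace = TRUE)
        left <- if (pos > 1) mat[, seq_len(pos - 1), drop = FALSE] else NULL
        right <- if (pos <= ncol(mat)) mat[, pos:ncol(mat), drop = FALSE] else NULL
        mat <- cbind(left, col, right)
    }
    strings <- apply(mat, 1, paste, collapse = "")
    ids <- c("M_marburgensis_ref", sprintf("seq_%02d", seq_len(nSeqs)))
    aln <- Biostrings::AAStringSet(strings)
    names(aln) <- ids
    truthClass <- ifelse(cls == "gapped", "other/gapped", cls)
    list(alignment = aln, referenceId = ids[1],
         truth = data.frame(id = ids[-1], class = truthClass,
                            stringsAsFactors = FALSE))
}
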