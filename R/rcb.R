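## Repetitive closed batch (RCB) handling: split a multi-cycle pressure log
## at repressurization jumps and evaluate each conversion cycle.

#' Segment an RCB pressure log into conversion cycles
#'
#' Between cycles the residual gas is released and the vessel repressurized,
#' which appears in the log as an abrupt pressure rise. A new segment starts
#' wherever the pressure rises by more than `jumpFraction` of the trace
#' maximum between consecutive samples; the detection is relative so the
#' same default works from 2 to 50 bar. Points inside a jump belong to the
#' following segment. Rises below the threshold (sensor noise) never split
#' a segment.
#'
#' @param series a [PressureSeries-class].
#' @param jumpFraction fraction of the maximum pressure that counts as a
#'   repressurization jump, in (0, 1] (default 0.2).
#' @param nMax maximum number of segments accepted (default 10).
#' @return A list of [CycleSegment-class] objects, ordered in time and
#'   indexed RCB1, RCB2, ...
#' @export
segmentCycles <- function(series, jumpFraction = 0.2, nMax = 10) {
    if (jumpFraction <= 0 || jumpFraction > 1)
        stop("jumpFraction must lie in (0, 1]")
    p <- series@pressures
    jump <- which(diff(p) > jumpFraction * max(p))
    starts <- 1L
    for (j in jump) {
        # a multi-sample repressurization ramp yields consecutive jump
        # indices; only the first opens a new segment
        if (j + 1L - starts[length(starts)] >= 2L)
            starts <- c(starts, j + 1L)
    }
    if (length(starts) > nMax)
        stop(sprintf("detected %d segments, more than nMax = %d",
                     length(starts), nMax))
    ends <- c(starts[-1] - 1L, length(p))
    keep <- ends - starts >= 1L      # a segment needs >= 2 points
    starts <- starts[keep]; ends <- ends[keep]
    lapply(seq_along(starts), function(k) {
        idx <- starts[k]:ends[k]
        sub <- PressureSeries(series@times[idx], p[idx],
                              vessel = series@vessel,
                              vesselId = series@vesselId)
        new("CycleSegment", index = k, series = sub, p0 = p[idx[1]])
    })
}

#' Evaluate every cycle of a segmented RCB run
#'
#' Runs [summarizeKinetics()] on each segment and adds a full-conversion
#' verdict: a cycle is fully converted iff its minimum pressure reaches the
#' stoichiometric residual (one-fifth of the cycle's initial pressure for
#' the 4:1 feed gas) within `fullConversionTol` relative. Cycles whose rate
#' never exceeds the active threshold are reported with a no-growth flag
#' rather than dropped.
#'
#' @param segments list of [CycleSegment-class] from [segmentCycles()].
#' @param vessel a [VesselSpec-class]; defaults to the vessel on the first
#'   segment.
#' @param composition initial [GasComposition-class] (restored by each
#'   repressurization).
#' @param fullConversionTol relative tolerance on the residual pressure.
#' @param ... further arguments passed to [summarizeKinetics()].
#' @return A data.frame with one row per cycle: `cycle` (RCB1, ...), all
#'   kinetic summary fields, `full_conversion` and `no_growth`.
#' @export
evaluateCycles <- function(segments, vessel = segments[[1]]@series@vessel,
                           composition = GasComposition(),
                           fullConversionTol = 0.02, ...) {
    rows <- lapply(segments, function(seg) {
        k <- summarizeKinetics(seg@series, vessel,
                               composition = composition,
                               fullConversionTol = fullConversionTol, ...)
        pRes <- residualPressureFullConversion(seg@p0, composition)
        row <- .kineticsRow(k)
        row$cycle <- sprintf("RCB%d", seg@index)
        row$p0 <- seg@p0
        row$full_conversion <-
            min(seg@series@pressures) <= pRes * (1 + fullConversionTol)
        row
    })
    df <- do.call(rbind, rows)
    front <- c("vessel_id", "cycle", "p0")
    df[, c(front, setdiff(names(df), front)), drop = FALSE]
}
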