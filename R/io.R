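## Tabular input/output. Inputs are plain CSV with a header row, '.' decimal
## separator and times in hours; outputs are deterministic TSV.

.requireColumns <- function(df, cols, path) {
    missing <- setdiff(cols, names(df))
    if (length(missing))
        stop(sprintf("file '%s' is missing required column(s): %s",
                     path, paste(missing, collapse = ", ")))
}

.loadSeriesFrame <- function(path, valueCol) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0) stop(sprintf("file '%s' is empty", path))
    .requireColumns(df, c("time_h", valueCol), path)
    if (!"vessel_id" %in% names(df)) df$vessel_id <- "R1"
    df <- df[order(df$vessel_id, df$time_h), ]
    # collapse duplicate timestamps by mean
    key <- paste(df$vessel_id, df$time_h)
    if (anyDuplicated(key)) {
        message("collapsing duplicate timestamps by mean")
        agg <- stats::aggregate(df[[valueCol]],
                                by = list(vessel_id = df$vessel_id,
                                          time_h = df$time_h), FUN = mean)
        names(agg)[3] <- valueCol
        df <- agg[order(agg$vessel_id, agg$time_h), ]
    }
    if (anyNA(df[[valueCol]]))
        stop(sprintf("file '%s' has missing values in '%s'", path, valueCol))
    df
}

#' Read a pressure, OD or GC time-series CSV
#'
#' Expects a header with columns `time_h` and `value` (plus an optional
#' `vessel_id` for multi-reactor files). Rows are sorted by time per vessel;
#' duplicate timestamps are collapsed by their mean with a message.
#'
#' @param path CSV file path.
#' @param kind one of `"pressure"`, `"od"`, `"gc"`.
#' @param vessel a [VesselSpec-class] attached to pressure series.
#' @return A named list with one element per `vessel_id`:
#'   [PressureSeries-class], [ODSeries-class] or [GCResult-class] objects.
#' @export
readTimeseries <- function(path, kind = c("pressure", "od", "gc"),
                           vessel = VesselSpec()) {
    kind <- match.arg(kind)
    df <- .loadSeriesFrame(path, "value")
    out <- lapply(split(df, df$vessel_id), function(d) {
        switch(kind,
            pressure = PressureSeries(d$time_h, d$value, vessel = vessel,
                                      vesselId = d$vessel_id[1]),
            od = ODSeries(d$time_h, d$value),
            gc = GCResult(yCH4 = d$value[nrow(d)],
                          sampledAt = d$time_h[nrow(d)],
                          vesselId = d$vessel_id[1]))
    })
    out[order(names(out))]
}

.kineticsRow <- function(k) {
    data.frame(
        vessel_id = k@vesselId,
        mer_max = k@merMax, t_mer_max = k@tMerMax,
        mer_global = k@merGlobal, mer_total = k@merTotal,
        k_min = k@kMin, t_k_min = k@tKMin,
        turnover_max_pct = k@turnoverMax,
        turnover_rate_max = k@turnoverRateMax,
        time_to_full_conversion = k@timeToFullConversion,
        x_start = k@xStart, x_end = k@xEnd, delta_t = k@deltaT,
        no_growth = k@noGrowth,
        stringsAsFactors = FALSE)
}

#' Write result objects to a deterministic TSV
#'
#' Accepts a non-empty list of results of one kind ([KineticsResult-class]
#' objects, a [ClusterResult-class], or a motif report data.frame) and
#' writes a TSV with fixed column order, floats at 6 significant digits and
#' deterministic row ordering, so identical inputs yield byte-identical
#' files.
#'
#' @param results list of [KineticsResult-class] objects (all of one kind),
#'   or a single [ClusterResult-class] / motif report data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeResults <- function(results, path) {
    if (length(results) == 0) stop("no results to write")
    if (methods::is(results, "ClusterResult")) {
        df <- data.frame(row = seq_along(results@labels),
                         cluster = results@labels)
    } else if (is.data.frame(results)) {
        df <- results
    } else {
        if (!all(vapply(results, methods::is, logical(1), "KineticsResult")))
            stop("mixed or unsupported result kinds in one writeResults() call")
        df <- do.call(rbind, lapply(results, .kineticsRow))
        df <- df[order(df$vessel_id), , drop = FALSE]
    }
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 6))
    con <- file(path, open = "wt")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
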