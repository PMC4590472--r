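#' Accessors for bactoSeries classes
#'
#' \code{seriesValues} returns the monthly values; \code{seriesName} the
#' variable name; \code{monthIndex} the 0-based integer month index;
#' \code{calendarMonth} the calendar month (1--12) of each sample;
#' \code{calendarYear} the calendar year; \code{harmonics},
#' \code{trendComponent} and \code{arComponent} the retained components of
#' a decomposition; \code{varianceLedger} the one-row percent-variance
#' ledger.
#'
#' @param x a \linkS4class{MonthlySeries} or
#'   \linkS4class{SeriesDecomposition}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' @rdname accessors
#' @export
setGeneric("seriesName", function(x) standardGeneric("seriesName"))

#' @rdname accessors
#' @export
setGeneric("monthIndex", function(x) standardGeneric("monthIndex"))

#' @rdname accessors
#' @export
setGeneric("calendarMonth", function(x) standardGeneric("calendarMonth"))

#' @rdname accessors
#' @export
setGeneric("calendarYear", function(x) standardGeneric("calendarYear"))

#' @rdname accessors
#' @export
setGeneric("harmonics", function(x) standardGeneric("harmonics"))

#' @rdname accessors
#' @export
setGeneric("trendComponent", function(x) standardGeneric("trendComponent"))

#' @rdname accessors
#' @export
setGeneric("arComponent", function(x) standardGeneric("arComponent"))

#' @rdname accessors
#' @export
setGeneric("varianceLedger", function(x) standardGeneric("varianceLedger"))

#' @rdname accessors
setMethod("seriesValues", "MonthlySeries", function(x) x@values)

#' @rdname accessors
setMethod("seriesValues", "SeriesDecomposition",
          function(x) x@series@values)

#' @rdname accessors
setMethod("seriesName", "MonthlySeries", function(x) x@name)

#' @rdname accessors
setMethod("monthIndex", "MonthlySeries",
          function(x) seq_along(x@values) - 1L)

#' @rdname accessors
setMethod("calendarMonth", "MonthlySeries", function(x) {
  ((x@startMonth - 1L + monthIndex(x)) %% 12L) + 1L
})

#' @rdname accessors
setMethod("calendarYear", "MonthlySeries", function(x) {
  x@startYear + (x@startMonth - 1L + monthIndex(x)) %/% 12L
})

#' @rdname accessors
setMethod("harmonics", "SeriesDecomposition", function(x) x@harmonics)

#' @rdname accessors
setMethod("trendComponent", "SeriesDecomposition", function(x) x@trend)

#' @rdname accessors
setMethod("arComponent", "SeriesDecomposition", function(x) x@ar)

#' @param object a \linkS4class{SeriesDecomposition}.
#' @rdname accessors
#' @export
setMethod("residuals", "SeriesDecomposition", function(object) {
  object@residuals
})

setMethod("length", "MonthlySeries", function(x) length(x@values))

setMethod("show", "MonthlySeries", function(object) {
  v <- object@values
  cat(sprintf("MonthlySeries '%s' (%s%s): %d months from %04d-%02d, %d missing\n",
              object@name,
              if (object@log10) "log10 " else "",
              object@units, length(v),
              object@startYear, object@startMonth, sum(is.na(v))))
  cat(sprintf("  range %.4g .. %.4g, mean %.4g\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)),
              mean(v, na.rm = TRUE)))
  invisible(object)
})

setMethod("show", "CtdProfile", function(object) {
  cat(sprintf("CtdProfile: %d levels, %g-%g m", length(object@depth),
              min(object@depth), max(object@depth)))
  if (ncol(object@extra))
    cat(sprintf(", extra: %s", paste(names(object@extra), collapse = ", ")))
  cat("\n")
  invisible(object)
})

setMethod("show", "SizeCalibration", function(object) {
  cat(sprintf("SizeCalibration: d[um] = %.4g * RALS^%.3g over RALS %g-%g\n",
              10^object@logIntercept, object@logSlope,
              object@ralsRange[1], object@ralsRange[2]))
  invisible(object)
})

setMethod("show", "SeriesDecomposition", function(object) {
  cat(sprintf("SeriesDecomposition of '%s' (n = %d, alpha = %g)\n",
              object@series@name, length(object@series@values),
              object@alpha))
  cat(sprintf("  climatological mean: %.4g\n", object@mean))
  if (nrow(object@trend))
    cat(sprintf("  trend: b = %.4g / month (%.4g / yr), %%var = %.2f\n",
                object@trend$slope, object@trend$slopePerYear,
                object@trend$pctVar))
  if (nrow(object@harmonics))
    for (i in seq_len(nrow(object@harmonics)))
      with(object@harmonics[i, ],
           cat(sprintf("  harmonic: T = %.4g mo, A = %.4g, theta = %.3f, Tmax = %.2f, %%var = %.2f\n",
                       period, amplitude, phase, tMax, pctVar)))
  if (nrow(object@ar))
    cat(sprintf("  AR: lag %d, phi = %.3f, %%var = %.2f\n",
                object@ar$lag, object@ar$phi, object@ar$pctVar))
  cat(sprintf("  total %%var explained: %.2f\n", object@totalPctVar))
  invisible(object)
})

#' Variance ledger of a decomposition
#'
#' One row per series in the conventional ledger layout: climatological
#' mean, trend slope/intercept and percent variance, first harmonic
#' (period, amplitude, phase, month of maximum, percent variance),
#' autocorrelation (lag, phi, percent variance), and the total percent
#' variance explained. Absent components are NA.
#'
#' @param x a \linkS4class{SeriesDecomposition}.
#' @return A one-row \code{data.frame}.
#' @rdname accessors
setMethod("varianceLedger", "SeriesDecomposition", function(x) {
  tr <- x@trend; hm <- x@harmonics; ar <- x@ar
  data.frame(
    variable  = x@series@name,
    mean      = x@mean,
    b         = if (nrow(tr)) tr$slopePerYear else NA_real_,
    a         = if (nrow(tr)) tr$intercept else NA_real_,
    pctVarTrend = if (nrow(tr)) tr$pctVar else NA_real_,
    T         = if (nrow(hm)) hm$period[1] else NA_real_,
    A         = if (nrow(hm)) hm$amplitude[1] else NA_real_,
    theta     = if (nrow(hm)) hm$phase[1] else NA_real_,
    tMax      = if (nrow(hm)) hm$tMax[1] else NA_real_,
    pctVarPeriodic = if (nrow(hm)) sum(hm$pctVar) else NA_real_,
    lag       = if (nrow(ar)) ar$lag else NA_integer_,
    phi       = if (nrow(ar)) ar$phi else NA_real_,
    pctVarAr  = if (nrow(ar)) ar$pctVar else NA_real_,
    pctVarTotal = x@totalPctVar,
    stringsAsFactors = FALSE
  )
})
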