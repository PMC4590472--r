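#' @import methods
NULL

#' MonthlySeries: one variable on a regular monthly grid
#'
#' Container for a single variable sampled at regular monthly steps. Gaps
#' are represented as \code{NA} and are never silently filled. The internal
#' time index \code{t} runs in integer months from 0 at the first sample;
#' the calendar anchor (\code{startYear}, \code{startMonth}) is kept so that
#' seasonal windows (e.g. April--July) and April--March analysis years can
#' be resolved.
#'
#' @slot values numeric vector of monthly values, \code{NA} for gaps.
#' @slot name variable name.
#' @slot units unit string (after any transform).
#' @slot log10 logical; whether values are log10-transformed. Abundance,
#'   size and biomass variables are conventionally analysed on the log10
#'   scale.
#' @slot startYear calendar year of the first sample.
#' @slot startMonth calendar month (1--12) of the first sample.
#'
#' @aliases MonthlySeries-class
#' @exportClass MonthlySeries
setClass("MonthlySeries",
  representation(
    values     = "numeric",
    name       = "character",
    units      = "character",
    log10      = "logical",
    startYear  = "integer",
    startMonth = "integer"
  ),
  prototype(
    values = numeric(), name = "x", units = "", log10 = FALSE,
    startYear = 2002L, startMonth = 4L
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@values) < 1L)
      msg <- c(msg, "values must contain at least one month")
    if (length(object@startMonth) != 1L ||
        !object@startMonth %in% 1:12)
      msg <- c(msg, "startMonth must be a single value in 1..12")
    if (length(object@name) != 1L)
      msg <- c(msg, "name must be a single string")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a MonthlySeries
#'
#' @param values numeric vector of monthly values (\code{NA} = gap).
#' @param name variable name.
#' @param units unit string.
#' @param log10 logical, whether values are on the log10 scale.
#' @param startYear,startMonth calendar anchor of the first sample.
#' @return A \linkS4class{MonthlySeries}.
#' @examples
#' s <- monthlySeries(rnorm(24), name = "temperature", units = "degC")
#' length(seriesValues(s))
#' @export
monthlySeries <- function(values, name = "x", units = "",
                          log10 = FALSE, startYear = 2002L,
                          startMonth = 4L) {
  new("MonthlySeries", values = as.numeric(values), name = name,
      units = units, log10 = log10,
      startYear = as.integer(startYear),
      startMonth = as.integer(startMonth))
}

#' CtdProfile: a depth-indexed hydrographic cast
#'
#' Temperature and density (sigma-t acceptable) on a strictly increasing
#' depth grid, with optional extra per-depth variables (e.g. bacterial
#' properties to be averaged over the mixed layer).
#'
#' @slot depth depths in m, strictly increasing, non-negative.
#' @slot temperature temperature in degC, same length as depth.
#' @slot density density in kg m-3 (sigma-t acceptable).
#' @slot extra data.frame of additional per-depth variables (may have 0
#'   columns).
#'
#' @aliases CtdProfile-class
#' @exportClass CtdProfile
setClass("CtdProfile",
  representation(
    depth       = "numeric",
    temperature = "numeric",
    density     = "numeric",
    extra       = "data.frame"
  ),
  prototype(depth = c(0, 10), temperature = c(15, 15),
            density = c(26, 26), extra = data.frame()),
  validity = function(object) {
    msg <- character()
    n <- length(object@depth)
    if (n < 2L) msg <- c(msg, "a cast needs at least 2 depth levels")
    if (any(object@depth < 0)) msg <- c(msg, "depths must be non-negative")
    if (n >= 2L && any(diff(object@depth) <= 0))
      msg <- c(msg, "depths must be strictly increasing")
    if (length(object@temperature) != n || length(object@density) != n)
      msg <- c(msg, "temperature and density must match the depth grid")
    if (nrow(object@extra) > 0L && nrow(object@extra) != n)
      msg <- c(msg, "extra variables must match the depth grid")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a CtdProfile
#'
#' @param depth depths in m, strictly increasing.
#' @param temperature temperature in degC.
#' @param density density in kg m-3 (sigma-t acceptable).
#' @param extra optional data.frame of additional per-depth variables.
#' @return A \linkS4class{CtdProfile}.
#' @examples
#' p <- ctdProfile(depth = c(0, 10, 20, 50, 75, 100),
#'                 temperature = c(20, 19, 16, 13, 12.5, 12.2),
#'                 density = c(26, 26, 26.4, 26.9, 27, 27.1))
#' mixedLayerDepth(p)
#' @export
ctdProfile <- function(depth, temperature, density,
                       extra = data.frame()) {
  new("CtdProfile", depth = as.numeric(depth),
      temperature = as.numeric(temperature),
      density = as.numeric(density),
      extra = as.data.frame(extra))
}

#' SizeCalibration: empirical scatter-to-diameter mapping
#'
#' Power-law calibration between mean right-angle light scatter (RALS,
#' arbitrary instrument units, bead-normalised) and cell diameter (um),
#' stored as log-log linear coefficients:
#' \eqn{\log_{10} d = c_0 + c_1 \log_{10}(\mathrm{RALS})}. The instrument's
#' own empirical curve is unpublished, so calibrations are user-supplied
#' configuration; \code{\link{defaultSizeCalibration}} provides a synthetic
#' illustrative curve matched to the synthetic cytogram generator.
#'
#' @slot logIntercept intercept \eqn{c_0} on the log10 scale.
#' @slot logSlope slope \eqn{c_1}; must be > 0 so that the mapping is
#'   strictly increasing.
#' @slot ralsRange calibrated RALS range; values outside trigger an
#'   extrapolation warning.
#'
#' @aliases SizeCalibration-class
#' @exportClass SizeCalibration
setClass("SizeCalibration",
  representation(
    logIntercept = "numeric",
    logSlope     = "numeric",
    ralsRange    = "numeric"
  ),
  prototype(logIntercept = -0.64, logSlope = 0.25, ralsRange = c(1, 100)),
  validity = function(object) {
    msg <- character()
    if (length(object@logSlope) != 1L || object@logSlope <= 0)
      msg <- c(msg, "logSlope must be a single positive number (mapping must increase)")
    if (length(object@ralsRange) != 2L ||
        any(object@ralsRange <= 0) || diff(object@ralsRange) <= 0)
      msg <- c(msg, "ralsRange must be an increasing positive pair")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a SizeCalibration
#'
#' @param logIntercept,logSlope log10-log10 linear coefficients mapping
#'   RALS to diameter (um): \code{log10(d) = logIntercept + logSlope *
#'   log10(rals)}.
#' @param ralsRange calibrated RALS range (a.u.).
#' @return A \linkS4class{SizeCalibration}.
#' @export
sizeCalibration <- function(logIntercept, logSlope,
                            ralsRange = c(1, 100)) {
  new("SizeCalibration", logIntercept = as.numeric(logIntercept),
      logSlope = as.numeric(logSlope), ralsRange = as.numeric(ralsRange))
}

#' Synthetic default size calibration
#'
#' An illustrative power-law calibration \eqn{d = 0.23\,
#' \mathrm{RALS}^{0.25}} um, chosen so that the synthetic cytogram
#' generator's default RALS centers map to cell volumes inside the
#' plausible coastal bacterioplankton range (0.03--0.12 um3). It is a
#' synthetic stand-in for an instrument-specific empirical curve and should
#' be replaced by the user's own calibration for real data.
#'
#' @return A \linkS4class{SizeCalibration}.
#' @examples
#' ralsToVolume(10, defaultSizeCalibration())
#' @export
defaultSizeCalibration <- function() {
  sizeCalibration(logIntercept = log10(0.23), logSlope = 0.25,
                  ralsRange = c(0.5, 200))
}

#' SeriesDecomposition: fitted additive model and variance ledger
#'
#' Result of \code{\link{decomposeSeries}}: the series is expressed as the
#' sum of a climatological mean, an optional linear trend, zero or more
#' harmonic (periodic) components retained by the exact Fisher G-test, an
#' optional single-lag autoregressive term on the remainder, and residuals.
#' Each retained component carries the percentage of the original series
#' variance it explains; the total is their sum.
#'
#' @slot series the input \linkS4class{MonthlySeries}.
#' @slot mean climatological mean (series units).
#' @slot trend one-row data.frame (slope per month, slope per year,
#'   intercept, p, pctVar) or 0-row if not retained.
#' @slot harmonics data.frame with columns period, amplitude, phase, tMax,
#'   pctVar, p; one row per retained component, in extraction order.
#' @slot ar one-row data.frame (lag, phi, pctVar) or 0-row if not retained.
#' @slot residuals pre-whitened residuals, NA where the series has gaps or
#'   the AR term has no lagged predecessor.
#' @slot totalPctVar sum of component pctVar entries.
#' @slot alpha significance level used for component retention.
#'
#' @aliases SeriesDecomposition-class
#' @exportClass SeriesDecomposition
setClass("SeriesDecomposition",
  representation(
    series      = "MonthlySeries",
    mean        = "numeric",
    trend       = "data.frame",
    harmonics   = "data.frame",
    ar          = "data.frame",
    residuals   = "numeric",
    totalPctVar = "numeric",
    alpha       = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@residuals) != length(object@series@values))
      msg <- c(msg, "residuals must match the series length")
    parts <- c(object@trend$pctVar, object@harmonics$pctVar,
               object@ar$pctVar)
    if (length(parts) &&
        abs(sum(parts) - object@totalPctVar) > 1e-8)
      msg <- c(msg, "totalPctVar must equal the sum of component pctVar")
    if (nrow(object@harmonics) > 0L) {
      if (any(object@harmonics$amplitude < 0))
        msg <- c(msg, "harmonic amplitudes must be non-negative")
      if (any(object@harmonics$phase < 0 |
              object@harmonics$phase >= 2 * pi))
        msg <- c(msg, "harmonic phases must lie in [0, 2*pi)")
    }
    if (nrow(object@ar) > 0L && any(abs(object@ar$phi) >= 1))
      msg <- c(msg, "|phi| must be < 1")
    if (length(msg)) msg else TRUE
  }
)
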