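#' Read and write pipeline tables
#'
#' Plain-CSV readers and writers for the pipeline's external formats.
#' Dates are ISO-8601 (\code{YYYY-MM-DD}); month indices are derived
#' internally, never stored. \code{readCastTable} returns one
#' \linkS4class{CtdProfile} per date; \code{readEventTable} restores the
#' flow-rate/acquisition-time metadata columns as attributes;
#' \code{readUmlTable} assembles \linkS4class{MonthlySeries} objects from
#' a long (date, variable, value) table, inserting NA for missed months.
#'
#' @param path file path.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
readCastTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "depth_m", "temp_C", "density_kg_m3")
  if (!all(need %in% names(d)))
    stop("cast CSV must have columns ", paste(need, collapse = ", "))
  extraCols <- setdiff(names(d), need)
  lapply(split(d, d$date), function(g) {
    g <- g[order(g$depth_m), ]
    ctdProfile(g$depth_m, g$temp_C, g$density_kg_m3,
               extra = g[, extraCols, drop = FALSE])
  })
}

#' @rdname pipeline-io
#' @export
readEventTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("green", "rals", "red") %in% names(d)))
    stop("event CSV must have columns green, rals, red")
  for (meta in c("flowRate", "acquisitionTime")) {
    if (meta %in% names(d)) {
      attr(d, meta) <- d[[meta]][1]
      d[[meta]] <- NULL
    }
  }
  d
}

#' @rdname pipeline-io
#' @param events event table with metadata attributes.
#' @export
writeEventTable <- function(events, path) {
  out <- events
  out$flowRate <- attr(events, "flowRate")
  out$acquisitionTime <- attr(events, "acquisitionTime")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readUmlTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "variable", "value") %in% names(d)))
    stop("UML CSV must have columns date, variable, value")
  dt <- as.Date(d$date)
  mIdx <- function(x) (as.integer(format(x, "%Y")) * 12L +
                         as.integer(format(x, "%m")) - 1L)
  idx0 <- min(mIdx(dt))
  lapply(split(d, d$variable), function(g) {
    gi <- mIdx(as.Date(g$date)) - idx0
    v <- rep(NA_real_, max(gi) + 1L)
    v[gi + 1L] <- g$value
    first <- as.Date(paste0(idx0 %/% 12L, "-",
                            sprintf("%02d", idx0 %% 12L + 1L), "-01"))
    monthlySeries(v, name = g$variable[1],
                  startYear = as.integer(format(first, "%Y")),
                  startMonth = as.integer(format(first, "%m")))
  })
}

#' @rdname pipeline-io
#' @param series a \linkS4class{MonthlySeries}.
#' @export
writeSeriesTable <- function(series, path) {
  dates <- sprintf("%04d-%02d-01", calendarYear(series),
                   calendarMonth(series))
  v <- series@values
  ok <- !is.na(v)
  utils::write.csv(data.frame(date = dates[ok],
                              variable = series@name,
                              value = v[ok]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Reference decadal variance ledger
#'
#' The published decadal variance-decomposition ledger for the monitored
#' coastal study site (upper-mixed-layer series, 120 months): per
#' variable, the climatological mean, linear trend slope/intercept,
#' annual-harmonic period/amplitude/phase/month-of-maximum,
#' autocorrelation lag and coefficient, and the percent variance of each
#' retained component. Used by the package's consistency checks: the
#' phase-to-maximum convention must reproduce the printed \code{tMax}
#' from (\code{theta}, \code{T}), and printed component percent variances
#' must sum to the printed totals. Abundance, size and biomass rows are on
#' the log10 scale.
#'
#' @return A \code{data.frame}, one row per variable; absent components
#'   are NA.
#' @examples
#' ref <- referenceLedger()
#' with(ref[1, ], tMax(theta, T))  # 8.14 vs printed 8.13
#' @export
referenceLedger <- function() {
  utils::read.csv(system.file("extdata", "reference_ledger.csv",
                              package = "bactoSeries"),
                  stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one validated list:
#' the significance level, the variables analysed on the log10 scale, the
#' mixed-layer density criterion (kg m-3 per 5 m), the stratification
#' reference depth (m), the seasonal window months, the RALS size
#' calibration, and the master seed. Round-trips through YAML unchanged.
#'
#' @param alpha significance level for all retention decisions.
#' @param log10Variables variable names analysed as log10.
#' @param mldThreshold density increase threshold, kg m-3 over 5 m.
#' @param siRefDepth stratification reference depth, m.
#' @param windowMonths seasonal window (subset of 1..12).
#' @param calibration list(logIntercept, logSlope, ralsRange).
#' @param redThreshold photosynthetic red-fluorescence exclusion (a.u.).
#' @param seed master integer seed.
#' @return A validated named list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(alpha = 0.05,
                           log10Variables = c("totalAbundance",
                                              "lnaAbundance",
                                              "hnaAbundance", "totalSize",
                                              "lnaSize", "hnaSize",
                                              "totalBiomass", "lnaBiomass",
                                              "hnaBiomass"),
                           mldThreshold = 0.05, siRefDepth = 75,
                           windowMonths = 4:7,
                           calibration = list(
                             logIntercept = log10(0.23),
                             logSlope = 0.25, ralsRange = c(0.5, 200)),
                           redThreshold = 100, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, mldThreshold > 0, siRefDepth > 0,
            all(windowMonths %in% 1:12), redThreshold > 0)
  cfg <- list(alpha = alpha, log10Variables = log10Variables,
              mldThreshold = mldThreshold, siRefDepth = siRefDepth,
              windowMonths = as.integer(windowMonths),
              calibration = calibration,
              redThreshold = redThreshold, seed = as.integer(seed))
  class(cfg) <- c("pipelineConfig", "list")
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML file path.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, raw)
}

#' @rdname pipelineConfig
#' @param config a \code{pipelineConfig}.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Hash of a pipeline configuration
#'
#' MD5 of the canonical YAML serialisation; stamped into every output so
#' results can be traced to the configuration that produced them.
#'
#' @param config a \code{pipelineConfig}.
#' @return Character MD5 hash.
#' @export
configHash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf, precision = 15)
  unname(tools::md5sum(tf))
}
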