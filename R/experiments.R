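#' Temperature response of cell size in one incubation
#'
#' Model I (ordinary least squares) regression of mean cell size on
#' incubation temperature for one month and one flow-cytometric group,
#' using per-bottle summary sizes. The slope (um3 per degC) estimates the
#' group's monthly size response to warming.
#'
#' @param records data.frame with columns \code{temperature} and
#'   \code{size} (and optionally \code{month}, \code{group}); one row per
#'   bottle.
#' @return A one-row \code{data.frame}: \code{month}, \code{group},
#'   \code{slope}, \code{slopeSe}, \code{intercept}, \code{r2}, \code{p},
#'   \code{n}.
#' @examples
#' ex <- generateExperiment(noiseSd = 0, seed = 1)
#' sizeTemperatureSlope(ex[ex$group == "HNA", ])  # slope -0.00091
#' @export
sizeTemperatureSlope <- function(records) {
  stopifnot(all(c("temperature", "size") %in% names(records)))
  if (nrow(records) < 3L)
    stop("regression needs at least 3 (temperature, size) points")
  if (length(unique(records$temperature)) < 2L)
    stop("regression needs more than one temperature level")
  if (any(records$size <= 0)) stop("cell sizes must be positive")
  fit <- stats::lm(size ~ temperature, data = records)
  sm <- summary(fit)
  data.frame(
    month = if ("month" %in% names(records))
      records$month[1] else NA_integer_,
    group = if ("group" %in% names(records))
      records$group[1] else NA_character_,
    slope = unname(stats::coef(fit)["temperature"]),
    slopeSe = sm$coefficients["temperature", "Std. Error"],
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r2 = sm$r.squared,
    p = sm$coefficients["temperature", "Pr(>|t|)"],
    n = nrow(records), stringsAsFactors = FALSE)
}

#' Monthly size-temperature slopes for both groups
#'
#' Applies \code{\link{sizeTemperatureSlope}} per (month, group) cell of a
#' full experiment table.
#'
#' @param records experiment data.frame with columns \code{month},
#'   \code{group}, \code{temperature}, \code{size}.
#' @return A \code{data.frame} of slope results, one row per month and
#'   group.
#' @export
monthlySlopes <- function(records) {
  parts <- split(records, list(records$month, records$group), drop = TRUE)
  out <- do.call(rbind, lapply(parts, sizeTemperatureSlope))
  rownames(out) <- NULL
  out[order(out$group, out$month), ]
}

#' Regression of HNA on LNA monthly temperature responses
#'
#' OLS of the HNA monthly size-temperature slopes on the matched LNA
#' slopes, quantifying how much more strongly HNA cell size responds to
#' warming than LNA cell size across the year.
#'
#' @param lnaSlopes,hnaSlopes data.frames from
#'   \code{\link{sizeTemperatureSlope}}/\code{\link{monthlySlopes}} with
#'   columns \code{month} and \code{slope}.
#' @return A one-row \code{data.frame}: \code{slope}, \code{slopeSe},
#'   \code{intercept}, \code{r2}, \code{p}, \code{n}.
#' @export
crossGroupSlopeRegression <- function(lnaSlopes, hnaSlopes) {
  m <- merge(lnaSlopes[, c("month", "slope")],
             hnaSlopes[, c("month", "slope")],
             by = "month", suffixes = c(".lna", ".hna"))
  if (nrow(m) < 3L) stop("fewer than 3 matched months")
  fit <- stats::lm(slope.hna ~ slope.lna, data = m)
  sm <- summary(fit)
  data.frame(slope = unname(stats::coef(fit)["slope.lna"]),
             slopeSe = sm$coefficients["slope.lna", "Std. Error"],
             intercept = unname(stats::coef(fit)["(Intercept)"]),
             r2 = sm$r.squared,
             p = sm$coefficients["slope.lna", "Pr(>|t|)"],
             n = nrow(m))
}

#' Seasonal-window annual means of a monthly series
#'
#' Averages a series over a set of calendar months (e.g. April--July)
#' within each analysis year. Analysis years run April--March, so that a
#' sampling campaign starting in April forms complete years; the year
#' label is the calendar year of the April. Years with no observed window
#' month are dropped.
#'
#' @param series a \linkS4class{MonthlySeries} spanning >= 2 years.
#' @param window calendar months (subset of 1..12), default April--July.
#' @param yearStartMonth first month of the analysis year (default 4).
#' @return A \code{data.frame}: \code{year}, \code{mean}, \code{se},
#'   \code{nMonths}.
#' @examples
#' s <- generateScenarioSeries("temperature", seed = 1)
#' windowMeanSeries(s, window = 4:7)
#' @export
windowMeanSeries <- function(series, window = 4:7, yearStartMonth = 4L) {
  stopifnot(is(series, "MonthlySeries"), length(window) >= 1L,
            all(window %in% 1:12))
  if (length(series@values) < 24L)
    stop("window means need a series spanning at least 2 years")
  m <- calendarMonth(series)
  y <- calendarYear(series)
  analysisYear <- ifelse(m >= yearStartMonth, y, y - 1L)
  v <- series@values
  sel <- m %in% window & !is.na(v)
  if (!any(sel)) stop("no observed months inside the window")
  agg <- tapply(v[sel], analysisYear[sel], function(z)
    c(mean = mean(z), se = stats::sd(z) / sqrt(length(z)),
      n = length(z)))
  out <- data.frame(year = as.integer(names(agg)),
                    mean = vapply(agg, `[[`, numeric(1), "mean"),
                    se = vapply(agg, `[[`, numeric(1), "se"),
                    nMonths = vapply(agg, `[[`, numeric(1), "n"))
  rownames(out) <- NULL
  out
}

#' Decadal trend of annual (window) means
#'
#' OLS regression of annual means against year, the standard presentation
#' of decadal trends. The slope is in series units per year.
#'
#' @param annualMeans data.frame with columns \code{year} and \code{mean}
#'   (as from \code{\link{windowMeanSeries}}).
#' @return A one-row \code{data.frame}: \code{slope}, \code{slopeSe},
#'   \code{intercept}, \code{r2}, \code{p}, \code{n},
#'   \code{decadalChange} (slope x span in years).
#' @export
annualTrend <- function(annualMeans) {
  stopifnot(all(c("year", "mean") %in% names(annualMeans)))
  ok <- !is.na(annualMeans$mean)
  if (sum(ok) < 5L) stop("decadal trend needs >= 5 annual means")
  d <- annualMeans[ok, ]
  fit <- stats::lm(mean ~ year, data = d)
  sm <- summary(fit)
  span <- diff(range(d$year))
  data.frame(slope = unname(stats::coef(fit)["year"]),
             slopeSe = sm$coefficients["year", "Std. Error"],
             intercept = unname(stats::coef(fit)["(Intercept)"]),
             r2 = sm$r.squared,
             p = sm$coefficients["year", "Pr(>|t|)"],
             n = nrow(d),
             decadalChange = unname(stats::coef(fit)["year"]) * span)
}

#' Projected community cell-size change under warming
#'
#' Applies per-group size responses to warming to baseline sizes and
#' aggregates to a community percent change:
#' \deqn{100 \sum_g w_g \frac{\mathrm{slope}_g \times
#'   \Delta T}{\mathrm{baseline}_g}.}
#' The aggregation weights are not uniquely defined by the source
#' analyses, so both a composition-weighted and an unweighted (equal
#' weights) call are natural; pass the weights explicitly.
#'
#' @param slopes named numeric, um3 per degC per group.
#' @param warming temperature increase, degC.
#' @param baselines named numeric, baseline sizes um3 (> 0).
#' @param weights named numeric weights summing to 1 (default equal).
#' @return Percent size change (negative = shrinking).
#' @examples
#' projectedSizeChange(c(g = -0.0005), 2, c(g = 0.05), c(g = 1))  # -2
#' @export
projectedSizeChange <- function(slopes, warming, baselines,
                                weights = NULL) {
  g <- names(slopes)
  if (is.null(weights))
    weights <- stats::setNames(rep(1 / length(g), length(g)), g)
  if (any(baselines[g] <= 0)) stop("baselines must be positive")
  if (abs(sum(weights[g]) - 1) > 1e-8) stop("weights must sum to 1")
  100 * sum(weights[g] * slopes[g] * warming / baselines[g])
}
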