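#' Pre-whitened residuals of a fitted series
#'
#' Removes everything the decomposition modelled: climatological mean,
#' linear trend, all retained harmonics, and the autoregressive
#' dependence (\eqn{\varepsilon_t = \eta_t - \phi\,\eta_{t-lag}}). The
#' result is the residual series suitable for cross-variable correlation,
#' free of the seasonal and long-term structure that would otherwise
#' produce spurious associations.
#'
#' @param series the \linkS4class{MonthlySeries} that was decomposed.
#' @param fit the matching \linkS4class{SeriesDecomposition}.
#' @return A \linkS4class{MonthlySeries} of residuals (same calendar
#'   anchor; NA at gaps and at months without a lagged AR predecessor).
#' @examples
#' s <- generateScenarioSeries("temperature", seed = 1)
#' r <- prewhiten(s, decomposeSeries(s))
#' mean(seriesValues(r), na.rm = TRUE)  # ~ 0
#' @export
prewhiten <- function(series, fit) {
  stopifnot(is(series, "MonthlySeries"), is(fit, "SeriesDecomposition"))
  if (length(series@values) != length(fit@series@values) ||
      !isTRUE(all.equal(series@values, fit@series@values)))
    stop("fit was not produced from this series")
  monthlySeries(fit@residuals,
                name = paste0(series@name, ".resid"),
                units = series@units, log10 = series@log10,
                startYear = series@startYear,
                startMonth = series@startMonth)
}

#' Significance stars for a p-value
#'
#' \code{***} for p < 0.001, \code{**} for p < 0.01, \code{*} for
#' p < 0.05, \code{ns} otherwise.
#'
#' @param p p-value(s).
#' @return Character vector of bands.
#' @export
pValueStars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "ns")))
}

#' Correlate two pre-whitened residual series
#'
#' Pearson correlation on month-matched pairs (pairwise-complete, no
#' imputation), with the two-tailed p-value from the t transform on
#' n - 2 degrees of freedom and the conventional significance band.
#'
#' @param a,b \linkS4class{MonthlySeries} residual series (or numeric
#'   vectors) on the same monthly grid.
#' @param minPairs minimum number of common months (default 10).
#' @return A one-row \code{data.frame}: \code{r}, \code{p}, \code{n},
#'   \code{stars}.
#' @export
correlateResiduals <- function(a, b, minPairs = 10L) {
  va <- if (is(a, "MonthlySeries")) a@values else as.numeric(a)
  vb <- if (is(b, "MonthlySeries")) b@values else as.numeric(b)
  if (length(va) != length(vb))
    stop("residual series must share the monthly grid")
  ok <- !is.na(va) & !is.na(vb)
  n <- sum(ok)
  if (n < minPairs)
    stop(sprintf("fewer than %d common months", minPairs))
  if (stats::sd(va[ok]) == 0 || stats::sd(vb[ok]) == 0) {
    warning("zero-variance residual series; correlation undefined")
    return(data.frame(r = NA_real_, p = NA_real_, n = n, stars = "ns"))
  }
  ct <- stats::cor.test(va[ok], vb[ok], method = "pearson",
                        alternative = "two.sided")
  data.frame(r = unname(ct$estimate), p = ct$p.value, n = n,
             stars = pValueStars(ct$p.value))
}

#' Correlation matrix of pre-whitened residuals
#'
#' Full cross-table of Pearson correlations between two sets of residual
#' series (rows x columns), each cell computed on pairwise-complete months
#' with its own n. By default only significant cells are reported (the
#' rest dashed, mirroring the conventional presentation); set
#' \code{onlySignificant = FALSE} to report all. An optional
#' Benjamini--Hochberg adjustment across cells is available but off by
#' default, mirroring the unadjusted convention.
#'
#' @param rows,cols named lists of residual \linkS4class{MonthlySeries}
#'   (or numeric vectors on a common grid).
#' @param alpha significance level for the dash convention.
#' @param onlySignificant logical; blank non-significant cells.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return A long-format \code{data.frame} with columns \code{row},
#'   \code{col}, \code{r}, \code{p}, \code{n}, \code{stars},
#'   \code{display} (formatted "r stars" or "-").
#' @export
correlationMatrix <- function(rows, cols, alpha = 0.05,
                              onlySignificant = TRUE,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  grid <- expand.grid(row = names(rows), col = names(cols),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  recs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    correlateResiduals(rows[[grid$row[i]]], cols[[grid$col[i]]])
  }))
  out <- cbind(grid, recs)
  if (adjust == "BH") {
    out$p <- stats::p.adjust(out$p, method = "BH")
    out$stars <- pValueStars(out$p)
  }
  out$display <- ifelse(!is.na(out$p) & out$p < alpha,
                        sprintf("%.2f%s", out$r,
                                sub("^ns$", "", out$stars)),
                        if (onlySignificant) "-" else
                          sprintf("%.2f", out$r))
  if (onlySignificant)
    out$display[is.na(out$p) | out$p >= alpha] <- "-"
  out
}
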