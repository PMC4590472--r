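#' Mixed-layer depth from a density cast
#'
#' The upper-mixed-layer depth is the shallowest sampled depth \eqn{z} at
#' which the density increase over the following 5 m first reaches the
#' threshold (default 0.05 kg m-3). Candidates are the sampled (bottle)
#' depths; the density at \eqn{z + 5} m is obtained by linear
#' interpolation between sampled depths. Evaluating at sampled depths
#' keeps a sharp pycnocline attributed to the last mixed bottle rather
#' than to an interpolated depth above it. If no crossing exists (a
#' homogeneous cast) the deepest sampled depth is returned by convention.
#'
#' @param profile a \linkS4class{CtdProfile}.
#' @param threshold density increase threshold, kg m-3 over \code{dz} m.
#' @param dz vertical span of the density comparison, m (default 5).
#' @return Mixed-layer depth in m.
#' @examples
#' mixedLayerDepth(generateProfile(15))
#' @export
mixedLayerDepth <- function(profile, threshold = 0.05, dz = 5) {
  stopifnot(is(profile, "CtdProfile"), threshold > 0, dz > 0)
  d <- profile@depth
  rho <- profile@density
  ok <- !is.na(rho)
  if (sum(ok) < 2L) stop("unusable cast: fewer than two density levels")
  d <- d[ok]; rho <- rho[ok]
  if (max(d) - min(d) < dz)
    stop(sprintf("unusable cast: density levels span less than %g m", dz))
  zCand <- d[d + dz <= max(d)]
  rhoAt <- function(z) stats::approx(d, rho, xout = z)$y
  crossing <- (rhoAt(zCand + dz) - rho[seq_along(zCand)]) >= threshold
  if (!any(crossing)) return(max(d))
  zCand[which(crossing)[1L]]
}

#' Stratification index of a cast
#'
#' Per-metre temperature difference between the surface and a reference
#' depth (75 m): \eqn{(T_{surf} - T_{ref}) / ref}. The surface value is
#' taken at the shallowest sampled depth, which must be within 5 m of the
#' surface; the reference value is linearly interpolated. Negative values
#' (winter inversion) are allowed.
#'
#' @param profile a \linkS4class{CtdProfile}.
#' @param refDepth reference depth, m (default 75).
#' @return Stratification index in degC m-1.
#' @examples
#' p <- generateProfile(15, surfaceT = 20, deepT = 12.5)
#' stratificationIndex(p)  # (20 - 12.5) / 75 = 0.1
#' @export
stratificationIndex <- function(profile, refDepth = 75) {
  stopifnot(is(profile, "CtdProfile"), refDepth > 0)
  d <- profile@depth
  temp <- profile@temperature
  ok <- !is.na(temp)
  d <- d[ok]; temp <- temp[ok]
  if (length(d) < 2L) stop("unusable cast: fewer than two temperature levels")
  if (min(d) > 5)
    stop("no surface level: shallowest temperature sample deeper than 5 m")
  if (max(d) < refDepth)
    stop(sprintf("cast shallower than the %g m reference depth", refDepth))
  tSurf <- temp[which.min(d)]
  tRef <- stats::approx(d, temp, xout = refDepth)$y
  (tSurf - tRef) / refDepth
}

#' Upper-mixed-layer average of a cast variable
#'
#' Unweighted mean of a variable over the sampled depths within
#' \code{[0, mld]}. Depths below the mixed layer never enter the average.
#'
#' @param profile a \linkS4class{CtdProfile}.
#' @param mld mixed-layer depth, m.
#' @param variable one of \code{"temperature"}, \code{"density"}, or the
#'   name of a column of the profile's extra variables.
#' @return The mean over in-layer sampled depths.
#' @export
umlAverage <- function(profile, mld, variable = "temperature") {
  stopifnot(is(profile, "CtdProfile"), mld > 0)
  v <- switch(variable,
              temperature = profile@temperature,
              density = profile@density,
              {
                if (!variable %in% names(profile@extra))
                  stop(sprintf("variable '%s' not present in cast", variable))
                profile@extra[[variable]]
              })
  inLayer <- profile@depth <= mld & !is.na(v)
  if (!any(inLayer))
    stop(sprintf("no sampled depth within the %g m mixed layer", mld))
  mean(v[inLayer])
}

#' Summarise a cast over its upper mixed layer
#'
#' Applies the mixed-layer-depth rule, the stratification index (when the
#' cast reaches the reference depth) and the in-layer average of every
#' requested variable.
#'
#' @param profile a \linkS4class{CtdProfile}.
#' @param variables variables to average (default: temperature plus every
#'   extra column).
#' @param threshold,dz,refDepth passed to \code{\link{mixedLayerDepth}} and
#'   \code{\link{stratificationIndex}}.
#' @return A one-row \code{data.frame}: \code{mld},
#'   \code{stratificationIndex} (NA for shallow casts) and one column per
#'   averaged variable.
#' @export
umlSummary <- function(profile, variables = NULL, threshold = 0.05,
                       dz = 5, refDepth = 75) {
  stopifnot(is(profile, "CtdProfile"))
  if (is.null(variables))
    variables <- c("temperature", names(profile@extra))
  mld <- mixedLayerDepth(profile, threshold = threshold, dz = dz)
  si <- tryCatch(stratificationIndex(profile, refDepth = refDepth),
                 error = function(e) NA_real_)
  out <- data.frame(mld = mld, stratificationIndex = si)
  for (v in variables)
    out[[v]] <- umlAverage(profile, mld, v)
  out
}
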