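#' Gate events into LNA and HNA groups
#'
#' Splits bacterioplankton events into low and high nucleic-acid content
#' groups by two-cluster k-means on the (log10 green fluorescence, log10
#' right-angle light scatter) plane; the cluster with the higher mean green
#' fluorescence is HNA, since the nucleic-acid stain drives that channel.
#' Events whose red (photosynthetic pigment) fluorescence exceeds
#' \code{redThreshold} are excluded first, so that naturally fluorescent
#' picocyanobacteria such as Prochlorococcus cannot contaminate the HNA
#' cluster; they are labelled \code{NA}.
#'
#' Initial cluster centers are placed deterministically at the lower and
#' upper green-fluorescence quartiles, so gating is reproducible without
#' touching the random-number stream. Degenerate data that cannot support
#' two clusters are labelled as a single LNA group with attribute
#' \code{singleCluster = TRUE}.
#'
#' @param events data.frame with columns \code{green}, \code{rals},
#'   \code{red} (all positive).
#' @param redThreshold red-fluorescence exclusion threshold (a.u.);
#'   \code{Inf} disables the guard.
#' @param minEvents minimum events required to gate.
#' @return Factor of labels (\code{"LNA"}/\code{"HNA"}, \code{NA} for
#'   excluded events) with attribute \code{singleCluster}.
#' @examples
#' ev <- generateCytogram(200, seed = 1)
#' table(gateLnaHna(ev), ev$trueGroup)
#' @export
gateLnaHna <- function(events, redThreshold = 100, minEvents = 50L) {
  stopifnot(all(c("green", "rals", "red") %in% names(events)))
  if (any(events$green < 0 | events$rals < 0 | events$red < 0,
          na.rm = TRUE))
    stop("channel values must be non-negative")
  keep <- events$red <= redThreshold
  labels <- factor(rep(NA_character_, nrow(events)),
                   levels = c("LNA", "HNA"))
  n <- sum(keep)
  if (n < minEvents)
    stop(sprintf("too few bacterial events to gate (%d < %d)", n, minEvents))
  lg <- log10(pmax(events$green[keep], .Machine$double.eps))
  lr <- log10(pmax(events$rals[keep], .Machine$double.eps))
  X <- cbind(green = lg, rals = lr)

  # deterministic initial centers at the green-fluorescence quartiles
  qs <- stats::quantile(lg, c(0.25, 0.75), names = FALSE)
  centers <- rbind(c(qs[1], stats::median(lr)), c(qs[2], stats::median(lr)))
  single <- FALSE
  if (diff(qs) < sqrt(.Machine$double.eps)) {
    single <- TRUE
    cl <- rep(1L, n)
  } else {
    km <- tryCatch(stats::kmeans(X, centers = centers),
                   error = function(e) NULL,
                   warning = function(w) NULL)
    if (is.null(km) || length(unique(km$cluster)) < 2L) {
      single <- TRUE
      cl <- rep(1L, n)
    } else {
      cl <- km$cluster
      hnaCluster <- which.max(tapply(lg, cl, mean))
      cl <- as.integer(cl == hnaCluster) + 1L  # 1 = LNA, 2 = HNA
    }
  }
  labels[keep] <- c("LNA", "HNA")[cl]
  attr(labels, "singleCluster") <- single
  labels
}

#' Abundance per cytometric group
#'
#' Cell concentration per group from event counts and the analysed sample
#' volume, \code{flowRate} (ul min-1) x \code{acquisitionTime} (s).
#'
#' @param events event data.frame carrying \code{flowRate} and
#'   \code{acquisitionTime} attributes (as from
#'   \code{\link{generateCytogram}}), unless given explicitly.
#' @param labels group labels as returned by \code{\link{gateLnaHna}}.
#' @param flowRate,acquisitionTime metadata overrides.
#' @return Named numeric: cells mL-1 for \code{LNA}, \code{HNA} and
#'   \code{total}.
#' @export
cytometryAbundance <- function(events, labels,
                               flowRate = attr(events, "flowRate"),
                               acquisitionTime = attr(events,
                                                      "acquisitionTime")) {
  if (is.null(flowRate) || is.null(acquisitionTime))
    stop("flow-rate and acquisition-time metadata are required")
  if (flowRate <= 0 || acquisitionTime <= 0)
    stop("analysed volume must be positive")
  volumeMl <- flowRate * (acquisitionTime / 60) / 1000  # ul -> ml
  counts <- table(factor(labels, levels = c("LNA", "HNA")))
  ab <- as.numeric(counts) / volumeMl
  c(LNA = ab[1], HNA = ab[2], total = sum(ab))
}

#' Convert mean RALS to cell volume
#'
#' Maps the group-mean right-angle light scatter to a cell diameter via
#' the power-law calibration and converts to volume assuming spherical
#' cells: \eqn{V = (\pi/6) d^3}.
#'
#' @param meanRals mean RALS of the group, a.u. (bead-normalised).
#' @param cal a \linkS4class{SizeCalibration}.
#' @return Cell volume in um3.
#' @examples
#' # a calibration mapping RALS 10 to d = 0.5 um:
#' cal <- sizeCalibration(logIntercept = log10(0.5) - 0.25, logSlope = 0.25,
#'                        ralsRange = c(1, 100))
#' ralsToVolume(10, cal)  # (pi/6) * 0.5^3 = 0.0654
#' @export
ralsToVolume <- function(meanRals, cal = defaultSizeCalibration()) {
  stopifnot(is(cal, "SizeCalibration"), all(meanRals > 0))
  if (any(meanRals < cal@ralsRange[1] | meanRals > cal@ralsRange[2]))
    warning("mean RALS outside the calibrated range; extrapolating")
  d <- 10^(cal@logIntercept + cal@logSlope * log10(meanRals))
  (pi / 6) * d^3
}

#' Carbon content of a cell from its volume
#'
#' Allometric carbon conversion \eqn{\mathrm{pg\,C\,cell^{-1}} = 0.12
#' \times V^{0.72}} with \eqn{V} in um3.
#'
#' @param volume cell volume, um3 (> 0).
#' @return Carbon per cell, pg C.
#' @examples
#' biomassPerCell(1)     # 0.12
#' biomassPerCell(0.05)  # 0.0139
#' @export
biomassPerCell <- function(volume) {
  if (any(volume <= 0)) stop("cell volume must be positive")
  0.12 * volume^0.72
}

#' Biomass concentration from abundance and cell volume
#'
#' \eqn{\mathrm{\mu g\,C\,l^{-1}}} = abundance (cells mL-1) x carbon per
#' cell (pg C) x 1e-3 (pg mL-1 to ug L-1).
#'
#' @param abundance cells mL-1 (>= 0).
#' @param volume mean cell volume, um3 (> 0).
#' @return Biomass in ug C L-1.
#' @examples
#' biomassConcentration(1e6, 1)  # 120
#' @export
biomassConcentration <- function(abundance, volume) {
  if (any(abundance < 0)) stop("abundance must be non-negative")
  abundance * biomassPerCell(volume) * 1e-3
}

#' Biovolume of a rod-shaped cell from length and width
#'
#' Volume of a cylinder with hemispherical caps,
#' \eqn{V = (\pi/4) w^2 (l - w/3)}, the standard conversion for length and
#' width measured by image analysis of DAPI-stained cells. For cocci
#' (\eqn{l = w = d}) it reduces to the sphere \eqn{(\pi/6) d^3}.
#'
#' @param length cell length, um.
#' @param width cell width, um (0 < width <= length).
#' @return Biovolume in um3.
#' @examples
#' biovolumeFromDimensions(1, 0.5)  # 0.1636
#' @export
biovolumeFromDimensions <- function(length, width) {
  if (any(width <= 0)) stop("width must be positive")
  if (any(width > length)) stop("width cannot exceed length")
  (pi / 4) * width^2 * (length - width / 3)
}

#' Standing stocks per cytometric group from an event table
#'
#' Gates events, computes per-group abundance, converts the group-mean
#' RALS to mean cell size via the calibration (total size is the
#' abundance-weighted mean of the group sizes), and derives biomass
#' through the allometric carbon conversion.
#'
#' @param events event data.frame with metadata attributes.
#' @param cal a \linkS4class{SizeCalibration}.
#' @param redThreshold passed to \code{\link{gateLnaHna}}.
#' @return A \code{data.frame} with one row per group (LNA, HNA, total)
#'   and columns \code{group}, \code{abundance} (cells mL-1), \code{size}
#'   (um3) and \code{biomass} (ug C L-1).
#' @examples
#' populationStats(generateCytogram(1000, seed = 1))
#' @export
populationStats <- function(events, cal = defaultSizeCalibration(),
                            redThreshold = 100) {
  labels <- gateLnaHna(events, redThreshold = redThreshold)
  ab <- cytometryAbundance(events, labels)
  meanRals <- tapply(events$rals, labels, mean)
  sizes <- c(LNA = NA_real_, HNA = NA_real_)
  for (g in c("LNA", "HNA"))
    if (!is.na(meanRals[g]))
      sizes[g] <- ralsToVolume(meanRals[[g]], cal)
  wTot <- ab[c("LNA", "HNA")] / max(ab[["total"]], .Machine$double.eps)
  sizeTot <- if (ab[["total"]] > 0)
    sum(wTot * sizes, na.rm = TRUE) else NA_real_
  out <- data.frame(
    group = c("LNA", "HNA", "total"),
    abundance = c(ab[["LNA"]], ab[["HNA"]], ab[["total"]]),
    size = c(sizes[["LNA"]], sizes[["HNA"]], sizeTot),
    stringsAsFactors = FALSE)
  out$biomass <- ifelse(out$abundance > 0 & !is.na(out$size),
                        biomassConcentration(out$abundance,
                                             pmax(out$size, 1e-12)), 0)
  if (any(!is.na(out$size) & (out$size < 0.01 | out$size > 0.5)))
    warning("mean cell size outside the plausible 0.01-0.5 um3 band")
  out
}
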