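#' @include AllClasses.R accessors.R
NULL

## cumulative "at least" counts: percent of v >= each threshold d
cumAtLeast <- function(v, d) {
  sv <- sort(v)
  100 * (length(sv) - findInterval(d, sv, left.open = TRUE)) / length(sv)
}

#' Cumulative dose-volume histogram
#'
#' \code{ordinate(d) = 100 * |{v in mask : dose(v) >= d}| / |mask|},
#' evaluated on an equal-interval dose grid from 0 to the maximum dose in
#' the mask. Bin edges use ">=", so the curve always starts at 100% at zero
#' dose. A structure receiving no dose at all yields the degenerate
#' single-point curve (0, 100).
#'
#' @param dose a \linkS4class{DoseGrid}.
#' @param mask nonempty logical array on the same grid.
#' @param nBins number of abscissa samples (>= 2); the default keeps the
#'   interpolation error far below the evaluation metric tolerances.
#' @param structure structure name stored on the curve.
#' @return a \linkS4class{CumHist} of kind \code{"DVH"}.
#' @examples
#' g <- gridSpec(c(8, 8, 8))
#' d <- array(0, gridShape(g)); d[1:4] <- c(10, 20, 30, 40)
#' m <- array(FALSE, gridShape(g)); m[1:4] <- TRUE
#' dg <- new("DoseGrid", grid = g, values = d, label = "demo")
#' volumeAtDose(computeDVH(dg, m, 1001), 25) # 50%
#' @export
computeDVH <- function(dose, mask, nBins = 1000L, structure = "structure") {
  if (!any(mask))
    stop("empty mask for structure '", structure, "'")
  if (nBins < 2L) stop("'nBins' must be >= 2")
  v <- dose@values[mask]
  dmax <- max(v)
  if (dmax <= 0) {
    return(new("CumHist", kind = "DVH", abscissa = 0, ordinate = 100,
               structure = structure, sourceLabel = dose@label))
  }
  d <- seq(0, dmax, length.out = nBins)
  new("CumHist", kind = "DVH", abscissa = d, ordinate = cumAtLeast(v, d),
      structure = structure, sourceLabel = dose@label)
}

#' Signed distance-to-target histogram
#'
#' For every OAR voxel centre the signed Euclidean distance to the PTV
#' surface is computed (negative inside the PTV, positive outside,
#' anisotropic spacing respected, via two distance transforms on the voxel
#' lattice); the curve gives the percent of OAR volume within each signed
#' distance, on an equal-interval grid spanning the observed range.
#'
#' @param oarMask,ptvMask nonempty logical arrays on \code{grid}.
#' @param grid a \linkS4class{GridSpec}.
#' @param nBins number of abscissa samples.
#' @param structure,target names stored on the curve.
#' @return a \linkS4class{CumHist} of kind \code{"DTH"}.
#' @export
computeDTH <- function(oarMask, ptvMask, grid, nBins = 1000L,
                       structure = "structure", target = "PTV") {
  if (!any(oarMask)) stop("empty OAR mask for structure '", structure, "'")
  if (!any(ptvMask)) stop("empty PTV mask '", target, "'")
  if (nBins < 2L) stop("'nBins' must be >= 2")
  sd <- signedDistance(ptvMask, grid)[oarMask]
  lo <- min(sd); hi <- max(sd)
  if (hi - lo < .Machine$double.eps) {
    return(new("CumHist", kind = "DTH", abscissa = hi, ordinate = 100,
               structure = structure, sourceLabel = target))
  }
  r <- seq(lo, hi, length.out = nBins)
  ssd <- sort(sd)
  ord <- 100 * findInterval(r, ssd) / length(ssd)
  ord[length(ord)] <- 100 # guard against fp noise at the right endpoint
  new("CumHist", kind = "DTH", abscissa = r, ordinate = ord,
      structure = structure, sourceLabel = target)
}

#' Dose at volume (Dy)
#'
#' The dose received by at least \code{y} percent of the structure: the
#' abscissa where the cumulative DVH crosses \code{y}, with linear
#' interpolation between samples. On flat segments the tie is broken
#' towards the largest dose for y = 100 and the smallest dose for y = 0,
#' so \code{D0} is the maximum voxel dose. A \code{y} outside the curve's
#' ordinate range returns the nearest boundary dose with a warning.
#'
#' @param curve a DVH \linkS4class{CumHist}.
#' @param yPct volume percentage in [0, 100].
#' @return dose in the curve's abscissa units.
#' @export
doseAtVolume <- function(curve, yPct) {
  if (curve@kind != "DVH") stop("dose_at_volume requires a DVH curve")
  if (yPct < 0 || yPct > 100) stop("'yPct' must be in [0, 100]")
  a <- curve@abscissa
  o <- curve@ordinate
  n <- length(o)
  if (n == 1L) return(a[1])
  if (yPct > o[1]) {
    warning("requested volume exceeds the curve's range; returning minimum dose")
    return(a[1])
  }
  if (yPct >= o[1]) { # == o[1]: largest dose still at the top ordinate
    i <- max(which(o >= o[1] - 1e-12))
    return(a[i])
  }
  if (yPct < o[n]) {
    if (yPct > 0)
      warning("requested volume below the curve's range; returning maximum dose")
    return(a[n])
  }
  i <- max(which(o > yPct)) # last sample above y
  if (i == n) return(a[n])
  if (o[i] == o[i + 1]) return(a[i + 1])
  a[i] + (o[i] - yPct) / (o[i] - o[i + 1]) * (a[i + 1] - a[i])
}

#' Volume at dose (Vx)
#'
#' The percent volume receiving at least \code{x}: the DVH ordinate at
#' \code{x}, linearly interpolated, and 0 beyond the largest abscissa.
#'
#' @param curve a DVH \linkS4class{CumHist}.
#' @param xGy dose (same units as the curve abscissa), >= 0.
#' @return volume percentage.
#' @export
volumeAtDose <- function(curve, xGy) {
  if (curve@kind != "DVH") stop("volume_at_dose requires a DVH curve")
  if (xGy < 0) stop("'xGy' must be >= 0")
  a <- curve@abscissa
  o <- curve@ordinate
  if (xGy > a[length(a)]) return(0)
  if (length(a) == 1L) return(o[1])
  stats::approx(a, o, xout = xGy, rule = 2, ties = "ordered")$y
}
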