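#' @include AllClasses.R accessors.R
NULL

#' Construct a BeamSet
#'
#' Site presets follow the nine-field arrangements used for the two disease
#' sites: the HN preset uses the fixed IMRT gantry angles 160, 120, 80, 40,
#' 0, 200, 240, 280 and 320 degrees with every aperture fitted to PTV54; the
#' PELVIS preset approximates an arc with nine equally spaced fields (0,
#' 40, ..., 320) fitted to PTV45. All fields share one weight.
#'
#' @param site preset, \code{"HN"} or \code{"PELVIS"}.
#' @param gantryAnglesDeg override the preset angles.
#' @param fitTarget override the preset fit target.
#' @param apertureMarginCm aperture expansion beyond the projected target (cm).
#' @param muPerCm effective linear attenuation coefficient (1/cm).
#' @param penumbraSigmaCm Gaussian penumbra width (cm).
#' @param fieldWeight common field weight.
#' @return a \linkS4class{BeamSet}.
#' @export
beamSet <- function(site = c("HN", "PELVIS"), gantryAnglesDeg = NULL,
                    fitTarget = NULL, apertureMarginCm = 0.5,
                    muPerCm = 0.05, penumbraSigmaCm = 0.3,
                    fieldWeight = 1) {
  site <- match.arg(site)
  if (is.null(gantryAnglesDeg))
    gantryAnglesDeg <- if (site == "HN")
      c(160, 120, 80, 40, 0, 200, 240, 280, 320)
    else seq(0, 320, by = 40)
  if (is.null(fitTarget)) fitTarget <- if (site == "HN") "PTV54" else "PTV45"
  new("BeamSet", gantryAnglesDeg = as.numeric(gantryAnglesDeg),
      fitTarget = fitTarget, apertureMarginCm = apertureMarginCm,
      muPerCm = muPerCm, penumbraSigmaCm = penumbraSigmaCm,
      fieldWeight = fieldWeight)
}

#' Dose of one uniform-intensity conformal field
#'
#' Parallel-beam model: the aperture is the beam's-eye-view projection of
#' the fit target (a per-slice lateral interval, like per-slice conformal
#' leaf fitting), expanded by the aperture margin and edge-softened by a
#' Gaussian penumbra; the dose decays exponentially with the in-body depth
#' along the beam axis, \code{dose = D0 * T * exp(-mu * depth)}, and is zero
#' outside the body. \code{D0} is chosen so the maximum dose inside the fit
#' target is 1 (arbitrary units, before any plan-level scaling).
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param angleDeg gantry angle in degrees; values outside [0, 360) are
#'   normalized with a warning.
#' @param beams a \code{\link{beamSet}}.
#' @return a \linkS4class{DoseGrid} labelled \code{FIELD_<angle>}.
#' @export
fieldDose <- function(phantom, angleDeg, beams) {
  if (angleDeg < 0 || angleDeg >= 360) {
    angleDeg <- angleDeg %% 360
    warning("gantry angle normalized to ", angleDeg, " degrees")
  }
  tgt <- structureMask(phantom, beams@fitTarget)
  if (!any(tgt)) stop("fit target '", beams@fitTarget, "' is empty")
  body <- structureMask(phantom, "body")
  grid <- phantom@grid
  raw <- cpp_field_dose(as.logical(body), as.logical(tgt), dim3(grid),
                        grid@spacing, angleDeg, beams@apertureMarginCm,
                        beams@penumbraSigmaCm, beams@muPerCm)
  raw <- array(raw, dim3(grid))
  d0 <- max(raw[tgt])
  if (d0 <= 0) stop("fit target '", beams@fitTarget, "' receives no dose")
  new("DoseGrid", grid = grid, values = raw / d0,
      label = sprintf("FIELD_%03d", as.integer(round(angleDeg))))
}

#' Equal-weight conformal plan dose
#'
#' Sums all field doses with equal weight and scales the sum globally so
#' the median dose inside the highest-dose PTV equals the prescription.
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param beams a \code{\link{beamSet}}.
#' @param prescriptionGy prescription dose in Gy.
#' @param fields optional precomputed list of \linkS4class{DoseGrid}, one
#'   per gantry angle (to avoid recomputation).
#' @return a \linkS4class{DoseGrid} labelled \code{CONFORMAL_PLAN}.
#' @export
conformalPlan <- function(phantom, beams, prescriptionGy, fields = NULL) {
  if (is.null(fields))
    fields <- lapply(beams@gantryAnglesDeg,
                     function(a) fieldDose(phantom, a, beams))
  total <- Reduce(`+`, lapply(fields, function(f) f@values)) *
    beams@fieldWeight
  ptvHi <- structureMask(phantom, ptvNames(phantom)[1])
  med <- stats::median(total[ptvHi])
  if (med <= 0) stop("highest PTV receives no conformal dose")
  new("DoseGrid", grid = phantom@grid,
      values = total * (prescriptionGy / med), label = "CONFORMAL_PLAN")
}

#' Default pseudo-clinical sparing parameters
#'
#' @return list with \code{sRange} (per-patient OAR sparing strength drawn
#'   uniformly from this range), \code{lambdaCm} (sparing fall-off length),
#'   \code{noiseSd} (relative smooth in-target noise) and
#'   \code{hotspotFactor} (target D1 as a multiple of the prescription).
#' @export
sparingParams <- function(sRange = c(0.2, 0.5), lambdaCm = 2.0,
                          noiseSd = 0.02, hotspotFactor = 1.06) {
  if (length(sRange) != 2 || any(sRange < 0) || any(sRange > 1) ||
      sRange[1] > sRange[2])
    stop("'sRange' must be an increasing range within [0, 1]")
  if (lambdaCm <= 0) stop("'lambdaCm' must be > 0")
  if (noiseSd < 0) stop("'noiseSd' must be >= 0")
  if (hotspotFactor < 1) stop("'hotspotFactor' must be >= 1")
  list(sRange = sRange, lambdaCm = lambdaCm, noiseSd = noiseSd,
       hotspotFactor = hotspotFactor)
}

#' Pseudo-clinical (optimized-like) plan dose
#'
#' Stands in for an inverse-optimized clinical plan so the prediction models
#' have a learnable ground truth. Starting from the conformal plan, dose
#' outside the PTV union is multiplied by a sparing factor
#' \code{g(v) = 1 - s * (1 - exp(-dist(v)/lambda))} with the per-patient
#' sparing strength \code{s} drawn from \code{params$sRange} and
#' \code{dist} the Euclidean distance to the PTV union; inside each PTV the
#' dose is set to that PTV's prescription level (parsed from its name, e.g.
#' 60 Gy for PTV60, innermost level winning) times \code{1 + eps(v)} where
#' \code{eps} is white noise blurred at 1 cm and rescaled to the requested
#' standard deviation; finally the in-target dose is rescaled so the D1 of
#' the highest PTV equals \code{hotspotFactor * prescription}. Deterministic
#' given the seed.
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param beams a \code{\link{beamSet}}.
#' @param prescriptionGy prescription of the highest-dose PTV (Gy).
#' @param params see \code{\link{sparingParams}}.
#' @param seed integer seed for the per-patient sparing strength and noise.
#' @param conformal optional precomputed conformal \linkS4class{DoseGrid}.
#' @return a \linkS4class{DoseGrid} labelled \code{CLINICAL}.
#' @export
pseudoClinicalDose <- function(phantom, beams, prescriptionGy,
                               params = sparingParams(), seed = 0,
                               conformal = NULL) {
  if (is.null(conformal))
    conformal <- conformalPlan(phantom, beams, prescriptionGy)
  grid <- phantom@grid
  ptvs <- ptvNames(phantom)
  ptvUnion <- Reduce(`|`, lapply(ptvs, function(p) structureMask(phantom, p)))
  levels <- as.numeric(sub("^PTV", "", ptvs))
  if (any(is.na(levels)))
    stop("PTV names must encode their dose level, e.g. 'PTV70'")

  withSeed(seed, function() {
    s <- stats::runif(1, params$sRange[1], params$sRange[2])
    d <- conformal@values
    outside <- !ptvUnion
    distOut <- distanceToMask(ptvUnion, grid)
    g <- 1 - s * (1 - exp(-distOut / params$lambdaCm))
    d[outside] <- d[outside] * g[outside]

    eps <- array(0, dim3(grid))
    if (params$noiseSd > 0) {
      w <- array(stats::rnorm(prod(dim3(grid))), dim3(grid))
      w <- blurGaussian(w, grid, 1.0)
      eps <- (w - mean(w)) / stats::sd(w) * params$noiseSd
    }
    ## innermost (highest) level wins: assign lowest level first
    for (i in rev(seq_along(ptvs))) {
      m <- structureMask(phantom, ptvs[i])
      d[m] <- levels[i] * (1 + eps[m])
    }
    hi <- structureMask(phantom, ptvs[1])
    d1 <- stats::quantile(d[hi], 0.99, names = FALSE)
    if (d1 > 0)
      d[ptvUnion] <- d[ptvUnion] *
        (params$hotspotFactor * prescriptionGy / d1)
    d[d < 0] <- 0
    new("DoseGrid", grid = grid, values = d, label = "CLINICAL")
  })
}
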