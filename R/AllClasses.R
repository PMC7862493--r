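#' @import methods
NULL

#' GridSpec: geometry of a voxel grid
#'
#' Describes a regular anisotropic voxel grid: integer extent per axis,
#' voxel spacing in cm and the position (cm) of the grid corner. Voxel
#' centres are at \code{origin + (index - 0.5) * spacing} with 1-based
#' indices; slices are axial (along z) and the gantry rotates in the
#' axial x--y plane.
#'
#' @slot shape integer(3), voxels per axis, each >= 8.
#' @slot spacing numeric(3), voxel spacing in cm; in-plane <= 0.3 cm,
#'   slice thickness conventionally 0.3 cm.
#' @slot origin numeric(3), grid corner position in cm.
#' @export
setClass("GridSpec",
  representation(shape = "integer", spacing = "numeric", origin = "numeric"),
  prototype(shape = c(96L, 96L, 48L), spacing = c(0.2, 0.2, 0.3),
            origin = c(0, 0, 0))
)

setValidity("GridSpec", function(object) {
  msg <- NULL
  if (length(object@shape) != 3L || any(is.na(object@shape)))
    msg <- c(msg, "'shape' must be an integer triple")
  else if (any(object@shape < 8L))
    msg <- c(msg, "all grid dimensions must be >= 8 voxels")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be three positive lengths (cm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be a finite position triple (cm)")
  if (is.null(msg)) TRUE else msg
})

#' Phantom: one synthetic patient
#'
#' A voxel grid together with named boolean structure masks (an external
#' \code{"body"} mask, nested PTVs and the site's OARs).
#'
#' @slot grid a \linkS4class{GridSpec}.
#' @slot structures named list of logical arrays, one per structure.
#' @slot site \code{"HN"} (head-and-neck-like) or \code{"PELVIS"}.
#' @slot ptvNames ordered character vector, highest dose level first.
#' @slot oarNames character vector of organ-at-risk mask names.
#' @slot patientId character scalar.
#' @slot seed integer scalar used to generate this patient.
#' @export
setClass("Phantom",
  representation(grid = "GridSpec", structures = "list", site = "character",
                 ptvNames = "character", oarNames = "character",
                 patientId = "character", seed = "numeric")
)

setValidity("Phantom", function(object) {
  msg <- NULL
  if (!object@site %in% c("HN", "PELVIS"))
    msg <- c(msg, "'site' must be \"HN\" or \"PELVIS\"")
  nms <- names(object@structures)
  if (is.null(nms) || anyDuplicated(nms))
    msg <- c(msg, "structures must be uniquely named")
  if (!"body" %in% nms)
    msg <- c(msg, "an external \"body\" mask is required")
  dims <- dim3(object@grid)
  for (nm in nms) {
    m <- object@structures[[nm]]
    if (!is.logical(m) || !identical(dim(m), dims))
      msg <- c(msg, sprintf("mask '%s' must be a logical array of grid shape", nm))
  }
  if (is.null(msg)) {
    for (nm in object@ptvNames)
      if (!any(object@structures[[nm]]))
        msg <- c(msg, sprintf("PTV mask '%s' is empty", nm))
    body <- object@structures[["body"]]
    for (nm in setdiff(nms, "body"))
      if (any(object@structures[[nm]] & !body))
        msg <- c(msg, sprintf("mask '%s' extends outside the body", nm))
    if (length(object@ptvNames) > 1L)
      for (i in seq_len(length(object@ptvNames) - 1L)) {
        hi <- object@structures[[object@ptvNames[i]]]
        lo <- object@structures[[object@ptvNames[i + 1L]]]
        if (any(hi & !lo))
          msg <- c(msg, sprintf("PTV '%s' is not nested inside '%s'",
                                object@ptvNames[i], object@ptvNames[i + 1L]))
      }
  }
  if (is.null(msg)) TRUE else msg
})

#' CohortConfig: parameters of a synthetic cohort
#'
#' @slot site \code{"HN"} or \code{"PELVIS"}.
#' @slot nPatients integer >= 0.
#' @slot prescriptionGy prescription of the highest-dose PTV (HN 70, PELVIS 50).
#' @slot marginCm CTV-to-PTV margin in cm (HN 0.3, PELVIS 0.5).
#' @slot geometry named list of \code{c(lo, hi)} ranges (cm) for the random
#'   structure geometry; see \code{\link{hnGeometry}} / \code{\link{pelvisGeometry}}.
#' @slot masterSeed integer master seed; per-patient seeds are derived from it.
#' @slot grid a \linkS4class{GridSpec}.
#' @export
setClass("CohortConfig",
  representation(site = "character", nPatients = "integer",
                 prescriptionGy = "numeric", marginCm = "numeric",
                 geometry = "list", masterSeed = "numeric", grid = "GridSpec")
)

setValidity("CohortConfig", function(object) {
  msg <- NULL
  if (!object@site %in% c("HN", "PELVIS"))
    msg <- c(msg, "'site' must be \"HN\" or \"PELVIS\"")
  if (object@nPatients < 0L) msg <- c(msg, "'nPatients' must be >= 0")
  if (!is.finite(object@prescriptionGy) || object@prescriptionGy <= 0)
    msg <- c(msg, "'prescriptionGy' must be > 0")
  if (!is.finite(object@marginCm) || object@marginCm < 0)
    msg <- c(msg, "'marginCm' must be >= 0")
  for (nm in names(object@geometry)) {
    r <- object@geometry[[nm]]
    if (length(r) != 2L || any(!is.finite(r)))
      msg <- c(msg, sprintf("geometry range '%s' must be c(lo, hi)", nm))
    else if (r[1] > r[2])
      msg <- c(msg, sprintf("geometry range '%s' has min > max", nm))
  }
  if (is.null(msg)) TRUE else msg
})

#' BeamSet: the uniform-intensity field arrangement
#'
#' @slot gantryAnglesDeg ordered gantry angles in degrees; the HN preset is
#'   the fixed nine-field arrangement c(160,120,80,40,0,200,240,280,320),
#'   the PELVIS preset nine equally spaced angles.
#' @slot fitTarget structure each aperture is fitted to (HN "PTV54",
#'   PELVIS "PTV45").
#' @slot apertureMarginCm aperture expansion beyond the projected target, cm.
#' @slot muPerCm effective linear attenuation coefficient, 1/cm.
#' @slot penumbraSigmaCm Gaussian penumbra width, cm.
#' @slot fieldWeight common relative weight of every field.
#' @export
setClass("BeamSet",
  representation(gantryAnglesDeg = "numeric", fitTarget = "character",
                 apertureMarginCm = "numeric", muPerCm = "numeric",
                 penumbraSigmaCm = "numeric", fieldWeight = "numeric")
)

setValidity("BeamSet", function(object) {
  msg <- NULL
  if (length(object@gantryAnglesDeg) < 1L)
    msg <- c(msg, "at least one gantry angle is required")
  if (object@muPerCm <= 0) msg <- c(msg, "'muPerCm' must be > 0")
  if (object@apertureMarginCm < 0) msg <- c(msg, "'apertureMarginCm' must be >= 0")
  if (object@penumbraSigmaCm <= 0) msg <- c(msg, "'penumbraSigmaCm' must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' DoseGrid: scalar dose per voxel
#'
#' @slot grid a \linkS4class{GridSpec}.
#' @slot values numeric array of doses (Gy, or arbitrary units for a single
#'   field before plan-level scaling); non-negative and finite.
#' @slot label source label, e.g. \code{"FIELD_080"}, \code{"CONFORMAL_PLAN"}
#'   or \code{"CLINICAL"}.
#' @export
setClass("DoseGrid",
  representation(grid = "GridSpec", values = "array", label = "character")
)

setValidity("DoseGrid", function(object) {
  msg <- NULL
  if (!identical(dim(object@values), dim3(object@grid)))
    msg <- c(msg, "'values' must match the grid shape")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "doses must be finite")
  else if (any(object@values < 0))
    msg <- c(msg, "doses must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' CumHist: a cumulative histogram curve (DVH or DTH)
#'
#' For a DVH the ordinate is the percent volume receiving at least the
#' abscissa dose (monotone non-increasing, 100 at zero dose). For a DTH the
#' ordinate is the percent volume within a signed distance of the target
#' surface (monotone non-decreasing, reaching 100 at the largest abscissa;
#' negative distances are inside the target).
#'
#' @slot kind \code{"DVH"} or \code{"DTH"}.
#' @slot abscissa strictly increasing vector (Gy or cm, possibly normalized).
#' @slot ordinate volume percentages in [0, 100].
#' @slot structure structure name.
#' @slot sourceLabel which dose grid or target the curve was computed from.
#' @export
setClass("CumHist",
  representation(kind = "character", abscissa = "numeric",
                 ordinate = "numeric", structure = "character",
                 sourceLabel = "character")
)

setValidity("CumHist", function(object) {
  msg <- NULL
  tol <- 1e-9
  if (!object@kind %in% c("DVH", "DTH"))
    msg <- c(msg, "'kind' must be \"DVH\" or \"DTH\"")
  if (length(object@abscissa) != length(object@ordinate))
    msg <- c(msg, "abscissa and ordinate lengths differ")
  if (length(object@abscissa) > 1L && any(diff(object@abscissa) <= 0))
    msg <- c(msg, "abscissa must be strictly increasing")
  o <- object@ordinate
  if (any(o < -tol | o > 100 + tol))
    msg <- c(msg, "ordinate must lie in [0, 100]")
  if (object@kind == "DVH") {
    if (length(o) > 1L && any(diff(o) > tol))
      msg <- c(msg, "DVH ordinate must be monotone non-increasing")
  } else if (object@kind == "DTH") {
    if (length(o) > 1L && any(diff(o) < -tol))
      msg <- c(msg, "DTH ordinate must be monotone non-decreasing")
    if (length(o) >= 1L && o[length(o)] < 100 - tol)
      msg <- c(msg, "DTH must reach 100% at its maximum abscissa")
  }
  if (is.null(msg)) TRUE else msg
})

#' NormConstants: cohort-level normalization constants
#'
#' The four normalizations applied before feature sampling, each computed
#' over the training patients only: the IDVH dose axis is normalized to the
#' maximum dose of all individual fields, the DTH distance axis to the
#' maximum distance of all OARs, the CPDVH dose axis to the maximum PTV dose
#' of all conformal plans, and the clinical DVH dose axis to the maximum PTV
#' dose of all clinical plans.
#'
#' @slot maxFieldDose maximum individual-field dose (field units).
#' @slot maxDthDistance maximum OAR-to-target distance (cm).
#' @slot minDthNorm minimum observed signed distance divided by
#'   \code{maxDthDistance}; fixes the shared DTH sampling span.
#' @slot maxCpdvhPtvDose maximum PTV dose over all conformal plans (Gy).
#' @slot maxClinicalPtvDose maximum PTV dose over all clinical plans (Gy).
#' @slot fittedOn provenance hash of the training patient ids.
#' @slot patients training patient ids.
#' @export
setClass("NormConstants",
  representation(maxFieldDose = "numeric", maxDthDistance = "numeric",
                 minDthNorm = "numeric", maxCpdvhPtvDose = "numeric",
                 maxClinicalPtvDose = "numeric", fittedOn = "character",
                 patients = "character")
)

setValidity("NormConstants", function(object) {
  msg <- NULL
  for (nm in c("maxFieldDose", "maxDthDistance", "maxCpdvhPtvDose",
               "maxClinicalPtvDose"))
    if (!is.finite(slot(object, nm)) || slot(object, nm) <= 0)
      msg <- c(msg, sprintf("'%s' must be > 0", nm))
  if (is.null(msg)) TRUE else msg
})

#' PlanRecord: one patient's curve bundle
#'
#' Per structure: the nine individual-field DVHs in the fixed gantry-angle
#' order, the conformal-plan DVH, the clinical DVH and (OARs only) the
#' signed DTH. Scalar dose maxima needed for the cohort normalizations are
#' kept in \code{meta}.
#'
#' @slot patientId character scalar.
#' @slot site \code{"HN"} or \code{"PELVIS"}.
#' @slot curves named list (per structure) of lists with elements
#'   \code{idvh} (list of \linkS4class{CumHist}), \code{cpdvh},
#'   \code{clinical} and optionally \code{dth}.
#' @slot ptvNames,oarNames structure names, as in \linkS4class{Phantom}.
#' @slot gantryAnglesDeg angle order shared by all IDVH lists.
#' @slot meta named list of scalars (\code{fieldMaxDose},
#'   \code{cpdvhPtvMaxDose}, \code{clinicalPtvMaxDose}, \code{prescriptionGy}).
#' @export
setClass("PlanRecord",
  representation(patientId = "character", site = "character",
                 curves = "list", ptvNames = "character",
                 oarNames = "character", gantryAnglesDeg = "numeric",
                 meta = "list")
)

setValidity("PlanRecord", function(object) {
  msg <- NULL
  nAng <- length(object@gantryAnglesDeg)
  for (nm in names(object@curves)) {
    cs <- object@curves[[nm]]
    if (!is.null(cs$idvh) && length(cs$idvh) != nAng)
      msg <- c(msg, sprintf("structure '%s' needs %d individual-field DVHs",
                            nm, nAng))
  }
  for (nm in object@oarNames)
    if (!nm %in% names(object@curves))
      msg <- c(msg, sprintf("missing curves for OAR '%s'", nm))
  if (is.null(msg)) TRUE else msg
})

#' GRNNModel: a generalized regression neural network
#'
#' Stores the training exemplars (feature vectors and 50-point target
#' curves) and the Gaussian kernel spread. Prediction is Nadaraya-Watson
#' kernel regression: a convex combination of the stored target curves with
#' weights \code{exp(-||x - x_i||^2 / (2 sigma^2))}.
#'
#' @slot exemplarsX n x d matrix of training feature vectors (d = 450 for
#'   the IDVHs method, 100 for DTH + CPDVH).
#' @slot exemplarsY n x 50 matrix of training target curves (volume %).
#' @slot spread kernel width sigma > 0 in feature-space distance units.
#' @slot method \code{"IDVHS"} or \code{"DTH_CPDVH"}.
#' @slot structureType structure type the model was trained for.
#' @slot normsRef provenance hash of the normalization constants used.
#' @export
setClass("GRNNModel",
  representation(exemplarsX = "matrix", exemplarsY = "matrix",
                 spread = "numeric", method = "character",
                 structureType = "character", normsRef = "character")
)

setValidity("GRNNModel", function(object) {
  msg <- NULL
  if (nrow(object@exemplarsX) < 1L)
    msg <- c(msg, "at least one exemplar is required")
  if (nrow(object@exemplarsX) != nrow(object@exemplarsY))
    msg <- c(msg, "exemplar X and Y row counts differ")
  if (!is.finite(object@spread) || object@spread <= 0)
    msg <- c(msg, "'spread' must be > 0")
  if (any(object@exemplarsY < -1e-9 | object@exemplarsY > 100 + 1e-9))
    msg <- c(msg, "target curves must lie in [0, 100]")
  if (!object@method %in% c("IDVHS", "DTH_CPDVH"))
    msg <- c(msg, "'method' must be \"IDVHS\" or \"DTH_CPDVH\"")
  if (is.null(msg)) TRUE else msg
})

#' RunConfig: an end-to-end pipeline configuration
#'
#' @slot site \code{"HN"} or \code{"PELVIS"}.
#' @slot nTrain,nTest cohort split sizes (defaults HN 70/20, PELVIS 45/15).
#' @slot methods feature methods to train (subset of \code{"IDVHS"},
#'   \code{"DTH_CPDVH"}).
#' @slot seed master seed for cohort generation, the pseudo-clinical dose
#'   noise and the train/test split.
#' @slot grid the voxel grid used for every patient.
#' @slot outDir output directory, or \code{NA} for in-memory results only.
#' @export
setClass("RunConfig",
  representation(site = "character", nTrain = "integer", nTest = "integer",
                 methods = "character", seed = "numeric", grid = "GridSpec",
                 outDir = "character")
)

setValidity("RunConfig", function(object) {
  msg <- NULL
  if (object@nTest < 1L) msg <- c(msg, "'nTest' must be >= 1")
  if (object@nTrain < 1L) msg <- c(msg, "'nTrain' must be >= 1")
  if (!all(object@methods %in% c("IDVHS", "DTH_CPDVH")))
    msg <- c(msg, "unknown feature method")
  if (is.null(msg)) TRUE else msg
})
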