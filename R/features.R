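#' @include AllClasses.R accessors.R histograms.R
NULL

#' Sample a curve at 50 equally spaced points on a normalized axis
#'
#' Rescales the curve abscissa by \code{axisMax}, then evaluates the
#' ordinate by linear interpolation at \code{n} equally spaced points from
#' \code{axisMin} (0 for a DVH; the cohort minimum normalized signed
#' distance for a DTH) to 1, endpoints included. Beyond the curve's last
#' point a DVH is 0 and a DTH is 100; before its first point a DVH is 100
#' and a DTH is 0. Abscissa values exceeding the normalization constant
#' (possible for test patients outside the training range) are clipped to 1
#' with a warning.
#'
#' @param curve a \linkS4class{CumHist}.
#' @param n number of samples (default 50).
#' @param axisMax normalization constant, > 0 (Gy or cm).
#' @param axisMin lower end of the normalized sampling span (default 0).
#' @return numeric vector of \code{n} volume percentages.
#' @export
sampleCurve <- function(curve, n = 50L, axisMax, axisMin = 0) {
  if (axisMax <= 0) stop("'axisMax' must be > 0")
  if (axisMin >= 1) stop("'axisMin' must be < 1")
  isDVH <- curve@kind == "DVH"
  a <- curve@abscissa / axisMax
  o <- curve@ordinate
  if (any(a > 1 + 1e-12)) {
    warning("curve abscissa exceeds the normalization constant; clipping to 1")
    oAt1 <- if (length(a) > 1L)
      stats::approx(a, o, xout = 1, ties = "ordered")$y
    else o[1]
    keep <- a < 1
    a <- c(a[keep], 1)
    o <- c(o[keep], oAt1)
  }
  t <- seq(axisMin, 1, length.out = n)
  if (length(a) == 1L) {
    lowVal <- if (isDVH) o[1] else 0
    hiVal <- if (isDVH) 0 else 100
    out <- ifelse(t < a[1] - 1e-15, if (isDVH) 100 else 0,
                  ifelse(t > a[1] + 1e-15, hiVal, o[1]))
    return(as.numeric(out))
  }
  yLeft <- if (isDVH) o[1] else 0
  yRight <- if (isDVH) 0 else 100
  out <- stats::approx(a, o, xout = t, ties = "ordered",
                       yleft = yLeft, yright = yRight)$y
  ## approx() treats x exactly at the ends as inside; enforce the
  ## out-of-support conventions only strictly beyond the curve ends
  as.numeric(out)
}

recordCurves <- function(record, structure) {
  cs <- record@curves[[structure]]
  if (is.null(cs)) stop("no curves stored for structure '", structure, "'")
  cs
}

#' Fit cohort normalization constants
#'
#' Computes the four axis normalizations over the training records only:
#' the maximum individual-field dose, the maximum (and minimum, for the
#' shared sampling span) OAR signed distance, and the maximum PTV dose of
#' the conformal and the clinical plans. The result carries a provenance
#' hash of the training patient ids so downstream stages can verify that
#' test patients never contributed.
#'
#' @param trainingRecords nonempty list of \linkS4class{PlanRecord}.
#' @return a \linkS4class{NormConstants}.
#' @export
fitNormConstants <- function(trainingRecords) {
  if (length(trainingRecords) == 0)
    stop("at least one training record is required")
  missing <- vapply(trainingRecords, function(r)
    length(r@curves) == 0 || is.null(r@meta$fieldMaxDose), logical(1))
  if (any(missing))
    stop("records with missing curves: ",
         paste(vapply(trainingRecords[missing], patientId, character(1)),
               collapse = ", "))
  maxField <- max(vapply(trainingRecords,
                         function(r) r@meta$fieldMaxDose, numeric(1)))
  maxCp <- max(vapply(trainingRecords,
                      function(r) r@meta$cpdvhPtvMaxDose, numeric(1)))
  maxClin <- max(vapply(trainingRecords,
                        function(r) r@meta$clinicalPtvMaxDose, numeric(1)))
  dthHi <- -Inf
  dthLo <- Inf
  for (r in trainingRecords)
    for (nm in r@oarNames) {
      dth <- r@curves[[nm]]$dth
      if (!is.null(dth)) {
        dthHi <- max(dthHi, max(dth@abscissa))
        dthLo <- min(dthLo, min(dth@abscissa))
      }
    }
  if (!is.finite(dthHi) || dthHi <= 0)
    stop("no positive OAR-to-target distances found in the training records")
  ids <- vapply(trainingRecords, patientId, character(1))
  new("NormConstants", maxFieldDose = maxField, maxDthDistance = dthHi,
      minDthNorm = dthLo / dthHi, maxCpdvhPtvDose = maxCp,
      maxClinicalPtvDose = maxClin, fittedOn = provenanceHash(ids),
      patients = ids)
}

#' Build a model input feature vector
#'
#' \code{"IDVHS"}: the nine per-field 50-point DVH samples, concatenated in
#' the record's fixed gantry-angle order (450 values, dose axis normalized
#' to the maximum individual-field dose). \code{"DTH_CPDVH"}: 50 DTH
#' samples on the shared normalized distance span followed by 50 conformal
#' DVH samples on the normalized conformal dose axis (100 values). PTVs
#' carry only the dosimetric IDVHs feature; requesting \code{"DTH_CPDVH"}
#' for a PTV is an error.
#'
#' @param record a \linkS4class{PlanRecord}.
#' @param structure structure name within the record.
#' @param method \code{"IDVHS"} or \code{"DTH_CPDVH"}.
#' @param norms a \code{\link{fitNormConstants}} result.
#' @param n samples per curve part (default 50).
#' @return numeric feature vector of length \code{9 * n} or \code{2 * n},
#'   with attributes \code{method}, \code{structure} and \code{patientId}.
#' @export
buildFeatures <- function(record, structure, method = c("IDVHS", "DTH_CPDVH"),
                          norms, n = 50L) {
  method <- match.arg(method)
  cs <- recordCurves(record, structure)
  if (method == "IDVHS") {
    if (is.null(cs$idvh)) stop("record has no individual-field DVHs for '",
                               structure, "'")
    vec <- unlist(lapply(cs$idvh, sampleCurve, n = n,
                         axisMax = norms@maxFieldDose), use.names = FALSE)
  } else {
    if (structure %in% record@ptvNames)
      stop("the DTH_CPDVH method applies to OARs only; '", structure,
           "' is a PTV (PTVs use the IDVHs feature)")
    if (is.null(cs$dth) || is.null(cs$cpdvh))
      stop("record lacks DTH/CPDVH curves for '", structure, "'")
    dthPart <- sampleCurve(cs$dth, n = n, axisMax = norms@maxDthDistance,
                           axisMin = norms@minDthNorm)
    cpPart <- sampleCurve(cs$cpdvh, n = n, axisMax = norms@maxCpdvhPtvDose)
    vec <- c(dthPart, cpPart)
  }
  structure(vec, method = method, structure = structure,
            patientId = record@patientId)
}

#' Build the 50-point prediction target
#'
#' Samples the clinical cumulative DVH at 50 equally spaced points on the
#' dose axis normalized to the maximum clinical PTV dose of the training
#' cohort.
#'
#' @inheritParams buildFeatures
#' @return numeric vector of length \code{n} (monotone non-increasing
#'   volume percentages).
#' @export
buildTarget <- function(record, structure, norms, n = 50L) {
  cs <- recordCurves(record, structure)
  if (is.null(cs$clinical))
    stop("record has no clinical DVH for '", structure, "'")
  structure(sampleCurve(cs$clinical, n = n,
                        axisMax = norms@maxClinicalPtvDose),
            structure = structure, patientId = record@patientId)
}
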