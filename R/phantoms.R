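#' @include AllClasses.R accessors.R
NULL

## ---- analytic mask primitives ---------------------------------------------

ellipsoidMask <- function(grid, center, semi) {
  cc <- axisCoords(grid)
  q <- outer(outer(((cc[[1]] - center[1]) / semi[1])^2,
                   ((cc[[2]] - center[2]) / semi[2])^2, `+`),
             ((cc[[3]] - center[3]) / semi[3])^2, `+`)
  q <= 1
}

## elliptic cylinder along z, optionally restricted to [z0, z1]
cylinderMask <- function(grid, center, radii, zRange = NULL) {
  cc <- axisCoords(grid)
  inPlane <- outer(((cc[[1]] - center[1]) / radii[1])^2,
                   ((cc[[2]] - center[2]) / radii[2])^2, `+`) <= 1
  zOk <- if (is.null(zRange)) rep(TRUE, grid@shape[3])
         else cc[[3]] >= zRange[1] & cc[[3]] <= zRange[2]
  outer(inPlane, zOk, `&`)
}

sphereMask <- function(grid, center, r) ellipsoidMask(grid, center, c(r, r, r))

## guarantee sub-voxel structures are represented by their centre voxel
ensureCenterVoxel <- function(mask, grid, center) {
  if (any(mask)) return(mask)
  idx <- pmin(pmax(ceiling((center - grid@origin) / grid@spacing), 1L),
              grid@shape)
  mask[idx[1], idx[2], idx[3]] <- TRUE
  mask
}

## error if an analytic extent pokes outside the grid
checkFits <- function(name, center, semi, grid) {
  lo <- grid@origin
  hi <- grid@origin + grid@shape * grid@spacing
  if (any(center - semi < lo) || any(center + semi > hi))
    stop("structure '", name, "' does not fit in the grid")
}

## ---- geometry defaults ----------------------------------------------------

#' Default geometry ranges for the synthetic sites
#'
#' Each entry is a \code{c(lo, hi)} range in cm from which a patient-specific
#' value is drawn uniformly. The ranges are artifact choices tuned to give
#' head-and-neck-like and pelvis-like topologies on the default grid (a
#' central nested target hierarchy, a posterior serial cord-like tube, paired
#' lateral parotid-like glands and small anterior lens-like spheres for HN;
#' a central target, an anterior bladder-like shell, paired femoral-head-like
#' spheres and a superior bowel-like blob for PELVIS); they are documented
#' here, not derived from any clinical dataset.
#'
#' @return named list of ranges (cm).
#' @export
hnGeometry <- function() {
  list(
    body_rx = c(6.3, 7.0), body_ry = c(7.0, 7.8),
    ctv_jitter = c(-0.4, 0.4), ctv_zjitter = c(-0.5, 0.5),
    ctv70_a = c(1.5, 2.4), ctv70_b = c(1.2, 2.0), ctv70_c = c(1.5, 2.4),
    ctv60_extra = c(0.5, 1.0), ctv54_extra = c(1.0, 1.6),
    cord_offset_y = c(4.3, 5.2), cord_radius = c(0.35, 0.55),
    parotid_offset_x = c(3.8, 4.8), parotid_offset_y = c(0.6, 1.4),
    parotid_ab = c(0.8, 1.2), parotid_c = c(1.2, 1.8),
    lens_offset_x = c(1.3, 1.8), lens_offset_y = c(4.8, 5.6),
    lens_offset_z = c(2.0, 3.0), lens_radius = c(0.3, 0.45)
  )
}

#' @rdname hnGeometry
#' @export
pelvisGeometry <- function() {
  list(
    body_rx = c(7.6, 8.4), body_ry = c(5.4, 6.2),
    ctv_jitter = c(-0.4, 0.4), ctv_offset_y = c(0.5, 1.5),
    ctv50_a = c(1.5, 2.2), ctv50_b = c(1.2, 1.8), ctv50_c = c(2.0, 3.0),
    ctv45_extra = c(0.8, 1.4),
    bladder_offset_y = c(2.4, 3.0), bladder_router = c(1.5, 2.0),
    bladder_wall = c(0.5, 0.7),
    femur_offset_x = c(4.8, 5.6), femur_jitter_y = c(-0.5, 0.5),
    femur_radius = c(1.2, 1.6),
    bowel_offset_y = c(0.5, 1.5), bowel_offset_z = c(2.5, 3.5),
    bowel_a = c(2.0, 2.8), bowel_b = c(1.5, 2.2), bowel_c = c(1.5, 2.2)
  )
}

#' Configure a synthetic cohort
#'
#' @param site \code{"HN"} (70 Gy prescription, 0.3 cm CTV-to-PTV margin,
#'   targets PTV70/PTV60/PTV54) or \code{"PELVIS"} (50 Gy, 0.5 cm margin,
#'   PTV50/PTV45).
#' @param nPatients number of phantoms to generate.
#' @param masterSeed master seed; each patient's seed is derived from it and
#'   the patient index, so extending the cohort never reshuffles it.
#' @param prescriptionGy,marginCm site defaults can be overridden.
#' @param geometry named list of \code{c(lo, hi)} geometry ranges; defaults
#'   from \code{\link{hnGeometry}} or \code{\link{pelvisGeometry}}.
#' @param grid the voxel \code{\link{gridSpec}} shared by the cohort.
#' @return a \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(site = c("HN", "PELVIS"), nPatients = 10L,
                         masterSeed = 1L, prescriptionGy = NULL,
                         marginCm = NULL, geometry = NULL,
                         grid = gridSpec()) {
  site <- match.arg(site)
  if (is.null(prescriptionGy))
    prescriptionGy <- if (site == "HN") 70 else 50
  if (is.null(marginCm)) marginCm <- if (site == "HN") 0.3 else 0.5
  if (is.null(geometry))
    geometry <- if (site == "HN") hnGeometry() else pelvisGeometry()
  new("CohortConfig", site = site, nPatients = as.integer(nPatients),
      prescriptionGy = prescriptionGy, marginCm = marginCm,
      geometry = geometry, masterSeed = as.numeric(masterSeed), grid = grid)
}

## ---- margin expansion -----------------------------------------------------

#' Expand a mask by an isotropic margin
#'
#' Returns the voxels whose centre lies within \code{marginCm} (Euclidean,
#' anisotropic spacing respected) of any true voxel centre of the input.
#' Implemented by thresholding an exact Euclidean distance transform rather
#' than by structuring-element dilation, so 0.3 cm slices are handled
#' correctly. The output is always a superset of the input and is monotone
#' in the margin.
#'
#' @param mask logical array (nonempty).
#' @param marginCm margin in cm, >= 0.
#' @param grid the \linkS4class{GridSpec} the mask lives on.
#' @return logical array of the same shape.
#' @examples
#' g <- gridSpec(c(16, 16, 8), c(0.1, 0.1, 0.3))
#' m <- array(FALSE, gridShape(g)); m[8, 8, 4] <- TRUE
#' sum(expandMargin(m, 0.3, g))
#' @export
expandMargin <- function(mask, marginCm, grid) {
  if (!any(mask)) stop("cannot expand an empty mask")
  if (marginCm < 0) stop("'marginCm' must be >= 0")
  if (marginCm == 0) return(mask)
  ## tiny absolute tolerance so voxels at exactly the margin distance are
  ## kept despite floating-point rounding of the coordinate products
  distanceToMask(mask, grid) <= marginCm + 1e-9
}

## ---- patient generation ---------------------------------------------------

rnd <- function(geom, key) {
  r <- geom[[key]]
  if (is.null(r)) stop("missing geometry range '", key, "'")
  stats::runif(1, r[1], r[2])
}

generateHN <- function(config, id, seed) {
  grid <- config@grid
  geom <- config@geometry
  ext <- grid@shape * grid@spacing
  ctr <- grid@origin + ext / 2

  withSeed(seed, function() {
    bodyR <- c(rnd(geom, "body_rx"), rnd(geom, "body_ry"))
    body <- cylinderMask(grid, ctr[1:2], bodyR)

    cc <- ctr + c(rnd(geom, "ctv_jitter"), rnd(geom, "ctv_jitter"),
                  rnd(geom, "ctv_zjitter"))
    a70 <- c(rnd(geom, "ctv70_a"), rnd(geom, "ctv70_b"), rnd(geom, "ctv70_c"))
    e60 <- rnd(geom, "ctv60_extra")
    e54 <- rnd(geom, "ctv54_extra")
    checkFits("CTV54", cc, a70 + e54 + config@marginCm, grid)
    ctv70 <- ellipsoidMask(grid, cc, a70)
    ctv60 <- ellipsoidMask(grid, cc, a70 + e60) | ctv70
    ctv54 <- ellipsoidMask(grid, cc, a70 + e54) | ctv60

    cordY <- rnd(geom, "cord_offset_y")
    cordR <- rnd(geom, "cord_radius")
    cord <- cylinderMask(grid, c(ctr[1], ctr[2] + cordY), c(cordR, cordR))

    pax <- rnd(geom, "parotid_offset_x")
    pay <- rnd(geom, "parotid_offset_y")
    pab <- c(rnd(geom, "parotid_ab"), rnd(geom, "parotid_ab"))
    pc <- rnd(geom, "parotid_c")
    parL <- ellipsoidMask(grid, c(ctr[1] - pax, ctr[2] + pay, cc[3]),
                          c(pab, pc))
    parR <- ellipsoidMask(grid, c(ctr[1] + pax, ctr[2] + pay, cc[3]),
                          c(pab, pc))

    lx <- rnd(geom, "lens_offset_x")
    ly <- rnd(geom, "lens_offset_y")
    lz <- rnd(geom, "lens_offset_z")
    lr <- rnd(geom, "lens_radius")
    cL <- c(ctr[1] - lx, ctr[2] - ly, ctr[3] + lz)
    cR <- c(ctr[1] + lx, ctr[2] - ly, ctr[3] + lz)
    lensL <- ensureCenterVoxel(sphereMask(grid, cL, lr), grid, cL)
    lensR <- ensureCenterVoxel(sphereMask(grid, cR, lr), grid, cR)

    str <- list(
      body = body,
      PTV70 = expandMargin(ctv70, config@marginCm, grid) & body,
      PTV60 = expandMargin(ctv60, config@marginCm, grid) & body,
      PTV54 = expandMargin(ctv54, config@marginCm, grid) & body,
      cord = cord & body,
      parotid_L = parL & body, parotid_R = parR & body,
      lens_L = lensL & body, lens_R = lensR & body
    )
    for (nm in names(str))
      if (!any(str[[nm]])) stop("structure '", nm, "' is empty after generation")
    new("Phantom", grid = grid, structures = str, site = "HN",
        ptvNames = c("PTV70", "PTV60", "PTV54"),
        oarNames = c("cord", "parotid_L", "parotid_R", "lens_L", "lens_R"),
        patientId = id, seed = seed)
  })
}

generatePelvis <- function(config, id, seed) {
  grid <- config@grid
  geom <- config@geometry
  ext <- grid@shape * grid@spacing
  ctr <- grid@origin + ext / 2

  withSeed(seed, function() {
    bodyR <- c(rnd(geom, "body_rx"), rnd(geom, "body_ry"))
    body <- cylinderMask(grid, ctr[1:2], bodyR)

    cc <- c(ctr[1] + rnd(geom, "ctv_jitter"),
            ctr[2] + rnd(geom, "ctv_offset_y"), ctr[3])
    a50 <- c(rnd(geom, "ctv50_a"), rnd(geom, "ctv50_b"), rnd(geom, "ctv50_c"))
    e45 <- rnd(geom, "ctv45_extra")
    checkFits("CTV45", cc, a50 + e45 + config@marginCm, grid)
    ctv50 <- ellipsoidMask(grid, cc, a50)
    ctv45 <- ellipsoidMask(grid, cc, a50 + e45) | ctv50

    by <- rnd(geom, "bladder_offset_y")
    bro <- rnd(geom, "bladder_router")
    bwall <- rnd(geom, "bladder_wall")
    bctr <- c(ctr[1], ctr[2] - by, ctr[3])
    bladder <- sphereMask(grid, bctr, bro) & !sphereMask(grid, bctr, bro - bwall)

    fx <- rnd(geom, "femur_offset_x")
    fy <- rnd(geom, "femur_jitter_y")
    fr <- rnd(geom, "femur_radius")
    femL <- sphereMask(grid, c(ctr[1] - fx, ctr[2] + fy, ctr[3]), fr)
    femR <- sphereMask(grid, c(ctr[1] + fx, ctr[2] + fy, ctr[3]), fr)

    bwy <- rnd(geom, "bowel_offset_y")
    bwz <- rnd(geom, "bowel_offset_z")
    bw <- c(rnd(geom, "bowel_a"), rnd(geom, "bowel_b"), rnd(geom, "bowel_c"))
    bowel <- ellipsoidMask(grid, c(ctr[1], ctr[2] - bwy, ctr[3] + bwz), bw)

    str <- list(
      body = body,
      PTV50 = expandMargin(ctv50, config@marginCm, grid) & body,
      PTV45 = expandMargin(ctv45, config@marginCm, grid) & body,
      bladder = bladder & body,
      femoral_head_L = femL & body, femoral_head_R = femR & body,
      bowel = bowel & body
    )
    for (nm in names(str))
      if (!any(str[[nm]])) stop("structure '", nm, "' is empty after generation")
    new("Phantom", grid = grid, structures = str, site = "PELVIS",
        ptvNames = c("PTV50", "PTV45"),
        oarNames = c("bladder", "femoral_head_L", "femoral_head_R", "bowel"),
        patientId = id, seed = seed)
  })
}

#' Generate a seeded synthetic cohort
#'
#' Produces \code{nPatients} phantoms whose structure geometry is drawn
#' uniformly from the configured ranges. Each patient's seed is derived
#' deterministically from the master seed and the patient index, so the same
#' configuration always yields bit-identical masks and a cohort can be
#' extended without changing existing patients.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return list of \linkS4class{Phantom} objects (empty for
#'   \code{nPatients = 0}).
#' @examples
#' cfg <- cohortConfig("HN", nPatients = 1, masterSeed = 7,
#'                     grid = gridSpec(c(48, 48, 16), c(0.4, 0.4, 0.6)))
#' ph <- generateCohort(cfg)[[1]]
#' p70 <- structureMask(ph, "PTV70")
#' all(structureMask(ph, "PTV60")[p70]) # nesting holds
#' @export
generateCohort <- function(config) {
  validObject(config)
  gen <- if (config@site == "HN") generateHN else generatePelvis
  lapply(seq_len(config@nPatients), function(i) {
    gen(config, sprintf("%s-%03d", tolower(config@site), i),
        patientSeed(config@masterSeed, i))
  })
}
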