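#' @include AllClasses.R accessors.R
NULL

#' Write a phantom (and optional dose grids) to a patient directory
#'
#' Masks and doses are written as NIfTI volumes with the grid spacing in
#' the header, plus a \code{phantom.json} sidecar carrying the site,
#' structure roles and generation seed.
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param dir output directory (created).
#' @param doses optional named list of \linkS4class{DoseGrid} to write
#'   alongside the masks (e.g. \code{field_080}, \code{conformal},
#'   \code{clinical}).
#' @return the directory, invisibly.
#' @export
writePhantom <- function(phantom, dir, doses = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- phantom@grid@spacing * 10 # cm -> mm, the NIfTI convention
  for (nm in structureNames(phantom)) {
    img <- RNifti::asNifti(array(as.integer(structureMask(phantom, nm)),
                                 dim3(phantom@grid)), pixdim = sp)
    RNifti::writeNifti(img, file.path(dir, paste0("mask_", nm, ".nii.gz")))
  }
  for (nm in names(doses)) {
    img <- RNifti::asNifti(doses[[nm]]@values, pixdim = sp)
    RNifti::writeNifti(img, file.path(dir, paste0(nm, ".nii.gz")))
  }
  meta <- list(patient_id = phantom@patientId, site = phantom@site,
               ptv_names = phantom@ptvNames, oar_names = phantom@oarNames,
               seed = phantom@seed, shape = phantom@grid@shape,
               spacing_cm = phantom@grid@spacing,
               origin_cm = phantom@grid@origin)
  jsonlite::write_json(meta, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom written by \code{\link{writePhantom}}
#'
#' @param dir a patient directory.
#' @return a \linkS4class{Phantom}.
#' @export
readPhantom <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "phantom.json"),
                              simplifyVector = TRUE)
  grid <- gridSpec(meta$shape, meta$spacing_cm, meta$origin_cm)
  files <- list.files(dir, pattern = "^mask_.*\\.nii\\.gz$")
  str <- lapply(files, function(f) {
    v <- RNifti::readNifti(file.path(dir, f))
    array(as.vector(v) != 0, dim3(grid))
  })
  names(str) <- sub("^mask_(.*)\\.nii\\.gz$", "\\1", files)
  new("Phantom", grid = grid, structures = str, site = meta$site,
      ptvNames = meta$ptv_names, oarNames = meta$oar_names,
      patientId = meta$patient_id, seed = meta$seed)
}

#' Write a curve as CSV with a JSON sidecar
#'
#' @param curve a \linkS4class{CumHist}.
#' @param path CSV path; the sidecar replaces the extension with
#'   \code{.json}.
#' @return the path, invisibly.
#' @export
writeCurve <- function(curve, path) {
  utils::write.csv(data.frame(abscissa = curve@abscissa,
                              volume_pct = curve@ordinate),
                   path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(kind = curve@kind, structure = curve@structure,
                            source = curve@sourceLabel),
                       side, auto_unbox = TRUE)
  invisible(path)
}

## write the pipeline result tables + manifest under outDir
writeRunOutputs <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$predictions$scores,
                   file.path(outDir, "curve_scores.csv"), row.names = FALSE)
  utils::write.csv(result$predictions$metrics,
                   file.path(outDir, "dose_metrics.csv"), row.names = FALSE)
  for (nm in names(result$report))
    utils::write.csv(result$report[[nm]],
                     file.path(outDir, paste0("report_", nm, ".csv")),
                     row.names = FALSE)
  cfg <- result$config
  manifest <- list(
    site = cfg@site, n_train = cfg@nTrain, n_test = cfg@nTest,
    methods = cfg@methods, seed = cfg@seed,
    grid = list(shape = cfg@grid@shape, spacing_cm = cfg@grid@spacing),
    split = result$split,
    norm_constants = list(
      max_field_dose = result$norms@maxFieldDose,
      max_dth_distance_cm = result$norms@maxDthDistance,
      min_dth_norm = result$norms@minDthNorm,
      max_cpdvh_ptv_dose_gy = result$norms@maxCpdvhPtvDose,
      max_clinical_ptv_dose_gy = result$norms@maxClinicalPtvDose,
      fitted_on = result$norms@fittedOn),
    models = lapply(result$models, function(m)
      list(method = m@method, structure_type = m@structureType,
           n_exemplars = nrow(m@exemplarsX), spread = m@spread)),
    package_version = as.character(utils::packageVersion("kbdvh")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
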