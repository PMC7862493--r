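#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a GridSpec
#'
#' @param shape integer triple of voxel counts (nx, ny, nz).
#' @param spacing numeric triple of voxel spacings in cm; the default keeps
#'   the conventional 0.3 cm slice thickness.
#' @param origin numeric triple, grid corner position in cm.
#' @return a \linkS4class{GridSpec}.
#' @examples
#' g <- gridSpec(c(48, 48, 24))
#' voxelVolume(g)
#' @export
gridSpec <- function(shape = c(96L, 96L, 48L), spacing = c(0.2, 0.2, 0.3),
                     origin = c(0, 0, 0)) {
  new("GridSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Accessors for kbdvh objects
#'
#' Small read-only accessors for the package's S4 classes.
#'
#' @param x an object.
#' @param name a structure name.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("gridShape", "GridSpec", function(x) x@shape)

#' @rdname accessors
#' @export
setMethod("gridSpacing", "GridSpec", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("voxelVolume", "GridSpec", function(x) prod(x@spacing))

#' @rdname accessors
#' @export
setMethod("structures", "Phantom", function(x) x@structures)

#' @rdname accessors
#' @export
setMethod("structureNames", "Phantom", function(x) names(x@structures))

#' @rdname accessors
#' @export
setMethod("structureMask", "Phantom", function(x, name) {
  if (!name %in% names(x@structures))
    stop("unknown structure '", name, "'")
  x@structures[[name]]
})

#' @rdname accessors
#' @export
setMethod("ptvNames", "Phantom", function(x) x@ptvNames)

#' @rdname accessors
#' @export
setMethod("oarNames", "Phantom", function(x) x@oarNames)

#' @rdname accessors
#' @export
setMethod("patientId", "Phantom", function(x) x@patientId)

#' @rdname accessors
#' @export
setMethod("site", "Phantom", function(x) x@site)

#' @rdname accessors
#' @export
setMethod("gridShape", "Phantom", function(x) x@grid@shape)

#' @rdname accessors
#' @export
setMethod("doseValues", "DoseGrid", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("abscissa", "CumHist", function(x) x@abscissa)

#' @rdname accessors
#' @export
setMethod("ordinate", "CumHist", function(x) x@ordinate)

#' @rdname accessors
#' @export
setMethod("curveKind", "CumHist", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("gantryAngles", "BeamSet", function(x) x@gantryAnglesDeg)

#' @rdname accessors
#' @export
setMethod("spread", "GRNNModel", function(x) x@spread)

#' @rdname accessors
#' @export
setMethod("patientId", "PlanRecord", function(x) x@patientId)

#' @rdname accessors
#' @export
setMethod("site", "PlanRecord", function(x) x@site)

#' @rdname accessors
#' @export
setMethod("ptvNames", "PlanRecord", function(x) x@ptvNames)

#' @rdname accessors
#' @export
setMethod("oarNames", "PlanRecord", function(x) x@oarNames)

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) cm\n",
              object@shape[1], object@shape[2], object@shape[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
})

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom '%s' (%s site)\n", object@patientId, object@site))
  show(object@grid)
  cat("  PTVs:", paste(object@ptvNames, collapse = ", "), "\n")
  cat("  OARs:", paste(object@oarNames, collapse = ", "), "\n")
})

setMethod("show", "DoseGrid", function(object) {
  v <- object@values[object@values > 0]
  cat(sprintf("DoseGrid '%s': max %.3g, mean(>0) %.3g over %d voxels\n",
              object@label, if (length(v)) max(v) else 0,
              if (length(v)) mean(v) else 0, length(v)))
})

setMethod("show", "CumHist", function(object) {
  cat(sprintf("%s of '%s' (%s): %d points, abscissa [%.3g, %.3g]\n",
              object@kind, object@structure, object@sourceLabel,
              length(object@abscissa), min(object@abscissa),
              max(object@abscissa)))
})

setMethod("show", "GRNNModel", function(object) {
  cat(sprintf("GRNNModel (%s) for '%s': %d exemplars, d = %d, spread = %.4g\n",
              object@method, object@structureType, nrow(object@exemplarsX),
              ncol(object@exemplarsX), object@spread))
})

setMethod("show", "PlanRecord", function(object) {
  cat(sprintf("PlanRecord '%s' (%s): %d structures, %d fields\n",
              object@patientId, object@site, length(object@curves),
              length(object@gantryAnglesDeg)))
})
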