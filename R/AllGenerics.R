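#' @include AllClasses.R
NULL

#' @rdname accessors
#' @export
setGeneric("structures", function(x) standardGeneric("structures"))

#' @rdname accessors
#' @export
setGeneric("structureMask", function(x, name) standardGeneric("structureMask"))

#' @rdname accessors
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))

#' @rdname accessors
#' @export
setGeneric("ptvNames", function(x) standardGeneric("ptvNames"))

#' @rdname accessors
#' @export
setGeneric("oarNames", function(x) standardGeneric("oarNames"))

#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname accessors
#' @export
setGeneric("site", function(x) standardGeneric("site"))

#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname accessors
#' @export
setGeneric("doseValues", function(x) standardGeneric("doseValues"))

#' @rdname accessors
#' @export
setGeneric("abscissa", function(x) standardGeneric("abscissa"))

#' @rdname accessors
#' @export
setGeneric("ordinate", function(x) standardGeneric("ordinate"))

#' @rdname accessors
#' @export
setGeneric("curveKind", function(x) standardGeneric("curveKind"))

#' @rdname accessors
#' @export
setGeneric("gantryAngles", function(x) standardGeneric("gantryAngles"))

#' @rdname accessors
#' @export
setGeneric("spread", function(x) standardGeneric("spread"))
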