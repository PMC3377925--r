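#' @rdname CaseGeometry-accessors
#' @param x object to query.
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))

#' @rdname CaseGeometry-accessors
#' @param name structure name.
#' @export
setGeneric("structureMask", function(x, name) standardGeneric("structureMask"))

#' @rdname CaseGeometry-accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname CaseGeometry-accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname CaseGeometry-accessors
#' @export
setGeneric("caseName", function(x) standardGeneric("caseName"))

#' @rdname CaseGeometry-accessors
#' @param target target structure name.
#' @export
setGeneric("prescriptionDose", function(x, target = "ptv")
  standardGeneric("prescriptionDose"))

#' @rdname Aperture-utils
#' @param x an \code{Aperture} (or object holding one).
#' @export
setGeneric("openArea", function(x) standardGeneric("openArea"))

#' @rdname TreatmentPlan-accessors
#' @param x a \code{TreatmentPlan}.
#' @export
setGeneric("numBeams", function(x) standardGeneric("numBeams"))

#' @rdname TreatmentPlan-accessors
#' @export
setGeneric("numSegments", function(x) standardGeneric("numSegments"))

#' @rdname TreatmentPlan-accessors
#' @export
setGeneric("segmentsPerBeam", function(x) standardGeneric("segmentsPerBeam"))

#' @rdname TreatmentPlan-accessors
#' @export
setGeneric("totalMU", function(x) standardGeneric("totalMU"))

#' @rdname TreatmentPlan-accessors
#' @export
setGeneric("planSegments", function(x) standardGeneric("planSegments"))

#' @rdname TreatmentPlan-accessors
#' @export
setGeneric("beamAngles", function(x) standardGeneric("beamAngles"))
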