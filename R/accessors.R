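#' Accessors for CaseGeometry
#'
#' @name CaseGeometry-accessors
#' @aliases structureNames structureMask voxelSize gridDim caseName
#'   prescriptionDose
NULL

#' @rdname CaseGeometry-accessors
#' @export
setMethod("structureNames", "CaseGeometry", function(x) names(x@structures))

#' @rdname CaseGeometry-accessors
#' @export
setMethod("structureMask", "CaseGeometry", function(x, name) {
  if (!name %in% names(x@structures))
    stop(sprintf("unknown structure '%s'; available: %s", name,
                 paste(names(x@structures), collapse = ", ")))
  x@structures[[name]]
})

#' @rdname CaseGeometry-accessors
#' @export
setMethod("voxelSize", "CaseGeometry", function(x) x@voxelSize)

#' @rdname CaseGeometry-accessors
#' @export
setMethod("gridDim", "CaseGeometry", function(x) x@gridDim)

#' @rdname CaseGeometry-accessors
#' @export
setMethod("caseName", "CaseGeometry", function(x) x@caseName)

#' @rdname CaseGeometry-accessors
#' @export
setMethod("prescriptionDose", "CaseGeometry", function(x, target = "ptv") {
  if (!target %in% names(x@prescription))
    stop(sprintf("no prescription for structure '%s'", target))
  unname(x@prescription[[target]])
})

#' Aperture utilities
#'
#' \code{openArea} returns the open area of an aperture in cm^2 (interval
#' width times leaf width, summed over open leaf pairs).
#'
#' @name Aperture-utils
NULL

#' @rdname Aperture-utils
#' @export
setMethod("openArea", "Aperture", function(x) {
  iv <- x@intervals
  open <- !is.na(iv[, 1L])
  if (!any(open)) return(0)
  sum((iv[open, 2L] - iv[open, 1L]) * x@leafWidth) / 100
})

#' @rdname Aperture-utils
#' @export
setMethod("openArea", "Segment", function(x) openArea(x@aperture))

#' Accessors for TreatmentPlan
#'
#' \code{numBeams} counts beams carrying at least one segment, \code{numSegments}
#' the total segment count, \code{segmentsPerBeam} the per-angle counts,
#' \code{totalMU} the summed segment weights (MU_eff), \code{beamAngles}
#' the distinct gantry angles in use, and \code{planSegments} the segment list.
#'
#' @name TreatmentPlan-accessors
NULL

#' @rdname TreatmentPlan-accessors
#' @export
setMethod("planSegments", "TreatmentPlan", function(x) x@segments)

#' @rdname TreatmentPlan-accessors
#' @export
setMethod("beamAngles", "TreatmentPlan", function(x)
  sort(unique(vapply(x@segments, function(s) s@beam@gantryAngle, numeric(1)))))

#' @rdname TreatmentPlan-accessors
#' @export
setMethod("numBeams", "TreatmentPlan", function(x) length(beamAngles(x)))

#' @rdname TreatmentPlan-accessors
#' @export
setMethod("numSegments", "TreatmentPlan", function(x) length(x@segments))

#' @rdname TreatmentPlan-accessors
#' @export
setMethod("segmentsPerBeam", "TreatmentPlan", function(x) {
  a <- vapply(x@segments, function(s) s@beam@gantryAngle, numeric(1))
  table(factor(format(a, nsmall = 4)))
})

#' @rdname TreatmentPlan-accessors
#' @export
setMethod("totalMU", "TreatmentPlan", function(x) {
  if (!length(x@segments)) return(0)
  sum(vapply(x@segments, function(s) s@weight, numeric(1)))
})

#' Replace the segment weights of a plan
#'
#' @param plan a \code{TreatmentPlan}.
#' @param weights numeric vector, one non-negative MU_eff value per segment.
#' @return the plan with updated weights.
#' @export
setPlanWeights <- function(plan, weights) {
  stopifnot(length(weights) == numSegments(plan), all(weights >= 0))
  plan@segments <- mapply(function(s, w) { s@weight <- w; s },
                          plan@segments, weights, SIMPLIFY = FALSE)
  plan
}

#' Extract the segment weights of a plan
#'
#' @param plan a \code{TreatmentPlan}.
#' @return numeric vector of MU_eff weights.
#' @export
planWeights <- function(plan)
  vapply(plan@segments, function(s) s@weight, numeric(1))
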