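#' @import methods
#' @importFrom stats quantile setNames
#' @importFrom utils modifyList
#' @importClassesFrom Matrix Matrix
NULL

# Coordinate conventions used throughout:
#  - voxel grids are (nx, ny, nz) arrays; world coordinates are mm relative to
#    the isocenter at the grid center; x = patient left-right, y = posterior->
#    anterior, z = longitudinal (cranio-caudal).
#  - gantry angle follows IEC 61217: 0 deg = source anterior (+y), increasing
#    clockwise viewed from the patient's feet.
#  - beam's-eye-view (BEV) x is the MLC leaf-travel axis (axial plane), BEV y
#    the leaf-stacking axis (patient longitudinal), both in mm at the
#    isocenter plane.

#' CaseGeometry: a voxel phantom with labelled structures
#'
#' Container for a 3D voxel phantom: grid shape, voxel size and a set of named
#' binary structure masks (at least \code{body} and \code{ptv}), plus the
#' prescription dose per target volume (the 100\% dose level used for all
#' relative-dose reporting).
#'
#' Validity requires every structure to lie inside \code{body}, the \code{ptv}
#' and \code{oar_primary} masks to be disjoint, and \code{ptv_boost} (when
#' present) to be nested inside \code{ptv}.
#'
#' @slot gridDim integer(3), voxel counts per axis.
#' @slot voxelSize numeric(3), voxel edge lengths in mm.
#' @slot structures named list of logical arrays of dimension \code{gridDim}.
#' @slot prescription named numeric, prescribed dose in Gy per target
#'   structure (names must be structure names).
#' @slot caseName character scalar label.
#' @export
setClass("CaseGeometry",
  representation(
    gridDim = "integer",
    voxelSize = "numeric",
    structures = "list",
    prescription = "numeric",
    caseName = "character"
  )
)

setValidity("CaseGeometry", function(object) {
  msg <- character()
  if (length(object@gridDim) != 3L || any(object@gridDim < 1L))
    msg <- c(msg, "gridDim must be three positive integers")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive lengths [mm]")
  st <- object@structures
  if (is.null(names(st)) || any(!nzchar(names(st))))
    msg <- c(msg, "all structures must be named")
  if (!all(c("body", "ptv") %in% names(st)))
    msg <- c(msg, "structures must include 'body' and 'ptv'")
  for (nm in names(st)) {
    m <- st[[nm]]
    if (!is.logical(m) || !identical(dim(m), as.integer(object@gridDim))) {
      msg <- c(msg, sprintf("structure '%s' must be a logical array of dim gridDim", nm))
      next
    }
  }
  if (length(msg) == 0L) {
    body <- st[["body"]]
    for (nm in setdiff(names(st), "body"))
      if (any(st[[nm]] & !body))
        msg <- c(msg, sprintf("structure '%s' extends outside 'body'", nm))
    if ("oar_primary" %in% names(st) && any(st[["ptv"]] & st[["oar_primary"]]))
      msg <- c(msg, "'ptv' and 'oar_primary' overlap")
    if ("ptv_boost" %in% names(st) && any(st[["ptv_boost"]] & !st[["ptv"]]))
      msg <- c(msg, "'ptv_boost' is not nested inside 'ptv'")
  }
  if (length(object@prescription)) {
    if (is.null(names(object@prescription)) ||
        !all(names(object@prescription) %in% names(st)))
      msg <- c(msg, "prescription names must be structure names")
    if (any(object@prescription <= 0))
      msg <- c(msg, "prescription doses must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CaseGeometry compact summary
#' @param object a \code{CaseGeometry}
#' @export
setMethod("show", "CaseGeometry", function(object) {
  cat(sprintf("CaseGeometry '%s': %s voxels at %s mm\n",
              object@caseName,
              paste(object@gridDim, collapse = "x"),
              paste(signif(object@voxelSize, 3), collapse = "x")))
  vols <- vapply(names(object@structures), function(nm)
    structureVolume(object, nm), numeric(1))
  cat("  structures [cm^3]:",
      paste(sprintf("%s=%.1f", names(vols), vols), collapse = ", "), "\n")
  if (length(object@prescription))
    cat("  prescription [Gy]:",
        paste(sprintf("%s=%g", names(object@prescription), object@prescription),
              collapse = ", "), "\n")
})

#' A treatment beam
#'
#' One coplanar external beam: gantry angle (IEC 61217), isocenter position
#' and source-axis distance.
#'
#' @slot gantryAngle numeric, degrees in [0, 360).
#' @slot isocenter numeric(3), mm in grid world coordinates.
#' @slot sad numeric, source-axis distance in mm (default 1000).
#' @export
setClass("Beam",
  representation(gantryAngle = "numeric", isocenter = "numeric", sad = "numeric"),
  prototype(isocenter = c(0, 0, 0), sad = 1000)
)

setValidity("Beam", function(object) {
  msg <- character()
  if (length(object@gantryAngle) != 1L || object@gantryAngle < 0 ||
      object@gantryAngle >= 360)
    msg <- c(msg, "gantryAngle must be a scalar in [0, 360)")
  if (length(object@isocenter) != 3L)
    msg <- c(msg, "isocenter must be numeric(3)")
  if (length(object@sad) != 1L || object@sad <= 0)
    msg <- c(msg, "sad must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a Beam
#'
#' @param gantryAngle gantry angle in degrees; normalized into [0, 360).
#' @param isocenter isocenter position, mm (default origin = grid center).
#' @param sad source-axis distance, mm.
#' @return a \code{\link{Beam}} object.
#' @export
Beam <- function(gantryAngle, isocenter = c(0, 0, 0), sad = 1000) {
  new("Beam", gantryAngle = normalizeAngle(gantryAngle),
      isocenter = as.numeric(isocenter), sad = as.numeric(sad))
}

setMethod("show", "Beam", function(object) {
  cat(sprintf("Beam: gantry %.2f deg, SAD %g mm\n",
              object@gantryAngle, object@sad))
})

#' Multi-leaf collimator model
#'
#' @slot leafWidth leaf width projected to the isocenter plane, mm.
#' @slot nLeafPairs number of opposed leaf pairs.
#' @slot maxFieldExtent maximum opening along the travel axis, mm.
#' @export
setClass("MLCModel",
  representation(leafWidth = "numeric", nLeafPairs = "integer",
                 maxFieldExtent = "numeric"))

setValidity("MLCModel", function(object) {
  msg <- character()
  if (object@leafWidth <= 0) msg <- c(msg, "leafWidth must be positive")
  if (object@nLeafPairs < 1L) msg <- c(msg, "nLeafPairs must be >= 1")
  if (object@maxFieldExtent <= 0) msg <- c(msg, "maxFieldExtent must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MLCModel", function(object) {
  cat(sprintf("MLCModel: %d leaf pairs x %g mm, travel extent %g mm\n",
              object@nLeafPairs, object@leafWidth, object@maxFieldExtent))
})

#' MLC presets
#'
#' Two collimator presets: a fine 4 mm-leaf head (\code{"s4"}) and a standard
#' 10 mm-leaf head (\code{"s10"}).
#'
#' @param name \code{"s4"} or \code{"s10"}.
#' @return an \code{\link{MLCModel}}.
#' @export
mlcPreset <- function(name = c("s4", "s10")) {
  name <- match.arg(name)
  switch(name,
    s4  = new("MLCModel", leafWidth = 4,  nLeafPairs = 40L, maxFieldExtent = 210),
    s10 = new("MLCModel", leafWidth = 10, nLeafPairs = 40L, maxFieldExtent = 400))
}

#' Beam's-eye-view raster of one structure
#'
#' Occupancy raster of a structure projected (divergently, from the point
#' source) onto the isocenter plane. Columns sample the leaf-travel axis at
#' \code{resolution} mm; each row is one MLC leaf pair.
#'
#' @slot occupancy logical matrix (leaf pairs x travel samples).
#' @slot xCenters numeric, travel-axis sample centers, mm.
#' @slot rowEdges numeric, leaf-pair boundaries along the stacking axis, mm
#'   (length nrow + 1).
#' @slot resolution numeric, travel-axis sampling step, mm.
#' @slot structureName character.
#' @slot gantryAngle numeric, degrees.
#' @export
setClass("BEVMask",
  representation(occupancy = "matrix", xCenters = "numeric",
                 rowEdges = "numeric", resolution = "numeric",
                 structureName = "character", gantryAngle = "numeric"))

setValidity("BEVMask", function(object) {
  msg <- character()
  if (!is.logical(object@occupancy)) msg <- c(msg, "occupancy must be logical")
  if (length(object@xCenters) != ncol(object@occupancy))
    msg <- c(msg, "xCenters length must equal ncol(occupancy)")
  if (length(object@rowEdges) != nrow(object@occupancy) + 1L)
    msg <- c(msg, "rowEdges length must equal nrow(occupancy) + 1")
  if (object@resolution <= 0) msg <- c(msg, "resolution must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BEVMask", function(object) {
  cat(sprintf("BEVMask '%s' at gantry %.1f deg: %d rows x %d samples (%g mm), area %.1f cm^2\n",
              object@structureName, object@gantryAngle,
              nrow(object@occupancy), ncol(object@occupancy),
              object@resolution, bevArea(object)))
})

#' A deliverable MLC aperture
#'
#' Per leaf pair either closed or a single open interval [x1, x2] in mm on
#' the isocenter plane (the step-and-shoot deliverability contract: at most
#' one opening per leaf pair).
#'
#' @slot intervals numeric matrix (leaf pairs x 2): columns x1 < x2; both NA
#'   for a closed pair.
#' @slot rowEdges numeric, leaf-pair boundaries, mm (length nrow + 1).
#' @slot leafWidth numeric, mm.
#' @slot valid logical: FALSE marks an aperture rejected by the validity
#'   rules (e.g. open area below threshold), used to drive beam discard.
#' @export
setClass("Aperture",
  representation(intervals = "matrix", rowEdges = "numeric",
                 leafWidth = "numeric", valid = "logical"))

setValidity("Aperture", function(object) {
  iv <- object@intervals
  msg <- character()
  if (ncol(iv) != 2L) msg <- c(msg, "intervals must have two columns")
  if (length(object@rowEdges) != nrow(iv) + 1L)
    msg <- c(msg, "rowEdges length must equal nrow(intervals) + 1")
  open <- !is.na(iv[, 1L])
  if (any(is.na(iv[open, 2L])))
    msg <- c(msg, "half-open interval (x1 set, x2 NA)")
  if (any(open) && !all(iv[open, 1L] < iv[open, 2L]))
    msg <- c(msg, "open intervals must have x1 < x2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Aperture", function(object) {
  nOpen <- sum(!is.na(object@intervals[, 1L]))
  cat(sprintf("Aperture: %d/%d leaf pairs open, area %.2f cm^2%s\n",
              nOpen, nrow(object@intervals), openArea(object),
              if (object@valid) "" else " [INVALID]"))
})

#' One plan segment
#'
#' A segment couples a beam, one deliverable aperture, its order tag (S0
#' conformal / S1 OAR-blocking / S2 rim strip) and a weight in effective
#' monitor units (MU_eff; 100 MU_eff deposit 1 Gy at reference conditions).
#'
#' @slot beam a \code{\link{Beam}}.
#' @slot aperture an \code{\link{Aperture}}.
#' @slot order character: "S0", "S1" or "S2".
#' @slot weight numeric, MU_eff >= 0.
#' @export
setClass("Segment",
  representation(beam = "Beam", aperture = "Aperture",
                 order = "character", weight = "numeric"))

setValidity("Segment", function(object) {
  msg <- character()
  if (!object@order %in% c("S0", "S1", "S2"))
    msg <- c(msg, "order must be one of S0, S1, S2")
  if (length(object@weight) != 1L || object@weight < 0 || !is.finite(object@weight))
    msg <- c(msg, "weight must be a finite non-negative scalar")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Segment", function(object) {
  cat(sprintf("Segment %s at gantry %.1f deg, %.1f MU_eff, area %.2f cm^2\n",
              object@order, object@beam@gantryAngle, object@weight,
              openArea(object@aperture)))
})

#' A step-and-shoot treatment plan
#'
#' An ordered collection of segments. Derived quantities: \code{numBeams}
#' (beams with at least one segment), \code{numSegments} (total), the
#' per-angle segment counts and the total MU_eff. Single-segment-per-beam
#' ("Fast") plans satisfy numSegments == numBeams.
#'
#' @slot segments list of \code{\link{Segment}}.
#' @slot caseName character, the phantom the plan was built for.
#' @slot plannedAngles numeric, the full equidistant angle set before any
#'   beam discard (degrees).
#' @slot arcDeg numeric, arc span of the planned angle set (degrees).
#' @slot name character plan label.
#' @slot discardLog data.frame logging every discarded beam or segment with
#'   its gantry angle, order and reason ("invalid_aperture" or "below_mu").
#' @export
setClass("TreatmentPlan",
  representation(segments = "list", caseName = "character",
                 plannedAngles = "numeric", arcDeg = "numeric",
                 name = "character", discardLog = "data.frame"),
  prototype(arcDeg = 360, name = "plan",
            discardLog = data.frame(angle = numeric(), order = character(),
                                    reason = character())))

setValidity("TreatmentPlan", function(object) {
  msg <- character()
  if (!all(vapply(object@segments, is, logical(1), class2 = "Segment")))
    msg <- c(msg, "segments must all be Segment objects")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TreatmentPlan", function(object) {
  cat(sprintf("TreatmentPlan '%s' (%s): n=%d beams, N=%d segments, %.1f MU_eff\n",
              object@name, object@caseName, numBeams(object),
              numSegments(object), totalMU(object)))
  if (numSegments(object)) {
    tab <- segmentsPerBeam(object)
    cat("  segments/beam:", paste(sprintf("%.0f:%d", as.numeric(names(tab)), tab),
                                  collapse = " "), "\n")
  }
})

#' Dose calibration model
#'
#' Primary-fluence dose model parameters. The output factor is set by
#' \code{\link{calibrate}} so that 100 MU_eff deposit 1 Gy on the central
#' axis of a 100 x 100 mm field at 100 mm depth, SAD 1000 mm.
#'
#' @slot muAttenuation linear attenuation coefficient, 1/mm.
#' @slot outputFactor Gy per MU_eff at reference conditions.
#' @slot penumbraSigma Gaussian penumbra sigma along the travel axis, mm.
#' @slot sad source-axis distance, mm.
#' @export
setClass("CalibrationModel",
  representation(muAttenuation = "numeric", outputFactor = "numeric",
                 penumbraSigma = "numeric", sad = "numeric"))

setValidity("CalibrationModel", function(object) {
  if (object@muAttenuation <= 0 || object@outputFactor <= 0 ||
      object@penumbraSigma < 0 || object@sad <= 0)
    "muAttenuation, outputFactor, sad must be positive; penumbraSigma >= 0"
  else TRUE
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel: mu=%g /mm, OF=%.5f Gy/MU_eff, sigma=%g mm, SAD=%g mm\n",
              object@muAttenuation, object@outputFactor,
              object@penumbraSigma, object@sad))
})

#' Influence matrix: per-beamlet unit dose
#'
#' Sparse matrix of dose per unit MU_eff: rows are scoring voxels (linear
#' grid indices in \code{voxelIndex}), columns are beamlets (leaf-row x
#' travel-step cells of the BEV raster, one set per beam angle). A segment's
#' unit dose is the sum of the beamlet columns its aperture opens; plan dose
#' is the weighted sum over segments. Gaussian leaf-edge penumbra is baked
#' into the beamlet kernels, and adjacent beamlet fluences telescope, so the
#' beamlet sum reproduces the full-aperture erf profile exactly.
#'
#' @slot matrix sparse dgCMatrix, scoring voxels x beamlets, Gy per MU_eff.
#' @slot voxelIndex integer, linear grid index of each scoring row.
#' @slot beamlets data.frame: angle, row (leaf pair), x0, x1 (mm edges).
#' @slot xEdges list per beam angle: the travel-axis beamlet edge grid, mm.
#' @slot caseName character.
#' @export
setClass("InfluenceMatrix",
  representation(matrix = "Matrix", voxelIndex = "integer",
                 beamlets = "data.frame", xEdges = "list",
                 caseName = "character"))

setValidity("InfluenceMatrix", function(object) {
  msg <- character()
  if (nrow(object@beamlets) != ncol(object@matrix))
    msg <- c(msg, "beamlets table must have one row per matrix column")
  if (length(object@voxelIndex) != nrow(object@matrix))
    msg <- c(msg, "voxelIndex length must equal nrow(matrix)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "InfluenceMatrix", function(object) {
  cat(sprintf("InfluenceMatrix '%s': %d scoring voxels x %d beamlets (%d beams), %.1f%% dense\n",
              object@caseName, nrow(object@matrix), ncol(object@matrix),
              length(unique(object@beamlets$angle)),
              100 * Matrix::nnzero(object@matrix) /
                (as.numeric(nrow(object@matrix)) * ncol(object@matrix))))
})

#' Linac delivery-time machine model
#'
#' Parameters of the plan delivery-time model: full-rotation gantry time,
#' gantry start-stop time, mean segment shaping time, per-beam data handling
#' time and dose rate. See \code{\link{machinePreset}} for the "old" and
#' "new" linac presets.
#'
#' @slot name character label.
#' @slot rotationTime seconds per full 360 degree gantry rotation.
#' @slot tauSS gantry start-stop time, s.
#' @slot tauS mean segment shaping time, s.
#' @slot tauF data handling time per beam, s.
#' @slot doseRate dose rate, MU_eff per minute.
#' @export
setClass("MachineModel",
  representation(name = "character", rotationTime = "numeric",
                 tauSS = "numeric", tauS = "numeric", tauF = "numeric",
                 doseRate = "numeric"))

setValidity("MachineModel", function(object) {
  vals <- c(object@rotationTime, object@tauSS, object@tauS, object@tauF,
            object@doseRate)
  if (any(!is.finite(vals)) || any(vals <= 0))
    "all machine parameters must be strictly positive"
  else TRUE
})

setMethod("show", "MachineModel", function(object) {
  cat(sprintf("MachineModel '%s': %g s/360deg, tauSS=%g s, tauS=%g s, tauF=%g s, %g MU_eff/min\n",
              object@name, object@rotationTime, object@tauSS, object@tauS,
              object@tauF, object@doseRate))
})
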