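# Construction of S0/S1/S2 apertures from PTV/OAR BEV topology and assembly
# of single-segment-per-beam ("Fast") and multi-segment plans.
#
# Segment orders:
#   S0 - conformal: covers the whole PTV shadow, row-wise convex hull.
#   S1 - covers the PTV but blocks the (margin-expanded) OAR shadow; only the
#        chosen side of the OAR is opened so consecutive beams need little
#        leaf travel.
#   S2 - narrow strip saturating the underdosed PTV rim immediately beside
#        the OAR shadow; only rows where the OAR is present.

#' Segmentation parameters
#'
#' @param oar_margin_mm margin added around the OAR shadow before blocking
#'   (approximates the penumbra), mm.
#' @param s2_width_mm fixed width of the S2 rim strip, mm; \code{NULL}
#'   selects the default rule: a quarter of the chosen-side PTV extent beyond
#'   the OAR edge in the central OAR row, clamped to [5, 30] mm.
#' @param min_open_area_cm2 validity threshold: apertures with less open
#'   area are marked invalid (drives beam discard in Fast plans). The
#'   default (1 cm^2) sits below the area of a typical rim (S2) strip on the
#'   bundled phantoms — rim segments are narrow by design — while still
#'   rejecting degenerate slivers.
#' @param side which side of the dominant OAR shadow to open ("left" = smaller
#'   BEV travel coordinate).
#' @return a list of class \code{segmentation_params}.
#' @export
segmentationParams <- function(oar_margin_mm = 3, s2_width_mm = NULL,
                               min_open_area_cm2 = 1,
                               side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(oar_margin_mm >= 0, min_open_area_cm2 > 0,
            is.null(s2_width_mm) || s2_width_mm > 0)
  structure(list(oar_margin_mm = oar_margin_mm, s2_width_mm = s2_width_mm,
                 min_open_area_cm2 = min_open_area_cm2, side = side),
            class = "segmentation_params")
}

newAperture <- function(intervals, rowEdges, leafWidth, valid = TRUE) {
  colnames(intervals) <- c("x1", "x2")
  new("Aperture", intervals = intervals, rowEdges = rowEdges,
      leafWidth = leafWidth, valid = valid)
}

# per-row [lo, hi] cell-edge interval of an occupancy row, or c(NA, NA)
rowHull <- function(occRow, xCenters, res) {
  w <- which(occRow)
  if (!length(w)) return(c(NA_real_, NA_real_))
  c(xCenters[w[1L]] - res / 2, xCenters[w[length(w)]] + res / 2)
}

apertureValid <- function(ap, minArea) {
  ap@valid <- any(!is.na(ap@intervals[, 1L])) && openArea(ap) >= minArea
  ap
}

#' Zeroth-order (conformal) aperture
#'
#' Opens, per leaf pair, the full extent of the PTV shadow in that row (the
#' row-wise convex hull), covering every occupied PTV cell without regard to
#' any OAR.
#'
#' @param ptvBev PTV \code{\link{BEVMask}}.
#' @param mlc an \code{\link{MLCModel}}.
#' @param params \code{\link{segmentationParams}}.
#' @return an \code{\link{Aperture}} (invalid if the PTV shadow is empty or
#'   the open area is below threshold).
#' @export
makeS0 <- function(ptvBev, mlc, params = segmentationParams()) {
  occ <- ptvBev@occupancy
  iv <- t(apply(occ, 1L, rowHull, xCenters = ptvBev@xCenters,
                res = ptvBev@resolution))
  ap <- newAperture(iv, ptvBev@rowEdges, mlc@leafWidth)
  apertureValid(ap, params$min_open_area_cm2)
}

# margin-expanded OAR interval per row: list of n x 2 matrix (NA = no OAR)
oarIntervals <- function(oarBev, margin) {
  iv <- t(apply(oarBev@occupancy, 1L, rowHull, xCenters = oarBev@xCenters,
                res = oarBev@resolution))
  iv[, 1L] <- iv[, 1L] - margin
  iv[, 2L] <- iv[, 2L] + margin
  iv
}

#' First-order (OAR-blocking) aperture
#'
#' Covers the PTV while blocking the margin-expanded OAR shadow. In rows
#' without OAR the S0 row is used; in rows with OAR only the chosen-side
#' portion of the PTV row strictly outside the expanded OAR interval is
#' opened; rows whose chosen side holds no PTV are closed. The aperture never
#' overlaps the expanded OAR shadow.
#'
#' @inheritParams makeS0
#' @param oarBev OAR \code{\link{BEVMask}} (same beam and raster lattice).
#' @return an \code{\link{Aperture}}.
#' @export
makeS1 <- function(ptvBev, oarBev, params = segmentationParams(), mlc) {
  al <- alignBEV(ptvBev, oarBev)
  ptv <- al[[1L]]; oar <- al[[2L]]
  pIv <- t(apply(ptv@occupancy, 1L, rowHull, xCenters = ptv@xCenters,
                 res = ptv@resolution))
  oIv <- oarIntervals(oar, params$oar_margin_mm)
  n <- nrow(pIv)
  iv <- matrix(NA_real_, n, 2L)
  for (r in seq_len(n)) {
    if (is.na(pIv[r, 1L])) next
    if (is.na(oIv[r, 1L])) { iv[r, ] <- pIv[r, ]; next }
    if (params$side == "left") {
      x1 <- pIv[r, 1L]; x2 <- min(oIv[r, 1L], pIv[r, 2L])
    } else {
      x1 <- max(oIv[r, 2L], pIv[r, 1L]); x2 <- pIv[r, 2L]
    }
    # open only if some PTV cells lie strictly on the chosen side
    hasPtv <- any(ptv@occupancy[r, ] & ptv@xCenters > x1 & ptv@xCenters < x2)
    if (x1 < x2 && hasPtv) iv[r, ] <- c(x1, x2)
  }
  ap <- newAperture(iv, ptv@rowEdges, mlc@leafWidth)
  apertureValid(ap, params$min_open_area_cm2)
}

# default S2 width rule: quarter of the chosen-side PTV extent beyond the
# OAR edge in the central OAR row, clamped to [5, 30] mm
s2Width <- function(pIv, oIv, params) {
  if (!is.null(params$s2_width_mm)) return(params$s2_width_mm)
  both <- which(!is.na(pIv[, 1L]) & !is.na(oIv[, 1L]))
  if (!length(both)) return(NA_real_)
  r <- both[ceiling(length(both) / 2)]
  ext <- if (params$side == "left") oIv[r, 1L] - pIv[r, 1L]
         else pIv[r, 2L] - oIv[r, 2L]
  min(max(0.25 * ext, 5), 30)
}

#' Second-order (rim) aperture
#'
#' A narrow strip immediately on the chosen side of the margin-expanded OAR
#' shadow, intersected with the S0 row interval — it saturates the PTV rim
#' left underdosed by S1 segments while still sparing the OAR. Rows without
#' OAR shadow are closed. If no row contains both PTV and OAR the aperture is
#' invalid (no rim to saturate), which drives beam discard in Fast plans.
#'
#' @inheritParams makeS1
#' @return an \code{\link{Aperture}}.
#' @export
makeS2 <- function(ptvBev, oarBev, params = segmentationParams(), mlc) {
  al <- alignBEV(ptvBev, oarBev)
  ptv <- al[[1L]]; oar <- al[[2L]]
  pIv <- t(apply(ptv@occupancy, 1L, rowHull, xCenters = ptv@xCenters,
                 res = ptv@resolution))
  oIv <- oarIntervals(oar, params$oar_margin_mm)
  n <- nrow(pIv)
  iv <- matrix(NA_real_, n, 2L)
  w2 <- s2Width(pIv, oIv, params)
  if (!is.na(w2) && w2 > 0) {
    for (r in seq_len(n)) {
      if (is.na(pIv[r, 1L]) || is.na(oIv[r, 1L])) next
      strip <- if (params$side == "left") c(oIv[r, 1L] - w2, oIv[r, 1L])
               else c(oIv[r, 2L], oIv[r, 2L] + w2)
      x1 <- max(strip[1L], pIv[r, 1L])
      x2 <- min(strip[2L], pIv[r, 2L])
      if (x1 < x2) iv[r, ] <- c(x1, x2)
    }
  }
  ap <- newAperture(iv, ptv@rowEdges, mlc@leafWidth)
  apertureValid(ap, params$min_open_area_cm2)
}

#' Cyclic assignment of segment orders to gantry angles
#'
#' @param nAngles number of gantry angles.
#' @param pattern character vector of segment orders, e.g.
#'   \code{c("S1", "S2")} or \code{c("S0", "S2", "S1", "S2", "S1", "S2")};
#'   repeated cyclically over the angle list.
#' @return character vector of length \code{nAngles}.
#' @export
assignOrderPattern <- function(nAngles, pattern) {
  stopifnot(nAngles >= 1, length(pattern) >= 1,
            all(pattern %in% c("S0", "S1", "S2")))
  rep(pattern, length.out = nAngles)
}

# build one aperture of the requested order for a beam; returns Aperture
buildAperture <- function(order, ptvBev, oarBev, params, mlc) {
  switch(order,
    S0 = makeS0(ptvBev, mlc, params),
    S1 = makeS1(ptvBev, oarBev, params, mlc),
    S2 = makeS2(ptvBev, oarBev, params, mlc))
}

emptyBEV <- function(template) {
  new("BEVMask", occupancy = matrix(FALSE, nrow(template@occupancy),
                                    ncol(template@occupancy)),
      xCenters = template@xCenters, rowEdges = template@rowEdges,
      resolution = template@resolution, structureName = "none",
      gantryAngle = template@gantryAngle)
}

projectPair <- function(case, beam, mlc, resolution, target, oarStructure) {
  ptvBev <- projectStructure(case, target, beam, mlc, resolution)
  oarBev <- if (!is.null(oarStructure) &&
                oarStructure %in% structureNames(case))
    projectStructure(case, oarStructure, beam, mlc, resolution)
  else emptyBEV(ptvBev)
  list(ptv = ptvBev, oar = oarBev)
}

#' Build a single-segment-per-beam ("Fast") plan
#'
#' Distributes a cyclic segment-order pattern over equidistant gantry angles
#' and constructs exactly one aperture per retained angle. Beams whose
#' assigned-order aperture is invalid (e.g. an S2 beam at an angle where the
#' OAR does not shadow the PTV) are discarded and logged. Initial segment
#' weights are uniform, pending weight optimization.
#'
#' @param case a \code{\link{CaseGeometry}}.
#' @param n number of planned gantry angles.
#' @param arcDeg arc span, degrees (360 = full circle).
#' @param pattern segment-order pattern, see \code{\link{assignOrderPattern}}.
#' @param params \code{\link{segmentationParams}}.
#' @param mlc an \code{\link{MLCModel}}.
#' @param resolution BEV raster step along the travel axis, mm.
#' @param startDeg first gantry angle.
#' @param target PTV structure used for segment shaping.
#' @param oarStructure dominant OAR structure (only this one is considered
#'   during pre-segmentation; others enter at optimization time).
#' @param initWeight initial MU_eff per segment.
#' @param sad source-axis distance, mm.
#' @param name plan label.
#' @return a \code{\link{TreatmentPlan}} with one segment per retained beam.
#' @export
buildFastPlan <- function(case, n, arcDeg = 360, pattern = c("S1", "S2"),
                          params = segmentationParams(), mlc = mlcPreset("s4"),
                          resolution = 2, startDeg = 0, target = "ptv",
                          oarStructure = "oar_primary", initWeight = 10,
                          sad = 1000, name = "fast") {
  angles <- equidistantAngles(n, startDeg, arcDeg)
  orders <- assignOrderPattern(length(angles), pattern)
  segs <- list()
  log <- data.frame(angle = numeric(), order = character(),
                    reason = character())
  for (i in seq_along(angles)) {
    beam <- Beam(angles[i], sad = sad)
    bev <- projectPair(case, beam, mlc, resolution, target, oarStructure)
    ap <- buildAperture(orders[i], bev$ptv, bev$oar, params, mlc)
    if (!ap@valid) {
      log <- rbind(log, data.frame(angle = angles[i], order = orders[i],
                                   reason = "invalid_aperture"))
      next
    }
    segs[[length(segs) + 1L]] <- new("Segment", beam = beam, aperture = ap,
                                     order = orders[i], weight = initWeight)
  }
  if (!length(segs))
    stop("empty plan: every beam was discarded (no valid aperture)")
  new("TreatmentPlan", segments = segs, caseName = case@caseName,
      plannedAngles = angles, arcDeg = arcDeg, name = name, discardLog = log)
}

#' Build a multi-segment plan (several orders per beam)
#'
#' Constructs every requested valid segment order at every gantry angle,
#' optionally with both left- and right-sided variants of S1 and S2 — the
#' conventional multi-segment reference against which Fast plans are
#' compared. Invalid apertures are skipped and logged.
#'
#' @inheritParams buildFastPlan
#' @param orders character vector of segment orders built per beam.
#' @param bothSides if TRUE, S1 and S2 are built for both sides of the OAR.
#' @return a \code{\link{TreatmentPlan}}.
#' @export
buildMultisegmentPlan <- function(case, n, arcDeg = 360,
                                  orders = c("S0", "S1", "S2"),
                                  bothSides = FALSE,
                                  params = segmentationParams(),
                                  mlc = mlcPreset("s4"), resolution = 2,
                                  startDeg = 0, target = "ptv",
                                  oarStructure = "oar_primary",
                                  initWeight = 10, sad = 1000,
                                  name = "multiseg") {
  stopifnot(length(orders) >= 1)
  angles <- equidistantAngles(n, startDeg, arcDeg)
  segs <- list()
  log <- data.frame(angle = numeric(), order = character(),
                    reason = character())
  for (i in seq_along(angles)) {
    beam <- Beam(angles[i], sad = sad)
    bev <- projectPair(case, beam, mlc, resolution, target, oarStructure)
    for (ord in orders) {
      sides <- if (bothSides && ord %in% c("S1", "S2")) c("left", "right")
               else params$side
      for (sd in sides) {
        pp <- params; pp$side <- sd
        ap <- buildAperture(ord, bev$ptv, bev$oar, pp, mlc)
        if (!ap@valid) {
          log <- rbind(log, data.frame(angle = angles[i], order = ord,
                                       reason = "invalid_aperture"))
          next
        }
        segs[[length(segs) + 1L]] <- new("Segment", beam = beam,
                                         aperture = ap, order = ord,
                                         weight = initWeight)
      }
    }
  }
  if (!length(segs)) stop("empty plan: no valid aperture at any angle")
  new("TreatmentPlan", segments = segs, caseName = case@caseName,
      plannedAngles = angles, arcDeg = arcDeg, name = name, discardLog = log)
}
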