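# Beam geometry: equidistant gantry angles and divergent beam's-eye-view
# (BEV) projection of structure masks onto the isocenter plane.

#' Equidistant gantry angles
#'
#' For a full circle the spacing is \code{arcDeg / n} (no duplicate beam at
#' 360 degrees); for a partial arc the \code{n} beams span the arc
#' inclusively with spacing \code{arcDeg / (n - 1)}.
#'
#' @param n number of beams (>= 1).
#' @param startDeg first gantry angle, degrees.
#' @param arcDeg arc span in (0, 360].
#' @return numeric vector of n angles, normalized to [0, 360).
#' @examples
#' equidistantAngles(9)          # 0, 40, 80, ...
#' equidistantAngles(10, 300, 190)
#' @export
equidistantAngles <- function(n, startDeg = 0, arcDeg = 360) {
  if (n < 1) stop("n must be >= 1")
  if (arcDeg <= 0 || arcDeg > 360) stop("arcDeg must lie in (0, 360]")
  ang <- if (arcDeg == 360) startDeg + (seq_len(n) - 1) * arcDeg / n
         else if (n == 1L) startDeg
         else startDeg + (seq_len(n) - 1) * arcDeg / (n - 1)
  normalizeAngle(ang)
}

# beam unit vectors in the axial plane: u = isocenter -> source,
# v = BEV travel axis (IEC 61217: gantry 0 anterior, clockwise from feet)
beamAxes <- function(gantryAngle) {
  th <- gantryAngle * pi / 180
  list(u = c(sin(th), cos(th)), v = c(cos(th), -sin(th)))
}

# leaf-row edge lattice: edges at integer multiples of leafWidth
rowEdgeRange <- function(yLo, yHi, leafWidth, mlc) {
  lo <- floor(yLo / leafWidth); hi <- ceiling(yHi / leafWidth)
  half <- mlc@nLeafPairs / 2
  lo <- max(lo, -half); hi <- min(hi, half)
  if (hi <= lo) c(lo, lo + 1) * leafWidth else (lo:hi) * leafWidth
}

#' Project a structure into the beam's-eye-view
#'
#' Divergent (point-source) projection of a structure mask onto the isocenter
#' plane: each voxel is projected through the source with magnification
#' SAD / (SAD - depth past isocenter), and its axial/longitudinal footprint
#' marks the BEV raster cells it overlaps. Columns sample the leaf-travel
#' axis at \code{resolution} mm (edges on the absolute \code{resolution}
#' lattice); rows are MLC leaf pairs (edges on the absolute leaf-width
#' lattice), so projections of different structures for the same beam align
#' cell-by-cell after \code{\link{alignBEV}}.
#'
#' @param case a \code{\link{CaseGeometry}}.
#' @param structure structure name.
#' @param beam a \code{\link{Beam}}.
#' @param mlc an \code{\link{MLCModel}}.
#' @param resolution travel-axis sampling step, mm; must not exceed half the
#'   leaf width.
#' @return a \code{\link{BEVMask}} (empty raster if the structure is empty).
#' @export
projectStructure <- function(case, structure, beam, mlc, resolution = 1) {
  if (resolution <= 0 || resolution > mlc@leafWidth / 2)
    stop("resolution must be positive and <= leafWidth / 2")
  mask <- structureMask(case, structure)
  lw <- mlc@leafWidth
  if (!any(mask)) {
    return(new("BEVMask",
               occupancy = matrix(FALSE, 1L, 1L),
               xCenters = resolution / 2, rowEdges = c(0, lw),
               resolution = resolution, structureName = structure,
               gantryAngle = beam@gantryAngle))
  }
  pc <- voxelCenters(case, mask)
  pc <- sweep(pc, 2L, beam@isocenter)
  ax <- beamAxes(beam@gantryAngle)
  sad <- beam@sad
  a <- -(pc[, 1L] * ax$u[1L] + pc[, 2L] * ax$u[2L])   # downstream of isocenter
  scale <- sad / (sad + a)
  xb <- (pc[, 1L] * ax$v[1L] + pc[, 2L] * ax$v[2L]) * scale
  yb <- pc[, 3L] * scale
  vs <- case@voxelSize
  hx <- 0.5 * max(vs[1L], vs[2L]) * scale
  hy <- 0.5 * vs[3L] * scale

  maxHalf <- mlc@maxFieldExtent / 2
  xEdgeLo <- max(floor(min(xb - hx) / resolution), -ceiling(maxHalf / resolution))
  xEdgeHi <- min(ceiling(max(xb + hx) / resolution), ceiling(maxHalf / resolution))
  nx <- max(xEdgeHi - xEdgeLo, 1L)
  xEdges <- (xEdgeLo + 0:nx) * resolution
  rowEdges <- rowEdgeRange(min(yb - hy), max(yb + hy), lw, mlc)
  nrows <- length(rowEdges) - 1L

  occ <- matrix(FALSE, nrows, nx)
  cLo <- pmax(floor((xb - hx) / resolution) - xEdgeLo + 1L, 1L)
  cHi <- pmin(ceiling((xb + hx) / resolution) - xEdgeLo, nx)
  rLo <- pmax(floor((yb - hy) / lw) - rowEdges[1L] / lw + 1L, 1L)
  rHi <- pmin(ceiling((yb + hy) / lw) - rowEdges[1L] / lw, nrows)
  keep <- cLo <= cHi & rLo <= rHi
  cLo <- cLo[keep]; cHi <- cHi[keep]; rLo <- rLo[keep]; rHi <- rHi[keep]
  if (length(cLo)) {
    for (dr in 0:max(rHi - rLo)) {
      rr <- rLo + dr
      okr <- rr <= rHi
      for (dc in 0:max(cHi - cLo)) {
        cc <- cLo + dc
        ok <- okr & cc <= cHi
        if (any(ok)) occ[cbind(rr[ok], cc[ok])] <- TRUE
      }
    }
  }
  new("BEVMask", occupancy = occ, xCenters = (xEdges[-1L] + xEdges[-length(xEdges)]) / 2,
      rowEdges = rowEdges, resolution = resolution,
      structureName = structure, gantryAngle = beam@gantryAngle)
}

#' Align two BEV masks onto a common raster
#'
#' Expands both masks to the union of their extents. Requires equal
#' resolution and leaf width lattices (guaranteed when both come from
#' \code{\link{projectStructure}} with the same beam/MLC settings).
#'
#' @param a,b \code{\link{BEVMask}} objects.
#' @return list of the two masks on identical rasters.
#' @export
alignBEV <- function(a, b) {
  stopifnot(abs(a@resolution - b@resolution) < 1e-9)
  res <- a@resolution
  lwA <- diff(a@rowEdges)[1L]; lwB <- diff(b@rowEdges)[1L]
  stopifnot(abs(lwA - lwB) < 1e-9)
  lw <- lwA
  xLo <- min(a@xCenters[1L], b@xCenters[1L]) - res / 2
  xHi <- max(a@xCenters[length(a@xCenters)], b@xCenters[length(b@xCenters)]) + res / 2
  nx <- round((xHi - xLo) / res)
  xCenters <- xLo + (seq_len(nx) - 0.5) * res
  rLo <- min(a@rowEdges[1L], b@rowEdges[1L])
  rHi <- max(a@rowEdges[length(a@rowEdges)], b@rowEdges[length(b@rowEdges)])
  rowEdges <- seq(rLo, rHi, by = lw)
  embed <- function(m) {
    occ <- matrix(FALSE, length(rowEdges) - 1L, nx)
    r0 <- round((m@rowEdges[1L] - rLo) / lw)
    c0 <- round((m@xCenters[1L] - res / 2 - xLo) / res)
    occ[r0 + seq_len(nrow(m@occupancy)), c0 + seq_len(ncol(m@occupancy))] <-
      m@occupancy
    new("BEVMask", occupancy = occ, xCenters = xCenters, rowEdges = rowEdges,
        resolution = res, structureName = m@structureName,
        gantryAngle = m@gantryAngle)
  }
  list(embed(a), embed(b))
}

#' Projected area of a BEV mask
#'
#' @param bev a \code{\link{BEVMask}}.
#' @return occupied area in cm^2.
#' @export
bevArea <- function(bev) {
  lw <- diff(bev@rowEdges)[1L]
  sum(bev@occupancy) * bev@resolution * lw / 100
}
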