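# Fixtures shared across the suite. Everything is generated in code;
# small grids keep each file fast.

# quasimodo phantom small enough for fast module tests
smallQuasi <- function(gridDim = c(96L, 96L, 8L), voxel = 2.5,
                       params = list(bodyAxes = c(220, 160))) {
  makePhantom("quasimodo", gridDim = gridDim, voxel = voxel, params = params)
}

# rectangular water slab with the beam entry surface at +y; isotropic voxels
# so the voxel-count radiological depth is exact along any axial ray
slabCase <- function(nx = 121L, ny = 201L, nz = 5L, voxel = 1,
                     ptvBox = NULL) {
  gd <- as.integer(c(nx, ny, nz))
  st <- list(body = array(TRUE, gd))
  ptv <- array(FALSE, gd)
  if (is.null(ptvBox)) {
    cx <- (nx + 1L) %/% 2L; cy <- (ny + 1L) %/% 2L; cz <- (nz + 1L) %/% 2L
    ptv[(cx - 2L):(cx + 2L), (cy - 2L):(cy + 2L), max(1L, cz - 1L):min(nz, cz + 1L)] <- TRUE
  } else {
    ptv[ptvBox$x, ptvBox$y, ptvBox$z] <- TRUE
  }
  st$ptv <- ptv
  new("CaseGeometry", gridDim = gd, voxelSize = rep(voxel, 3L),
      structures = st, prescription = c(ptv = 60), caseName = "slab")
}

# fully open rectangular aperture covering [x1,x2] x rows spanning [-h, h]
rectAperture <- function(x1, x2, rowEdges, leafWidth) {
  n <- length(rowEdges) - 1L
  newAp <- new("Aperture",
               intervals = cbind(x1 = rep(x1, n), x2 = rep(x2, n)),
               rowEdges = rowEdges, leafWidth = leafWidth, valid = TRUE)
  newAp
}

# a BEVMask built directly from a logical matrix (rows = leaf pairs)
bevFromMatrix <- function(occ, resolution = 2, leafWidth = 4, x0 = 0,
                          structureName = "ptv", gantryAngle = 0) {
  nr <- nrow(occ); nc <- ncol(occ)
  new("BEVMask", occupancy = occ,
      xCenters = x0 + (seq_len(nc) - 0.5) * resolution,
      rowEdges = (0:nr) * leafWidth - nr / 2 * leafWidth,
      resolution = resolution, structureName = structureName,
      gantryAngle = gantryAngle)
}

# random admissible quasimodo parameter set (fixed-seed property tests)
randomQuasiParams <- function() {
  list(bodyAxes = c(runif(1, 190, 230), runif(1, 150, 170)),
       oarRadius = runif(1, 15, 28),
       gap = runif(1, 6, 10),
       ptvThickness = runif(1, 14, 24),
       openingDeg = runif(1, 60, 130))
}

# brute-force per-row hull oracle on an occupancy matrix: list of c(x1,x2)
# cell-edge intervals or NA
rowHullOracle <- function(occ, xCenters, res) {
  t(apply(occ, 1L, function(row) {
    w <- which(row)
    if (!length(w)) return(c(NA_real_, NA_real_))
    c(xCenters[min(w)] - res / 2, xCenters[max(w)] + res / 2)
  }))
}

# sorting-free brute-force DVH oracle: largest dose d (scanning all values)
# such that at least v% of voxels receive >= d
dvhOracle <- function(doses, v) {
  cand <- sort(unique(doses))
  best <- cand[1L]
  for (d in cand) {
    if (mean(doses >= d) * 100 >= v - 1e-12) best <- d else break
  }
  best
}
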