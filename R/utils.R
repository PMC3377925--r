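# Internal geometry helpers.

#' Normalize angles into [0, 360)
#'
#' @param a numeric vector of angles in degrees.
#' @return angles wrapped into [0, 360).
#' @export
normalizeAngle <- function(a) {
  a <- a %% 360
  a[a < 0] <- a[a < 0] + 360
  # guard against 360 - eps rounding back to 360 after %%
  a[abs(a - 360) < 1e-9] <- 0
  a
}

# voxel-center coordinates along one axis, mm, isocenter at grid center
axisCoords <- function(n, d) (seq_len(n) - (n + 1) / 2) * d

# list(x=, y=, z=) of voxel-center coordinates for a case
gridCoords <- function(case) {
  gd <- case@gridDim; vs <- case@voxelSize
  list(x = axisCoords(gd[1L], vs[1L]),
       y = axisCoords(gd[2L], vs[2L]),
       z = axisCoords(gd[3L], vs[3L]))
}

# world coordinates (n x 3 matrix) of TRUE voxels of a mask
voxelCenters <- function(case, mask) {
  co <- gridCoords(case)
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = co$x[idx[, 1L]], y = co$y[idx[, 2L]], z = co$z[idx[, 3L]])
}

# 2D (axial, in-plane) erosion/dilation of a 3D mask by a disc of radius r mm.
# Implemented as AND/OR over integer voxel shifts inside the disc; adequate for
# the smooth analytic shapes the phantom factory produces.
maskMorph2D <- function(mask, r_mm, voxel_xy, op = c("erode", "dilate")) {
  op <- match.arg(op)
  if (r_mm <= 0) return(mask)
  rx <- floor(r_mm / voxel_xy[1L]); ry <- floor(r_mm / voxel_xy[2L])
  offs <- expand.grid(dx = -rx:rx, dy = -ry:ry)
  keep <- (offs$dx * voxel_xy[1L])^2 + (offs$dy * voxel_xy[2L])^2 <= r_mm^2
  offs <- offs[keep, , drop = FALSE]
  d <- dim(mask)
  out <- if (op == "erode") array(TRUE, d) else array(FALSE, d)
  for (k in seq_len(nrow(offs))) {
    sh <- shiftMask2D(mask, offs$dx[k], offs$dy[k], pad = (op == "dilate"))
    out <- if (op == "erode") out & sh else out | sh
  }
  if (op == "erode") out & mask else out
}

# shift a 3D mask in-plane by (dx, dy) voxels; out-of-range filled with
# FALSE when pad=FALSE semantics matter for erosion (treat outside as empty)
shiftMask2D <- function(mask, dx, dy, pad = FALSE) {
  d <- dim(mask)
  out <- array(FALSE, d)
  xs <- seq_len(d[1L]); ys <- seq_len(d[2L])
  xs_src <- xs - dx; ys_src <- ys - dy
  okx <- xs_src >= 1L & xs_src <= d[1L]
  oky <- ys_src >= 1L & ys_src <= d[2L]
  out[xs[okx], ys[oky], ] <- mask[xs_src[okx], ys_src[oky], , drop = FALSE]
  out
}

# rounding to the 0.1-precision used in delivery-time reports
round01 <- function(x) round(x, 1)

# canonical string key for a gantry angle (element-wise, padding-free)
angleKey <- function(a) sprintf("%.6f", a)
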