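# Synthetic voxel phantoms and per-case objective templates.

ellipseMask2D <- function(xg, yg, semi, center = c(0, 0)) {
  outer(((xg - center[1L]) / semi[1L])^2, ((yg - center[2L]) / semi[2L])^2, "+") <= 1
}

circleMask2D <- function(xg, yg, r, center = c(0, 0))
  ellipseMask2D(xg, yg, c(r, r), center)

# replicate an axial 2D mask over all z slices
stackAxial <- function(m2, nz) array(m2, dim = c(dim(m2), nz))

#' Generate a synthetic planning phantom
#'
#' Builds one of three synthetic planning cases on a water-equivalent
#' elliptical body:
#' \describe{
#'   \item{\code{quasimodo}}{a horseshoe (concave) PTV partially enclosing a
#'     central cylindrical OAR, separated by a narrow gap — the stress case
#'     for steep dose gradients around a dominant OAR.}
#'   \item{\code{sib}}{nested target volumes (outer PTV with an integrated
#'     central boost) indented by an adjacent OAR, plus a secondary OAR —
#'     a simultaneous-integrated-boost constellation.}
#'   \item{\code{tangent}}{a crescent-shaped PTV wrapped around a large
#'     lateral lung-like OAR, suited to partial-arc (tangent) planning.}
#' }
#' All masks are voxel-center rasterizations of analytic shapes. Derived help
#' structures (envelope rings, eroded central-plateau volumes, healthy
#' tissue) are included so the per-case objective templates can reference
#' them directly.
#'
#' @param preset one of \code{"quasimodo"}, \code{"sib"}, \code{"tangent"}.
#' @param gridDim integer(3) voxel counts (default 256 x 256 x 16).
#' @param voxel voxel edge length in mm (isotropic; default 2).
#' @param params named list overriding preset geometry parameters (mm):
#'   \code{bodyAxes} (full ellipse axes), and for \code{quasimodo}:
#'   \code{oarRadius}, \code{gap}, \code{ptvThickness}, \code{openingDeg}.
#'   Prescriptions (\code{rxGy}, and \code{rxBoostGy} for \code{sib}) are
#'   per fraction, so segment weights and plan MU_eff totals are on the
#'   scale of a single treatment session.
#' @return a \code{\link{CaseGeometry}}.
#' @examples
#' case <- makePhantom("quasimodo", gridDim = c(96, 96, 8), voxel = 2.5,
#'                     params = list(bodyAxes = c(220, 160)))
#' structureVolume(case, "ptv")
#' @export
makePhantom <- function(preset = c("quasimodo", "sib", "tangent"),
                        gridDim = c(256L, 256L, 16L), voxel = 2,
                        params = list()) {
  preset <- match.arg(preset)
  gridDim <- as.integer(gridDim)
  if (length(gridDim) != 3L || any(gridDim < 4L))
    stop("gridDim must be three integers >= 4")
  if (voxel <= 0) stop("voxel size must be positive")
  vs <- rep(voxel, 3L)
  xg <- axisCoords(gridDim[1L], vs[1L])
  yg <- axisCoords(gridDim[2L], vs[2L])
  nz <- gridDim[3L]

  p <- switch(preset,
    quasimodo = modifyList(list(bodyAxes = c(300, 200), oarRadius = 25,
                                gap = 5, ptvThickness = 20, openingDeg = 100,
                                plateauErosion = 5, envWidth = 10,
                                rxGy = 2), params),
    sib = modifyList(list(bodyAxes = c(300, 200), rxGy = 1.8, rxBoostGy = 2.3),
                     params),
    tangent = modifyList(list(bodyAxes = c(300, 200), rxGy = 2), params))

  semiBody <- p$bodyAxes / 2
  if (any(semiBody <= 0)) stop("bodyAxes must be positive")
  body2 <- ellipseMask2D(xg, yg, semiBody)
  st <- list(body = stackAxial(body2, nz))

  if (preset == "quasimodo") {
    if (p$oarRadius <= 0 || p$ptvThickness <= 0)
      stop("oarRadius and ptvThickness must be positive")
    if (p$openingDeg <= 0 || p$openingDeg >= 180)
      stop("openingDeg must lie in (0, 180) for a concave horseshoe")
    if (p$gap < 2 * voxel)
      stop(sprintf("grid too coarse: PTV-OAR gap (%g mm) < 2 voxels (%g mm)",
                   p$gap, 2 * voxel))
    rIn <- p$oarRadius + p$gap
    rOut <- rIn + p$ptvThickness
    if (rOut >= min(semiBody))
      stop("inconsistent radii: PTV annulus does not fit inside the body")
    r2 <- outer(xg^2, yg^2, "+")
    # axial polar angle, 0 = anterior (+y), clockwise towards +x;
    # horseshoe opening centered posteriorly (180 deg)
    phi <- normalizeAngle(atan2(outer(xg, rep(1, length(yg))),
                                outer(rep(1, length(xg)), yg)) * 180 / pi)
    inWedge <- abs(phi - 180) < p$openingDeg / 2
    oar2 <- r2 <= p$oarRadius^2
    ptv2 <- r2 >= rIn^2 & r2 <= rOut^2 & !inWedge
    st$oar_primary <- stackAxial(oar2, nz) & st$body
    st$ptv <- stackAxial(ptv2, nz) & st$body
    st$ptv_plateau <- maskMorph2D(st$ptv, p$plateauErosion, vs[1:2], "erode")
    env <- maskMorph2D(st$ptv, p$envWidth, vs[1:2], "dilate") &
      st$body & !st$ptv & !st$oar_primary
    st$envelope <- env
    st$neck <- stackAxial(inWedge & r2 <= (rOut + p$envWidth)^2, nz) &
      st$body & !st$ptv & !st$oar_primary
    st$healthy <- st$body & !st$ptv & !st$oar_primary & !st$envelope
    rx <- c(ptv = p$rxGy)
  } else if (preset == "sib") {
    outer2 <- ellipseMask2D(xg, yg, c(42, 36))
    oar2 <- circleMask2D(xg, yg, 16, c(0, -38))
    oarExp3 <- circleMask2D(xg, yg, 19, c(0, -38))
    oarExp5 <- circleMask2D(xg, yg, 21, c(0, -38))
    boost2 <- ellipseMask2D(xg, yg, c(26, 22), c(0, 4)) & !oarExp5
    eso2 <- circleMask2D(xg, yg, 8, c(0, -62))
    ptv2 <- outer2 & !oarExp3
    st$oar_primary <- stackAxial(oar2, nz) & st$body
    st$oar_secondary <- stackAxial(eso2, nz) & st$body & !st$oar_primary
    st$ptv <- stackAxial(ptv2, nz) & st$body
    st$ptv_boost <- stackAxial(boost2, nz) & st$ptv
    boostExp <- maskMorph2D(st$ptv_boost, 3, vs[1:2], "dilate")
    st$ptv_ring <- st$ptv & !boostExp
    st$boost_plateau <- maskMorph2D(st$ptv_boost, 4, vs[1:2], "erode")
    st$ptv_plateau <- maskMorph2D(st$ptv, 5, vs[1:2], "erode") & !boostExp
    st$gtv <- maskMorph2D(st$ptv_boost, 6, vs[1:2], "erode")
    ves2 <- xg >= -12 & xg <= 12
    ves <- stackAxial(outer(ves2, yg >= 20 & yg <= 34), nz) & st$ptv
    st$vesicles <- ves
    env1 <- maskMorph2D(st$ptv, 8, vs[1:2], "dilate")
    env2 <- maskMorph2D(st$ptv, 16, vs[1:2], "dilate")
    st$envelope <- env1 & st$body & !st$ptv & !st$oar_primary
    st$envelope2 <- env2 & st$body & !env1 & !st$oar_primary
    st$healthy <- st$body & !st$ptv & !st$oar_primary & !st$envelope
    rx <- c(ptv = p$rxGy, ptv_boost = p$rxBoostGy)
  } else { # tangent
    lungC <- c(-55, 5)
    lung2 <- ellipseMask2D(xg, yg, c(55, 45), lungC)
    shell <- ellipseMask2D(xg, yg, c(75, 62), lungC) &
      !ellipseMask2D(xg, yg, c(60, 49), lungC)
    psi <- atan2(outer(rep(1, length(xg)), yg - lungC[2L]),
                 outer(xg - lungC[1L], rep(1, length(yg)))) * 180 / pi
    psi <- psi %% 360
    window <- psi >= 45 & psi <= 250
    ptv2 <- shell & window
    st$oar_primary <- stackAxial(lung2, nz) & st$body
    st$ptv <- stackAxial(ptv2, nz) & st$body & !st$oar_primary
    st$contra_lung <- stackAxial(
      ellipseMask2D(xg, yg, c(55, 45), c(55, 5)), nz) & st$body & !st$ptv
    st$oar_secondary <- stackAxial(circleMask2D(xg, yg, 25, c(5, -15)), nz) &
      st$body & !st$ptv
    st$contra_breast <- stackAxial(circleMask2D(xg, yg, 25, c(70, 60)), nz) &
      st$body & !st$ptv
    st$ptv_plateau <- maskMorph2D(st$ptv, 5, vs[1:2], "erode")
    env1 <- maskMorph2D(st$ptv, 8, vs[1:2], "dilate")
    env2 <- maskMorph2D(st$ptv, 16, vs[1:2], "dilate")
    st$envelope <- env1 & st$body & !st$ptv & !st$oar_primary
    st$envelope2 <- env2 & st$body & !env1 & !st$oar_primary
    st$healthy <- st$body & !st$ptv & !st$envelope & !st$oar_primary
    rx <- c(ptv = p$rxGy)
  }

  core <- intersect(c("body", "ptv", "ptv_boost", "oar_primary"), names(st))
  empty <- core[vapply(core, function(nm) !any(st[[nm]]), logical(1))]
  if (length(empty))
    stop("grid too coarse: empty structure mask(s): ",
         paste(empty, collapse = ", "))

  new("CaseGeometry", gridDim = gridDim, voxelSize = vs, structures = st,
      prescription = rx, caseName = preset)
}

#' Structure volume
#'
#' @param case a \code{\link{CaseGeometry}}.
#' @param name structure name.
#' @return volume in cm^3 (voxel count times voxel volume).
#' @export
structureVolume <- function(case, name) {
  m <- structureMask(case, name)
  sum(m) * prod(case@voxelSize) / 1000
}

#' Per-case objective template
#'
#' Builds the weighted dose-volume objective set for a planning case. Each
#' row is one objective term: a DVH point \code{D_v} on a structure with a
#' lower bound (\code{kind = "lower"}: at least v\% of the volume must
#' receive at least \code{dose_pct}\%) or an upper bound, plus a penalty
#' weight. Doses are expressed in \% of the reference prescription given by
#' the \code{ref} column (\code{ref_gy} holds the resolved Gy value). The
#' target pattern follows common clinical practice: two terms near the
#' minimum dose (D_100 > 95, D_98 > 97), two near the maximum (D_02 < 102,
#' D_00 < 104) and a central-plateau window per target, with up to three
#' DVH-shaping terms per organ at risk. Per-case term counts: quasimodo 14,
#' sib-prostate 21, sib-spine 28, tangent 25. All weights lie in [0.1, 100].
#'
#' @param case a \code{\link{CaseGeometry}}.
#' @param preset objective preset; defaults to a preset matching the case.
#' @return a data.frame of objective terms (class \code{objective_set}) with
#'   columns structure, kind, vpct, dose_pct, weight, ref, ref_gy.
#' @export
makeObjectiveTemplate <- function(case,
    preset = c("auto", "quasimodo", "sib-prostate", "sib-spine", "tangent")) {
  preset <- match.arg(preset)
  if (preset == "auto")
    preset <- switch(case@caseName, quasimodo = "quasimodo",
                     sib = "sib-prostate", tangent = "tangent",
                     stop("no default objective preset for case '",
                          case@caseName, "'"))
  term <- function(structure, kind, vpct, dose_pct, weight, ref = "ptv")
    data.frame(structure = structure, kind = kind, vpct = vpct,
               dose_pct = dose_pct, weight = weight, ref = ref,
               stringsAsFactors = FALSE)
  obj <- switch(preset,
    quasimodo = rbind(
      term("ptv", "lower", 100, 95, 50), term("ptv", "lower", 98, 97, 50),
      term("ptv", "upper", 2, 102, 50),  term("ptv", "upper", 0, 104, 50),
      term("ptv_plateau", "lower", 50, 98, 10),
      term("ptv_plateau", "upper", 50, 102, 10),
      term("oar_primary", "upper", 5, 50, 20),
      term("oar_primary", "upper", 30, 30, 20),
      term("oar_primary", "upper", 50, 20, 20),
      term("envelope", "upper", 5, 90, 5), term("envelope", "upper", 50, 60, 1),
      term("neck", "upper", 50, 40, 1),
      term("healthy", "upper", 2, 70, 1), term("healthy", "upper", 0, 107, 10)),
    `sib-prostate` = rbind(
      term("ptv_boost", "lower", 100, 95, 50, "ptv_boost"),
      term("ptv_boost", "lower", 98, 97, 50, "ptv_boost"),
      term("ptv_boost", "upper", 2, 102, 50, "ptv_boost"),
      term("ptv_boost", "upper", 0, 104, 50, "ptv_boost"),
      term("boost_plateau", "lower", 50, 98, 10, "ptv_boost"),
      term("boost_plateau", "upper", 50, 102, 10, "ptv_boost"),
      term("ptv_ring", "lower", 100, 95, 30),
      term("ptv_ring", "lower", 98, 97, 30),
      term("ptv_ring", "upper", 2, 120, 10),
      term("ptv_ring", "upper", 0, 126, 10),
      term("vesicles", "lower", 90, 90, 5),
      term("vesicles", "upper", 0, 126, 1),
      term("envelope", "upper", 5, 95, 5), term("envelope", "upper", 50, 60, 1),
      term("envelope2", "upper", 5, 80, 2), term("envelope2", "upper", 50, 50, 1),
      term("oar_primary", "upper", 5, 75, 20),
      term("oar_primary", "upper", 30, 60, 10),
      term("oar_primary", "upper", 60, 40, 5),
      term("healthy", "upper", 2, 70, 1), term("healthy", "upper", 0, 107, 10)),
    `sib-spine` = rbind(
      term("gtv", "lower", 100, 95, 50, "ptv_boost"),
      term("gtv", "lower", 98, 97, 50, "ptv_boost"),
      term("gtv", "upper", 2, 104, 30, "ptv_boost"),
      term("gtv", "upper", 0, 107, 30, "ptv_boost"),
      term("ptv_boost", "lower", 100, 93, 40, "ptv_boost"),
      term("ptv_boost", "lower", 98, 95, 40, "ptv_boost"),
      term("ptv_boost", "upper", 2, 105, 20, "ptv_boost"),
      term("ptv_boost", "upper", 0, 108, 20, "ptv_boost"),
      term("boost_plateau", "lower", 50, 98, 10, "ptv_boost"),
      term("boost_plateau", "upper", 50, 103, 10, "ptv_boost"),
      term("ptv_ring", "lower", 100, 93, 20),
      term("ptv_ring", "lower", 98, 95, 20),
      term("ptv_ring", "upper", 2, 120, 10),
      term("ptv_ring", "upper", 0, 126, 10),
      term("ptv_plateau", "lower", 50, 96, 10),
      term("ptv_plateau", "upper", 50, 110, 5),
      term("oar_primary", "upper", 2, 50, 50),
      term("oar_primary", "upper", 30, 35, 20),
      term("oar_primary", "upper", 50, 25, 10),
      term("oar_secondary", "upper", 5, 60, 10),
      term("oar_secondary", "upper", 30, 45, 5),
      term("oar_secondary", "upper", 50, 30, 2),
      term("envelope", "upper", 5, 95, 5), term("envelope", "upper", 50, 60, 1),
      term("envelope2", "upper", 5, 80, 2), term("envelope2", "upper", 50, 50, 1),
      term("healthy", "upper", 2, 70, 1), term("healthy", "upper", 0, 107, 10)),
    tangent = rbind(
      term("ptv", "lower", 100, 95, 50), term("ptv", "lower", 98, 97, 50),
      term("ptv", "upper", 2, 102, 50),  term("ptv", "upper", 0, 104, 50),
      term("ptv_plateau", "lower", 50, 98, 10),
      term("ptv_plateau", "upper", 50, 102, 10),
      term("oar_primary", "upper", 5, 50, 20),
      term("oar_primary", "upper", 30, 20, 10),
      term("oar_primary", "upper", 50, 10, 5),
      term("oar_secondary", "upper", 2, 60, 10),
      term("oar_secondary", "upper", 30, 30, 5),
      term("oar_secondary", "upper", 50, 15, 2),
      term("contra_lung", "upper", 2, 20, 10),
      term("contra_lung", "upper", 30, 10, 5),
      term("contra_lung", "upper", 50, 5, 2),
      term("contra_breast", "upper", 2, 20, 5),
      term("contra_breast", "upper", 50, 5, 2),
      term("envelope", "upper", 2, 100, 5), term("envelope", "upper", 5, 90, 5),
      term("envelope", "upper", 50, 60, 1),
      term("envelope2", "upper", 2, 80, 2), term("envelope2", "upper", 5, 70, 2),
      term("envelope2", "upper", 50, 40, 1),
      term("healthy", "upper", 2, 70, 1), term("healthy", "upper", 0, 107, 10)))
  missing <- setdiff(unique(obj$structure), structureNames(case))
  if (length(missing))
    stop("objective template references missing structure(s): ",
         paste(missing, collapse = ", "))
  rxNames <- names(case@prescription)
  badRef <- setdiff(unique(obj$ref), rxNames)
  if (length(badRef))
    stop("no prescription for reference structure(s): ",
         paste(badRef, collapse = ", "))
  obj$ref_gy <- unname(case@prescription[obj$ref])
  class(obj) <- c("objective_set", "data.frame")
  obj
}
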