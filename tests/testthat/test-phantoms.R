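test_that("preset phantoms satisfy the geometry invariants", {
  set.seed(11)
  cases <- list(
    makePhantom("quasimodo", c(96L, 96L, 8L), 2.5,
                list(bodyAxes = c(220, 160))),
    makePhantom("sib", c(96L, 96L, 8L), 2.5, list(bodyAxes = c(220, 160))),
    makePhantom("tangent", c(128L, 128L, 8L), 2.5))
  for (i in 1:8)
    cases[[length(cases) + 1L]] <-
      makePhantom("quasimodo", c(72L, 64L, 6L), 3, randomQuasiParams())
  for (case in cases) {
    body <- structureMask(case, "body")
    for (nm in structureNames(case)) {
      m <- structureMask(case, nm)
      expect_true(any(m), info = paste(caseName(case), nm, "non-empty"))
      expect_false(any(m & !body), info = paste(caseName(case), nm, "in body"))
    }
    if ("oar_primary" %in% structureNames(case))
      expect_false(any(structureMask(case, "ptv") &
                         structureMask(case, "oar_primary")))
    if ("ptv_boost" %in% structureNames(case))
      expect_false(any(structureMask(case, "ptv_boost") &
                         !structureMask(case, "ptv")))
  }
})

test_that("quasimodo PTV-OAR gap matches the requested distance", {
  gap <- 6
  case <- makePhantom("quasimodo", c(80L, 72L, 4L), 2.5,
                      list(bodyAxes = c(200, 160), gap = gap))
  co <- TwoStepIMRT:::gridCoords(case)
  # both masks are z-uniform cylinders: the minimum is attained in one slice
  sl <- function(nm) which(structureMask(case, nm)[, , 1L], arr.ind = TRUE)
  p <- sl("ptv"); o <- sl("oar_primary")
  px <- co$x[p[, 1L]]; py <- co$y[p[, 2L]]
  ox <- co$x[o[, 1L]]; oy <- co$y[o[, 2L]]
  dmin <- sqrt(min(outer(px, ox, "-")^2 + outer(py, oy, "-")^2))
  diag2 <- sqrt(sum(voxelSize(case)[1:2]^2))
  expect_gte(dmin, gap)
  expect_lte(dmin, gap + diag2)
})

test_that("quasimodo PTV is concave around the OAR", {
  case <- smallQuasi()
  co <- TwoStepIMRT:::gridCoords(case)
  ptv <- structureMask(case, "ptv")[, , 4L]
  oar <- structureMask(case, "oar_primary")[, , 4L]
  idx <- which(ptv, arr.ind = TRUE)
  x <- co$x[idx[, 1L]]; y <- co$y[idx[, 2L]]
  phi <- TwoStepIMRT:::normalizeAngle(atan2(x, y) * 180 / pi)
  a <- which.min(abs(phi - 125)); b <- which.min(abs(phi - 235))
  # walk the straight line between the two horns and look for OAR voxels
  tt <- seq(0, 1, length.out = 200)
  lx <- x[a] + tt * (x[b] - x[a]); ly <- y[a] + tt * (y[b] - y[a])
  ix <- round(lx / voxelSize(case)[1L] + (gridDim(case)[1L] + 1) / 2)
  iy <- round(ly / voxelSize(case)[2L] + (gridDim(case)[2L] + 1) / 2)
  expect_true(any(oar[cbind(ix, iy)]))
})

test_that("objective templates reproduce the per-case counts and bounds", {
  quasi <- smallQuasi()
  sib <- makePhantom("sib", c(96L, 96L, 8L), 2.5,
                     list(bodyAxes = c(220, 160)))
  tang <- makePhantom("tangent", c(128L, 128L, 8L), 2.5)
  counts <- c(quasimodo = 14L, `sib-prostate` = 21L, `sib-spine` = 28L,
              tangent = 25L)
  sets <- list(makeObjectiveTemplate(quasi),
               makeObjectiveTemplate(sib, "sib-prostate"),
               makeObjectiveTemplate(sib, "sib-spine"),
               makeObjectiveTemplate(tang))
  for (k in seq_along(sets)) {
    obj <- sets[[k]]
    expect_identical(nrow(obj), counts[[k]])
    expect_true(all(obj$weight >= 0.1 & obj$weight <= 100))
    # every prescribed target carries >= 2 lower and >= 2 upper objectives
    for (tgt in intersect(unique(obj$ref), obj$structure)) {
      sub <- obj[obj$structure == tgt, ]
      expect_gte(sum(sub$kind == "lower"), 2L)
      expect_gte(sum(sub$kind == "upper"), 2L)
    }
  }
  expect_error(makeObjectiveTemplate(quasi, "sib-prostate"), "missing")
})

test_that("structure volumes follow voxel arithmetic and refine stably", {
  gd <- c(20L, 25L, 4L)
  m <- array(FALSE, gd); m[seq_len(1000)] <- TRUE
  st <- list(body = array(TRUE, gd), ptv = m,
             empty = array(FALSE, gd))
  case <- new("CaseGeometry", gridDim = gd, voxelSize = c(2, 2, 2),
              structures = st, prescription = c(ptv = 60),
              caseName = "toy")
  expect_equal(structureVolume(case, "ptv"), 8)
  expect_equal(structureVolume(case, "empty"), 0)
  expect_error(structureVolume(case, "nope"), "unknown structure")

  # sphere radius 20 mm rasterized at 1 mm vs the analytic volume
  n <- 45L
  co <- (seq_len(n) - (n + 1) / 2)
  r2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  sph <- array(r2 <= 20^2, c(n, n, n))
  caseS <- new("CaseGeometry", gridDim = rep(n, 3L), voxelSize = rep(1, 3L),
               structures = list(body = array(TRUE, rep(n, 3L)), ptv = sph),
               prescription = c(ptv = 60), caseName = "sphere")
  expect_lt(abs(structureVolume(caseS, "ptv") - 4 / 3 * pi * 8) / (4 / 3 * pi * 8),
            0.02)

  # halving the voxel size changes preset volumes by < 5%
  c4 <- makePhantom("quasimodo", c(60L, 50L, 4L), 4,
                    list(bodyAxes = c(200, 160), gap = 8))
  c2 <- makePhantom("quasimodo", c(120L, 100L, 8L), 2,
                    list(bodyAxes = c(200, 160), gap = 8))
  for (nm in c("ptv", "oar_primary", "body"))
    expect_lt(abs(structureVolume(c4, nm) - structureVolume(c2, nm)) /
                structureVolume(c2, nm), 0.05)
})

test_that("inadmissible phantom parameters are rejected with diagnostics", {
  expect_error(makePhantom("quasimodo", c(64L, 64L, 4L), 4,
                           list(gap = 5)), "too coarse")
  expect_error(makePhantom("quasimodo", c(96L, 96L, 4L), 2.5,
                           list(bodyAxes = c(80, 60), oarRadius = 25,
                                gap = 6, ptvThickness = 20)),
               "inconsistent radii")
  expect_error(makePhantom("quasimodo", c(96L, 96L, 4L), 2.5,
                           list(openingDeg = 190)), "openingDeg")
})
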