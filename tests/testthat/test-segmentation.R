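mlc4 <- mlcPreset("s4")

test_that("S0 equals the per-row hull (rectangles exact, concavities bridged)", {
  rect <- bevFromMatrix(matrix(TRUE, 4, 20))
  a <- makeS0(rect, mlc4)
  expect_true(a@valid)
  expect_equal(unname(a@intervals[, 1]), rep(rect@xCenters[1] - 1, 4))
  expect_equal(unname(a@intervals[, 2]), rep(rect@xCenters[20] + 1, 4))

  cshape <- matrix(TRUE, 4, 20)
  cshape[2:3, 8:13] <- FALSE          # concavity in the middle rows
  a2 <- makeS0(bevFromMatrix(cshape), mlc4)
  expect_equal(a2@intervals[2, ], a2@intervals[1, ])  # bridged

  single <- matrix(FALSE, 3, 10); single[2, 5] <- TRUE
  a3 <- makeS0(bevFromMatrix(single), mlc4, segmentationParams(
    min_open_area_cm2 = 0.001))
  expect_equal(unname(diff(a3@intervals[2, ])), 2)    # one raster cell wide
  expect_true(all(is.na(a3@intervals[c(1, 3), ])))
})

test_that("S1 blocks the expanded OAR and shrinks monotonically with margin", {
  ptv <- bevFromMatrix(matrix(TRUE, 4, 30))
  oarOcc <- matrix(FALSE, 4, 30); oarOcc[, 14:17] <- TRUE
  oar <- bevFromMatrix(oarOcc, structureName = "oar_primary")

  # disjoint OAR -> S1 == S0
  farOar <- bevFromMatrix(matrix(FALSE, 4, 30), structureName = "oar_primary")
  s1free <- makeS1(ptv, farOar, segmentationParams(), mlc4)
  s0 <- makeS0(ptv, mlc4)
  expect_equal(s1free@intervals, s0@intervals)

  p0 <- segmentationParams(oar_margin_mm = 0)
  p5 <- segmentationParams(oar_margin_mm = 5)
  s1a <- makeS1(ptv, oar, p0, mlc4)
  s1b <- makeS1(ptv, oar, p5, mlc4)
  # 5 mm margin aperture is a row-wise subset of the 0 mm aperture
  expect_true(all(s1b@intervals[, 1] >= s1a@intervals[, 1]))
  expect_true(all(s1b@intervals[, 2] <= s1a@intervals[, 2]))
  # zero raster overlap with the expanded OAR shadow
  al <- alignBEV(ptv, oar)
  oIv <- TwoStepIMRT:::oarIntervals(al[[2]], 5)
  for (r in seq_len(4)) {
    xs <- al[[1]]@xCenters
    inAp <- xs > s1b@intervals[r, 1] & xs < s1b@intervals[r, 2]
    inOar <- xs > oIv[r, 1] & xs < oIv[r, 2]
    expect_equal(sum(inAp & inOar), 0)
  }
})

test_that("S2 is a rim strip beside the OAR and degenerates predictably", {
  ptv <- bevFromMatrix(matrix(TRUE, 4, 30))
  oarOcc <- matrix(FALSE, 4, 30); oarOcc[, 14:17] <- TRUE
  oar <- bevFromMatrix(oarOcc, structureName = "oar_primary")
  prm <- segmentationParams(oar_margin_mm = 0, s2_width_mm = 6,
                            min_open_area_cm2 = 0.5)
  s2 <- makeS2(ptv, oar, prm, mlc4)
  expect_true(s2@valid)
  al <- alignBEV(ptv, oar)
  oLo <- al[[2]]@xCenters[14] - 1
  expect_equal(unname(s2@intervals[, 2]), rep(oLo, 4))
  expect_equal(unname(s2@intervals[, 1]), rep(oLo - 6, 4))
  # area equals the exhaustive raster count of strip-covered PTV cells
  expect_equal(openArea(s2), 4 * 6 * 4 / 100)

  # OAR absent -> invalid aperture (drives beam discard)
  none <- bevFromMatrix(matrix(FALSE, 4, 30), structureName = "oar_primary")
  expect_false(makeS2(ptv, none, prm, mlc4)@valid)
  # vanishing strip width -> open area below any sane threshold -> invalid
  tiny <- segmentationParams(oar_margin_mm = 0, s2_width_mm = 0.05)
  expect_false(makeS2(ptv, oar, tiny, mlc4)@valid)
})

test_that("order patterns repeat cyclically with the documented counts", {
  p <- assignOrderPattern(30, c("S1", "S2"))
  expect_equal(as.vector(table(p)[c("S1", "S2")]), c(15L, 15L))
  expect_equal(p[1:4], c("S1", "S2", "S1", "S2"))
  p23 <- assignOrderPattern(23, c("S0", "S1", "S2"))
  expect_equal(as.vector(table(p23)[c("S0", "S1", "S2")]), c(8L, 8L, 7L))
  pq <- assignOrderPattern(30, c("S0", "S2", "S1", "S2", "S1", "S2"))
  expect_equal(as.vector(table(pq)[c("S0", "S1", "S2")]), c(5L, 10L, 15L))
})

test_that("Fast plans keep one segment per retained beam", {
  case <- smallQuasi()
  plan <- buildFastPlan(case, 30, pattern = c("S1", "S2"), mlc = mlc4,
                        resolution = 2)
  expect_equal(numBeams(plan), 30)
  expect_equal(numSegments(plan), 30)
  expect_true(all(segmentsPerBeam(plan) == 1))
  expect_equal(nrow(plan@discardLog), 0)

  # without an OAR every S2 beam is discarded: N = ceil(n/2)
  noOar <- slabCase(nx = 61L, ny = 61L, nz = 5L, voxel = 2,
                    ptvBox = list(x = 22:40, y = 22:40, z = 1:5))
  p2 <- buildFastPlan(noOar, 9, pattern = c("S1", "S2"), mlc = mlc4,
                      resolution = 2)
  expect_equal(numSegments(p2), 5)
  expect_true(all(vapply(planSegments(p2), function(s) s@order,
                         character(1)) == "S1"))
  expect_equal(unique(p2@discardLog$order), "S2")
  expect_equal(unique(p2@discardLog$reason), "invalid_aperture")

  p1 <- buildFastPlan(case, 1, pattern = "S1", mlc = mlc4, resolution = 2)
  expect_equal(numSegments(p1), 1)
})

test_that("multi-segment plans enumerate every valid order per beam", {
  case <- smallQuasi()
  ref1 <- buildMultisegmentPlan(case, 9, orders = c("S0", "S1", "S2"),
                                mlc = mlc4, resolution = 2)
  expect_lte(numSegments(ref1), 27)
  ref2 <- buildMultisegmentPlan(case, 9, orders = c("S0", "S1", "S2"),
                                bothSides = TRUE, mlc = mlc4, resolution = 2)
  expect_lte(numSegments(ref2), 45)
  # exact count matches a per-beam validity enumeration
  prm <- segmentationParams()
  nValid <- 0L
  for (ang in equidistantAngles(9)) {
    bev <- TwoStepIMRT:::projectPair(case, Beam(ang), mlc4, 2, "ptv",
                                     "oar_primary")
    for (ord in c("S0", "S1", "S2")) {
      sides <- if (ord == "S0") "left" else c("left", "right")
      for (sd in sides) {
        pp <- prm; pp$side <- sd
        ap <- TwoStepIMRT:::buildAperture(ord, bev$ptv, bev$oar, pp, mlc4)
        if (ap@valid) nValid <- nValid + 1L
      }
    }
  }
  expect_equal(numSegments(ref2), nValid)
  ref15 <- buildMultisegmentPlan(case, 15, orders = c("S0", "S1", "S2"),
                                 mlc = mlc4, resolution = 2)
  expect_gte(numSegments(ref15), numSegments(ref1))
})

test_that("generated apertures honor deliverability and OAR blocking", {
  set.seed(33)
  nPh <- 25L
  for (k in seq_len(nPh)) {
    case <- makePhantom("quasimodo", c(72L, 64L, 6L), 3, randomQuasiParams())
    ang <- runif(1, 0, 360)
    bev <- TwoStepIMRT:::projectPair(case, Beam(ang), mlc4, 2, "ptv",
                                     "oar_primary")
    prm <- segmentationParams(side = sample(c("left", "right"), 1))
    s0 <- makeS0(bev$ptv, mlc4, prm)
    s1 <- makeS1(bev$ptv, bev$oar, prm, mlc4)
    s2 <- makeS2(bev$ptv, bev$oar, prm, mlc4)
    al <- alignBEV(bev$ptv, bev$oar)
    hull <- rowHullOracle(al[[1]]@occupancy, al[[1]]@xCenters, 2)
    oIv <- TwoStepIMRT:::oarIntervals(al[[2]], prm$oar_margin_mm)
    for (ap in list(s0, s1, s2)) {
      iv <- ap@intervals
      open <- !is.na(iv[, 1])
      expect_true(all(iv[open, 1] < iv[open, 2]))
    }
    # S0 covers the PTV shadow row hull exactly
    expect_equal(unname(s0@intervals), unname(hull))
    # S1/S2 never intersect the expanded OAR shadow (exact raster check)
    xs <- al[[1]]@xCenters
    for (ap in list(s1, s2)) {
      for (r in seq_len(nrow(ap@intervals))) {
        if (is.na(ap@intervals[r, 1]) || is.na(oIv[r, 1])) next
        inAp <- xs > ap@intervals[r, 1] & xs < ap@intervals[r, 2]
        inOar <- xs > oIv[r, 1] & xs < oIv[r, 2]
        expect_equal(sum(inAp & inOar), 0)
      }
    }
    # S2 stays inside the S0 row interval
    for (r in seq_len(nrow(s2@intervals))) {
      if (is.na(s2@intervals[r, 1]) || is.na(hull[r, 1])) next
      expect_gte(s2@intervals[r, 1], hull[r, 1] - 1e-9)
      expect_lte(s2@intervals[r, 2], hull[r, 2] + 1e-9)
    }
  }
})

test_that("mirroring the side parameter mirrors apertures on a symmetric phantom", {
  case <- smallQuasi()          # horseshoe is left-right symmetric
  bev <- TwoStepIMRT:::projectPair(case, Beam(0), mlc4, 2, "ptv",
                                   "oar_primary")
  sL <- makeS1(bev$ptv, bev$oar, segmentationParams(side = "left"), mlc4)
  sR <- makeS1(bev$ptv, bev$oar, segmentationParams(side = "right"), mlc4)
  open <- !is.na(sL@intervals[, 1])
  expect_equal(sL@intervals[open, 1], -sR@intervals[open, 2],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sL@intervals[open, 2], -sR@intervals[open, 1],
               tolerance = 1e-9, ignore_attr = TRUE)
})
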