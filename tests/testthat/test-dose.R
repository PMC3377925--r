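# Water slab with the beam entry edge at y = +100.5 mm (1 mm voxels), so the
# isocenter sits at 100.5 mm radiological depth.
referenceSlab <- function(voxel = 1) {
  ny <- as.integer(round(201 / voxel))
  if (ny %% 2L == 0L) ny <- ny + 1L
  slabCase(nx = as.integer(round(121 / voxel)), ny = ny, nz = 5L,
           voxel = voxel)
}

refSegment <- function(weight = 100) {
  rowEdges <- seq(-50, 50, by = 4)
  ap <- rectAperture(-50, 50, rowEdges, 4)
  new("Segment", beam = Beam(0), aperture = ap, order = "S0", weight = weight)
}

test_that("calibration delivers 1 Gy per 100 MU_eff at reference conditions", {
  case <- referenceSlab()
  calib <- calibrate()
  ud <- segmentUnitDose(case, refSegment(), calib)
  gd <- gridDim(case)
  iso <- ud[(gd[1] + 1) / 2, (gd[2] + 1) / 2, 3] * 100
  expect_lt(abs(iso - 1), 0.005)           # 1.000 Gy +/- 0.5%
  expect_equal(ud * 0, array(0, gd))       # linearity zero: 0 MU -> 0 Gy
  expect_lt(abs(ud[(gd[1] + 1) / 2, (gd[2] + 1) / 2, 3] * 50 - 0.5), 0.0025)
})

test_that("grid refinement keeps the reference-point contract within 0.5%", {
  for (v in c(2, 1)) {
    case <- referenceSlab(voxel = v)
    ud <- segmentUnitDose(case, refSegment(), calibrate())
    gd <- gridDim(case)
    iso <- ud[(gd[1] + 1) / 2, (gd[2] + 1) / 2, 3] * 100
    expect_lt(abs(iso - 1), 0.005 + 1e-12)
  }
})

test_that("central-axis depth dose follows the closed-form attenuation", {
  case <- referenceSlab()
  calib <- calibrate()
  ud <- segmentUnitDose(case, refSegment(), calib)
  gd <- gridDim(case)
  cx <- (gd[1] + 1) / 2; cy <- (gd[2] + 1) / 2
  d100 <- ud[cx, cy, 3]              # y = 0, depth 100.5, distance 1000
  d150 <- ud[cx, cy - 50L, 3]        # y = -50, depth 150.5, distance 1050
  expected <- exp(-calib@muAttenuation * 50) * (1000 / 1050)^2
  expect_lt(abs(d150 / d100 - expected) / expected, 0.01)
})

test_that("closed apertures give zero dose; mirror symmetry holds", {
  case <- referenceSlab(voxel = 2)
  rowEdges <- seq(-8, 8, by = 4)
  closed <- new("Aperture",
                intervals = matrix(NA_real_, 4, 2),
                rowEdges = rowEdges, leafWidth = 4, valid = FALSE)
  segC <- new("Segment", beam = Beam(0), aperture = closed, order = "S1",
              weight = 50)
  expect_equal(segmentUnitDose(case, segC), array(0, gridDim(case)))

  ap <- rectAperture(-20, 20, rowEdges, 4)       # mirror-symmetric in x
  seg <- new("Segment", beam = Beam(0), aperture = ap, order = "S0",
             weight = 1)
  ud <- segmentUnitDose(case, seg)
  gd <- gridDim(case)
  mid <- ud[, (gd[2] + 1) / 2, 2]
  expect_equal(mid, rev(mid), tolerance = 1e-9)
})

test_that("dose is monotone in the aperture without penumbra", {
  case <- referenceSlab(voxel = 2)
  calib0 <- calibrate(penumbraSigma = 0)
  rowEdges <- seq(-8, 8, by = 4)
  small <- new("Segment", beam = Beam(40),
               aperture = rectAperture(-10, 10, rowEdges, 4),
               order = "S0", weight = 1)
  big <- new("Segment", beam = Beam(40),
             aperture = rectAperture(-20, 16, rowEdges, 4),
             order = "S0", weight = 1)
  udS <- segmentUnitDose(case, small, calib0)
  udB <- segmentUnitDose(case, big, calib0)
  expect_true(all(udB - udS >= -1e-12))
})

test_that("plan dose is exactly linear in the segment weights", {
  case <- smallQuasi()
  plan <- buildFastPlan(case, 6, pattern = c("S1", "S2"), resolution = 2)
  infl <- buildInfluence(case, plan, resolution = 2)
  segDose <- segmentDoseMatrix(infl, plan)
  w <- seq_len(numSegments(plan)) * 10
  p1 <- setPlanWeights(plan, w)
  p2 <- setPlanWeights(plan, 2 * w)
  d1 <- planDose(p1, infl, segDose)
  expect_equal(planDose(p2, infl, segDose), 2 * d1, tolerance = 1e-12)
  expect_equal(planDose(setPlanWeights(plan, 0 * w), infl, segDose),
               rep(0, nrow(segDose)))
  # two identical segments at weight w == one segment at weight 2w
  s <- planSegments(plan)[[1]]
  ud <- segmentUnitDose(case, s)
  s2 <- s; s2@weight <- 2 * s@weight
  expect_equal(s@weight * ud + s@weight * ud, s2@weight * ud,
               tolerance = 1e-12)
})

test_that("beamlet influence columns reproduce the direct aperture trace", {
  case <- smallQuasi()
  plan <- buildFastPlan(case, 4, pattern = "S0", resolution = 2)
  calib <- calibrate()
  infl <- buildInfluence(case, plan, calib, resolution = 2)
  segDose <- segmentDoseMatrix(infl, plan)
  for (j in seq_len(numSegments(plan))) {
    direct <- segmentUnitDose(case, planSegments(plan)[[j]], calib)
    dVec <- direct[infl@voxelIndex]
    # beamlet kernels are truncated at 4 sigma -> sub-percent tail loss
    expect_lt(max(abs(segDose[, j] - dVec)), 0.012 * max(dVec))
    expect_lt(sum(abs(segDose[, j] - dVec)) / sum(dVec), 0.005)
  }
})

test_that("missing influence for a segment is reported by name", {
  case <- smallQuasi()
  plan <- buildFastPlan(case, 4, pattern = "S0", resolution = 2)
  infl <- buildInfluence(case, plan, resolution = 2)
  segDose <- segmentDoseMatrix(infl, plan)
  bigger <- buildFastPlan(case, 6, pattern = "S0", resolution = 2)
  expect_error(planDose(bigger, infl, segDose), "missing influence")
})
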