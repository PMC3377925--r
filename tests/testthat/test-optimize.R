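# A small planning context reused by the optimizer tests: one horseshoe
# phantom, a handful of beams, band-surrogate scoring by default.
miniContext <- function(n = 8, pattern = c("S1", "S2")) {
  case <- smallQuasi(gridDim = c(64L, 64L, 6L), voxel = 3,
                     params = list(bodyAxes = c(180, 150), gap = 6))
  plan <- buildFastPlan(case, n, pattern = pattern, resolution = 2)
  infl <- buildInfluence(case, plan, resolution = 2)
  obj <- makeObjectiveTemplate(case)
  list(case = case, plan = plan, infl = infl, obj = obj)
}

test_that("a single weight is recovered within 1% of the closed form", {
  case <- slabCase(nx = 41L, ny = 41L, nz = 5L, voxel = 2,
                   ptvBox = list(x = 15:27, y = 15:27, z = 2:4))
  plan <- buildFastPlan(case, 1, pattern = "S0", resolution = 2,
                        oarStructure = NULL)
  infl <- buildInfluence(case, plan, resolution = 2)
  segDose <- segmentDoseMatrix(infl, plan)
  # paired lower/upper objective at 100% pins D_50 to the prescription:
  # the optimum weight is rx / (unit D_50) in closed form
  obj <- data.frame(structure = "ptv", kind = c("lower", "upper"),
                    vpct = 50, dose_pct = 100, weight = 1,
                    ref = "ptv", ref_gy = 60)
  pIdx <- which(structureMask(case, "ptv")[infl@voxelIndex])
  unitD50 <- dvhPercentile(segDose[pIdx, 1], 50)
  wStar <- 60 / unitD50
  res <- optimizeWeights(plan, infl, obj, case,
                         optimizerConfig(normalize_init = FALSE))
  expect_lt(abs(planWeights(res$plan) - wStar) / wStar, 0.01)
})

test_that("two weights match the 2x2 linear-system solution within 1%", {
  gd <- c(41L, 41L, 5L)
  st <- list(body = array(TRUE, gd), ptv = array(FALSE, gd),
             boxA = array(FALSE, gd), boxB = array(FALSE, gd))
  st$ptv[13:29, 13:29, 2:4] <- TRUE
  st$boxA[21, 27, 3] <- TRUE           # single-voxel probes: D_v is exact
  st$boxB[27, 21, 3] <- TRUE
  case <- new("CaseGeometry", gridDim = gd, voxelSize = rep(2, 3),
              structures = st, prescription = c(ptv = 60), caseName = "toy")
  # two perpendicular beams (0 and 90 degrees) give a well-conditioned system
  plan <- buildFastPlan(case, 2, arcDeg = 90, pattern = "S0", resolution = 2,
                        oarStructure = NULL)
  infl <- buildInfluence(case, plan, resolution = 2)
  segDose <- segmentDoseMatrix(infl, plan)
  obj <- data.frame(structure = rep(c("boxA", "boxB"), each = 2),
                    kind = rep(c("lower", "upper"), 2),
                    vpct = 50, dose_pct = c(100, 100, 90, 90), weight = 1,
                    ref = "ptv", ref_gy = 60)
  iA <- which(structureMask(case, "boxA")[infl@voxelIndex])
  iB <- which(structureMask(case, "boxB")[infl@voxelIndex])
  A <- rbind(segDose[iA, ], segDose[iB, ])
  wStar <- solve(A, c(60, 0.9 * 60))
  expect_true(all(wStar > 0))          # interior optimum: NNLS == LS here
  res <- optimizeWeights(plan, infl, obj, case,
                         optimizerConfig(normalize_init = FALSE))
  expect_lt(max(abs(planWeights(res$plan) - wStar) / wStar), 0.01)
})

test_that("COV traces are non-increasing and no survivor is below 2 MU", {
  mc <- miniContext()
  for (cfg in list(optimizerConfig(runs = 2, steps = 10),
                   optimizerConfig(runs = 2, steps = 10, scoring = "dvh",
                                   aperture_sweeps = 1, pre_sweeps = 1,
                                   move_limit = 2))) {
    resW <- optimizeWeights(mc$plan, mc$infl, mc$obj, mc$case, cfg)
    expect_true(all(diff(resW$trace) <= 1e-9))
    expect_true(all(planWeights(resW$plan) >= cfg$mu_discard))
    resT <- fineTunePlan(mc$plan, mc$infl, mc$obj, mc$case, cfg)
    expect_true(all(diff(resT$trace) <= 1e-9))
    expect_true(all(planWeights(resT$plan) >= cfg$mu_discard))
  }
})

test_that("a segment dosing only a penalized organ is discarded at the run boundary", {
  # slab with a central PTV plus a far OAR-like box that only the second
  # segment irradiates: pure penalty, no coverage benefit
  gd <- c(41L, 41L, 5L)
  st <- list(body = array(TRUE, gd), ptv = array(FALSE, gd),
             farbox = array(FALSE, gd))
  st$ptv[15:27, 15:27, 2:4] <- TRUE
  st$farbox[15:27, 6:10, 2:4] <- TRUE      # y in [-30, -20] mm
  case <- new("CaseGeometry", gridDim = gd, voxelSize = rep(2, 3),
              structures = st, prescription = c(ptv = 60), caseName = "toy")
  plan <- buildFastPlan(case, 1, pattern = "S0", resolution = 2,
                        oarStructure = NULL)
  # second segment from the side, shadowing only the far box
  apFar <- rectAperture(20, 30, seq(-8, 8, by = 4), 4)
  segFar <- new("Segment", beam = Beam(90), aperture = apFar, order = "S0",
                weight = 10)
  plan@segments <- c(plan@segments, list(segFar))
  infl <- buildInfluence(case, plan, resolution = 2)
  obj <- data.frame(structure = c("ptv", "ptv", "farbox"),
                    kind = c("lower", "upper", "upper"),
                    vpct = c(50, 50, 0), dose_pct = c(100, 100, 2),
                    weight = c(1, 1, 100), ref = "ptv", ref_gy = 60)
  res <- optimizeWeights(plan, infl, obj, case,
                         optimizerConfig(runs = 2, steps = 15,
                                         normalize_init = FALSE))
  expect_equal(numSegments(res$plan), 1L)
  expect_true("below_mu" %in% res$plan@discardLog$reason)
  expect_equal(planSegments(res$plan)[[1]]@beam@gantryAngle, 0)
})

test_that("aperture fine-tuning finds the exhaustive single-leaf optimum", {
  case <- slabCase(nx = 41L, ny = 41L, nz = 6L, voxel = 2,
                   ptvBox = list(x = 13:29, y = 13:29, z = 2:5))
  plan <- buildFastPlan(case, 1, pattern = "S0", resolution = 2,
                        oarStructure = NULL)
  seg <- planSegments(plan)[[1]]
  r <- 2L
  seg@aperture@intervals[r, 2] <- seg@aperture@intervals[r, 2] - 8  # over-blocked
  plan@segments[[1]] <- seg
  infl <- buildInfluence(case, plan, resolution = 2, padMM = 16)
  obj <- data.frame(structure = "ptv", kind = c("lower", "upper"),
                    vpct = c(100, 0), dose_pct = c(98, 102), weight = 1,
                    ref = "ptv", ref_gy = 60)
  cfg <- optimizerConfig(runs = 1, steps = 10, aperture_sweeps = 2,
                         pre_sweeps = 1, move_limit = 8,
                         normalize_init = TRUE)
  res <- fineTunePlan(plan, infl, obj, case, cfg)
  # iterate to the joint weight/shape fixed point
  cfgFP <- optimizerConfig(runs = 1, steps = 5, aperture_sweeps = 1,
                           pre_sweeps = 1, move_limit = 8,
                           normalize_init = FALSE)
  for (it in 1:6) {
    nxt <- fineTunePlan(res$plan, infl, obj, case, cfgFP)
    same <- identical(planSegments(nxt$plan)[[1]]@aperture@intervals,
                      planSegments(res$plan)[[1]]@aperture@intervals)
    res <- nxt
    if (same) break
  }
  tuned <- unname(planSegments(res$plan)[[1]]@aperture@intervals[r, 2])

  # exhaustive oracle over that leaf edge on the beamlet lattice, at the
  # tuned plan's weight
  wT <- planWeights(res$plan)
  ctx <- TwoStepIMRT:::objectiveContext(case, obj, infl@voxelIndex)
  ge <- infl@xEdges[[TwoStepIMRT:::angleKey(0)]]
  cand <- ge$xEdges[ge$xEdges > seg@aperture@intervals[r, 1]]
  best <- NULL
  for (x2 in cand) {
    p2 <- res$plan
    s2 <- planSegments(p2)[[1]]
    s2@aperture@intervals[r, 2] <- x2
    p2@segments[[1]] <- s2
    covHere <- TwoStepIMRT:::covOnly(wT, segmentDoseMatrix(infl, p2), ctx, cfg)
    if (is.null(best) || covHere < best$cov) best <- list(cov = covHere, x2 = x2)
  }
  expect_equal(tuned, best$x2)
  # fixed point: re-running the sweep leaves the plan unchanged
  res2 <- fineTunePlan(res$plan, infl, obj, case,
                       optimizerConfig(runs = 1, steps = 1,
                                       aperture_sweeps = 1, pre_sweeps = 1,
                                       move_limit = 8,
                                       normalize_init = FALSE))
  expect_equal(planSegments(res2$plan)[[1]]@aperture@intervals,
               planSegments(res$plan)[[1]]@aperture@intervals)
})
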