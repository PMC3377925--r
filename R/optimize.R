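# Fine-tuning of segment weights and apertures: projected-gradient descent
# on the composite objective value over non-negative MU_eff weights, and
# greedy coordinate descent over leaf positions, with low-MU segments
# discarded at run boundaries.

#' Optimizer configuration
#'
#' @param runs number of consecutive optimization runs (segments below the
#'   MU threshold are discarded at the end of each run).
#' @param steps weight-update steps per run (default 2 x 40 = 80 total).
#' @param mu_discard segments with weight below this MU_eff value at a run
#'   boundary are removed from the plan.
#' @param move_limit maximum leaf moves (in beamlet steps) per leaf edge per
#'   aperture sweep.
#' @param aperture_sweeps aperture coordinate-descent sweeps per run,
#'   interleaved before each block of weight steps (0 disables shape
#'   fine-tuning).
#' @param pre_sweeps shape-conditioning aperture sweeps executed once before
#'   the first run, while the weight distribution is still uniform.
#' @param window_frac fraction of a structure's voxels averaged around the
#'   DVH quantile when forming the weight subgradient.
#' @param scoring objective scoring mode used inside the optimizer:
#'   \code{"band"} (default) scores each DVH objective as a per-voxel
#'   quadratic sum over the voxels between the current D_v and the objective
#'   level (a smooth surrogate with the same zero set as the DVH-point
#'   penalty); \code{"dvh"} scores the DVH statistic itself (the reported
#'   COV). Reported plan quality always uses the DVH statistic
#'   (\code{\link{compositeObjectiveValue}}).
#' @param normalize_init if TRUE, initial weights are scaled uniformly so the
#'   mean target dose equals the prescription before optimization starts.
#' @param target structure whose mean dose anchors the initial scaling.
#' @param seed integer seed fixing any stochastic component (the default
#'   path is fully deterministic; the seed also freezes tie-breaks).
#' @return a list of class \code{optimizer_config}.
#' @export
optimizerConfig <- function(runs = 2, steps = 40, mu_discard = 2,
                            move_limit = 8, aperture_sweeps = 6,
                            pre_sweeps = 6, window_frac = 0.01,
                            scoring = c("band", "dvh"),
                            normalize_init = TRUE, target = "ptv",
                            seed = 0) {
  scoring <- match.arg(scoring)
  stopifnot(runs >= 1, steps >= 1, mu_discard >= 0, move_limit >= 0,
            pre_sweeps >= 0)
  structure(list(runs = runs, steps = steps, mu_discard = mu_discard,
                 move_limit = move_limit, aperture_sweeps = aperture_sweeps,
                 pre_sweeps = pre_sweeps, window_frac = window_frac,
                 scoring = scoring, normalize_init = normalize_init,
                 target = target, seed = seed),
            class = "optimizer_config")
}

# Search directions and acceptance value at weights w.
# Directions always come from the smooth DVH-aware band surrogate (gradient
# + Gauss-Newton Hessian over the active voxel bands); the acceptance value
# `cov` is scored in the configured mode (default: the DVH-statistic COV
# itself, so accepted iterations are monotone in the reported metric). The
# DVH-statistic subgradient is kept as a fallback direction.
covAndGrad <- function(w, segDose, ctx, config) {
  doseGy <- as.numeric(segDose %*% w)
  terms <- ctx$terms
  g <- numeric(length(w))
  H <- matrix(0, length(w), length(w))
  for (t in seq_len(nrow(terms))) {
    idx <- ctx$idx[[terms$structure[t]]]
    ref <- terms$ref_gy[t]
    dPct <- 100 * doseGy[idx] / ref
    C <- terms$dose_pct[t]
    Dv <- dvhPercentile(dPct, terms$vpct[t])
    act <- if (terms$kind[t] == "lower")
      dPct < C & dPct >= Dv - 1e-9
    else dPct > C & dPct <= Dv + 1e-9
    if (!any(act)) next
    viol <- abs(dPct[act] - C)
    sgn <- if (terms$kind[t] == "lower") -1 else 1
    scl <- terms$weight[t] * 2 / length(idx) * (100 / ref)
    Aact <- segDose[idx[act], , drop = FALSE]
    g <- g + sgn * scl * as.numeric(crossprod(Aact, viol))
    H <- H + scl * (100 / ref) * crossprod(Aact)
  }
  # DVH-statistic subgradient (quantile-window averaged) as a fallback
  ev <- covEval(doseGy, ctx, gradientInfo = TRUE,
                windowFrac = config$window_frac,
                perVoxel = config$scoring == "band")
  gSub <- NULL
  if (!is.null(ev$rows)) {
    gSub <- numeric(length(w))
    for (t in seq_len(nrow(terms))) {
      C <- terms$dose_pct[t]
      viol <- if (terms$kind[t] == "lower") C - ev$M[t] else ev$M[t] - C
      if (viol <= 0 || is.null(ev$rows[[t]])) next
      sgn <- if (terms$kind[t] == "lower") -1 else 1
      rows <- ev$rows[[t]]
      a <- colMeans(segDose[rows, , drop = FALSE]) * (100 / terms$ref_gy[t])
      gSub <- gSub + terms$weight[t] * 2 * sgn * viol * a
    }
  }
  list(cov = ev$cov, grad = g, hessian = H, gradSub = gSub)
}

covOnly <- function(w, segDose, ctx, config) {
  doseGy <- as.numeric(segDose %*% w)
  covEval(doseGy, ctx, perVoxel = config$scoring == "band")$cov
}

# one projected-gradient run of `steps` accepted-only iterations; in
# per-voxel mode the gradient is scaled by the Gauss-Newton diagonal
weightRun <- function(w, segDose, ctx, config, trace) {
  cg <- covAndGrad(w, segDose, ctx, config)
  t0 <- NA_real_
  for (s in seq_len(config$steps)) {
    g <- cg$grad
    gm <- max(abs(g), if (is.null(cg$gradSub)) 0 else abs(cg$gradSub))
    if (!is.finite(gm) || gm < 1e-14) break
    if (any(diag(cg$hessian) > 0)) {
      # candidate directions, most to least aggressive: damped Gauss-Newton
      # (two damping levels), diagonally preconditioned surrogate gradient,
      # DVH-statistic subgradient, raw surrogate gradient; the first
      # direction whose backtracking line search finds a COV decrease wins.
      # Updates are clamped to the non-negative orthant.
      dh <- diag(cg$hessian)
      mdh <- mean(dh)
      gn <- function(lam) tryCatch(
        solve(cg$hessian + diag(lam * mdh, length(g)), g),
        error = function(e) NULL)
      dirs <- Filter(Negate(is.null),
                     list(gn(1e-5), gn(1e-2), g / (dh + 1e-8 * mdh)))
      t0s <- rep(min(if (is.na(t0)) 1 else t0, 2), length(dirs))
      if (!is.null(cg$gradSub) && max(abs(cg$gradSub)) > 1e-14) {
        dirs <- c(dirs, list(cg$gradSub))
        t0s <- c(t0s, (0.05 * max(w, 1)) / max(abs(cg$gradSub)))
      }
    } else if (!is.null(cg$gradSub) && max(abs(cg$gradSub)) > 1e-14) {
      dirs <- list(cg$gradSub)
      t0s <- (0.05 * max(w, 1)) / max(abs(cg$gradSub))
    } else {
      dirs <- list(g)
      t0s <- if (is.na(t0)) (0.05 * max(w, 1)) / gm else t0
    }
    accepted <- FALSE
    for (d in seq_along(dirs)) {
      t <- t0s[d]
      for (h in seq_len(25)) {
        wNew <- pmax(w - t * dirs[[d]], 0)
        covNew <- covOnly(wNew, segDose, ctx, config)
        if (covNew < cg$cov - 1e-12) { accepted <- TRUE; break }
        t <- t / 2
      }
      if (accepted) break
    }
    if (!accepted) break
    w <- wNew
    t0 <- t * 2
    cg <- covAndGrad(w, segDose, ctx, config)
    cg$cov <- min(cg$cov, covNew)
    trace <- c(trace, cg$cov)
  }
  list(w = w, trace = trace)
}

discardLowMU <- function(plan, w, segDose, threshold, log) {
  keep <- w >= threshold
  if (!any(keep)) stop("empty plan: every segment fell below ", threshold,
                       " MU_eff and was discarded")
  if (!all(keep)) {
    dropped <- planSegments(plan)[!keep]
    log <- rbind(log, data.frame(
      angle = vapply(dropped, function(s) s@beam@gantryAngle, numeric(1)),
      order = vapply(dropped, function(s) s@order, character(1)),
      reason = "below_mu"))
    plan@segments <- plan@segments[keep]
    segDose <- segDose[, keep, drop = FALSE]
    w <- w[keep]
  }
  list(plan = plan, w = w, segDose = segDose, log = log)
}

#' Optimize segment weights
#'
#' Projected-gradient (non-negativity constrained) minimization of the
#' composite objective value over segment weights. Only COV-decreasing steps
#' are accepted (backtracking line search), so the COV trace is
#' non-increasing. Runs \code{config$runs} consecutive runs of
#' \code{config$steps} steps; at the end of each run, segments whose weight
#' has fallen below \code{config$mu_discard} MU_eff are discarded.
#'
#' @param plan a \code{\link{TreatmentPlan}}.
#' @param influence an \code{\link{InfluenceMatrix}} covering the plan.
#' @param objectives objective set (see \code{\link{makeObjectiveTemplate}}).
#' @param case the \code{\link{CaseGeometry}}.
#' @param config an \code{\link{optimizerConfig}}.
#' @param segDose optional precomputed \code{\link{segmentDoseMatrix}}.
#' @return list with elements \code{plan} (optimized weights), \code{trace}
#'   (accepted COV values, starting at the initial COV), \code{cov} (final),
#'   and \code{segDose}.
#' @export
optimizeWeights <- function(plan, influence, objectives, case,
                            config = optimizerConfig(), segDose = NULL) {
  set.seed(config$seed)
  if (is.null(segDose)) segDose <- segmentDoseMatrix(influence, plan)
  ctx <- objectiveContext(case, objectives, influence@voxelIndex)
  w <- planWeights(plan)
  if (config$normalize_init && config$target %in% structureNames(case)) {
    tIdx <- which(structureMask(case, config$target)[influence@voxelIndex])
    meanDose <- mean(as.numeric(segDose[tIdx, , drop = FALSE] %*% w))
    rx <- prescriptionDose(case, config$target)
    if (meanDose > 0) w <- w * rx / meanDose
  }
  trace <- covOnly(w, segDose, ctx, config)
  log <- plan@discardLog
  for (run in seq_len(config$runs)) {
    res <- weightRun(w, segDose, ctx, config, trace)
    w <- res$w; trace <- res$trace
    d <- discardLowMU(plan, w, segDose, config$mu_discard, log)
    plan <- d$plan; w <- d$w; segDose <- d$segDose; log <- d$log
  }
  plan <- setPlanWeights(plan, w)
  plan@discardLog <- log
  list(plan = plan, trace = trace, cov = trace[length(trace)],
       segDose = segDose)
}

# try greedy moves of one aperture edge; returns updated state
sweepApertures <- function(plan, influence, ctx, config, w, segDose) {
  doseGy <- as.numeric(segDose %*% w)
  cov <- covEval(doseGy, ctx, perVoxel = config$scoring == "band")$cov
  segs <- planSegments(plan)
  bl <- influence@beamlets
  for (j in seq_along(segs)) {
    if (w[j] <= 0) next
    seg <- segs[[j]]
    ang <- seg@beam@gantryAngle
    ge <- influence@xEdges[[angleKey(ang)]]
    res <- diff(ge$xEdges)[1L]
    atAng <- which(abs(bl$angle - ang) < 1e-9)
    rowCenter <- (ge$rowEdges[bl$row[atAng]] + ge$rowEdges[bl$row[atAng] + 1L]) / 2
    xc <- (bl$x0[atAng] + bl$x1[atAng]) / 2
    ap <- seg@aperture
    changed <- FALSE
    for (r in seq_len(nrow(ap@intervals))) {
      if (is.na(ap@intervals[r, 1L])) next
      rMid <- (ap@rowEdges[r] + ap@rowEdges[r + 1L]) / 2
      inRow <- abs(rowCenter - rMid) < 1e-6
      if (!any(inRow)) next
      for (side in 1:2) {
        for (mv in seq_len(config$move_limit)) {
          cur <- ap@intervals[r, ]
          best <- NULL
          for (dir in c(-1, 1)) {
            cand <- cur
            cand[side] <- cand[side] + dir * res
            if (cand[1L] >= cand[2L]) next
            if (cand[1L] < ge$xEdges[1L] ||
                cand[2L] > ge$xEdges[length(ge$xEdges)]) next
            oldIn <- inRow & xc >= cur[1L] & xc <= cur[2L]
            newIn <- inRow & xc >= cand[1L] & xc <= cand[2L]
            dCols <- atAng[xor(oldIn, newIn)]
            if (!length(dCols)) next
            sgn <- if (sum(newIn) > sum(oldIn)) 1 else -1
            delta <- sgn * w[j] *
              as.numeric(Matrix::rowSums(influence@matrix[, dCols,
                                                          drop = FALSE]))
            covNew <- covEval(doseGy + delta, ctx,
                              perVoxel = config$scoring == "band")$cov
            if (covNew < cov - 1e-12 &&
                (is.null(best) || covNew < best$cov))
              best <- list(cov = covNew, cand = cand, delta = delta,
                           dCols = dCols, sgn = sgn)
          }
          if (is.null(best)) break
          ap@intervals[r, ] <- best$cand
          doseGy <- doseGy + best$delta
          cov <- best$cov
          segDose[, j] <- segDose[, j] + best$sgn *
            as.numeric(Matrix::rowSums(influence@matrix[, best$dCols,
                                                        drop = FALSE]))
          changed <- TRUE
        }
      }
    }
    if (changed) {
      seg@aperture <- ap
      segs[[j]] <- seg
    }
  }
  plan@segments <- segs
  list(plan = plan, segDose = segDose, cov = cov)
}

#' Fine-tune segment apertures (and weights)
#'
#' Greedy coordinate descent over leaf positions: every open leaf edge is
#' moved in steps of one beamlet (up to \code{move_limit} per sweep),
#' accepting only COV-decreasing moves, interleaved with projected-gradient
#' weight re-optimization. Deliverability (one interval per leaf pair) and
#' the influence beamlet extent bound every move. Deterministic for a fixed
#' sweep order (segments in plan order, rows caudal to cranial, left edge
#' before right).
#'
#' @inheritParams optimizeWeights
#' @return list with elements \code{plan}, \code{trace} (accepted COV
#'   values across both phases), \code{cov} and \code{segDose}.
#' @export
fineTunePlan <- function(plan, influence, objectives, case,
                         config = optimizerConfig(), segDose = NULL) {
  set.seed(config$seed)
  if (is.null(segDose)) segDose <- segmentDoseMatrix(influence, plan)
  ctx <- objectiveContext(case, objectives, influence@voxelIndex)
  w <- planWeights(plan)
  if (config$normalize_init && config$target %in% structureNames(case)) {
    tIdx <- which(structureMask(case, config$target)[influence@voxelIndex])
    meanDose <- mean(as.numeric(segDose[tIdx, , drop = FALSE] %*% w))
    rx <- prescriptionDose(case, config$target)
    if (meanDose > 0) w <- w * rx / meanDose
  }
  trace <- covOnly(w, segDose, ctx, config)
  log <- plan@discardLog
  if (config$pre_sweeps > 0 && config$move_limit > 0) {
    # shape conditioning at the (still uniform) initial weights: the
    # apertures adapt before the weight distribution sharpens into a
    # brittle local minimum
    plan <- setPlanWeights(plan, w)
    for (sw in seq_len(config$pre_sweeps)) {
      swp <- sweepApertures(plan, influence, ctx, config, w, segDose)
      plan <- swp$plan; segDose <- swp$segDose
      trace <- c(trace, swp$cov)
    }
  }
  for (run in seq_len(config$runs)) {
    nSweep <- if (config$move_limit > 0) config$aperture_sweeps else 0
    if (nSweep == 0) {
      res <- weightRun(w, segDose, ctx, config, trace)
      w <- res$w; trace <- res$trace
    } else {
      # interleave: an aperture sweep before each block of weight steps, so
      # shapes adapt while the weight distribution is still soft and the
      # run ends with weights matched to the final shapes
      blockCfg <- config
      blockCfg$steps <- max(1L, ceiling(config$steps / nSweep))
      for (b in seq_len(nSweep)) {
        plan <- setPlanWeights(plan, w)
        swp <- sweepApertures(plan, influence, ctx, config, w, segDose)
        plan <- swp$plan; segDose <- swp$segDose
        trace <- c(trace, swp$cov)
        res <- weightRun(w, segDose, ctx, blockCfg, trace)
        w <- res$w; trace <- res$trace
      }
    }
    d <- discardLowMU(plan, w, segDose, config$mu_discard, log)
    plan <- d$plan; w <- d$w; segDose <- d$segDose; log <- d$log
  }
  plan <- setPlanWeights(plan, w)
  plan@discardLog <- log
  list(plan = plan, trace = trace, cov = trace[length(trace)],
       segDose = segDose)
}

#' @rdname fineTunePlan
#' @export
fineTuneApertures <- fineTunePlan
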