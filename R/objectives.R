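# Weighted quadratic DVH objectives and the composite objective value (COV).
# Doses inside objective evaluation are expressed in % of the term's
# reference prescription.

#' DVH percentile D_v
#'
#' The largest dose d such that at least v\% of the voxels receive at least
#' d: D_100 is the minimum dose, D_0 the maximum, D_50 the median-type
#' statistic used for plateau objectives.
#'
#' @param dose numeric vector or array of dose values.
#' @param v percent volume in [0, 100].
#' @param mask optional logical mask selecting voxels from \code{dose}.
#' @return D_v in the units of \code{dose}.
#' @export
dvhPercentile <- function(dose, v, mask = NULL) {
  if (!is.null(mask)) dose <- dose[mask]
  n <- length(dose)
  if (n == 0L) stop("empty mask: no voxels to evaluate")
  stopifnot(v >= 0, v <= 100)
  s <- sort(dose, method = "quick")
  s[dvhIndex(n, v)]
}

# index into the ascending-sorted dose vector for D_v
dvhIndex <- function(n, v) min(n, floor((100 - v) * n / 100 + 1e-9) + 1L)

#' Penalty of one DVH objective term
#'
#' Weighted one-sided quadratic: \code{w * max(0, C - M)^2} for a lower
#' bound and \code{w * max(0, M - C)^2} for an upper bound, with the
#' achieved value M and objective level C both in \% of prescription.
#'
#' @param M achieved DVH value D_v, \% of prescription.
#' @param kind "lower" or "upper".
#' @param C objective dose level, \% of prescription.
#' @param weight penalty weight.
#' @return dimensionless penalty (vectorized over rows).
#' @export
objectivePenalty <- function(M, kind, C, weight) {
  viol <- ifelse(kind == "lower", pmax(0, C - M), pmax(0, M - C))
  weight * viol^2
}

# Precomputed evaluation context: per-structure scoring-row indices plus the
# term table. `voxelIndex` = grid indices of the scoring dose vector.
objectiveContext <- function(case, objectives, voxelIndex = NULL) {
  if (is.null(voxelIndex)) voxelIndex <- seq_len(prod(case@gridDim))
  structs <- unique(objectives$structure)
  idx <- lapply(structs, function(nm) {
    m <- structureMask(case, nm)
    w <- which(m[voxelIndex])
    if (!length(w))
      stop("structure '", nm, "' has no scoring voxels")
    w
  })
  names(idx) <- structs
  list(terms = objectives, idx = idx)
}

# Core COV evaluation on a scoring dose vector (Gy). Returns the COV, the
# per-term achieved values M (% of prescription) and, if gradientInfo, the
# scoring rows around each term's DVH quantile (for subgradients).
covEval <- function(doseGy, ctx, gradientInfo = FALSE, windowFrac = 0.01,
                    perVoxel = FALSE) {
  terms <- ctx$terms
  nT <- nrow(terms)
  M <- numeric(nT)
  pen <- numeric(nT)
  rows <- if (gradientInfo) vector("list", nT) else NULL
  for (nm in names(ctx$idx)) {
    sel <- which(terms$structure == nm)
    dv <- doseGy[ctx$idx[[nm]]]
    if (perVoxel) {
      # DVH-aware per-voxel band penalty: only voxels between the current
      # D_v and the objective level C are penalized (for v < 100/0 the
      # allowed tail beyond D_v is exempt), so the zero set of the penalty
      # coincides with a satisfied DVH objective.
      for (t in sel) {
        dPct <- 100 * dv / terms$ref_gy[t]
        M[t] <- 100 * dvhPercentile(dv, terms$vpct[t]) / terms$ref_gy[t]
        C <- terms$dose_pct[t]
        act <- if (terms$kind[t] == "lower")
          dPct < C & dPct >= M[t] - 1e-9
        else dPct > C & dPct <= M[t] + 1e-9
        pen[t] <- terms$weight[t] * sum((dPct[act] - C)^2) / length(dPct)
      }
      next
    }
    ord <- order(dv)
    n <- length(dv)
    for (t in sel) {
      j <- dvhIndex(n, terms$vpct[t])
      M[t] <- 100 * dv[ord[j]] / terms$ref_gy[t]
      pen[t] <- objectivePenalty(M[t], terms$kind[t], terms$dose_pct[t],
                                 terms$weight[t])
      if (gradientInfo) {
        h <- max(1L, round(windowFrac * n / 2))
        win <- max(1L, j - h):min(n, j + h)
        rows[[t]] <- ctx$idx[[nm]][ord[win]]
      }
    }
  }
  list(cov = sum(pen), M = M, penalty = pen, rows = rows)
}

#' Evaluate every objective term against a dose distribution
#'
#' @param dose dose array (Gy, grid dimensions) or scoring vector (then
#'   supply \code{voxelIndex}).
#' @param case a \code{\link{CaseGeometry}}.
#' @param objectives an objective set from \code{\link{makeObjectiveTemplate}}.
#' @param voxelIndex grid indices of the entries of a dose vector.
#' @return the objective table extended by \code{M} (achieved D_v, \% of
#'   prescription), \code{penalty} and \code{violated}.
#' @export
evaluateObjectives <- function(dose, case, objectives, voxelIndex = NULL) {
  ctx <- objectiveContext(case, objectives, voxelIndex)
  ev <- covEval(as.numeric(dose), ctx)
  out <- as.data.frame(objectives)
  out$M <- ev$M
  out$penalty <- ev$penalty
  out$violated <- ifelse(out$kind == "lower", out$M < out$dose_pct,
                         out$M > out$dose_pct)
  out
}

#' Composite objective value (COV)
#'
#' The weighted sum of all quadratic objective penalties — the optimizer's
#' loss. Lower COV corresponds to a better plan. An empty objective set
#' scores 0.
#'
#' @inheritParams evaluateObjectives
#' @return non-negative scalar.
#' @export
compositeObjectiveValue <- function(dose, case, objectives,
                                    voxelIndex = NULL) {
  if (is.null(objectives) || nrow(objectives) == 0L) return(0)
  sum(evaluateObjectives(dose, case, objectives, voxelIndex)$penalty)
}
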