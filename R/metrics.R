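# Plan-quality reporting: dose-shortfall score S_D, normalized COV and
# cumulative DVH curves.

#' Dose-shortfall quality score S_D
#'
#' Sums, over violated objectives only, the absolute difference between the
#' achieved plan value M_j and the objective level C_j (in \% of
#' prescription): a lower objective contributes C_j - M_j when M_j < C_j, an
#' upper objective M_j - C_j when M_j > C_j, and satisfied (or over-achieved)
#' objectives contribute nothing. A plan fulfilling all objectives scores
#' exactly 0; S_D is independent of the objective weights.
#'
#' @param objectiveTable data.frame with columns \code{kind} ("lower" or
#'   "upper"), \code{dose_pct} (C_j) and \code{M} (achieved value, \% of
#'   prescription), e.g. from \code{\link{evaluateObjectives}}.
#' @return list with \code{s_d}, \code{s_d_per_n} (divided by the number of
#'   objectives) and \code{n}.
#' @export
qualityScoreSD <- function(objectiveTable) {
  if (is.null(objectiveTable) || nrow(objectiveTable) == 0L)
    stop("empty objective table")
  stopifnot(all(c("kind", "dose_pct", "M") %in% names(objectiveTable)))
  viol <- ifelse(objectiveTable$kind == "lower",
                 pmax(0, objectiveTable$dose_pct - objectiveTable$M),
                 pmax(0, objectiveTable$M - objectiveTable$dose_pct))
  sd <- sum(viol)
  list(s_d = sd, s_d_per_n = sd / nrow(objectiveTable),
       n = nrow(objectiveTable))
}

#' COV normalized to a reference plan
#'
#' @param planCov composite objective value of the plan under study.
#' @param referenceCov COV of the reference plan (> 0); the reference itself
#'   normalizes to exactly 1.
#' @return the ratio plan/reference. Differences beyond +25\%/-20\% of the
#'   reference are conventionally considered relevant; the returned value
#'   carries an attribute \code{relevant} flagging that band.
#' @export
normalizedCOV <- function(planCov, referenceCov) {
  if (!is.finite(referenceCov) || referenceCov <= 0)
    stop("reference COV must be positive")
  r <- planCov / referenceCov
  attr(r, "relevant") <- if (r > 1.25) "relevant worsening"
    else if (r < 0.80) "relevant improvement" else "within relevance band"
  r
}

#' Cumulative dose-volume histogram
#'
#' @param dose numeric vector or array of dose values.
#' @param mask optional logical mask selecting voxels.
#' @param binWidth histogram bin width in the units of \code{dose}.
#' @return data.frame with columns \code{dose} (bin lower edges, starting at
#'   0) and \code{volume_pct}, the percentage of voxels receiving at least
#'   that dose; monotone non-increasing, starting at 100.
#' @export
dvhCurve <- function(dose, mask = NULL, binWidth = 0.5) {
  if (!is.null(mask)) dose <- dose[mask]
  if (length(dose) == 0L) stop("empty mask: no voxels for DVH")
  edges <- seq(0, max(dose) + binWidth, by = binWidth)
  vol <- vapply(edges, function(d) 100 * mean(dose >= d), numeric(1))
  data.frame(dose = edges, volume_pct = vol)
}

#' Full plan-quality report
#'
#' @param dose dose array (Gy) or scoring vector with \code{voxelIndex}.
#' @param case a \code{\link{CaseGeometry}}.
#' @param objectives objective set.
#' @param referenceCov optional reference COV for normalization.
#' @param voxelIndex grid indices of a scoring dose vector.
#' @return list of class \code{quality_report}: \code{cov},
#'   \code{normalized_cov} (NA without a reference), \code{s_d},
#'   \code{s_d_per_n} and the per-objective \code{table}.
#' @export
qualityReport <- function(dose, case, objectives, referenceCov = NULL,
                          voxelIndex = NULL) {
  tab <- evaluateObjectives(dose, case, objectives, voxelIndex)
  sd <- qualityScoreSD(tab)
  out <- list(cov = sum(tab$penalty),
              normalized_cov = if (is.null(referenceCov)) NA_real_
                else as.numeric(normalizedCOV(sum(tab$penalty), referenceCov)),
              s_d = sd$s_d, s_d_per_n = sd$s_d_per_n, table = tab)
  class(out) <- "quality_report"
  out
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("Plan quality: COV = %.4g", x$cov))
  if (!is.na(x$normalized_cov))
    cat(sprintf(" (normalized %.2f)", x$normalized_cov))
  cat(sprintf(", S_D = %.2f, S_D/n = %.2f over %d objectives\n",
              x$s_d, x$s_d_per_n, nrow(x$table)))
  nv <- sum(x$table$violated)
  cat(sprintf("  %d objective(s) violated\n", nv))
  invisible(x)
}
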