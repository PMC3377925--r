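# Linac delivery-time model for step-and-shoot plans: gantry transitions
# (start-stop plus rotation), segment shaping concurrent with gantry motion,
# beam-on time and per-beam data handling.

#' Linac machine presets
#'
#' Measured timing parameters for two accelerator generations: a modern
#' machine with en-bloc data transfer (\code{"new"}: 60 s full rotation,
#' 3 s start-stop, 7 s mean segment shaping, 3 s data handling per beam) and
#' an older machine with per-beam data transfer (\code{"old"}: 78 s rotation,
#' 3 s start-stop, 12 s shaping, 9 s data handling). Dose rates (500 and
#' 350 MU_eff/min) are model defaults back-solved from published plan
#' delivery times rather than measured values, and can be overridden.
#'
#' @param name \code{"new"} or \code{"old"}.
#' @param doseRate override of the dose rate, MU_eff/min.
#' @return a \code{\link{MachineModel}}.
#' @export
machinePreset <- function(name = c("new", "old"), doseRate = NULL) {
  name <- match.arg(name)
  m <- switch(name,
    new = new("MachineModel", name = "new", rotationTime = 60, tauSS = 3,
              tauS = 7, tauF = 3, doseRate = 500),
    old = new("MachineModel", name = "old", rotationTime = 78, tauSS = 3,
              tauS = 12, tauF = 9, doseRate = 350))
  if (!is.null(doseRate)) m@doseRate <- doseRate
  m
}

#' Gantry transition time between beams
#'
#' Start-stop time plus rotation time scaled by the angular distance:
#' tau_GSS = tau_SS + delta_theta * rotationTime / 360.
#'
#' @param machine a \code{\link{MachineModel}}.
#' @param deltaThetaDeg gantry angle change, degrees in [0, 360].
#' @return seconds.
#' @export
gantryTransitionTime <- function(machine, deltaThetaDeg) {
  if (any(deltaThetaDeg < 0 | deltaThetaDeg > 360))
    stop("deltaThetaDeg must lie in [0, 360]")
  machine@tauSS + deltaThetaDeg * machine@rotationTime / 360
}

#' Plan delivery time
#'
#' Total delivery time of an n-beam, N-segment plan with total monitor units
#' MU and equidistant beam spacing:
#' \deqn{T = (n-1) \max\{\tau_{GSS}, \bar\tau_S\} + (N-n+1) \bar\tau_S +
#'   MU/\dot D + (n-1) \tau_F}
#' The max term encodes that segment shaping and gantry positioning run
#' concurrently, so the slower process dominates each inter-beam transition.
#'
#' @param machine a \code{\link{MachineModel}}.
#' @param n number of beams (>= 1).
#' @param N number of segments (>= n).
#' @param mu total MU_eff.
#' @param spacingDeg gantry angle spacing between consecutive beams, degrees.
#' @return delivery time in minutes (unrounded; reports round to 0.1 min).
#' @export
deliveryTime <- function(machine, n, N, mu, spacingDeg = 360 / n) {
  stopifnot(n >= 1, mu >= 0)
  if (N < n) stop("N (segments) must be >= n (beams)")
  tGSS <- gantryTransitionTime(machine, spacingDeg)
  secs <- (n - 1) * max(tGSS, machine@tauS) + (N - n + 1) * machine@tauS +
    mu / machine@doseRate * 60 + (n - 1) * machine@tauF
  secs / 60
}

#' Delivery statistics of a plan
#'
#' @param plan a \code{\link{TreatmentPlan}}.
#' @return list with \code{n} (beams), \code{N} (segments), \code{mu}
#'   (total MU_eff) and \code{spacingDeg}: 360/n for full-circle plans, the
#'   mean consecutive gap of the retained angles for partial arcs.
#' @export
planDeliveryStats <- function(plan) {
  n <- numBeams(plan)
  ang <- beamAngles(plan)
  spacing <- if (plan@arcDeg >= 360 || n <= 1) 360 / n
             else mean(diff(sort(ang)))
  list(n = n, N = numSegments(plan), mu = totalMU(plan),
       spacingDeg = spacing)
}

#' Delivery-time comparison table
#'
#' Computes the modelled delivery time of each plan on each machine and the
#' percent change relative to a designated reference plan. Times are rounded
#' to 0.1 min in the table (raw minutes kept in \code{T_<machine>_raw}).
#'
#' @param stats named list of plan delivery statistics (each as returned by
#'   \code{\link{planDeliveryStats}}, or a list with n, N, mu, spacingDeg).
#' @param machines list of \code{\link{MachineModel}} objects.
#' @param reference name (in \code{stats}) of the reference plan.
#' @return data.frame with one row per plan: n, N, mu and, per machine,
#'   \code{T_<name>} [min, rounded 0.1], \code{T_<name>_raw} and
#'   \code{dT_<name>_pct} (percent change vs the reference).
#' @export
timeReport <- function(stats, machines = list(machinePreset("new"),
                                              machinePreset("old")),
                       reference = names(stats)[1L]) {
  if (!reference %in% names(stats))
    stop("reference plan '", reference, "' not found")
  out <- data.frame(plan = names(stats),
                    n = vapply(stats, `[[`, numeric(1), "n"),
                    N = vapply(stats, `[[`, numeric(1), "N"),
                    mu = vapply(stats, `[[`, numeric(1), "mu"),
                    row.names = NULL)
  for (m in machines) {
    Traw <- vapply(stats, function(s)
      deliveryTime(m, s$n, s$N, s$mu, s$spacingDeg), numeric(1))
    Tref <- Traw[[reference]]
    out[[paste0("T_", m@name)]] <- round01(Traw)
    out[[paste0("T_", m@name, "_raw")]] <- Traw
    out[[paste0("dT_", m@name, "_pct")]] <- round(100 * (Traw - Tref) / Tref, 1)
  }
  out
}
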