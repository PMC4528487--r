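#' Choose a new heading at a CTL turn event
#'
#' A turn happens when a searching CTL exhausts its persistent segment,
#' finishes scanning an uninfected cell, or is released after lysing a
#' target. With probability `chemotaxis_prob` the new heading points exactly
#' at the nearest living infected cell (toroidal bearing); otherwise it is
#' the previous heading plus a uniform deviate on \[-45, +45\] degrees (or
#' exactly +/-45 degrees with `discrete = TRUE`). If a directed turn is
#' drawn but no infected cell exists, the turn falls back to an undirected
#' one. Chemotaxis never alters CTL speed.
#'
#' @param heading Current heading, radians.
#' @param position CTL position (x, y), um.
#' @param world A [tissue_world()].
#' @param chemotaxis_prob Probability that the turn is directed.
#' @param persistence_length Length of the new persistent segment, um.
#' @param discrete Use the two-point +/-45 degree turn distribution.
#' @return A list with `heading` (rad), `distance_remaining` (um) and
#'   `directed` (logical).
#' @examples
#' w <- tissue_world(16, 16)
#' w$state[5, 9] <- "infected"
#' set.seed(1)
#' choose_direction(0, c(5, 5), w, chemotaxis_prob = 1)
#' @export
choose_direction <- function(heading, position, world, chemotaxis_prob,
                             persistence_length = 25, discrete = FALSE) {
  stopifnot(chemotaxis_prob >= 0, chemotaxis_prob <= 1)
  directed <- FALSE
  if (chemotaxis_prob > 0 && stats::runif(1) < chemotaxis_prob) {
    target <- nearest_infected(position, world)
    if (!is.null(target)) {
      d <- world$cell_diameter
      centre <- c((target$site[["col"]] + 0.5) * d,
                  (target$site[["row"]] + 0.5) * d)
      delta <- centre - wrap_position(position, world$extent)
      delta <- delta - world$extent * round(delta / world$extent)
      if (any(delta != 0)) {
        heading <- unname(atan2(delta[2], delta[1]))
        directed <- TRUE
      }
    }
  }
  if (!directed) {
    turn <- if (discrete) sample(c(-45, 45), 1) else stats::runif(1, -45, 45)
    heading <- heading + turn * pi / 180
  }
  list(heading = heading, distance_remaining = persistence_length,
       directed = directed)
}

#' Measure the CTL surveillance rate
#'
#' Places `n_ctl` CTL on an inert (non-susceptible, uninfected) tissue and
#' counts how many distinct cells each CTL scans per minute: a scan is
#' registered whenever a living cell newly enters the CTL's contact set.
#' This is the operational definition of the surveillance rate `k` used in
#' the mass-action models.
#'
#' @param config A [simulation_config()]; its substrate is forced to
#'   non-susceptible and any infection switched off.
#' @param duration Measurement duration, min.
#' @param n_ctl Number of CTL.
#' @param seed Optional seed (defaults to the config's).
#' @return A list with `rate` (mean cells/min), `sd` (between-CTL SD of the
#'   per-CTL rates), `per_ctl` (scan counts) and `duration`.
#' @examples
#' cfg <- simulation_config(n_rows = 32, n_cols = 32, dt = 10, seed = 1)
#' measure_surveillance_rate(cfg, duration = 30, n_ctl = 20)$rate
#' @export
measure_surveillance_rate <- function(config, duration = 120, n_ctl = 100,
                                      seed = NULL) {
  stopifnot(inherits(config, "ctl_config"))
  cfg <- config
  cfg$substrate <- "non_susceptible"
  cfg$I_C <- 0L
  cfg$n_ctl <- as.integer(n_ctl)
  cfg$t_max <- duration / 1440
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (duration * max(cfg$ctl_velocity, 0) < cfg$cell_diameter)
    warning("duration may be too short for a single expected scan")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- abm_run_cpp(as_engine_cfg(cfg))
  per_ctl <- res$scans / duration
  list(rate = mean(per_ctl), sd = stats::sd(per_ctl),
       per_ctl = res$scans, duration = duration)
}

#' Calibrate the contact radius against a target surveillance rate
#'
#' The contact radius is the one free geometric parameter of contact
#' detection. This routine bisects it until the measured surveillance rate
#' matches `target_k` within `tol` (relative). The calibrated value is meant
#' to be frozen into the default configuration, not re-run per experiment.
#'
#' @param config Base configuration (velocity and scan time are taken from
#'   it).
#' @param target_k Target surveillance rate, cells/min.
#' @param tol Relative tolerance on the measured rate.
#' @param bracket Radius bracket in um.
#' @param duration,n_ctl Measurement settings per iteration.
#' @param seed Base seed; iteration i uses `seed + i`.
#' @param max_iter Bisection cap.
#' @return A list with `contact_radius`, `measured_k` and the evaluation
#'   `history` data.frame.
#' @export
calibrate_contact_radius <- function(config, target_k, tol = 0.05,
                                     bracket = c(1, 15), duration = 120,
                                     n_ctl = 100, seed = 1L, max_iter = 20L) {
  stopifnot(inherits(config, "ctl_config"), target_k > 0)
  measure <- function(radius, s) {
    cfg <- config
    cfg$contact_radius <- radius
    measure_surveillance_rate(cfg, duration = duration, n_ctl = n_ctl,
                              seed = s)$rate
  }
  lo <- bracket[1]; hi <- bracket[2]
  k_lo <- measure(lo, seed); k_hi <- measure(hi, seed + 1L)
  if (k_lo > target_k || k_hi < target_k)
    stop(sprintf(paste0("target surveillance rate %.3g not bracketed: ",
                        "k(%.3g um) = %.3g, k(%.3g um) = %.3g"),
                 target_k, lo, k_lo, hi, k_hi))
  hist <- data.frame(radius = c(lo, hi), k = c(k_lo, k_hi))
  mid <- NA_real_; k_mid <- NA_real_
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    k_mid <- measure(mid, seed + 1L + i)
    hist <- rbind(hist, data.frame(radius = mid, k = k_mid))
    if (abs(k_mid - target_k) <= tol * target_k) break
    if (k_mid < target_k) lo <- mid else hi <- mid
  }
  list(contact_radius = mid, measured_k = k_mid, history = hist)
}
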