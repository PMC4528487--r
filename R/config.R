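#' Build a simulation configuration
#'
#' Collects every parameter of the agent-based tissue simulation into a single
#' validated object: lattice geometry, infection kinetics, CTL behaviour and
#' run control. Defaults reproduce the full-scale study conditions: a
#' 320 x 320 lattice of 10 um cells (3.2 mm x 3.2 mm, 102,400 cells), 1 s
#' updates, uncontrolled infected-cell growth of 1 per day, a 1.4-day
#' cytopathic half-life, 4-h virion half-life, 30-min handling time, 5-s scan
#' time and a 25-um persistence length.
#'
#' @param n_rows,n_cols Lattice dimensions (sites).
#' @param cell_diameter Cell diameter in um; the lattice pitch.
#' @param dt Time step in seconds.
#' @param r_target Uncontrolled net growth rate of infected cells, per day.
#' @param infection_mode `"diffuse"` (new infections appear at uniformly
#'   random susceptible sites) or `"clustered"` (virion-mediated local
#'   spread producing foci).
#' @param diffuse_literal If `TRUE`, diffuse mode uses the literal rule of an
#'   infection probability `r*dt` per infected cell with cytopathic death
#'   disabled; by default the infection rate is `r + log(2)/1.4` per day with
#'   cytopathic death retained, so the realised net growth rate is still `r`.
#' @param infected_halflife Cytopathic half-life of infected cells, days.
#' @param virion_halflife Free-virion half-life, hours.
#' @param virion_speed Straight-line virion speed, um/min (clustered mode).
#' @param virion_production Virion production rate, virions per infected cell
#'   per day (clustered mode; the default was calibrated so the uncontrolled
#'   clustered growth rate matches `r_target = 1` per day).
#' @param ctl_velocity CTL speed while searching, um/min.
#' @param scan_time Time spent stationary scanning an uninfected cell, s.
#' @param handling_time Fixed conjugation (killing) time, min.
#' @param persistence_length Distance between spontaneous turns, um.
#' @param chemotaxis_prob Probability that a turn is directed at the nearest
#'   living infected cell rather than drawn uniformly from +/-45 degrees.
#' @param contact_radius Contact detection radius, um (distance from the
#'   coarse-grained CTL position to a cell centre). The default was fixed
#'   once by calibrating the measured surveillance rate to 1.1 cells/min at
#'   7.5 um/min and a 5-s scan, and is frozen thereafter.
#' @param I_C Infected-cell count at which CTL are introduced.
#' @param n_ctl Number of CTL introduced.
#' @param t_max Maximum simulated time after CTL introduction, days.
#' @param t_grow_max Cap on the initial CTL-free growth phase, days.
#' @param sample_interval Sampling interval of the time course, min.
#' @param substrate `"susceptible"` (all cells infectable, the infection
#'   setting) or `"non_susceptible"` (inert tissue used for surveillance-rate
#'   measurement).
#' @param conjugates_produce Do conjugated infected cells keep producing
#'   virions / seeding diffuse infections while being killed?
#' @param discrete_turns If `TRUE` undirected turns are exactly +/-45 degrees
#'   instead of uniform on \[-45, +45\].
#' @param saturation_fraction Cumulative epidemic fraction (sites ever
#'   infected) at which a run is stopped and scored as established; keeps
#'   runs on small lattices away from target-cell burnout, which is not part
#'   of the modelled dynamics.
#' @param seed Integer seed making the run fully reproducible.
#'
#' @return An object of class `ctl_config` (a validated named list).
#' @examples
#' cfg <- simulation_config(n_rows = 64, n_cols = 64, dt = 10, I_C = 40,
#'                          n_ctl = 120, seed = 1)
#' @export
simulation_config <- function(n_rows = 320L, n_cols = 320L, cell_diameter = 10,
                              dt = 1,
                              r_target = 1, infection_mode = c("diffuse", "clustered"),
                              diffuse_literal = FALSE,
                              infected_halflife = 1.4, virion_halflife = 4,
                              virion_speed = 10, virion_production = 1.548,
                              ctl_velocity = 7.5, scan_time = 5,
                              handling_time = 30, persistence_length = 25,
                              chemotaxis_prob = 0, contact_radius = 6.6875,
                              I_C = 1000L, n_ctl = 0L,
                              t_max = 10, t_grow_max = 30,
                              sample_interval = 10,
                              substrate = c("susceptible", "non_susceptible"),
                              conjugates_produce = TRUE, discrete_turns = FALSE,
                              saturation_fraction = 0.5, seed = NULL) {
  infection_mode <- match.arg(infection_mode)
  substrate <- match.arg(substrate)
  cfg <- list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    cell_diameter = cell_diameter, dt = dt,
    r_target = r_target, infection_mode = infection_mode,
    diffuse_literal = isTRUE(diffuse_literal),
    infected_halflife = infected_halflife, virion_halflife = virion_halflife,
    virion_speed = virion_speed, virion_production = virion_production,
    ctl_velocity = ctl_velocity, scan_time = scan_time,
    handling_time = handling_time, persistence_length = persistence_length,
    chemotaxis_prob = chemotaxis_prob, contact_radius = contact_radius,
    I_C = as.integer(I_C), n_ctl = as.integer(n_ctl),
    t_max = t_max, t_grow_max = t_grow_max,
    sample_interval = sample_interval, substrate = substrate,
    conjugates_produce = isTRUE(conjugates_produce),
    discrete_turns = isTRUE(discrete_turns),
    saturation_fraction = saturation_fraction,
    seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "ctl_config"
  cfg
}

validate_config <- function(cfg) {
  pos <- c("cell_diameter", "dt", "infected_halflife", "virion_halflife",
           "virion_speed", "scan_time", "handling_time",
           "persistence_length", "contact_radius", "sample_interval",
           "t_max", "t_grow_max")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || !is.finite(cfg[[f]]) ||
        cfg[[f]] <= 0)
      stop(sprintf("config field '%s' must be a single positive number", f))
  }
  nonneg <- c("r_target", "virion_production", "ctl_velocity", "n_ctl", "I_C")
  for (f in nonneg) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || !is.finite(cfg[[f]]) ||
        cfg[[f]] < 0)
      stop(sprintf("config field '%s' must be a single non-negative number", f))
  }
  if (cfg$n_rows < 2 || cfg$n_cols < 2) stop("grid must be at least 2 x 2")
  if (cfg$chemotaxis_prob < 0 || cfg$chemotaxis_prob > 1)
    stop("chemotaxis_prob must lie in [0, 1]")
  if (cfg$saturation_fraction <= 0 || cfg$saturation_fraction > 1)
    stop("saturation_fraction must lie in (0, 1]")
  # every per-step event probability must stay well below 1 (cap 0.1)
  rates <- engine_rates(cfg)
  dt_min <- cfg$dt / 60
  probs <- vapply(rates, function(r) 1 - exp(-r * dt_min), numeric(1))
  if (any(probs >= 0.1))
    stop("time step too coarse: a per-step event probability reaches ",
         sprintf("%.3f", max(probs)), "; reduce dt")
  invisible(cfg)
}

# per-minute event rates implied by a config
engine_rates <- function(cfg) {
  cyto <- if (cfg$infection_mode == "diffuse" && cfg$diffuse_literal) 0
          else log(2) / (cfg$infected_halflife * 1440)
  diffuse <- if (cfg$infection_mode != "diffuse") 0
             else if (cfg$diffuse_literal) cfg$r_target / 1440
             else (cfg$r_target + log(2) / cfg$infected_halflife) / 1440
  list(cyto_per_min = cyto,
       diffuse_per_min = diffuse,
       clear_per_min = log(2) / (cfg$virion_halflife * 60),
       prod_per_min = cfg$virion_production / 1440)
}

# flatten a ctl_config into the list the C++ engine expects
as_engine_cfg <- function(cfg, init_infected_sites = integer(),
                          ctl_xy = matrix(numeric(), 0, 2)) {
  rates <- engine_rates(cfg)
  list(n_rows = cfg$n_rows, n_cols = cfg$n_cols, cell_d = cfg$cell_diameter,
       dt_s = cfg$dt,
       mode = if (cfg$infection_mode == "clustered") 1L else 0L,
       cyto_per_min = rates$cyto_per_min,
       diffuse_per_min = rates$diffuse_per_min,
       clear_per_min = rates$clear_per_min,
       prod_per_min = rates$prod_per_min,
       vir_speed_um_min = cfg$virion_speed,
       ctl_v_um_min = cfg$ctl_velocity,
       scan_s = cfg$scan_time, handling_min = cfg$handling_time,
       persist_um = cfg$persistence_length, chemo_p = cfg$chemotaxis_prob,
       contact_um = cfg$contact_radius,
       discrete_turn = as.integer(cfg$discrete_turns),
       conj_produce = as.integer(cfg$conjugates_produce),
       saturation_frac = cfg$saturation_fraction,
       t_max_min = cfg$t_max * 1440,
       t_grow_max_min = cfg$t_grow_max * 1440,
       sample_every_min = cfg$sample_interval,
       I_C = cfg$I_C, n_ctl = cfg$n_ctl,
       substrate = if (cfg$substrate == "susceptible") 1L else 0L,
       init_infected_sites = as.integer(init_infected_sites),
       ctl_xy = ctl_xy)
}

#' @export
print.ctl_config <- function(x, ...) {
  cat("CTL tissue simulation configuration\n")
  cat(sprintf("  grid: %d x %d sites (%.1f x %.1f mm), dt = %g s\n",
              x$n_rows, x$n_cols, x$n_cols * x$cell_diameter / 1000,
              x$n_rows * x$cell_diameter / 1000, x$dt))
  cat(sprintf("  infection: %s, r = %g /day, I_C = %d\n",
              x$infection_mode, x$r_target, x$I_C))
  cat(sprintf("  CTL: n = %d, v = %g um/min, scan %g s, handling %g min, chemotaxis %g\n",
              x$n_ctl, x$ctl_velocity, x$scan_time, x$handling_time,
              x$chemotaxis_prob))
  invisible(x)
}

#' Convert a per-minute rate into a per-step event probability
#'
#' Exact exponential waiting-time conversion `1 - exp(-rate * dt / 60)`,
#' valid for any step size.
#'
#' @param rate Event rate per minute (non-negative).
#' @param dt Time step in seconds.
#' @return Event probability per step, in `[0, 1)`.
#' @examples
#' rate_to_prob(log(2) / 240, dt = 60)  # 4-h half-life, 1-min step
#' @export
rate_to_prob <- function(rate, dt) {
  if (any(!is.finite(rate)) || any(rate < 0)) stop("rate must be non-negative")
  if (any(!is.finite(dt)) || any(dt <= 0)) stop("dt must be positive")
  1 - exp(-rate * dt / 60)
}

#' Desk-scale preset configurations
#'
#' Reduced problem sizes the package uses for its own test and example runs:
#' a 64 x 64 lattice with 10-s steps for the slow-surveillance regime and a
#' 128 x 128 lattice for the fast regime, with the infected count at CTL
#' introduction scaled in proportion to the lattice area. The `k_ref` entry
#' is the surveillance rate (cells/min) measured for the preset's velocity,
#' scan time and contact radius, frozen at calibration time; it is the value
#' used to express critical densities in units of the mass-action prediction
#' `r/k`.
#'
#' @param regime `"slow"` (0.18 um/min CTL) or `"fast"` (7.5 um/min CTL).
#' @param infection_mode Passed to [simulation_config()].
#' @param I_C_fraction Infected fraction of all sites at CTL introduction.
#' @param ... Further overrides passed to [simulation_config()].
#' @return A `ctl_config` with an extra `k_ref` field.
#' @export
desk_preset <- function(regime = c("slow", "fast"),
                        infection_mode = c("diffuse", "clustered"),
                        I_C_fraction = 0.01, ...) {
  regime <- match.arg(regime)
  infection_mode <- match.arg(infection_mode)
  side <- if (regime == "slow") 64L else 128L
  v <- if (regime == "slow") 0.18 else 7.5
  k_ref <- if (regime == "slow") .ctlsim_k_slow else .ctlsim_k_fast
  N <- as.integer(side)^2
  cfg <- simulation_config(n_rows = side, n_cols = side, dt = 10,
                           ctl_velocity = v,
                           infection_mode = infection_mode,
                           I_C = max(1L, as.integer(round(I_C_fraction * N))),
                           t_max = 12,
                           ...)
  cfg$k_ref <- k_ref
  cfg
}

# surveillance rates measured once for the frozen contact radius (see
# calibrate_contact_radius); slow value is the same geometry at 0.18 um/min
.ctlsim_k_fast <- 1.07
.ctlsim_k_slow <- 0.0285
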