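#' One diffuse-infection step (reference implementation)
#'
#' In diffuse mode every infected cell independently infects one
#' susceptible cell chosen uniformly at random, regardless of distance,
#' with per-step probability `rate_to_prob(r_eff, dt)`. This mirrors the
#' rule used inside the compiled engine and is exposed for direct testing
#' and illustration on a [tissue_world()].
#'
#' @param world A [tissue_world()].
#' @param r Per-cell infection rate, per day.
#' @param dt Time step, seconds.
#' @return The updated world.
#' @export
diffuse_infect_step <- function(world, r, dt) {
  stopifnot(inherits(world, "tissue_world"), r >= 0, dt > 0)
  inf_n <- sum(world$state == "infected")
  if (inf_n == 0 || r == 0) return(world)
  p <- rate_to_prob(r / 1440, dt)
  n_new <- stats::rbinom(1, inf_n, p)
  if (n_new == 0) return(world)
  susc <- which(world$state == "susceptible")
  if (length(susc) == 0) return(world)
  # each event picks a susceptible uniformly; draws can collide, matching
  # independent per-cell choices within one step
  chosen <- unique(susc[sample.int(length(susc), n_new, replace = TRUE)])
  world$state[chosen] <- "infected"
  world
}

#' Estimate the exponential growth rate from a time course
#'
#' Ordinary least-squares fit of `log(infected)` against time over a
#' window, converted to per day. By default the window starts when the
#' infected count first reaches `min_count` (avoiding founder
#' stochasticity) and runs to the end of the course; zero counts are
#' dropped.
#'
#' @param tc A `ctl_timecourse` or data.frame with `time_min` and
#'   `infected`.
#' @param window Optional `c(t0, t1)` window in minutes.
#' @param min_count Count threshold that opens the default window.
#' @return Growth rate, per day.
#' @examples
#' tc <- data.frame(time_min = 0:100 * 14.4,
#'                  infected = 50 * exp(0:100 * 0.01))
#' estimate_growth_rate(tc, min_count = 1)
#' @export
estimate_growth_rate <- function(tc, window = NULL, min_count = 50) {
  stopifnot(all(c("time_min", "infected") %in% names(tc)))
  keep <- tc$infected > 0
  if (is.null(window)) {
    first <- which(tc$infected >= min_count)[1]
    if (is.na(first))
      stop("infected count never reached min_count; no growth window")
    keep <- keep & seq_len(nrow(tc)) >= first
  } else {
    keep <- keep & tc$time_min >= window[1] & tc$time_min <= window[2]
  }
  if (sum(keep) < 5)
    stop("fewer than 5 positive samples in the growth window")
  fit <- stats::lm.fit(cbind(1, tc$time_min[keep]), log(tc$infected[keep]))
  unname(stats::coef(fit)[2]) * 1440
}

#' Calibrate the virion production rate for clustered infections
#'
#' For clustered infections the uncontrolled growth rate is an emergent
#' property of virion production, speed and clearance, with production the
#' dominant factor. This routine sweeps the production rate around its
#' current value, simulates CTL-free growth repeatedly at each point,
#' estimates the growth rate per run, regresses the mean growth rate on the
#' production rate and returns the production rate solving the regression
#' for `target_r`.
#'
#' @param config A clustered-mode [simulation_config()] without CTL.
#' @param target_r Target growth rate, per day.
#' @param sweep_frac Sweep half-width as a fraction of the central value.
#' @param n_points Number of production rates in the sweep.
#' @param n_reps CTL-free growth simulations per point.
#' @param grow_days Length of each growth run, days.
#' @param seed Base seed.
#' @param runner Optional override `function(production, n_reps)` returning
#'   a vector of growth-rate estimates; used for testing the calibration
#'   arithmetic against synthetic responses.
#' @return An object of class `growth_calibration`: a list with the sweep
#'   `table` (production, mean_r, sd_r, n), the regression `coefficients`
#'   and the `production_rate` solving the regression.
#' @export
calibrate_virion_production <- function(config, target_r = 1,
                                        sweep_frac = 0.05, n_points = 21,
                                        n_reps = 50, grow_days = 6,
                                        seed = 1L, runner = NULL) {
  stopifnot(inherits(config, "ctl_config"))
  centre <- config$virion_production
  prods <- seq(centre * (1 - sweep_frac), centre * (1 + sweep_frac),
               length.out = n_points)
  if (is.null(runner)) {
    if (config$infection_mode != "clustered")
      stop("growth calibration applies to clustered mode")
    runner <- function(production, n) {
      cfg <- config
      cfg$virion_production <- production
      cfg$I_C <- 1L
      cfg$n_ctl <- 0L
      cfg$t_max <- grow_days
      rr <- vapply(seq_len(n), function(i) {
        cfg$seed <- as.integer((seed + 7919 * i + round(production * 1e4)) %% .Machine$integer.max)
        tc <- run_simulation(cfg)
        # founder lineages that fizzle before reaching the counting window
        # carry no growth information and are dropped
        tryCatch(estimate_growth_rate(tc, min_count = 50),
                 error = function(e) NA_real_)
      }, numeric(1))
      rr[!is.na(rr)]
    }
  }
  rows <- lapply(prods, function(p) {
    rr <- runner(p, n_reps)
    data.frame(production = p, mean_r = mean(rr), sd_r = stats::sd(rr),
               n = length(rr))
  })
  tab <- do.call(rbind, rows)
  fit <- stats::lm(mean_r ~ production, data = tab)
  co <- stats::coef(fit)
  if (!is.finite(co[2]) || co[2] <= 0)
    stop("growth rate did not increase with production over the sweep")
  solved <- unname((target_r - co[1]) / co[2])
  if (solved < min(prods) || solved > max(prods))
    stop(sprintf("target growth rate %.3g not bracketed by the sweep (solved %.4g outside [%.4g, %.4g])",
                 target_r, solved, min(prods), max(prods)))
  structure(list(table = tab, coefficients = co, production_rate = solved,
                 target_r = target_r),
            class = "growth_calibration")
}

#' @export
print.growth_calibration <- function(x, ...) {
  cat(sprintf("growth_calibration: production %.4g /cell/day gives r = %g /day\n",
              x$production_rate, x$target_r))
  cat(sprintf("  regression: mean_r = %.4g + %.4g * production over %d points\n",
              x$coefficients[1], x$coefficients[2], nrow(x$table)))
  invisible(x)
}

#' Write a growth-calibration report
#'
#' CSV of the sweep table plus a JSON summary with the regression
#' coefficients and the solved production rate.
#'
#' @param calib A `growth_calibration`.
#' @param path CSV path; JSON goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calib, path) {
  utils::write.csv(calib$table, path, row.names = FALSE)
  jsonlite::write_json(list(intercept = unname(calib$coefficients[1]),
                            slope = unname(calib$coefficients[2]),
                            production_rate = calib$production_rate,
                            target_r = calib$target_r),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
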