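#' Run one stochastic tissue simulation
#'
#' Seeds the tissue with a single infected cell, lets the infection grow
#' without control to `I_C` infected cells (diffuse appearance or
#' virion-mediated clustered spread depending on `infection_mode`), then
#' introduces `n_ctl` CTL uniformly at random and advances the agent-based
#' dynamics until the infection is extinct, the cumulative epidemic reaches
#' `saturation_fraction` of the tissue, or `t_max` days have elapsed since
#' CTL introduction. If the infection dies out by chance before reaching `I_C`
#' (cytopathic founder loss), the run is restarted on a fresh random
#' substream and the number of attempts is reported.
#'
#' @param config A [simulation_config()].
#' @param init_infected_sites Optional vector of 0-based site indices
#'   (`row * n_cols + col`) to infect at time zero instead of running the
#'   growth phase; used for controlled experiments and tests.
#' @param ctl_positions Optional `n_ctl` x 2 matrix of CTL starting
#'   positions (x, y in um); defaults to uniform random placement.
#' @param max_attempts Maximum number of growth-phase restarts.
#' @return A `ctl_timecourse`: a data.frame with columns `time_min`,
#'   `susceptible`, `infected`, `dead`, `ctl_free`, `ctl_conjugated`,
#'   `virions`, with attributes `outcome` (`"extinct"` or `"established"`,
#'   see [classify_outcome()]), `t_intro` (min), `attempts`, `kills`,
#'   `scans`, `infected_sites` (0-based indices `row * n_cols + col` of
#'   sites still infected at the end), `config` and `seed`.
#' @examples
#' cfg <- simulation_config(n_rows = 32, n_cols = 32, dt = 10, I_C = 10,
#'                          n_ctl = 50, t_max = 2, seed = 7)
#' tc <- run_simulation(cfg)
#' attr(tc, "outcome")
#' @export
run_simulation <- function(config, init_infected_sites = NULL,
                           ctl_positions = NULL, max_attempts = 1000L) {
  stopifnot(inherits(config, "ctl_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ecfg <- as_engine_cfg(config,
                        init_infected_sites = if (is.null(init_infected_sites))
                          integer() else init_infected_sites,
                        ctl_xy = if (is.null(ctl_positions))
                          matrix(numeric(), 0, 2) else ctl_positions)
  attempts <- 0L
  repeat {
    attempts <- attempts + 1L
    res <- abm_run_cpp(ecfg)
    if (res$status == 0) break
    if (res$status == 2)
      stop("infection failed to reach I_C within t_grow_max")
    if (attempts >= max_attempts)
      stop("infection died out before reaching I_C in every attempt")
  }
  tc <- data.frame(time_min = res$time_min,
                   susceptible = res$susceptible,
                   infected = res$infected,
                   dead = res$dead,
                   ctl_free = res$ctl_free,
                   ctl_conjugated = res$ctl_conjugated,
                   virions = res$virions)
  structure(tc,
            t_intro = res$t_intro_min,
            attempts = attempts,
            kills = res$kills,
            scans = res$scans,
            infected_sites = res$infected_sites,
            config = config,
            seed = config$seed,
            outcome = classify_outcome(tc),
            class = c("ctl_timecourse", "data.frame"))
}

#' Write a time course with its provenance sidecar
#'
#' Writes the sampled counts as CSV and a JSON sidecar carrying the full
#' configuration, seed and outcome, sufficient to regenerate the run
#' bit-identically.
#'
#' @param tc A `ctl_timecourse` from [run_simulation()].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE)
  meta <- list(config = unclass(attr(tc, "config")),
               seed = attr(tc, "seed"),
               t_intro_min = attr(tc, "t_intro"),
               attempts = attr(tc, "attempts"),
               outcome = attr(tc, "outcome"),
               package_version = as.character(utils::packageVersion("ctlsim")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @export
print.ctl_timecourse <- function(x, ...) {
  cat(sprintf("ctl_timecourse: %d samples over %.1f days; outcome: %s\n",
              nrow(x), max(x$time_min) / 1440, attr(x, "outcome")))
  cat(sprintf("  CTL introduced at %.1f days; final infected count %d\n",
              attr(x, "t_intro") / 1440, x$infected[nrow(x)]))
  invisible(x)
}
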