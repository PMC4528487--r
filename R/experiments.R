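#' Compare ABM mean kinetics with the two deterministic models
#'
#' For each experimental cell (a combination of infected count at CTL
#' introduction and effector:target ratio), runs replicate diffuse-mode
#' simulations, averages the infected-cell time course from CTL
#' introduction, integrates the simple and extended mass-action models at
#' the matching parameters and reports the root-mean-square discrepancy of
#' log infected fractions for each model. The extended model is expected to
#' track the ABM everywhere, while the simple model holds only at high
#' search:handling and/or high effector:target ratios.
#'
#' @param config Base diffuse-mode [simulation_config()] (its `k_ref` is
#'   used as the surveillance rate; supply `k` to override).
#' @param cells Data.frame with columns `I_C` (infected count at
#'   introduction) and `E_T` (effector:target ratio); one row per cell.
#' @param n_reps Replicates per cell.
#' @param horizon_days Comparison horizon after CTL introduction, days.
#' @param k Surveillance rate (cells/min) used by the ODE comparators.
#' @param seed Base seed.
#' @return A list with `summary` (one row per cell: `I_C`, `E_T`, `S_H`,
#'   `rms_simple`, `rms_extended`) and `trajectories` (per-cell mean ABM
#'   and ODE curves); class `fig1_comparison`.
#' @export
run_fig1_experiment <- function(config, cells, n_reps = 20, horizon_days = 2,
                                k = NULL, seed = 1L) {
  stopifnot(inherits(config, "ctl_config"),
            config$infection_mode == "diffuse",
            all(c("I_C", "E_T") %in% names(cells)))
  if (is.null(k)) k <- config$k_ref
  if (is.null(k)) stop("supply k or use a preset with a k_ref entry")
  N <- config$n_rows * config$n_cols
  trajectories <- list()
  summary <- cells
  summary$S_H <- NA_real_; summary$rms_simple <- NA_real_
  summary$rms_extended <- NA_real_
  for (ci in seq_len(nrow(cells))) {
    I_C <- as.integer(cells$I_C[ci]); E_T <- cells$E_T[ci]
    cfg <- config
    cfg$I_C <- I_C
    cfg$n_ctl <- as.integer(round(E_T * I_C))
    cfg$t_max <- horizon_days
    cfg$saturation_fraction <- 1
    grid_min <- seq(0, horizon_days * 1440, by = cfg$sample_interval)
    acc <- matrix(0, length(grid_min), 0)
    for (rep in seq_len(n_reps)) {
      cfg$seed <- as.integer((seed + 1000L * ci + rep) %% .Machine$integer.max)
      tc <- run_simulation(cfg)
      t0 <- attr(tc, "t_intro")
      post <- tc[tc$time_min >= t0 - 1e-9, ]
      y <- stats::approx(post$time_min - t0, post$infected, xout = grid_min,
                         rule = 2, ties = "ordered")$y
      acc <- cbind(acc, y)
    }
    abm_mean <- rowMeans(acc) / N
    T0 <- I_C / N; C0 <- cfg$n_ctl / N
    simple <- simple_mass_action(grid_min, k, C0, T0, cfg$r_target)
    ext <- solve_extended_model(k, C0, T0, h = cfg$handling_time,
                                r = cfg$r_target,
                                t_end = max(grid_min[-1]),
                                sample_interval = cfg$sample_interval)
    ext_tot <- stats::approx(ext$time_min, ext$total_infected,
                             xout = grid_min, rule = 2, ties = "ordered")$y
    ok <- abm_mean > 0
    summary$S_H[ci] <- (1 / (k * T0)) / cfg$handling_time
    summary$rms_simple[ci] <-
      sqrt(mean((log(abm_mean[ok]) - log(pmax(simple[ok], 1e-300)))^2))
    summary$rms_extended[ci] <-
      sqrt(mean((log(abm_mean[ok]) - log(pmax(ext_tot[ok], 1e-300)))^2))
    trajectories[[ci]] <- data.frame(time_min = grid_min, abm = abm_mean,
                                     simple = simple, extended = ext_tot)
  }
  structure(list(summary = summary, trajectories = trajectories,
                 provenance = provenance(config, seed)),
            class = "fig1_comparison")
}

#' Critical densities across spread modes and introduction times
#'
#' For each infection mode and infected count at CTL introduction, runs the
#' adaptive critical-density search, fits the extinction sigmoid and
#' reports the critical density in units of the mass-action prediction
#' `r/k`.
#'
#' @param config Base [simulation_config()] or preset; `k_ref` (or `k`)
#'   supplies the surveillance rate for the relative scale.
#' @param I_C_list Infected counts at CTL introduction.
#' @param modes Subset of `c("diffuse", "clustered")`.
#' @param n_reps Replicates per density evaluation.
#' @param guesses Initial density guesses in units of `r/k` (scaled
#'   internally to fractions).
#' @param k Surveillance rate override.
#' @param seed Base seed.
#' @param tolerance Bracket tolerance of the adaptive search.
#' @return Data.frame with one row per (mode, I_C): fitted `c_star`
#'   (fraction), `alpha`, `relative_cstar`, plus list-columns are avoided —
#'   curves are in `attr(, "curves")`.
#' @export
run_extinction_experiment <- function(config, I_C_list,
                                      modes = c("diffuse", "clustered"),
                                      n_reps = 50, guesses = c(0.4, 0.8, 1.6, 3.2),
                                      k = NULL, seed = 1L, tolerance = 0.1) {
  stopifnot(inherits(config, "ctl_config"))
  if (is.null(k)) k <- config$k_ref
  if (is.null(k)) stop("supply k or use a preset with a k_ref entry")
  base <- cstar_simple(config$r_target, k)
  rows <- list(); curves <- list()
  for (mode in modes) {
    for (I_C in I_C_list) {
      cfg <- config
      cfg$infection_mode <- mode
      cfg$I_C <- as.integer(I_C)
      ev <- make_abm_evaluator(cfg, seed = seed + 13L * length(rows))
      curve <- adaptive_cstar_search(ev, sort(guesses * base),
                                     n_reps = n_reps, tolerance = tolerance)
      fit <- fit_sigmoid(curve)
      tag <- sprintf("%s_I%d", mode, as.integer(I_C))
      curves[[tag]] <- curve
      rows[[tag]] <- data.frame(mode = mode, I_C = as.integer(I_C),
                                c_star = fit$c_star, alpha = fit$alpha,
                                relative_cstar = relative_cstar(fit$c_star, k,
                                                                config$r_target),
                                k = k)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  attr(out, "provenance") <- provenance(config, seed)
  out
}

#' Critical densities under increasing chemotaxis
#'
#' Re-runs the extinction experiment at each chemotaxis level and reports
#' relative critical densities; with any directed-turn probability the
#' critical density is expected to drop, the more so the earlier CTL are
#' introduced (the sparser the targets, the larger the fractional cut in
#' search time).
#'
#' @inheritParams run_extinction_experiment
#' @param chemotaxis_levels Directed-turn probabilities (subset of
#'   `c(0, 0.01, 0.05, 0.2)` in the study design; any values in `[0, 1]`
#'   are accepted).
#' @return Data.frame with one row per (level, mode, I_C).
#' @export
run_chemotaxis_experiment <- function(config, chemotaxis_levels, I_C_list,
                                      modes = "diffuse", n_reps = 50,
                                      guesses = c(0.2, 0.5, 1, 2),
                                      k = NULL, seed = 1L, tolerance = 0.1) {
  rows <- list()
  for (lev in chemotaxis_levels) {
    cfg <- config
    cfg$chemotaxis_prob <- lev
    res <- run_extinction_experiment(cfg, I_C_list, modes = modes,
                                     n_reps = n_reps, guesses = guesses,
                                     k = k, seed = seed, tolerance = tolerance)
    res$chemotaxis <- lev
    rows[[as.character(lev)]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "provenance") <- provenance(config, seed)
  out
}

#' Monte-Carlo lattice return probability
#'
#' Fraction of simple symmetric random walks on the `dimension`-cubic
#' lattice that return to their origin within `max_steps` steps — a lower
#' bound on the eventual-return probability (1 in two dimensions; the
#' three-dimensional constant is about 0.34). Used as a plausibility check
#' that target finding by undirected walkers is qualitatively harder in
#' three dimensions.
#'
#' @param dimension 2 or 3.
#' @param n_walks Number of walks.
#' @param max_steps Step cap per walk.
#' @param seed Optional seed.
#' @return Estimated return probability.
#' @examples
#' lattice_return_probability(3, n_walks = 2000, max_steps = 1000, seed = 1)
#' @export
lattice_return_probability <- function(dimension = 3, n_walks = 1e5,
                                       max_steps = 1e4, seed = NULL) {
  stopifnot(dimension %in% c(2, 3), n_walks >= 1, max_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  polya_return_cpp(as.integer(dimension), as.integer(n_walks),
                   as.integer(max_steps))
}

# provenance bundle attached to every experiment output
provenance <- function(config, seed) {
  list(config = unclass(config), seed = seed,
       package_version = as.character(utils::packageVersion("ctlsim")))
}
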