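#' Classify a simulation outcome
#'
#' A run whose infected count reached zero is extinct. Otherwise the
#' outcome is read from the ordinary least-squares gradient of the infected
#' count over the final 12 simulated hours: a negative gradient implies
#' eventual extinction, a positive (or zero) gradient an established
#' infection. Courses shorter than the window are classified on the full
#' course and flagged via the `"truncated_window"` attribute.
#'
#' @param tc A `ctl_timecourse` or data.frame with `time_min` and
#'   `infected`.
#' @param window_h Gradient window, hours.
#' @return `"extinct"` or `"established"`.
#' @examples
#' classify_outcome(data.frame(time_min = 0:80 * 10, infected = 81:1))
#' @export
classify_outcome <- function(tc, window_h = 12) {
  stopifnot(all(c("time_min", "infected") %in% names(tc)))
  if (tc$infected[nrow(tc)] == 0) return("extinct")
  t_end <- tc$time_min[nrow(tc)]
  t0 <- t_end - window_h * 60
  truncated <- t0 < tc$time_min[1]
  keep <- tc$time_min >= max(t0, tc$time_min[1])
  out <- if (sum(keep) < 2) {
    "established"
  } else {
    slope <- stats::coef(stats::lm.fit(cbind(1, tc$time_min[keep]),
                                       tc$infected[keep]))[2]
    if (is.finite(slope) && slope < 0) "extinct" else "established"
  }
  if (truncated) attr(out, "truncated_window") <- TRUE
  out
}

#' Estimate the extinction probability at a CTL density
#'
#' Runs `n_reps` independent simulations at CTL density `C` (a fraction of
#' all sites, converted to a CTL count) and returns the proportion whose
#' outcome is extinction, with a Wilson score interval.
#'
#' @param config A [simulation_config()].
#' @param C CTL density as a fraction of all lattice sites; overrides
#'   `config$n_ctl`.
#' @param n_reps Number of replicates.
#' @param seed Base seed; replicate i runs at `seed + i`.
#' @return A list with `proportion`, `ci` (95% Wilson), `n_extinct`,
#'   `n_reps`, `C` and `n_ctl`.
#' @export
extinction_probability <- function(config, C, n_reps = 200, seed = 1L) {
  stopifnot(inherits(config, "ctl_config"), n_reps >= 1, C >= 0, C <= 1)
  cfg <- config
  N <- cfg$n_rows * cfg$n_cols
  cfg$n_ctl <- as.integer(round(C * N))
  outcomes <- vapply(seq_len(n_reps), function(i) {
    cfg$seed <- as.integer((seed + i) %% .Machine$integer.max)
    attr(run_simulation(cfg), "outcome") == "extinct"
  }, logical(1))
  x <- sum(outcomes)
  list(proportion = x / n_reps, ci = wilson_interval(x, n_reps),
       n_extinct = x, n_reps = n_reps, C = C, n_ctl = cfg$n_ctl)
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level.
#' @return Length-2 vector `c(lower, upper)`.
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Sigmoid extinction-probability curve
#'
#' Two-parameter Hill form `p(C) = C^alpha / (C^alpha + C*^alpha)`: zero at
#' `C = 0`, exactly one half at `C = C*` (the defining property of the
#' critical density) and approaching one as `C` grows; `alpha` sets the
#' steepness.
#'
#' @param C CTL density (any non-negative scale).
#' @param c_star Critical density on the same scale.
#' @param alpha Steepness parameter (> 0).
#' @return Extinction probability.
#' @examples
#' extinction_sigmoid(c(0, 0.03, 1), c_star = 0.03, alpha = 8)
#' @export
extinction_sigmoid <- function(C, c_star, alpha) {
  stopifnot(all(C >= 0), c_star > 0, alpha > 0)
  Ca <- C^alpha
  Ca / (Ca + c_star^alpha)
}

#' Fit the sigmoid extinction curve
#'
#' Nelder-Mead minimisation (3 starts, best objective kept) of either
#' replicate-weighted least squares on the observed proportions (default)
#' or the negative binomial log-likelihood, over `log(C*)` and
#' `log(alpha)`.
#'
#' @param curve A data.frame with columns `C`, `n_reps` and either
#'   `n_extinct` or `proportion` (an `extinction_curve` from
#'   [adaptive_cstar_search()] works directly).
#' @param loss `"wls"` or `"binomial"`.
#' @return An object of class `sigmoid_fit`: list with `c_star`, `alpha`,
#'   `objective`, `converged` and the input `curve`.
#' @examples
#' cc <- data.frame(C = c(.01, .02, .03, .04, .06), n_reps = 200)
#' cc$proportion <- extinction_sigmoid(cc$C, 0.03, 8)
#' fit_sigmoid(cc)$c_star
#' @export
fit_sigmoid <- function(curve, loss = c("wls", "binomial")) {
  loss <- match.arg(loss)
  stopifnot(all(c("C", "n_reps") %in% names(curve)))
  if (!"proportion" %in% names(curve))
    curve$proportion <- curve$n_extinct / curve$n_reps
  curve <- curve[order(curve$C), , drop = FALSE]
  if (length(unique(curve$C)) < 3)
    stop("need at least 3 distinct CTL densities to fit the sigmoid")
  if (min(curve$proportion) > 0.5 || max(curve$proportion) < 0.5)
    warning("proportions do not span 0.5; the fit extrapolates C*")
  obj <- function(par) {
    cs <- exp(par[1]); al <- exp(par[2])
    p <- extinction_sigmoid(curve$C, cs, al)
    if (loss == "wls") {
      sum(curve$n_reps * (curve$proportion - p)^2)
    } else {
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      x <- curve$proportion * curve$n_reps
      -sum(x * log(p) + (curve$n_reps - x) * log(1 - p))
    }
  }
  # crude C* start: first crossing of 0.5 by interpolation
  above <- which(curve$proportion >= 0.5)
  cs0 <- if (length(above) && above[1] > 1) {
    i <- above[1]
    stats::approx(curve$proportion[c(i - 1, i)], curve$C[c(i - 1, i)],
                  xout = 0.5, ties = "ordered")$y
  } else stats::median(curve$C)
  if (!is.finite(cs0) || cs0 <= 0) cs0 <- stats::median(curve$C)
  starts <- list(c(log(cs0), log(4)), c(log(cs0 * 1.5), log(10)),
                 c(log(cs0 / 1.5), log(2)))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  structure(list(c_star = exp(best$par[1]), alpha = exp(best$par[2]),
                 objective = best$value, converged = best$convergence == 0,
                 loss = loss, curve = curve),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("sigmoid_fit: C* = %.4g, alpha = %.3g (%s, %sconverged)\n",
              x$c_star, x$alpha, x$loss, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Adaptive search for the critical CTL density
#'
#' Starting from broadly spaced density guesses, iteratively bisects the
#' bracketing interval on `estimated extinction proportion - 0.5`,
#' accumulating every evaluated `(C, proportion)` point, until the bracket
#' width falls below `tolerance` times its upper end. Estimated proportions
#' exactly at 0.5 are treated as the high side, so ties continue toward the
#' smaller density. The evaluator is a plain function so the search can be
#' driven by the agent-based model ([make_abm_evaluator()]) or by a
#' synthetic oracle in tests.
#'
#' @param eval_fn `function(C, n_reps)` returning an extinction proportion.
#' @param initial_guesses Increasing vector of densities. If they fail to
#'   bracket 0.5 the interval is widened automatically (down by halving,
#'   up to `C = 1`) before giving up.
#' @param n_reps Replicates per evaluation (passed to `eval_fn`).
#' @param tolerance Relative bracket-width stopping rule.
#' @param max_iter Bisection cap.
#' @return An `extinction_curve`: data.frame of all evaluated points
#'   (`C`, `n_reps`, `n_extinct`, `proportion`), with attributes `bracket`
#'   and `n_iter`.
#' @examples
#' oracle <- function(C, n_reps) extinction_sigmoid(C, 0.03, 8)
#' searched <- adaptive_cstar_search(oracle, c(0.01, 0.1), n_reps = 200)
#' attr(searched, "bracket")
#' @export
adaptive_cstar_search <- function(eval_fn, initial_guesses, n_reps = 200,
                                  tolerance = 0.05, max_iter = 30L) {
  stopifnot(length(initial_guesses) >= 2, all(diff(initial_guesses) > 0),
            all(initial_guesses > 0))
  pts <- data.frame(C = numeric(), n_reps = integer(), n_extinct = numeric(),
                    proportion = numeric())
  evaluate <- function(C) {
    p <- eval_fn(C, n_reps)
    pts[nrow(pts) + 1L, ] <<- list(C, as.integer(n_reps),
                                   round(p * n_reps), p)
    p
  }
  props <- vapply(initial_guesses, evaluate, numeric(1))
  widen <- 0L
  while (all(props < 0.5) && widen < 10L) {
    hi_try <- min(1, max(pts$C) * 2)
    props <- c(props, evaluate(hi_try))
    if (hi_try >= 1) break
    widen <- widen + 1L
  }
  while (all(props >= 0.5) && widen < 20L) {
    props <- c(props, evaluate(min(pts$C) / 2))
    widen <- widen + 1L
  }
  below <- pts$C[pts$proportion < 0.5]
  above <- pts$C[pts$proportion >= 0.5]
  if (!length(below) || !length(above))
    stop("could not bracket an extinction proportion of 0.5 in [0, 1]")
  hi <- min(above)
  # sampling noise can put a sub-0.5 estimate above `hi`; the bracket keeps
  # the largest below-density that is still consistent with ordering
  below <- below[below < hi]
  if (!length(below))
    stop("evaluated proportions are not orderable around 0.5; ",
         "increase n_reps or refine the guesses")
  lo <- max(below)
  iter <- 0L
  while ((hi - lo) > tolerance * hi && iter < max_iter) {
    iter <- iter + 1L
    mid <- (lo + hi) / 2
    p <- evaluate(mid)
    if (p >= 0.5) hi <- mid else lo <- mid
  }
  structure(pts[order(pts$C), ],
            bracket = c(lower = lo, upper = hi), n_iter = iter,
            class = c("extinction_curve", "data.frame"))
}

#' Build an ABM-backed extinction-proportion evaluator
#'
#' @param config A [simulation_config()].
#' @param seed Base seed for the replicate streams.
#' @return `function(C, n_reps)` suitable for [adaptive_cstar_search()].
#' @export
make_abm_evaluator <- function(config, seed = 1L) {
  force(config); force(seed)
  counter <- 0L
  function(C, n_reps) {
    counter <<- counter + 1L
    extinction_probability(config, C, n_reps = n_reps,
                           seed = seed + 1000L * counter)$proportion
  }
}

#' Express a critical density in units of the mass-action prediction
#'
#' @param c_star Critical density, fraction of sites.
#' @param k Surveillance rate, cells/min.
#' @param r Growth rate, per day.
#' @return `c_star / (r/k)` in consistent units (dimensionless).
#' @export
relative_cstar <- function(c_star, k, r = 1) c_star / cstar_simple(r, k)

#' Write an extinction curve as CSV
#'
#' @param curve An `extinction_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_extinction_curve <- function(curve, path) {
  cis <- t(mapply(wilson_interval, curve$n_extinct, curve$n_reps))
  out <- cbind(as.data.frame(curve), ci_lo = cis[, 1], ci_hi = cis[, 2])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
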