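#' Simple mass-action killing model (closed form)
#'
#' Infected cells `T` (a fraction of all surveyable cells) replicate at net
#' rate `r` and are killed at rate `k * C0 * T`, where `C0` is the CTL
#' density as a fraction of all surveyable cells and `k` the surveillance
#' rate in cells per minute. The solution is
#' `T(t) = T0 * exp((r/1440 - k*C0) * t)` with `t` in minutes.
#'
#' @param t Time(s) since CTL introduction, minutes.
#' @param k Surveillance rate, cells/min.
#' @param C0 CTL density, fraction of surveyable cells.
#' @param T0 Initial infected fraction.
#' @param r Net growth rate without CTL, per day.
#' @return Infected fraction at each `t`.
#' @examples
#' simple_mass_action(c(0, 1440), k = 0.022, C0 = 0.05, T0 = 0.01)
#' @export
simple_mass_action <- function(t, k, C0, T0, r = 1) {
  stopifnot(k >= 0, C0 >= 0, C0 <= 1, T0 >= 0, T0 <= 1)
  T0 * exp((r / 1440 - k * C0) * t)
}

#' Mass-action critical CTL density
#'
#' The CTL fraction at which killing exactly balances growth,
#' `C* = (r/1440) / k`; densities above it guarantee clearance in the
#' deterministic simple model.
#'
#' @inheritParams simple_mass_action
#' @return Critical density as a fraction of surveyable cells.
#' @examples
#' cstar_simple(r = 1, k = 0.022)  # ~0.0316
#' @export
cstar_simple <- function(r = 1, k) {
  if (!is.numeric(k) || any(k <= 0)) stop("k must be positive: no control is possible at k = 0")
  (r / 1440) / k
}

#' Expected CTL search time
#'
#' `1/(k*I)`: the mean time for one CTL to locate its next infected cell
#' when a fraction `I` of all surveyable cells is infected.
#'
#' @param k Surveillance rate, cells/min.
#' @param infected_fraction Infected fraction `I` in `(0, 1]`.
#' @return Search time in minutes; `Inf` (with a warning) when
#'   `infected_fraction` is zero.
#' @examples
#' expected_search_time(0.7, 0.01)   # ~143 min
#' expected_search_time(0.02, 1)     # 50 min within a packed cluster
#' @export
expected_search_time <- function(k, infected_fraction) {
  stopifnot(k > 0, infected_fraction >= 0, infected_fraction <= 1)
  if (infected_fraction == 0) {
    warning("no infected cells: search time is infinite")
    return(Inf)
  }
  1 / (k * infected_fraction)
}

#' Extended (age-structured conjugate) mass-action model
#'
#' Free targets `T` grow at rate `r` and are bound by free CTL at rate
#' `k * C_free * T`, entering a conjugate pool structured by conjugation age
#' `tau`. Conjugates age deterministically; at age `h` the target dies and
#' the CTL returns to the free pool:
#' \deqn{dT/dt = rT - k C_f T, \quad X(t,0) = k C_f T,}
#' \deqn{\partial X/\partial t + \partial X/\partial \tau = 0, \quad
#'       dC_f/dt = -k C_f T + X(t, h).}
#' Conjugated targets neither replicate nor are re-attacked. The age
#' transport is discretised by first-order upwind on a uniform `tau` grid
#' with time step equal to `dtau` (exact advection, no numerical
#' diffusion); CTL conservation `C_free + sum(X) = C0` holds to machine
#' precision. `h = 0` reduces exactly to [simple_mass_action()].
#'
#' @param k Surveillance rate, cells/min.
#' @param C0 Total CTL fraction.
#' @param T0 Initial infected fraction.
#' @param h Handling time, min.
#' @param r Net growth rate, per day.
#' @param t_end Integration horizon, min.
#' @param dtau Age resolution, min; must divide `h`. Default `h/30`.
#' @param sample_interval Output sampling interval, min.
#' @return A data.frame with `time_min`, `T` (free targets), `C_free`,
#'   `conjugates` (total conjugate density) and `total_infected`
#'   (`T + conjugates`), all as fractions.
#' @examples
#' out <- solve_extended_model(k = 0.7, C0 = 0.01, T0 = 0.01, h = 30,
#'                             t_end = 2880)
#' max(abs(out$C_free + out$conjugates - 0.01))  # CTL conservation
#' @export
solve_extended_model <- function(k, C0, T0, h = 30, r = 1, t_end = 14400,
                                 dtau = NULL, sample_interval = 10) {
  stopifnot(k >= 0, C0 >= 0, C0 <= 1, T0 >= 0, T0 <= 1, h >= 0, t_end > 0)
  r_min <- r / 1440
  if (h == 0) {
    tt <- seq(0, t_end, by = sample_interval)
    Tt <- simple_mass_action(tt, k, C0, T0, r)
    return(data.frame(time_min = tt, T = Tt, C_free = C0,
                      conjugates = 0, total_infected = Tt))
  }
  if (is.null(dtau)) dtau <- h / 30
  n_bins <- h / dtau
  if (abs(n_bins - round(n_bins)) > 1e-8)
    stop("dtau must divide the handling time h")
  if (k * max(T0, C0) * dtau >= 1)
    stop("dtau too coarse for the binding rate (CFL violation)")
  sample_every <- max(1L, as.integer(round(sample_interval / dtau)))
  out <- solve_extended_cpp(r_min, k, h, C0, T0, dtau, t_end, sample_every)
  data.frame(time_min = out$time_min, T = out$T, C_free = out$C_free,
             conjugates = out$conjugates,
             total_infected = out$T + out$conjugates)
}

#' Critical CTL density under the extended model
#'
#' No closed form exists once the handling time is finite; the critical
#' density is found by bisection on `C0` against the sign of the long-run
#' growth rate of free targets, measured as the log-linear slope over the
#' final 20% of the integration horizon. With `h = 0` the mass-action value
#' `r/k` is returned exactly. Because conjugation sequesters CTL, the result
#' is always `>= r/k`, increasingly so as `k*T0*h` grows (the quasi-steady
#' state approximation is `C* ~ r(1 + k*T0*h)/k`).
#'
#' @inheritParams solve_extended_model
#' @param horizon_days Integration horizon per bisection step, days.
#' @param tol Relative tolerance on `C0`.
#' @return Critical CTL density, fraction of surveyable cells.
#' @examples
#' cstar_extended(k = 0.7, T0 = 0.04, h = 30)
#' @export
cstar_extended <- function(k, T0, h = 30, r = 1, horizon_days = 20,
                           tol = 1e-4, dtau = NULL) {
  stopifnot(k > 0, T0 > 0, T0 <= 1)
  base <- cstar_simple(r, k)
  if (h == 0) return(base)
  growth_sign <- function(C0) {
    out <- solve_extended_model(k, C0, T0, h = h, r = r,
                                t_end = horizon_days * 1440, dtau = dtau,
                                sample_interval = horizon_days * 1440 / 200)
    tail_i <- out$time_min >= 0.8 * horizon_days * 1440
    y <- log(pmax(out$T[tail_i], 1e-280))
    stats::coef(stats::lm.fit(cbind(1, out$time_min[tail_i]), y))[2]
  }
  lo <- base  # growth is strictly positive here for h > 0
  hi <- base * 2
  while (growth_sign(hi) > 0) {
    lo <- hi
    hi <- hi * 2
    if (hi > 1) {
      if (growth_sign(1) > 0)
        stop("no critical density below C0 = 1 for these parameters")
      hi <- 1
      break
    }
  }
  while ((hi - lo) > tol * hi) {
    mid <- (lo + hi) / 2
    if (growth_sign(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
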