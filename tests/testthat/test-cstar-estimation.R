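test_that("outcomes are classified by trailing zeros or the 12-h gradient", {
  # trailing zeros: extinct
  expect_equal(classify_outcome(data.frame(time_min = 0:50 * 30,
                                           infected = c(50:1, rep(0, 1)))),
               "extinct")
  # monotone rising tail: established
  expect_equal(classify_outcome(data.frame(time_min = 0:100 * 30,
                                           infected = 1:101)),
               "established")
  # declining 100 -> 80 over the final 12 h: extinct by the gradient rule
  tt <- seq(0, 48 * 60, by = 30)
  inf <- c(rep(100, sum(tt < 36 * 60)),
           seq(100, 80, length.out = sum(tt >= 36 * 60)))
  expect_equal(classify_outcome(data.frame(time_min = tt, infected = inf)),
               "extinct")
  # a course shorter than the window is classified whole and flagged
  short <- data.frame(time_min = 0:10 * 30, infected = 11:21)
  got <- classify_outcome(short)
  expect_equal(as.character(got), "established")
  expect_true(attr(got, "truncated_window"))
})

test_that("the sigmoid has its defining fixed points and limits", {
  expect_equal(extinction_sigmoid(0.03, 0.03, 8), 0.5)
  expect_equal(extinction_sigmoid(0, 0.03, 8), 0)
  expect_gt(extinction_sigmoid(0.06, 0.03, 200), 1 - 1e-12)  # step limit
  expect_lt(extinction_sigmoid(0.02, 0.03, 200), 1e-12)
  p <- extinction_sigmoid(seq(0.001, 0.2, by = 0.001), 0.03, 8)
  expect_true(all(diff(p) > 0))
})

test_that("fitting recovers sigmoid parameters from noiseless curves", {
  C <- c(0.01, 0.02, 0.025, 0.03, 0.04, 0.06, 0.1)
  curve <- data.frame(C = C, n_reps = 200,
                      proportion = extinction_sigmoid(C, 0.03, 8))
  fit <- fit_sigmoid(curve)
  expect_lt(abs(fit$c_star / 0.03 - 1), 1e-4)
  expect_lt(abs(fit$alpha / 8 - 1), 1e-4)
  expect_true(fit$converged)
  # permuting the input rows leaves the fit unchanged
  fit2 <- fit_sigmoid(curve[sample(nrow(curve)), ])
  expect_identical(fit2$c_star, fit$c_star)
  # binomial likelihood loss agrees on noiseless data
  fitb <- fit_sigmoid(curve, loss = "binomial")
  expect_lt(abs(fitb$c_star / 0.03 - 1), 1e-3)
})

test_that("fitting is accurate under binomial sampling noise", {
  C <- c(0.015, 0.02, 0.025, 0.03, 0.04, 0.055, 0.08)
  truth <- extinction_sigmoid(C, 0.03, 8)
  set.seed(2024)
  est <- t(replicate(100, {
    x <- stats::rbinom(length(C), 200, truth)
    fit <- fit_sigmoid(data.frame(C = C, n_reps = 200, n_extinct = x))
    c(fit$c_star, fit$alpha)
  }))
  expect_lt(mean(abs(est[, 1] / 0.03 - 1)), 0.05)   # C* within 5%
  expect_lt(mean(abs(est[, 2] / 8 - 1)), 0.25)      # alpha within 25%
})

test_that("the adaptive search converges on synthetic oracles and keeps every point", {
  # deterministic step oracle: converges to the jump location
  step_oracle <- function(C, n_reps) as.numeric(C > 0.5)
  got <- adaptive_cstar_search(step_oracle, c(0.1, 0.9), n_reps = 10,
                               tolerance = 0.02)
  br <- attr(got, "bracket")
  expect_lte(br[["upper"]] - br[["lower"]], 0.02 * br[["upper"]])
  expect_true(br[["lower"]] <= 0.5 && 0.5 <= br[["upper"]])
  # all evaluated points are retained: initial guesses plus one per iteration
  expect_equal(nrow(got), 2 + attr(got, "n_iter"))
  # noisy Hill oracle: the final bracket contains the true critical density
  set.seed(31)
  hill_oracle <- function(C, n_reps) {
    stats::rbinom(1, n_reps, extinction_sigmoid(C, 0.03, 8)) / n_reps
  }
  got2 <- adaptive_cstar_search(hill_oracle, c(0.005, 0.015, 0.06, 0.15),
                                n_reps = 200, tolerance = 0.05)
  br2 <- attr(got2, "bracket")
  expect_true(br2[["lower"]] <= 0.032 && br2[["upper"]] >= 0.028)
  # guesses on one side of 0.5 are widened automatically
  got3 <- adaptive_cstar_search(step_oracle, c(0.01, 0.05), n_reps = 5,
                                tolerance = 0.05)
  expect_true(attr(got3, "bracket")[["upper"]] >= 0.5)
})

test_that("extinction probabilities from the ABM are monotone in CTL density", {
  cfg <- simulation_config(n_rows = 32, n_cols = 32, dt = 10, I_C = 10,
                           n_ctl = 0, t_max = 3, ctl_velocity = 7.5)
  ladder <- c(0, 0.004, 0.012, 0.04, 0.2)
  props <- vapply(ladder, function(C) {
    extinction_probability(cfg, C, n_reps = 12, seed = 17)$proportion
  }, numeric(1))
  # saturating controls at the ends: no CTL cannot clear, full CTL always do
  expect_equal(props[1], 0)
  expect_equal(props[length(props)], 1)
  # isotonic within binomial slack: pooled increasing fit explains the data
  iso <- stats::isoreg(ladder, props)
  expect_lt(mean((iso$yf - props)^2), 0.02)
  # Wilson interval sanity against the binomial limits
  wi <- wilson_interval(10, 12)
  expect_true(wi[1] > 0.5 && wi[2] < 1)
  ep <- extinction_probability(cfg, 0.2, n_reps = 5, seed = 2)
  expect_equal(ep$n_extinct, 5)
  expect_equal(ep$n_ctl, round(0.2 * 1024))
})
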