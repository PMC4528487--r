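test_that("diffuse_infect_step converts the expected number of cells", {
  w <- tissue_world(32, 32)
  w$state[1:10, 1:10] <- "infected"
  # r = 0: nothing happens
  expect_identical(diffuse_infect_step(w, 0, 10)$state, w$state)
  # saturated grid: no susceptibles left, no-op
  wfull <- tissue_world(8, 8)
  wfull$state[] <- "infected"
  expect_identical(diffuse_infect_step(wfull, 1, 10)$state, wfull$state)
  # closed-form expectation: n_inf * (1 - exp(-r dt)) new infections/step
  set.seed(11)
  n_steps <- 10000
  new_counts <- replicate(n_steps, {
    w2 <- diffuse_infect_step(w, 50, 10)  # inflated rate for a measurable mean
    sum(w2$state == "infected") - 100
  })
  expected <- 100 * (1 - exp(-50 / 1440 * 10 / 60))
  # Monte-Carlo relative SE ~3%; 0.1 is a 3-sigma band
  expect_lt(abs(mean(new_counts) / expected - 1), 0.1)
})

test_that("growth-rate estimation recovers known exponentials", {
  tt <- seq(0, 4 * 1440, by = 60)
  exact <- data.frame(time_min = tt, infected = 80 * exp(tt / 1440))
  expect_equal(estimate_growth_rate(exact, min_count = 1), 1, tolerance = 1e-9)
  flat <- data.frame(time_min = tt, infected = rep(200, length(tt)))
  expect_equal(estimate_growth_rate(flat, min_count = 1), 0)
  # lognormal noise, 50 samples: recovery within 5%
  set.seed(4)
  errs <- replicate(40, {
    tt50 <- seq(0, 2 * 1440, length.out = 50)
    noisy <- data.frame(time_min = tt50,
                        infected = 100 * exp(tt50 / 1440) *
                          exp(stats::rnorm(50, 0, 0.05)))
    estimate_growth_rate(noisy, min_count = 1) - 1
  })
  expect_lt(max(abs(errs)), 0.05)
  # too few usable points is an error
  expect_error(estimate_growth_rate(exact[1:3, ], min_count = 1), "fewer than 5")
  expect_error(estimate_growth_rate(
    data.frame(time_min = tt, infected = rep(2, length(tt)))), "min_count")
})

test_that("production-rate calibration solves a synthetic linear response exactly", {
  cfg <- simulation_config(n_rows = 16, n_cols = 16,
                           infection_mode = "clustered",
                           virion_production = 2)
  runner <- function(production, n) rep(0.55 * production - 0.1, n)
  cal <- calibrate_virion_production(cfg, target_r = 1, sweep_frac = 0.2,
                                     n_points = 7, n_reps = 5, runner = runner)
  expect_equal(cal$production_rate, 2, tolerance = 1e-8)
  expect_s3_class(cal, "growth_calibration")
  expect_equal(nrow(cal$table), 7L)
  # a target outside the swept range is a bracketing error
  expect_error(
    calibrate_virion_production(cfg, target_r = 10, sweep_frac = 0.2,
                                n_points = 7, n_reps = 5, runner = runner),
    "not bracketed")
  # a flat response cannot be solved for the target
  expect_error(
    calibrate_virion_production(cfg, target_r = 1, sweep_frac = 0.2,
                                n_points = 7, n_reps = 5,
                                runner = function(p, n) rep(1, n)),
    "did not increase|not bracketed")
})

test_that("growth response rises with virion production and the report round-trips", {
  cfg <- simulation_config(n_rows = 48, n_cols = 48, dt = 10,
                           infection_mode = "clustered", I_C = 1, n_ctl = 0,
                           t_max = 5)
  measure <- function(prod, seeds) {
    cfg$virion_production <- prod
    mean(vapply(seeds, function(s) {
      cfg$seed <- s
      tryCatch(estimate_growth_rate(run_simulation(cfg), min_count = 30),
               error = function(e) NA_real_)
    }, numeric(1)), na.rm = TRUE)
  }
  lo <- measure(1.0, 1:12)
  hi <- measure(2.4, 1:12)
  expect_gt(hi, lo)
  cal <- structure(list(table = data.frame(production = c(1, 2.4),
                                           mean_r = c(lo, hi),
                                           sd_r = c(0.1, 0.1), n = c(12, 12)),
                        coefficients = c(0, 1), production_rate = 1.5,
                        target_r = 1),
                   class = "growth_calibration")
  path <- tempfile(fileext = ".csv")
  write_calibration(cal, path)
  expect_equal(jsonlite::read_json(paste0(path, ".json"))$production_rate, 1.5)
  unlink(c(path, paste0(path, ".json")))
})

test_that("diffuse infections are spatially random while clustered ones aggregate", {
  # grow both modes to ~observable size and compare Clark-Evans indices
  ce <- function(mode, seed) {
    cfg <- simulation_config(n_rows = 64, n_cols = 64, dt = 10,
                             infection_mode = mode, I_C = 150, n_ctl = 0,
                             t_max = 0.01, seed = seed)
    tc <- run_simulation(cfg)
    s <- attr(tc, "infected_sites")
    sites <- cbind(row = s %/% 64L, col = s %% 64L)
    clark_evans(sites, 10, c(640, 640))
  }
  ce_diffuse <- mean(vapply(1:4, function(i) ce("diffuse", i), numeric(1)))
  ce_clustered <- mean(vapply(1:4, function(i) ce("clustered", i), numeric(1)))
  # complete spatial randomness gives ~1 (slightly below on a lattice with
  # a hard minimum spacing of one cell diameter); clusters sit far below
  expect_gt(ce_diffuse, 0.85)
  expect_lt(ce_clustered, 0.6)
  expect_gt(ce_diffuse, ce_clustered + 0.2)
})
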