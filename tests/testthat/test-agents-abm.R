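test_that("rate_to_prob is the exact exponential waiting-time conversion", {
  expect_equal(rate_to_prob(0, 1), 0)
  # virion clearance: survival over an accumulated 4 h equals one half
  lam <- log(2) / 240  # per min, 4-h half-life
  p_step <- rate_to_prob(lam, 1)
  expect_equal((1 - p_step)^(4 * 3600), 0.5, tolerance = 1e-9)
  # small-probability regime matches the linear approximation within 1%
  expect_lt(abs(rate_to_prob(0.001, 1) / (0.001 / 60) - 1), 0.01)
  expect_error(rate_to_prob(-1, 1), "non-negative")
  # monotone in both arguments
  expect_true(all(diff(rate_to_prob(c(0.1, 0.2, 0.5), 1)) > 0))
  expect_true(rate_to_prob(0.1, 10) > rate_to_prob(0.1, 1))
})

test_that("configuration validation rejects pathological inputs", {
  expect_error(simulation_config(dt = -1), "positive")
  expect_error(simulation_config(chemotaxis_prob = 1.5), "chemotaxis_prob")
  # a coarse step that pushes a per-step probability over the cap
  expect_error(simulation_config(dt = 86400 * 2, infected_halflife = 1.4),
               "time step too coarse")
})

test_that("identical seeds give bit-identical time courses", {
  cfg <- simulation_config(n_rows = 32, n_cols = 32, dt = 10, I_C = 10,
                           n_ctl = 40, t_max = 1, seed = 99)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "infected_sites"), attr(b, "infected_sites"))
})

test_that("site and CTL conservation hold at every sample", {
  for (mode in c("diffuse", "clustered")) {
    cfg <- simulation_config(n_rows = 32, n_cols = 32, dt = 10, I_C = 15,
                             n_ctl = 30, t_max = 2, seed = 5,
                             infection_mode = mode)
    tc <- as.data.frame(run_simulation(cfg))
    expect_true(all(tc$susceptible + tc$infected + tc$dead == 32 * 32))
    post <- tc$ctl_free + tc$ctl_conjugated
    expect_true(all(post[post > 0] == 30))  # after CTL introduction
  }
})

test_that("a world without agents or infection only advances the clock", {
  cfg <- simulation_config(n_rows = 16, n_cols = 16, dt = 10, I_C = 0,
                           n_ctl = 0, t_max = 0.1, seed = 1)
  tc <- as.data.frame(run_simulation(cfg))
  expect_true(all(tc$susceptible == 256))
  expect_true(all(tc$infected == 0 & tc$dead == 0 & tc$virions == 0))
  expect_equal(max(tc$time_min), 0.1 * 1440)
})

test_that("cytopathic death alone halves the infected pool over one half-life", {
  # clustered mode with zero virion production isolates cytopathic death
  cfg <- simulation_config(n_rows = 64, n_cols = 64, dt = 10,
                           infection_mode = "clustered",
                           virion_production = 1e-12, I_C = 0, n_ctl = 0,
                           t_max = 1.4, seed = 31)
  set.seed(31)
  sites <- sample.int(4096, 1000) - 1L
  tc <- as.data.frame(run_simulation(cfg, init_infected_sites = sites))
  surv <- tc$infected[nrow(tc)] / 1000
  # binomial MC error on 1000 trials: 3 sigma ~ 0.047
  expect_lt(abs(surv - 0.5), 0.05)
})

test_that("uncontrolled diffuse infections grow at the target rate", {
  cfg <- simulation_config(n_rows = 128, n_cols = 128, dt = 10, I_C = 0,
                           n_ctl = 0, t_max = 3, sample_interval = 60)
  set.seed(2)
  sites <- sample.int(128 * 128, 200) - 1L
  rr <- vapply(1:8, function(i) {
    cfg$seed <- 500 + i
    estimate_growth_rate(run_simulation(cfg, init_infected_sites = sites),
                         min_count = 1)
  }, numeric(1))
  expect_lt(abs(mean(rr) - 1), 0.05)
  # and the literal r*dt rule without death gives the same net rate
  cfg$diffuse_literal <- TRUE
  rr2 <- vapply(1:8, function(i) {
    cfg$seed <- 700 + i
    estimate_growth_rate(run_simulation(cfg, init_infected_sites = sites),
                         min_count = 1)
  }, numeric(1))
  expect_lt(abs(mean(rr2) - 1), 0.05)
})

test_that("a CTL on every cell clears the infection in essentially all runs", {
  cfg <- simulation_config(n_rows = 24, n_cols = 24, dt = 10, I_C = 6,
                           n_ctl = 24 * 24, t_max = 4, seed = 1)
  outcomes <- vapply(1:10, function(i) {
    cfg$seed <- i
    attr(run_simulation(cfg), "outcome")
  }, character(1))
  expect_true(all(outcomes == "extinct"))
})

test_that("time courses round-trip through CSV with a provenance sidecar", {
  cfg <- simulation_config(n_rows = 16, n_cols = 16, dt = 10, I_C = 4,
                           n_ctl = 10, t_max = 0.5, seed = 3)
  tc <- run_simulation(cfg)
  path <- tempfile(fileext = ".csv")
  write_timecourse(tc, path)
  back <- utils::read.csv(path)
  expect_equal(back, as.data.frame(tc), ignore_attr = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$config$seed, 3L)
  expect_equal(meta$outcome, attr(tc, "outcome"))
  unlink(c(path, paste0(path, ".json")))
})
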