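test_that("undirected turns are uniform on [-45, +45] degrees", {
  w <- tissue_world(8, 8)
  set.seed(123)
  turns <- replicate(1e4, {
    choose_direction(0, c(40, 40), w, chemotaxis_prob = 0)$heading * 180 / pi
  })
  expect_true(all(turns >= -45 & turns <= 45))
  ks <- stats::ks.test(turns, "punif", -45, 45)
  expect_gt(ks$p.value, 0.001)
  # discrete option: exactly the two-point distribution
  set.seed(5)
  dturns <- replicate(200, choose_direction(0, c(40, 40), w, 0,
                                            discrete = TRUE)$heading * 180 / pi)
  expect_setequal(round(unique(dturns), 6), c(-45, 45))
})

test_that("directed turns head exactly at the nearest infected cell", {
  w <- tissue_world(16, 16)
  w$state[5, 9] <- "infected"     # site (4, 8), centre (85, 45)
  set.seed(9)
  got <- choose_direction(1.2, c(45, 45), w, chemotaxis_prob = 1)
  expect_true(got$directed)
  expect_equal(got$heading, atan2(0, 40))  # due +x
  expect_equal(got$distance_remaining, 25)
  # toroidal bearing: a target across the seam is approached the short way
  w2 <- tissue_world(16, 16)
  w2$state[1, 1] <- "infected"    # centre (5, 5)
  got2 <- choose_direction(0, c(150, 5), w2, chemotaxis_prob = 1)
  expect_equal(got2$heading, atan2(0, 15))  # wraps through x = 160
  # no infected cells: a directed draw falls back to a random turn
  w3 <- tissue_world(8, 8)
  set.seed(2)
  got3 <- choose_direction(0.4, c(10, 10), w3, chemotaxis_prob = 1)
  expect_false(got3$directed)
  expect_lte(abs(got3$heading - 0.4), 46 * pi / 180)
})

test_that("the directed-turn frequency matches chemotaxis_prob", {
  w <- tissue_world(8, 8)
  w$state[3, 3] <- "infected"
  set.seed(77)
  frac <- mean(replicate(1e4, {
    choose_direction(0, c(60, 20), w, chemotaxis_prob = 0.2)$directed
  }))
  expect_lt(abs(frac - 0.2), 0.015)  # ~4 sigma of binomial error at 1e4 draws
})

test_that("a conjugated target dies exactly one handling time after contact", {
  # one infected cell, one fast CTL steered straight at it via certain
  # chemotaxis; cytopathic death disabled by a very long half-life
  cfg <- simulation_config(n_rows = 16, n_cols = 16, dt = 1,
                           infection_mode = "clustered",
                           virion_production = 1e-12,
                           infected_halflife = 1e6,
                           ctl_velocity = 30, chemotaxis_prob = 1,
                           handling_time = 30, I_C = 0, n_ctl = 1,
                           t_max = 0.5, sample_interval = 0.5, seed = 17)
  tc <- as.data.frame(run_simulation(cfg, init_infected_sites = 4L * 16L + 4L,
                                     ctl_positions = matrix(c(5, 5), 1)))
  t_conj <- tc$time_min[which(tc$ctl_conjugated == 1)[1]]
  t_kill <- tc$time_min[which(tc$infected == 0)[1]]
  expect_false(is.na(t_conj))
  expect_false(is.na(t_kill))
  # sampled at 0.5-min resolution, so the difference is 30 +/- one sample
  expect_lt(abs(t_kill - t_conj - 30), 1.01)
})

test_that("additional CTL binding the same target do not change its death time", {
  base <- simulation_config(n_rows = 16, n_cols = 16, dt = 1,
                            infection_mode = "clustered",
                            virion_production = 1e-12,
                            infected_halflife = 1e6,
                            ctl_velocity = 30, chemotaxis_prob = 1,
                            handling_time = 30, I_C = 0, t_max = 0.5,
                            sample_interval = 0.5, seed = 17)
  kill_time <- function(n_ctl, positions) {
    cfg <- base
    cfg$n_ctl <- as.integer(n_ctl)
    tc <- as.data.frame(run_simulation(cfg,
                                       init_infected_sites = 4L * 16L + 4L,
                                       ctl_positions = positions))
    tc$time_min[which(tc$infected == 0)[1]]
  }
  t1 <- kill_time(1, matrix(c(5, 5), 1))
  # the extra CTL start further away and attach while the first handles
  t8 <- kill_time(8, rbind(c(5, 5), matrix(rep(c(100, 100), 7), 7, byrow = TRUE)))
  expect_lt(abs(t8 - t1), 1.01)
})

test_that("a motionless CTL never scans and conservation still holds", {
  cfg <- simulation_config(n_rows = 16, n_cols = 16, dt = 10,
                           ctl_velocity = 1e-9, I_C = 0, n_ctl = 5,
                           t_max = 0.2, seed = 3,
                           substrate = "non_susceptible")
  expect_warning(
    out <- measure_surveillance_rate(cfg, duration = 60, n_ctl = 5, seed = 3),
    "too short")
  expect_equal(out$rate, 0)
})

test_that("measured surveillance rate rises with contact radius and scales with speed", {
  cfg <- simulation_config(n_rows = 48, n_cols = 48, dt = 1, seed = 1)
  rates <- vapply(c(2, 5, 9), function(r) {
    cfg$contact_radius <- r
    measure_surveillance_rate(cfg, duration = 60, n_ctl = 60, seed = 8)$rate
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
  # chemotaxis with no infected cells degenerates to the undirected walk
  cfg$chemotaxis_prob <- 0.2
  with_chemo <- measure_surveillance_rate(cfg, duration = 60, n_ctl = 60,
                                          seed = 8)$rate
  cfg$chemotaxis_prob <- 0
  without <- measure_surveillance_rate(cfg, duration = 60, n_ctl = 60,
                                       seed = 8)$rate
  expect_lt(abs(with_chemo / without - 1), 0.05)
})

test_that("contact-radius calibration converges and replays within tolerance", {
  cfg <- simulation_config(n_rows = 48, n_cols = 48, dt = 1, ctl_velocity = 7.5)
  cal <- calibrate_contact_radius(cfg, target_k = 0.9, tol = 0.08,
                                  bracket = c(1, 12), duration = 60,
                                  n_ctl = 60, seed = 41)
  expect_lt(abs(cal$measured_k / 0.9 - 1), 0.08)
  cfg$contact_radius <- cal$contact_radius
  replay <- measure_surveillance_rate(cfg, duration = 90, n_ctl = 80,
                                      seed = 999)$rate
  expect_lt(abs(replay / 0.9 - 1), 0.15)
  expect_error(
    calibrate_contact_radius(cfg, target_k = 50, bracket = c(1, 12),
                             duration = 30, n_ctl = 20, seed = 1),
    "not bracketed")
})
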