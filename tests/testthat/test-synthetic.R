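test_that("noise-free paths follow the deterministic growth curve", {
  sched <- vb_env_schedule(mu = rep(0.7, 5), sigma = 0, l_inf = 780, r_b = 0.3,
                           birth_mean = 50, birth_sd = 0)
  paths <- vb_simulate_individuals(sched, n = 3, horizon = 5, dt = 1e-3, seed = 1)
  for (a in 0:5) {
    expected <- constant_env_mean(a, 50, 0.3, 0.7 * 780)
    got <- paths$length[paths$age == a]
    expect_equal(got, rep(expected, 3), tolerance = 1e-3)
  }
})

test_that("simulation is reproducible and validates its step", {
  sched <- vb_env_schedule(mu = rep(0.7, 3), sigma = 0.5)
  a <- vb_simulate_individuals(sched, n = 50, horizon = 3, seed = 7, dt = 0.05)
  b <- vb_simulate_individuals(sched, n = 50, horizon = 3, seed = 7, dt = 0.05)
  expect_identical(a, b)
  expect_error(vb_simulate_individuals(sched, 10, 3, dt = 0), "positive")
  expect_error(vb_simulate_individuals(sched, 10, 3, dt = 0.5), "0.1")
  expect_error(vb_simulate_individuals(sched, 0, 3), "at least 1")
})

test_that("one-interval ensemble moments match the recursions", {
  # moment-matching at moderate n; the full-scale check runs in acceptance
  sched <- vb_env_schedule(mu = rep(0.8, 1), sigma = 0.5, l_inf = 780,
                           r_b = 0.25, birth_mean = 60, birth_sd = 12)
  paths <- vb_simulate_individuals(sched, n = 2e4, horizon = 1, dt = 0.01,
                                   seed = 8)
  x <- paths$length[paths$age == 1]
  e_exp <- propagate_mean(60, 0.25, 0.8 * 780)
  v_exp <- propagate_var(144, 0.25, (0.25 * 0.5 * 780)^2)
  expect_lt(abs(mean(x) - e_exp) / (sd(x) / sqrt(length(x))), 3)
  expect_lt(abs(var(x) - v_exp) / (var(x) * sqrt(2 / (length(x) - 1))), 3)
})

test_that("long-horizon variance approaches the asymptote", {
  sched <- vb_env_schedule(mu = rep(0.7, 40), sigma = 0.4, l_inf = 780,
                           r_b = 0.35, birth_mean = 50, birth_sd = 10)
  paths <- vb_simulate_individuals(sched, n = 2e4, horizon = 40, dt = 0.05,
                                   seed = 9)
  x <- paths$length[paths$age == 40]
  v_inf <- asymptotic_variance(0.35, (0.35 * 0.4 * 780)^2)
  expect_lt(abs(var(x) - v_inf) / v_inf, 4 * sqrt(2 / (length(x) - 1)))
})

test_that("survey sampling weights behave as inverse-CPUE corrections", {
  sched <- vb_env_schedule(mu = rep(0.7, 6), sigma = 0.5)
  set.seed(10)
  pop <- dplyr::bind_rows(lapply(-3:5, function(tb) {
    vb_simulate_individuals(sched, n = 400, horizon = min(5 - tb, 3),
                            dt = 0.05, birth_time = tb)
  }))
  # uniform catchability: all weights exactly 1
  des_u <- vb_survey_design(0:5, 50, "uniform")
  obs_u <- vb_sample_survey(pop, des_u, ages = 0:3)
  expect_true(all(obs_u$weight == 1))
  expect_equal(nrow(obs_u), 6L * 4L * 50L)

  # biased catchability: weighted moments track the population
  des_b <- vb_survey_design(0:5, 150, "increasing")
  obs_b <- vb_sample_survey(pop, des_b, ages = 0:3)
  old_pop <- pop$length[pop$time %in% 0:5 & pop$age == 3]
  old_obs <- obs_b[obs_b$age == 3, ]
  raw_gap <- mean(old_obs$length) - mean(old_pop)
  w_gap <- weighted.mean(old_obs$length, old_obs$weight) - mean(old_pop)
  expect_gt(raw_gap, 0)               # size-selection inflates the raw mean
  expect_lt(abs(w_gap), abs(raw_gap)) # weights pull it back

  # design occasions must lie within the simulated horizon
  expect_error(vb_sample_survey(pop, vb_survey_design(99, 10, "uniform")),
               "horizon")
})

test_that("generated datasets are reproducible with a coherent truth sidecar", {
  a <- vb_generate_dataset("constant-env", seed = 5, n_t = 5, n_a = 3,
                           n_per_cell = 20)
  b <- vb_generate_dataset("constant-env", seed = 5, n_t = 5, n_a = 3,
                           n_per_cell = 20)
  expect_identical(a$observations, b$observations)
  expect_error(vb_generate_dataset("no-such-scenario"), "Presets")

  # the constant scenario has a single environmental column entry
  expect_equal(dim(a$truth$mu_linf), c(1L, 1L))
  # the grouped scenario has distinct limitation per age group
  g <- vb_generate_dataset("grouped-env", seed = 6, n_t = 5, n_a = 8,
                           n_per_cell = 10)
  expect_equal(ncol(g$truth$mu_linf), 3L)
  expect_true(all(diff(g$truth$mu_linf[1, ]) < 0))
})

test_that("large-sample cell moments match the truth prediction", {
  sim <- vb_generate_dataset("trending-env", seed = 12, n_t = 6, n_a = 4,
                             n_per_cell = 400, n_pop_per_cohort = 500,
                             dt = 0.01)
  pred <- vb_predict(sim$truth)
  cells <- dplyr::group_by(sim$observations, time, age)
  cells <- dplyr::summarise(cells, m = mean(length), v = var(length),
                            n = dplyr::n(), .groups = "drop")
  cells <- dplyr::left_join(cells, pred, by = c("time", "age"))
  z_mean <- (cells$m - cells$mean) / sqrt(cells$var / cells$n)
  z_var <- (cells$v - cells$var) / (cells$var * sqrt(2 / (cells$n - 1)))
  # ~48 simultaneous z-statistics: 4.5 keeps the family-wise false-alarm
  # rate near 0.1% while still catching any systematic moment error
  expect_lt(max(abs(z_mean)), 4.5)
  expect_lt(max(abs(z_var)), 4.5)
})
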