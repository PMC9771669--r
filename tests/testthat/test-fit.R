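test_that("starting values recover a noiseless growth curve", {
  # exact deterministic curve, no year effects, unit weights
  g <- vb_grid(0, 6, 0, 8)
  ages <- rep(0:7, times = 6)
  obs <- make_obs(list(
    time = rep(0:5, each = 8),
    age = ages,
    length = constant_env_mean(ages, 120, 0.303, 380) + rep(c(-1, 1), 24),
    weight = 1
  ))
  st <- suppressWarnings(vb_initial_parameters(obs, g))
  expect_equal(st$e_first_age[1], 120, tolerance = 0.01)
  expect_equal(st$mu_linf[1, 1], 380, tolerance = 0.01)
  expect_equal(st$r_b, 0.303, tolerance = 0.01)
})

test_that("starting values flag degenerate spread and unidentifiable layouts", {
  g <- vb_grid(0, 3, 0, 3)
  flat <- make_obs(list(time = rep(0:2, each = 3), age = rep(0:2, 3),
                        length = 200, weight = 1))
  expect_warning(st <- vb_initial_parameters(flat, g), "floor")
  expect_equal(st$v_first_age[1], 1e-8)

  one_age <- make_obs(list(time = 0:2, age = 1L, length = c(100, 110, 120),
                           weight = 1))
  expect_error(vb_initial_parameters(one_age, vb_grid(0, 3, 0, 3)), "age class")
  one_occ <- make_obs(list(time = 1L, age = 0:2, length = c(100, 150, 190),
                           weight = 1))
  expect_error(vb_initial_parameters(one_occ, vb_grid(0, 3, 0, 3)), "occasions")
})

test_that("fitting improves on the start and stays in the valid domain", {
  sim <- fix_const
  fit <- suppressWarnings(vb_fit(sim$observations, sim$grid, env = "varying"))
  expect_lte(fit$stats$nll, fit$start_nll)
  expect_true(fit$converged)
  # log-space optimization cannot leave the positive orthant
  expect_true(fit$params$r_b > 0)
  expect_true(all(fit$params$v_first_age > 0))
  expect_true(all(fit$params$mu_linf > 0))
  expect_true(all(fit$params$sigma2_linf2 > 0))
  expect_equal(fit$stats$k, vb_param_count(sim$grid, "varying"))
  # the scaled limitation is reported when l_inf is supplied
  fit_s <- suppressWarnings(
    vb_fit(sim$observations, sim$grid, env = "constant", l_inf = 780)
  )
  tbl <- tidy(fit_s)
  mu_row <- tbl[tbl$term == "mu_linf", ]
  expect_equal(mu_row$scaled, mu_row$estimate / 780)
})

test_that("one all-encompassing group reproduces the ungrouped fit", {
  sim <- fix_const
  f0 <- suppressWarnings(vb_fit(sim$observations, sim$grid, env = "constant"))
  f1 <- suppressWarnings(
    vb_fit(sim$observations, sim$grid, env = "constant",
           groups = vb_groups("age", numeric(0)))
  )
  expect_equal(f1$stats$k, f0$stats$k)
  expect_equal(f1$stats$nll, f0$stats$nll, tolerance = 1e-8)
})

test_that("weakly identified boundary cells are reported", {
  sim <- fix_const
  obs <- sim$observations
  obs <- obs[!(obs$time == 3 & obs$age == 0), ]
  expect_warning(
    vb_fit(obs, sim$grid, env = "constant",
           control = vb_control(max_cycles = 2)),
    "first-age-class cells without data at occasion\\(s\\) 3"
  )
})

test_that("a mismatched starting object is refused", {
  sim <- fix_const
  st <- suppressWarnings(
    vb_initial_parameters(sim$observations, sim$grid, env = "constant")
  )
  expect_error(
    vb_fit(sim$observations, sim$grid, env = "varying", start = st),
    "variant"
  )
})
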