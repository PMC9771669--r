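test_that("cell log-likelihood is the weighted Gaussian log-density", {
  # a single standard-normal observation at the mode
  expect_equal(vb_cell_loglik(0, 1, mean = 0, var = 1), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  expect_equal(vb_cell_loglik(0, 1, 0, 1), -0.918939, tolerance = 1e-6)
  # zero-weight observations contribute exactly nothing
  expect_equal(vb_cell_loglik(c(5, 123), c(1, 0), mean = 5, var = 2),
               vb_cell_loglik(5, 1, mean = 5, var = 2))
  # additivity over observations
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(2, 200, 30)
    w <- runif(2, 0.1, 3)
    e <- rnorm(1, 200, 10)
    v <- runif(1, 10, 100)
    expect_equal(vb_cell_loglik(x, w, e, v),
                 vb_cell_loglik(x[1], w[1], e, v) + vb_cell_loglik(x[2], w[2], e, v),
                 tolerance = 1e-12)
  }
  # degenerate variance is floored with a warning, never -Inf/NaN
  expect_warning(out <- vb_cell_loglik(1, 1, 1, 0), "floor")
  expect_true(is.finite(out))
})

test_that("total negative log-likelihood decomposes over cells and rows", {
  p <- make_params(n_t = 4, n_a = 3)
  pred <- vb_predict(p)
  set.seed(22)
  obs <- make_obs(list(
    time = c(1L, 1L, 2L, 3L, 3L),
    age = c(0L, 0L, 1L, 2L, 2L),
    length = rnorm(5, 200, 40),
    weight = runif(5, 0.5, 2)
  ))
  got <- vb_nll(obs, pred)
  # brute-force loop over rows with dnorm
  by_hand <- 0
  for (i in seq_len(nrow(obs))) {
    cell <- pred[pred$time == obs$time[i] & pred$age == obs$age[i], ]
    by_hand <- by_hand - obs$weight[i] *
      dnorm(obs$length[i], cell$mean, sqrt(cell$var), log = TRUE)
  }
  expect_equal(got$nll, by_hand, tolerance = 1e-10)
  expect_equal(got$weighted_n, sum(obs$weight))

  # empty table contributes zero
  expect_equal(vb_nll(obs[0, ], pred)$nll, 0)

  # weight linearity: duplicating every row with halved weights changes nothing
  dup <- dplyr::bind_rows(obs, obs)
  dup$weight <- dup$weight / 2
  expect_equal(vb_nll(dup, pred)$nll, got$nll, tolerance = 1e-10)

  # row order invariance
  expect_equal(vb_nll(obs[sample(5), ], pred)$nll, got$nll, tolerance = 1e-12)

  # scaling all weights by c scales the objective by exactly c
  sc <- obs
  sc$weight <- sc$weight * 3.7
  expect_equal(vb_nll(sc, pred)$nll, 3.7 * got$nll, tolerance = 1e-10)

  # observations in cells absent from the lattice are a structural error
  bad <- make_obs(list(time = 99L, age = 0L, length = 100, weight = 1))
  expect_error(vb_nll(bad, pred), "\\(99, 0\\)")
})

test_that("compiled objective agrees with the reference implementation", {
  set.seed(23)
  sim <- fix_const
  for (env in c("varying", "constant")) {
    for (i in 1:5) {
      st <- suppressWarnings(
        vb_initial_parameters(sim$observations, sim$grid, env = env)
      )
      x <- vb_pack(st) + rnorm(vb_param_count(sim$grid, env), sd = 0.2)
      p <- vb_unpack(x, sim$grid, env = env)
      fn <- vbcohort:::vb_objective(sim$observations, sim$grid, env, NULL, FALSE)
      expect_equal(fn(x), vb_nll(sim$observations, p)$nll, tolerance = 1e-10)
    }
  }
  # grouped and non-shrink paths
  grp <- vb_groups("age", 2)
  st <- suppressWarnings(
    vb_initial_parameters(sim$observations, sim$grid, env = "varying", groups = grp)
  )
  x <- vb_pack(st) + rnorm(length(vb_pack(st)), sd = 0.2)
  p <- vb_unpack(x, sim$grid, env = "varying", groups = grp)
  fn <- vbcohort:::vb_objective(sim$observations, sim$grid, "varying", grp, TRUE)
  expect_equal(fn(x), vb_nll(sim$observations, p, non_shrink = TRUE)$nll,
               tolerance = 1e-10)
})

test_that("likelihood-ratio test matches the chi-square reference", {
  expect_equal(vb_lr_test(100, 100, 1)$p_value, 1)
  expect_equal(vb_lr_test(100 + 3.8415 / 2, 100, 1)$p_value, 0.05,
               tolerance = 1e-4)
  expect_equal(vb_lr_test(100 + 6.6349 / 2, 100, 1)$p_value, 0.01,
               tolerance = 1e-4)
  expect_error(vb_lr_test(90, 100, 1), "nesting")
  expect_error(vb_lr_test(100, 90, 0), "df")
})

test_that("fit statistics satisfy the AIC identity", {
  st <- vb_fit_statistics(nll = 1234.5, k = 85, weighted_n = 1e4)
  expect_identical(st$aic, 2 * 85 + 2 * 1234.5)
})
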