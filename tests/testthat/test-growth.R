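test_that("mean propagation matches its closed form and fixed points", {
  # fixed point: a cohort at the asymptotic length stays there
  expect_equal(propagate_mean(380, 0.7, 380), 380)
  # instant relaxation for very fast growth
  expect_equal(propagate_mean(100, 50, 380), 380, tolerance = 1e-9)
  # scalar evaluation at high precision
  expect_equal(propagate_mean(100, 0.3, 380),
               100 * exp(-0.3) + 380 * (1 - exp(-0.3)), tolerance = 1e-12)
  expect_equal(propagate_mean(100, 0.3, 380), 172.570899, tolerance = 1e-6)
  # strictly between start and asymptote when they differ
  out <- propagate_mean(100, 0.3, 380)
  expect_true(out > 100 && out < 380)
  expect_error(propagate_mean(100, 0, 380), "r_b")
  expect_error(propagate_mean(100, -1, 380), "r_b")
})

test_that("non-shrink propagation never lets a cohort mean decrease", {
  expect_equal(propagate_mean_nonshrink(400, 0.3, 380), 400)
  expect_equal(propagate_mean_nonshrink(100, 0.3, 380),
               propagate_mean(100, 0.3, 380))
  expect_equal(propagate_mean_nonshrink(380, 0.3, 380), 380)
})

test_that("variance propagation matches its closed form and fixed point", {
  # fixed point equals the asymptotic variance
  v_inf <- 1 / (2 * 0.5)
  expect_equal(propagate_var(v_inf, 0.5, 1), v_inf, tolerance = 1e-12)
  expect_equal(propagate_var(0, 0.5, 0), 0)
  expect_equal(propagate_var(0, 0.5, 1), (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(propagate_var(0, 0.5, 1), 0.632121, tolerance = 1e-6)
  expect_error(propagate_var(-1, 0.5, 1), "v_prev")
  expect_equal(asymptotic_variance(0.5, 1), 1)
  expect_equal(asymptotic_variance(0.25, 2), 4)
  expect_error(asymptotic_variance(0, 1), "r_b")
})

test_that("iterated variance propagation converges to the asymptote", {
  set.seed(1)
  for (i in 1:25) {
    r <- runif(1, 0.05, 2)
    s2 <- runif(1, 0, 5000)
    target <- asymptotic_variance(r, s2)
    v_lo <- 0
    v_hi <- 10 * target + 1
    lo_path <- hi_path <- numeric(50)
    for (k in 1:1000) {
      v_lo <- propagate_var(v_lo, r, s2)
      v_hi <- propagate_var(v_hi, r, s2)
      if (k <= 50) {
        lo_path[k] <- v_lo
        hi_path[k] <- v_hi
      }
    }
    expect_equal(v_lo, target, tolerance = 1e-10)
    expect_equal(v_hi, target, tolerance = 1e-10)
    # monotone convergence from below and above
    expect_true(all(diff(c(0, lo_path)) >= 0))
    expect_true(all(diff(c(10 * target + 1, hi_path)) <= 0))
  }
})

test_that("variance propagation is a contraction with rate exp(-2 r_b)", {
  set.seed(2)
  for (i in 1:20) {
    r <- runif(1, 0.05, 1.5)
    s2 <- runif(1, 0, 3000)
    v1 <- runif(1, 0, 5e4)
    v2 <- runif(1, 0, 5e4)
    gap <- abs(propagate_var(v1, r, s2) - propagate_var(v2, r, s2))
    expect_equal(gap, exp(-2 * r) * abs(v1 - v2), tolerance = 1e-9)
  }
})

test_that("mean propagation is monotone in the start value and the asymptote", {
  set.seed(3)
  for (i in 1:20) {
    r <- runif(1, 0.05, 1.5)
    e1 <- runif(1, 0, 500)
    e2 <- e1 + runif(1, 1, 100)
    mu <- runif(1, 100, 700)
    expect_lt(propagate_mean(e1, r, mu), propagate_mean(e2, r, mu))
    expect_lt(propagate_mean(e1, r, mu), propagate_mean(e1, r, mu + 50))
  }
})

test_that("the constant-environment curve equals iterated propagation", {
  expect_equal(constant_env_mean(0, 120, 0.3, 380), 120)
  expect_equal(constant_env_mean(500, 120, 0.3, 380), 380, tolerance = 1e-9)
  expect_error(constant_env_mean(-1, 120, 0.3, 380), "age_offset")
  e <- 120
  for (k in 1:20) {
    e <- propagate_mean(e, 0.3, 380)
    expect_equal(constant_env_mean(k, 120, 0.3, 380), e, tolerance = 1e-12)
  }
})

test_that("lattice prediction fills boundaries and propagates along diagonals", {
  # all boundary means at the asymptote: every interior mean stays there
  g <- vb_grid(0, 2, 0, 2)
  p <- vb_params(g, 0.4, e_first_age = c(380, 380), v_first_age = c(10, 10),
                 e_first_time = 380, v_first_time = 10,
                 mu_linf = 380, sigma2_linf2 = 0)
  pred <- vb_predict(p)
  expect_equal(pred$mean, rep(380, 4))
  expect_equal(nrow(pred), 4L)

  # constant environment: diagonals reproduce the closed-form curve exactly
  p2 <- make_params(n_t = 6, n_a = 6, env = "constant")
  p2$e_first_age[] <- 120
  pred2 <- vb_predict(p2)
  diag_cells <- pred2[pred2$cohort == 2, ]   # cohort entering at (2, 0)
  diag_cells <- diag_cells[order(diag_cells$age), ]
  expect_equal(diag_cells$mean,
               constant_env_mean(0:3, 120, p2$r_b, p2$mu_linf[1, 1]),
               tolerance = 1e-12)
})

test_that("prediction with a time-constant environment is cohort-invariant", {
  p <- make_params(n_t = 7, n_a = 5, env = "constant")
  p$e_first_age[] <- p$e_first_age[1]
  p$v_first_age[] <- p$v_first_age[1]
  pred <- vb_predict(p)
  # every cohort entering through the first age class shares one curve
  full <- pred[pred$cohort %in% 0:3, ]
  by_age <- split(full, full$age)
  for (cells in by_age) {
    expect_equal(max(cells$mean) - min(cells$mean), 0, tolerance = 1e-12)
    expect_equal(max(cells$var) - min(cells$var), 0, tolerance = 1e-12)
  }
})

test_that("group-specific environments drive the matching cohorts", {
  groups <- vb_groups("age", 2)
  g <- vb_grid(0, 3, 0, 4)
  p <- vb_params(g, 0.3,
                 e_first_age = rep(100, 3), v_first_age = rep(50, 3),
                 e_first_time = c(200, 300, 350), v_first_time = c(60, 70, 80),
                 mu_linf = matrix(c(400, 400, 600, 600), 2, 2),
                 sigma2_linf2 = matrix(1000, 2, 2),
                 env = "varying", groups = groups)
  pred <- vb_predict(p)
  # age-1 cell updated from an age-0 start: group 1 (mu 400)
  cell_young <- pred[pred$time == 1 & pred$age == 1, ]
  expect_equal(cell_young$mean, propagate_mean(100, 0.3, 400))
  # two group-1 updates in a row along the youngest cohort diagonal
  cell_12 <- pred[pred$time == 2 & pred$age == 2, ]
  expect_equal(cell_12$mean,
               propagate_mean(propagate_mean(100, 0.3, 400), 0.3, 400))
  # a cohort aged 2 at the interval start (at or above the boundary) uses
  # the group-2 column (mu 600)
  cell_old <- pred[pred$time == 1 & pred$age == 3, ]
  expect_equal(cell_old$mean, propagate_mean(300, 0.3, 600))
})

test_that("non-shrink prediction freezes cohorts above the asymptote", {
  g <- vb_grid(0, 3, 0, 3)
  p <- vb_params(g, 0.3, e_first_age = rep(500, 3), v_first_age = rep(10, 3),
                 e_first_time = c(500, 500), v_first_time = c(10, 10),
                 mu_linf = rep(380, 2), sigma2_linf2 = rep(0, 2))
  shrink <- vb_predict(p)
  frozen <- vb_predict(p, non_shrink = TRUE)
  inner <- shrink$time > 0 & shrink$age > 0
  expect_true(all(shrink$mean[inner] < 500))
  expect_true(all(frozen$mean[inner] == 500))
})
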