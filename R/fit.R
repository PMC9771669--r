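#' Starting values for the cohort growth model
#'
#' Produces the canonical starting point for [vb_fit()]:
#'
#' 1. A single deterministic Von Bertalanffy curve is fitted to all weighted
#'    observations, ignoring year and cohort structure, by weighted least
#'    squares. For a fixed growth rate the curve
#'    [constant_env_mean()] is linear in its two remaining parameters, so the
#'    rate is profiled with a one-dimensional search and the mean at the first
#'    age class (`e0`), the asymptotic length product (`mu_linf`) and the rate
#'    (`r_b`) come out of one pass over the data.
#' 2. The first-age-class variance starts at the weighted variance of the
#'    youngest observed age class (shared across occasions), and the
#'    environmental variance product is set so that the long-term asymptotic
#'    variance equals the weighted variance of the oldest age class.
#' 3. First-occasion distributions for older ages are seeded from the fitted
#'    curve and the oldest-class variance.
#'
#' @param observations A data frame with `time`, `age`, `length`, optional
#'   `weight`.
#' @param grid A [vb_grid()]; inferred from the data when `NULL`.
#' @param env,groups Variant for which starting values are laid out, as in
#'   [vb_params()].
#' @return A [vb_params()] object (constant starting values replicated across
#'   intervals and groups as the variant requires).
#' @export
vb_initial_parameters <- function(observations, grid = NULL,
                                  env = c("varying", "constant"),
                                  groups = NULL) {
  env <- match.arg(env)
  grid <- grid %||% vb_infer_grid(observations)
  obs <- vb_check_observations(observations, grid)
  if (length(unique(obs$age)) < 2L) {
    abort("All observations fall in one age class; a growth curve is unidentifiable.")
  }
  if (length(unique(obs$time)) < 2L) {
    abort("Observations must span at least 2 sampling occasions.")
  }

  vbc <- vb_curve_wls(obs$age - grid$a_min, obs$length, obs$weight)

  wvar <- function(x, w) {
    if (length(x) < 2L) return(VB_VAR_FLOOR)
    mu <- weighted.mean(x, w)
    sum(w * (x - mu)^2) / sum(w)
  }
  young <- obs[obs$age == min(obs$age), ]
  old <- obs[obs$age == max(obs$age), ]
  v_young <- wvar(young$length, young$weight)
  v_old <- wvar(old$length, old$weight)
  if (v_young < VB_VAR_FLOOR || v_old < VB_VAR_FLOOR) {
    warn("Degenerate length spread: starting variance floored at 1e-8.")
    v_young <- max(v_young, VB_VAR_FLOOR)
    v_old <- max(v_old, VB_VAR_FLOOR)
  }
  # environmental variance product whose asymptotic variance is v_old
  s2 <- max(2 * vbc$r_b * v_old, VB_VAR_FLOOR)

  n_groups <- if (is.null(groups)) 1L else groups$n_groups
  n_int <- if (env == "constant") 1L else grid$n_t - 1L
  older <- vb_ages(grid)[-1L]
  vb_params(
    grid = grid,
    r_b = vbc$r_b,
    e_first_age = rep(vbc$e0, grid$n_t),
    v_first_age = rep(v_young, grid$n_t),
    e_first_time = constant_env_mean(older - grid$a_min, vbc$e0, vbc$r_b, vbc$mu_linf),
    v_first_time = rep(v_old, grid$n_a - 1L),
    mu_linf = matrix(vbc$mu_linf, n_int, n_groups),
    sigma2_linf2 = matrix(s2, n_int, n_groups),
    env = env,
    groups = groups
  )
}

# weighted least-squares VB curve with the rate profiled out: for fixed r the
# mean is linear in (e0, mu_linf), so only a 1-D search over r is needed.
vb_curve_wls <- function(age_offset, length, weight, r_range = c(1e-3, 5)) {
  coefs_at <- function(r) {
    x1 <- exp(-r * age_offset)
    X <- cbind(e0 = x1, mu = 1 - x1)
    fit <- stats::lm.wfit(X, length, weight)
    fit
  }
  rss_at <- function(r) {
    fit <- coefs_at(r)
    sum(weight * fit$residuals^2)
  }
  opt <- optimize(rss_at, interval = r_range)
  fit <- coefs_at(opt$minimum)
  cf <- fit$coefficients
  e0 <- cf[["e0"]]
  mu <- cf[["mu"]]
  # guard pathological data; positivity is required downstream
  if (!is.finite(mu) || mu <= 0) mu <- max(length)
  if (!is.finite(e0) || e0 <= 0) e0 <- min(length[length > 0], mu)
  list(e0 = e0, mu_linf = mu, r_b = opt$minimum)
}

#' Optimizer settings for [vb_fit()]
#'
#' The likelihood is maximised in log-parameter space with a derivative-free
#' local search. The default, `"block-nm"`, is a subplex-style scheme:
#' Nelder-Mead is run cyclically on small overlapping blocks of coordinates
#' until a full cycle no longer improves the objective by more than `reltol`
#' in relative terms — far more robust than a single simplex when the
#' parameter vector is long. `"neldermead"` is a restarted full-space
#' Nelder-Mead; `"bfgs"` is quasi-Newton with numerical gradients (smooth
#' variants only, e.g. not `non_shrink`).
#'
#' @param optimizer One of `"block-nm"`, `"neldermead"`, `"bfgs"`.
#' @param reltol Relative convergence tolerance (default `1e-10`).
#' @param max_cycles Maximum block cycles (or restarts).
#' @param block_size Coordinates per Nelder-Mead block.
#' @param maxeval Cap on total objective evaluations.
#' @param n_starts Number of starts; starts beyond the first jitter the packed
#'   (log-scale) starting vector with Gaussian noise of sd `jitter_sd`.
#' @param jitter_sd Log-scale standard deviation of the start jitter.
#' @param seed Seed for the jitter draws (only used when `n_starts > 1`).
#' @return A list of class `vb_control`.
#' @export
vb_control <- function(optimizer = c("block-nm", "neldermead", "bfgs"),
                       reltol = 1e-10, max_cycles = 400L, block_size = 6L,
                       maxeval = 2e6, n_starts = 1L, jitter_sd = 0.1,
                       seed = NULL) {
  structure(
    list(
      optimizer = match.arg(optimizer),
      reltol = reltol,
      max_cycles = as.integer(max_cycles),
      block_size = max(2L, as.integer(block_size)),
      maxeval = maxeval,
      n_starts = as.integer(n_starts),
      jitter_sd = jitter_sd,
      seed = seed
    ),
    class = "vb_control"
  )
}

# ---- optimizer engines -----------------------------------------------------

vb_opt_blocknm <- function(fn, par, ctrl) {
  k <- length(par)
  f <- fn(par)
  n_eval <- 1L
  converged <- FALSE
  bs <- ctrl$block_size
  for (cycle in seq_len(ctrl$max_cycles)) {
    f_before <- f
    # alternate the partition offset so consecutive cycles couple different
    # coordinates (subplex-style subspace mixing)
    offset <- if (cycle %% 2L == 0L) bs %/% 2L else 0L
    idx <- ((seq_len(k) - 1L + offset) %/% bs)
    blocks <- split(seq_len(k), idx)
    blocks <- blocks[lengths(blocks) > 0L]
    for (b in blocks) {
      if (length(b) == 1L) b <- c(b, if (b[1L] == k) k - 1L else b[1L] + 1L)
      obj <- function(x) {
        p <- par
        p[b] <- x
        fn(p)
      }
      res <- optim(par[b], obj, method = "Nelder-Mead",
                   control = list(reltol = ctrl$reltol, maxit = 200L * length(b)))
      n_eval <- n_eval + res$counts[[1L]]
      if (is.finite(res$value) && res$value < f) {
        par[b] <- res$par
        f <- res$value
      }
      if (n_eval >= ctrl$maxeval) break
    }
    if (f_before - f <= ctrl$reltol * (abs(f) + ctrl$reltol)) {
      converged <- TRUE
      break
    }
    if (n_eval >= ctrl$maxeval) break
  }
  list(par = par, value = f, n_eval = n_eval, converged = converged)
}

vb_opt_neldermead <- function(fn, par, ctrl) {
  f <- fn(par)
  n_eval <- 1L
  converged <- FALSE
  for (restart in seq_len(ctrl$max_cycles)) {
    res <- optim(par, fn, method = "Nelder-Mead",
                 control = list(reltol = ctrl$reltol,
                                maxit = min(500L * length(par), 50000L)))
    n_eval <- n_eval + res$counts[[1L]]
    improved <- res$value < f
    if (improved) {
      par <- res$par
    }
    if (f - res$value <= ctrl$reltol * (abs(f) + ctrl$reltol)) {
      f <- min(f, res$value)
      converged <- TRUE
      break
    }
    f <- res$value
    if (n_eval >= ctrl$maxeval) break
  }
  list(par = par, value = f, n_eval = n_eval, converged = converged)
}

vb_opt_bfgs <- function(fn, par, ctrl) {
  res <- optim(par, fn, method = "BFGS",
               control = list(reltol = ctrl$reltol, maxit = ctrl$max_cycles * 50L))
  list(par = res$par, value = res$value,
       n_eval = res$counts[[1L]], converged = res$convergence == 0L)
}

vb_optimize <- function(fn, par0, ctrl) {
  engine <- switch(ctrl$optimizer,
    "block-nm" = vb_opt_blocknm,
    "neldermead" = vb_opt_neldermead,
    "bfgs" = vb_opt_bfgs
  )
  best <- engine(fn, par0, ctrl)
  if (ctrl$n_starts > 1L) {
    if (!is.null(ctrl$seed)) set.seed(ctrl$seed)
    for (s in seq_len(ctrl$n_starts - 1L)) {
      jittered <- par0 + rnorm(length(par0), sd = ctrl$jitter_sd)
      cand <- engine(fn, jittered, ctrl)
      cand$n_eval <- cand$n_eval + best$n_eval
      if (cand$value < best$value) {
        cand$converged <- cand$converged || best$converged
        best <- cand
      } else {
        best$n_eval <- cand$n_eval
      }
    }
  }
  best
}

# dense sufficient-statistic matrices for the compiled objective
vb_stat_matrices <- function(observations, grid) {
  stats <- vb_cell_stats(observations, grid)
  ti <- match(stats$time, vb_times(grid))
  ai <- match(stats$age, vb_ages(grid))
  mk <- function(v) {
    mat <- matrix(0, grid$n_t, grid$n_a)
    mat[cbind(ti, ai)] <- v
    mat
  }
  list(w = mk(stats$w), m = mk(stats$m), s = mk(stats$s))
}

vb_objective <- function(observations, grid, env, groups, non_shrink) {
  sm <- vb_stat_matrices(observations, grid)
  group_mode <- if (is.null(groups)) 0L else if (groups$mode == "age") 1L else 2L
  boundaries <- if (is.null(groups)) numeric(0) else groups$boundaries
  n_groups <- if (is.null(groups)) 1L else groups$n_groups
  function(par) {
    cpp_vb_nll(par, grid$n_t, grid$n_a, grid$a_min, env == "varying",
               n_groups, group_mode, boundaries, non_shrink,
               sm$w, sm$m, sm$s, VB_VAR_FLOOR)
  }
}

#' Fit the stochastic Von Bertalanffy cohort model by maximum likelihood
#'
#' Jointly fits the length distribution of every cohort on the lattice to a
#' table of individual (occasion, age class, length, weight) records by
#' weighted Gaussian maximum likelihood. All free parameters — the growth
#' rate scalar, the boundary length distributions, and the per-interval
#' environmental products — are optimised together in log space with a
#' derivative-free local search started from [vb_initial_parameters()].
#'
#' Only the products `mu * l_inf` (mean asymptotic length, mm) and
#' `sigma^2 * l_inf^2` (variance product) are identifiable; when a
#' species-specific maximum asymptotic length `l_inf` is supplied it is used
#' purely to report the dimensionless environmental limitation
#' `mu = mu_linf / l_inf` and its variance `sigma2 = sigma2_linf2 / l_inf^2`
#' alongside the products (see [tidy.vb_fit()]).
#'
#' @param observations Data frame with columns `time` (occasion index),
#'   `age` (integer age class), `length` (mm) and optional `weight`
#'   (non-negative; default 1).
#' @param grid A [vb_grid()]; inferred as the bounding lattice of the data
#'   when `NULL`.
#' @param env `"varying"` (one environmental mean/variance product per
#'   inter-occasion interval) or `"constant"` (one shared pair).
#' @param groups Optional [vb_groups()] giving age or mean-length classes
#'   with separate environmental products.
#' @param non_shrink If `TRUE`, cohort mean lengths are constrained to be
#'   non-decreasing (see [propagate_mean_nonshrink()]). Fit without it first.
#' @param l_inf Optional species maximum asymptotic length (mm) used for
#'   reporting the scaled limitation.
#' @param start Optional [vb_params()] starting point; defaults to
#'   [vb_initial_parameters()].
#' @param control A [vb_control()].
#'
#' @return An object of class `vb_fit` with elements `params` (a
#'   [vb_params()]), `stats` (see [vb_fit_statistics()]), `converged`,
#'   `n_eval`, `start_nll`, plus the variant descriptors. Methods:
#'   [tidy()], [glance()], [augment()], [predict()][predict.vb_fit],
#'   [autoplot()].
#'
#' @examples
#' sim <- vb_generate_dataset("constant-env", seed = 1,
#'                            n_t = 6, n_a = 4, n_per_cell = 40)
#' fit <- vb_fit(sim$observations, sim$grid, env = "constant")
#' glance(fit)
#' @export
vb_fit <- function(observations, grid = NULL, env = c("varying", "constant"),
                   groups = NULL, non_shrink = FALSE, l_inf = NULL,
                   start = NULL, control = vb_control()) {
  env <- match.arg(env)
  grid <- grid %||% vb_infer_grid(observations)
  obs <- vb_check_observations(observations, grid)
  vb_warn_empty_boundary(obs, grid)

  start <- start %||% vb_initial_parameters(obs, grid, env = env, groups = groups)
  if (start$env != env || !identical(start$groups, groups)) {
    abort("`start` was built for a different model variant (env/groups).")
  }
  par0 <- vb_pack(start)
  fn <- vb_objective(obs, grid, env, groups, non_shrink)
  f0 <- fn(par0)
  if (!is.finite(f0)) {
    abort(sprintf("Objective is not finite at the starting values (nll = %g).", f0))
  }

  res <- vb_optimize(fn, par0, control)
  if (res$value > f0) res <- list(par = par0, value = f0, n_eval = res$n_eval,
                                  converged = FALSE)
  params <- vb_unpack(res$par, grid, env = env, groups = groups)

  check <- vb_nll(obs, params, non_shrink = non_shrink)
  k <- vb_param_count(grid, env, groups)
  stats <- vb_fit_statistics(check$nll, k, check$weighted_n, check$n_floored)

  structure(
    list(
      params = params,
      stats = stats,
      grid = grid,
      env = env,
      groups = groups,
      non_shrink = non_shrink,
      l_inf = l_inf,
      converged = res$converged,
      n_eval = res$n_eval,
      start_nll = f0,
      start = start,
      control = control,
      data_fingerprint = vb_data_fingerprint(obs)
    ),
    class = "vb_fit"
  )
}

vb_data_fingerprint <- function(obs) {
  c(n = nrow(obs), w = sum(obs$weight),
    wx = sum(obs$weight * obs$length), t = sum(obs$time), a = sum(obs$age))
}

vb_warn_empty_boundary <- function(obs, grid) {
  have <- unique(obs[obs$weight > 0, c("time", "age")])
  first_age <- setdiff(vb_times(grid), have$time[have$age == grid$a_min])
  first_time <- setdiff(vb_ages(grid)[-1L], have$age[have$time == grid$t_min])
  msgs <- c(
    if (length(first_age)) {
      sprintf("first-age-class cells without data at occasion(s) %s",
              paste(first_age, collapse = ", "))
    },
    if (length(first_time)) {
      sprintf("first-occasion cells without data at age(s) %s",
              paste(first_time, collapse = ", "))
    }
  )
  if (length(msgs)) {
    warn(paste0("Weakly identified boundary parameters: ",
                paste(msgs, collapse = "; "), "."))
  }
  invisible(NULL)
}

#' Variant label of a fit
#' @param x A `vb_fit`.
#' @return A short string such as `"varying"` or `"constant+groups(age)"`.
#' @export
vb_variant_label <- function(x) {
  stopifnot(inherits(x, "vb_fit"))
  lab <- x$env
  if (!is.null(x$groups)) lab <- paste0(lab, "+groups(", x$groups$mode, ")")
  if (x$non_shrink) lab <- paste0(lab, "+non-shrink")
  lab
}

#' @export
print.vb_fit <- function(x, ...) {
  cat(sprintf(
    "<vb_fit> %s | k = %d | nll = %.4f | AIC = %.4f | %s\n",
    vb_variant_label(x), x$stats$k, x$stats$nll, x$stats$aic,
    if (x$converged) "converged" else "NOT converged"
  ))
  print(x$grid)
  invisible(x)
}

#' Predicted cohort length distributions from a fit
#'
#' @param object A `vb_fit`.
#' @param ... Unused.
#' @return The lattice tibble of [vb_predict()] at the fitted parameters.
#' @export
predict.vb_fit <- function(object, ...) {
  vb_predict(object$params, non_shrink = object$non_shrink)
}
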