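#' One-interval propagation of a cohort's length distribution
#'
#' Within a cohort, individual length follows a Gaussian distribution whose
#' mean and variance evolve across one inter-occasion interval according to a
#' mean-reverting (Ornstein-Uhlenbeck type) form of the Von Bertalanffy
#' growth equation. With `a = exp(-r_b)`:
#'
#' * mean: `E' = E a + mu_linf (1 - a)` — exponential relaxation toward the
#'   current asymptotic length `mu_linf`;
#' * variance: `V' = V a^2 + sigma2_linf2 (1 - a^2) / (2 r_b)` — geometric
#'   decay of inherited spread plus variance injected by between-individual
#'   variation in environmental limitation.
#'
#' `propagate_mean_nonshrink()` is the restricted variant in which a cohort
#' whose mean already exceeds the asymptotic length holds its length instead
#' of shrinking: `max(E, E')`. Use it only after inspecting an unrestricted
#' fit, as it inflates the influence of young cohorts on the environmental
#' estimates.
#'
#' @param e_prev,v_prev Cohort mean length (mm, >= 0) and variance (mm^2,
#'   >= 0) at the start of the interval. Vectorised.
#' @param r_b Von Bertalanffy growth rate scalar per interval (> 0).
#' @param mu_linf Mean asymptotic length for the interval: the product of the
#'   environmental limitation mean and the species maximum length (mm, > 0).
#' @param sigma2_linf2 Variance product for the interval (mm^2 x interval,
#'   >= 0).
#'
#' @return Updated mean (mm) or variance (mm^2) at the end of the interval.
#'
#' @examples
#' propagate_mean(100, r_b = 0.3, mu_linf = 380)    # 172.5709
#' propagate_var(0, r_b = 0.5, sigma2_linf2 = 1)    # 0.6321206
#' asymptotic_variance(r_b = 0.5, sigma2_linf2 = 1) # 1
#' @export
propagate_mean <- function(e_prev, r_b, mu_linf) {
  vb_check_rb(r_b)
  if (any(e_prev < 0)) abort("`e_prev` must be non-negative.")
  if (any(mu_linf <= 0)) abort("`mu_linf` must be strictly positive.")
  a <- exp(-r_b)
  e_prev * a + mu_linf * (1 - a)
}

#' @rdname propagate_mean
#' @export
propagate_mean_nonshrink <- function(e_prev, r_b, mu_linf) {
  pmax(e_prev, propagate_mean(e_prev, r_b, mu_linf))
}

#' @rdname propagate_mean
#' @export
propagate_var <- function(v_prev, r_b, sigma2_linf2) {
  vb_check_rb(r_b)
  if (any(v_prev < 0)) abort("`v_prev` must be non-negative.")
  if (any(sigma2_linf2 < 0)) abort("`sigma2_linf2` must be non-negative.")
  a2 <- exp(-2 * r_b)
  v_prev * a2 + sigma2_linf2 * (1 - a2) / (2 * r_b)
}

vb_check_rb <- function(r_b) {
  if (any(!is.finite(r_b)) || any(r_b <= 0)) {
    abort("`r_b` must be strictly positive and finite.")
  }
  invisible(r_b)
}

#' Long-term asymptotic within-cohort length variance
#'
#' The unique fixed point of [propagate_var()]: the spread a cohort would
#' reach after unbounded time in an environment with constant variability,
#' where variance lost to the mean-reverting growth balances variance gained
#' from between-individual variation in limitation.
#'
#' @inheritParams propagate_mean
#' @return `sigma2_linf2 / (2 r_b)` (mm^2).
#' @export
asymptotic_variance <- function(r_b, sigma2_linf2) {
  vb_check_rb(r_b)
  if (any(sigma2_linf2 < 0)) abort("`sigma2_linf2` must be non-negative.")
  sigma2_linf2 / (2 * r_b)
}

#' Closed-form mean length under a time-constant environment
#'
#' With a constant asymptotic length the mean recursion telescopes to the
#' classical Von Bertalanffy curve
#' `mu_linf + (e0 - mu_linf) exp(-r_b * age_offset)`; this equals
#' `age_offset` successive applications of [propagate_mean()].
#'
#' @param age_offset Number of intervals since the reference age (>= 0;
#'   vectorised, need not be integer).
#' @param e0 Mean length at the reference age (mm).
#' @inheritParams propagate_mean
#' @return Mean length (mm) after `age_offset` intervals.
#' @export
constant_env_mean <- function(age_offset, e0, r_b, mu_linf) {
  vb_check_rb(r_b)
  if (any(age_offset < 0)) abort("`age_offset` must be non-negative.")
  mu_linf + (e0 - mu_linf) * exp(-r_b * age_offset)
}

#' Predict the length distribution of every cohort on the lattice
#'
#' Fills the time-by-age lattice with the Gaussian length distribution of
#' each cohort. Cells of the first occasion and of the first age class are
#' the boundary distributions held in `params`; every other cell
#' `(T + 1, a + 1)` is obtained from `(T, a)` by [propagate_mean()] (or its
#' non-shrink variant) and [propagate_var()] with the environmental products
#' of interval `[T, T + 1)` — so prediction runs along cohort diagonals. When
#' `params` carries groups, the interval update of a cohort uses the
#' environmental column of the group the cohort belongs to at the *start* of
#' the interval.
#'
#' @param params A [vb_params()] object.
#' @param non_shrink If `TRUE`, cohort means never decrease (see
#'   [propagate_mean_nonshrink()]).
#' @return A tibble with one row per lattice cell: `time`, `age`, `cohort`
#'   (`time - age`: the birth occasion), `mean` (mm) and `var` (mm^2). Cells
#'   outside the lattice are not represented (absent, never zero).
#' @examples
#' g <- vb_grid(0, 5, 0, 4)
#' p <- vb_params(g, r_b = 0.3,
#'                e_first_age = rep(120, 5), v_first_age = rep(800, 5),
#'                e_first_time = c(190, 240, 280), v_first_time = rep(900, 3),
#'                mu_linf = rep(380, 4), sigma2_linf2 = rep(5800, 4))
#' vb_predict(p)
#' @export
vb_predict <- function(params, non_shrink = FALSE) {
  stopifnot(inherits(params, "vb_params"))
  g <- params$grid
  n_t <- g$n_t
  n_a <- g$n_a
  ages <- vb_ages(g)
  E <- matrix(NA_real_, n_t, n_a)
  V <- matrix(NA_real_, n_t, n_a)
  E[, 1L] <- params$e_first_age
  V[, 1L] <- params$v_first_age
  E[1L, -1L] <- params$e_first_time
  V[1L, -1L] <- params$v_first_time
  varying <- params$env == "varying"
  for (ti in seq_len(n_t - 1L)) {
    row <- if (varying) ti else 1L
    grp <- vb_assign_group(age = ages[-n_a], mean_length = E[ti, -n_a],
                           groups = params$groups)
    mu <- params$mu_linf[row, grp]
    s2 <- params$sigma2_linf2[row, grp]
    upd <- if (non_shrink) propagate_mean_nonshrink else propagate_mean
    E[ti + 1L, -1L] <- upd(E[ti, -n_a], params$r_b, mu)
    V[ti + 1L, -1L] <- propagate_var(V[ti, -n_a], params$r_b, s2)
  }
  time <- rep(vb_times(g), times = n_a)
  age <- rep(ages, each = n_t)
  tibble::tibble(
    time = time,
    age = age,
    cohort = time - age,
    mean = as.vector(E),
    var = as.vector(V)
  )
}
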