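#' Model parameters for the cohort growth model
#'
#' Bundles every free parameter of the cohort-propagation model on a given
#' lattice:
#'
#' * `r_b` — the Von Bertalanffy growth rate scalar, per inter-occasion
#'   interval (strictly positive);
#' * `e_first_age`, `v_first_age` — mean (mm) and variance (mm^2) of length in
#'   the first age class, one per occasion (`n_t` each);
#' * `e_first_time`, `v_first_time` — mean and variance of length for the
#'   older age classes at the first occasion (`n_a - 1` each);
#' * `mu_linf` — mean asymptotic length per interval and group, i.e. the
#'   product of the environmental limitation mean and the species maximum
#'   asymptotic length (mm); a matrix `n_intervals x n_groups`;
#' * `sigma2_linf2` — the matching variance product (mm^2 per interval of
#'   time); same shape.
#'
#' Only the products `mu * l_inf` and `sigma^2 * l_inf^2` are identifiable
#' from length-at-age data, so the model is parameterised in them; a
#' species-specific `l_inf` is applied only when reporting the dimensionless
#' limitation (see [vb_fit()]).
#'
#' With a time-constant environment (`env = "constant"`) there is a single
#' interval column shared by all `n_t - 1` intervals; with `env = "varying"`
#' each interval gets its own column. The free-parameter count is
#' `k = 1 + 2 n_t + 2 (n_a - 1) + 2 n_intervals n_groups`.
#'
#' @param grid A [vb_grid()].
#' @param r_b Growth rate scalar (> 0, per interval).
#' @param e_first_age,v_first_age Numeric vectors of length `grid$n_t`.
#' @param e_first_time,v_first_time Numeric vectors of length `grid$n_a - 1`.
#' @param mu_linf,sigma2_linf2 Matrices (`n_intervals x n_groups`) or vectors
#'   (recycled to one group). For `env = "constant"`, one row.
#' @param env `"varying"` (default) or `"constant"`.
#' @param groups A [vb_groups()] or `NULL`.
#'
#' @return An object of class `vb_params`.
#' @seealso [vb_pack()], [vb_predict()], [vb_fit()]
#' @export
vb_params <- function(grid, r_b, e_first_age, v_first_age, e_first_time,
                      v_first_time, mu_linf, sigma2_linf2,
                      env = c("varying", "constant"), groups = NULL) {
  stopifnot(inherits(grid, "vb_grid"))
  env <- match.arg(env)
  if (!is.null(groups)) stopifnot(inherits(groups, "vb_groups"))
  n_groups <- if (is.null(groups)) 1L else groups$n_groups
  n_int <- if (env == "constant") 1L else grid$n_t - 1L

  as_env_matrix <- function(x, name) {
    if (is.null(dim(x))) {
      if (length(x) == n_int && n_groups == 1L) {
        x <- matrix(x, nrow = n_int, ncol = 1L)
      } else if (length(x) == 1L) {
        x <- matrix(x, nrow = n_int, ncol = n_groups)
      } else {
        abort(sprintf("`%s` must be a %d x %d matrix (interval x group).",
                      name, n_int, n_groups))
      }
    }
    if (!all(dim(x) == c(n_int, n_groups))) {
      abort(sprintf("`%s` must be a %d x %d matrix (interval x group).",
                    name, n_int, n_groups))
    }
    storage.mode(x) <- "double"
    x
  }

  check_len <- function(x, n, name) {
    if (length(x) != n) abort(sprintf("`%s` must have length %d.", name, n))
    as.numeric(x)
  }

  p <- structure(
    list(
      grid = grid,
      r_b = as.numeric(r_b),
      e_first_age = check_len(e_first_age, grid$n_t, "e_first_age"),
      v_first_age = check_len(v_first_age, grid$n_t, "v_first_age"),
      e_first_time = check_len(e_first_time, grid$n_a - 1L, "e_first_time"),
      v_first_time = check_len(v_first_time, grid$n_a - 1L, "v_first_time"),
      mu_linf = as_env_matrix(mu_linf, "mu_linf"),
      sigma2_linf2 = as_env_matrix(sigma2_linf2, "sigma2_linf2"),
      env = env,
      groups = groups
    ),
    class = "vb_params"
  )
  vb_validate_params(p)
  p
}

vb_validate_params <- function(p) {
  if (length(p$r_b) != 1L || !is.finite(p$r_b) || p$r_b <= 0) {
    abort("`r_b` must be a single strictly positive number.")
  }
  pos <- function(x, name, strict = TRUE) {
    if (anyNA(x) || any(!is.finite(x))) abort(sprintf("`%s` must be finite.", name))
    if (strict && any(x <= 0)) abort(sprintf("`%s` must be strictly positive.", name))
    if (!strict && any(x < 0)) abort(sprintf("`%s` must be non-negative.", name))
  }
  pos(p$e_first_age, "e_first_age")
  pos(p$v_first_age, "v_first_age")
  pos(p$e_first_time, "e_first_time")
  pos(p$v_first_time, "v_first_time")
  pos(p$mu_linf, "mu_linf")
  pos(p$sigma2_linf2, "sigma2_linf2", strict = FALSE)
  invisible(p)
}

#' Free-parameter count for a model variant
#'
#' @inheritParams vb_params
#' @return The integer count
#'   `k = 1 + 2 n_t + 2 (n_a - 1) + 2 n_intervals n_groups` with
#'   `n_intervals = 1` for the constant-environment variant and `n_t - 1`
#'   otherwise. This is the `k` used in AIC and likelihood-ratio tests.
#' @examples
#' g <- vb_grid(0, 32, 0, 10)
#' vb_param_count(g, env = "constant") # 85
#' vb_param_count(g, env = "varying")  # 145
#' @export
vb_param_count <- function(grid, env = c("varying", "constant"), groups = NULL) {
  stopifnot(inherits(grid, "vb_grid"))
  env <- match.arg(env)
  n_groups <- if (is.null(groups)) 1L else groups$n_groups
  n_int <- if (env == "constant") 1L else grid$n_t - 1L
  1L + 2L * grid$n_t + 2L * (grid$n_a - 1L) + 2L * n_int * n_groups
}

#' Pack parameters into (and unpack from) the log-transformed optimizer vector
#'
#' All model parameters are strictly positive, so optimization is carried out
#' on their logarithms: positivity is guaranteed by construction and the
#' orders-of-magnitude differences between, say, `r_b` (~0.3) and variance
#' products (~10^3 mm^2) are evened out. `vb_pack()` lays parameters out as
#' `log r_b`, `log e_first_age`, `log v_first_age`, `log e_first_time`,
#' `log v_first_time`, `log mu_linf` (column-major), `log sigma2_linf2`;
#' `vb_unpack()` inverts it.
#'
#' @param params A [vb_params()] object.
#' @return `vb_pack()`: a numeric vector of length [vb_param_count()].
#' @export
vb_pack <- function(params) {
  stopifnot(inherits(params, "vb_params"))
  log(c(params$r_b,
        params$e_first_age, params$v_first_age,
        params$e_first_time, params$v_first_time,
        as.vector(params$mu_linf), as.vector(params$sigma2_linf2)))
}

#' @rdname vb_pack
#' @param x Packed numeric vector, as produced by `vb_pack()`.
#' @param grid A [vb_grid()].
#' @param env,groups Model variant, as in [vb_params()].
#' @return `vb_unpack()`: the reconstructed `vb_params` object;
#'   `vb_unpack(vb_pack(p), ...)` reproduces `p` exactly up to floating point.
#' @export
vb_unpack <- function(x, grid, env = c("varying", "constant"), groups = NULL) {
  stopifnot(inherits(grid, "vb_grid"))
  env <- match.arg(env)
  k <- vb_param_count(grid, env, groups)
  if (length(x) != k) {
    abort(sprintf("Packed vector has length %d; variant requires %d.", length(x), k))
  }
  n_groups <- if (is.null(groups)) 1L else groups$n_groups
  n_int <- if (env == "constant") 1L else grid$n_t - 1L
  v <- exp(x)
  i <- 1L
  take <- function(n) {
    out <- v[i:(i + n - 1L)]
    i <<- i + n
    out
  }
  vb_params(
    grid = grid,
    r_b = take(1L),
    e_first_age = take(grid$n_t),
    v_first_age = take(grid$n_t),
    e_first_time = take(grid$n_a - 1L),
    v_first_time = take(grid$n_a - 1L),
    mu_linf = matrix(take(n_int * n_groups), n_int, n_groups),
    sigma2_linf2 = matrix(take(n_int * n_groups), n_int, n_groups),
    env = env,
    groups = groups
  )
}

#' @export
print.vb_params <- function(x, ...) {
  g <- x$grid
  cat(sprintf(
    "<vb_params> %s environment, %d group(s), k = %d\n  r_b = %.4f per interval\n",
    x$env, ncol(x$mu_linf), vb_param_count(g, x$env, x$groups), x$r_b
  ))
  cat(sprintf("  mu_linf: %s mm; sigma2_linf2: %s mm^2\n",
              vb_range_label(x$mu_linf), vb_range_label(x$sigma2_linf2)))
  invisible(x)
}

vb_range_label <- function(x) {
  if (length(x) == 1L) sprintf("%.3g", x)
  else sprintf("%.3g..%.3g", min(x), max(x))
}

#' @export
tidy.vb_params <- function(x, ...) {
  g <- x$grid
  n_int <- nrow(x$mu_linf)
  n_groups <- ncol(x$mu_linf)
  # interval varies fastest, matching column-major as.vector() of the matrices
  env_idx <- tidyr::expand_grid(
    group = seq_len(n_groups),
    interval = if (n_int == 1L) NA_integer_ else vb_intervals(g)
  )
  env_tbl <- dplyr::bind_rows(
    dplyr::mutate(env_idx, term = "mu_linf", estimate = as.vector(x$mu_linf)),
    dplyr::mutate(env_idx, term = "sigma2_linf2", estimate = as.vector(x$sigma2_linf2))
  )
  dplyr::bind_rows(
    tibble::tibble(term = "r_b", time = NA_integer_, age = NA_integer_,
                   interval = NA_integer_, group = NA_integer_, estimate = x$r_b),
    tibble::tibble(term = "e_first_age", time = vb_times(g), age = g$a_min,
                   estimate = x$e_first_age),
    tibble::tibble(term = "v_first_age", time = vb_times(g), age = g$a_min,
                   estimate = x$v_first_age),
    tibble::tibble(term = "e_first_time", time = g$t_min, age = vb_ages(g)[-1L],
                   estimate = x$e_first_time),
    tibble::tibble(term = "v_first_time", time = g$t_min, age = vb_ages(g)[-1L],
                   estimate = x$v_first_time),
    env_tbl
  ) |>
    dplyr::select("term", "time", "age", "interval", "group", "estimate")
}
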