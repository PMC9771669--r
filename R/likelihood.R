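# Weighted Gaussian likelihood of an observation table against a predicted
# lattice. Observations collapse to per-cell sufficient statistics
# (sum w, sum w x, sum w x^2), so evaluation cost is independent of n.

# Lower bound for a cell variance inside the likelihood: cells whose predicted
# variance collapses (single observation, degenerate data) are floored rather
# than allowed to drive the log-density to +/-Inf.
VB_VAR_FLOOR <- 1e-8

#' Weighted Gaussian log-likelihood of one lattice cell
#'
#' Each cell of the lattice carries an independent Gaussian length
#' distribution, so a cell's contribution is
#' `sum_i w_i * log N(x_i; mean, var)`. Weights act as observation
#' multiplicities (an observation with weight 2 counts as two fish); a zero
#' weight contributes exactly 0.
#'
#' @param lengths Observed lengths (mm).
#' @param weights Non-negative observation weights, recycled to
#'   `length(lengths)`.
#' @param mean,var Predicted cell mean (mm) and variance (mm^2). Variances
#'   below the floor `1e-8` are floored with a warning.
#' @return The weighted log-likelihood (a single number).
#' @examples
#' vb_cell_loglik(0, 1, mean = 0, var = 1) # -0.5 * log(2 * pi)
#' @export
vb_cell_loglik <- function(lengths, weights = 1, mean, var) {
  stopifnot(length(mean) == 1L, length(var) == 1L)
  weights <- rep_len(weights, length(lengths))
  if (any(weights < 0) || anyNA(weights)) abort("`weights` must be non-negative.")
  if (var < VB_VAR_FLOOR) {
    warn(sprintf("Cell variance %.3g below floor %.0e; floored.", var, VB_VAR_FLOOR))
    var <- VB_VAR_FLOOR
  }
  w <- sum(weights)
  m <- sum(weights * lengths)
  s <- sum(weights * lengths^2)
  -0.5 * w * log(2 * pi * var) - 0.5 * (s - 2 * mean * m + w * mean^2) / var
}

# per-cell sufficient statistics of an observation table
vb_cell_stats <- function(observations, grid) {
  obs <- vb_check_observations(observations, grid)
  obs |>
    dplyr::group_by(.data$time, .data$age) |>
    dplyr::summarise(
      w = sum(.data$weight),
      m = sum(.data$weight * .data$length),
      s = sum(.data$weight * .data$length^2),
      .groups = "drop"
    )
}

vb_check_observations <- function(observations, grid = NULL, allow_empty = FALSE) {
  stopifnot(is.data.frame(observations))
  need <- c("time", "age", "length")
  miss <- setdiff(need, names(observations))
  if (length(miss)) {
    abort(paste0("Observation table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  obs <- tibble::as_tibble(observations)
  if (!"weight" %in% names(obs)) obs$weight <- 1
  if (any(!is.finite(obs$weight)) || any(obs$weight < 0)) {
    abort("Observation weights must be finite and non-negative.")
  }
  if (sum(obs$weight) <= 0 && !(allow_empty && nrow(obs) == 0L)) {
    abort("Total observation weight must be positive.")
  }
  if (!is.null(grid)) {
    on_grid <- obs$time %in% vb_times(grid) & obs$age %in% vb_ages(grid)
    if (!all(on_grid)) {
      bad <- unique(obs[!on_grid, c("time", "age")])
      abort(paste0(
        "Observations fall outside the lattice at (time, age): ",
        paste(sprintf("(%d, %d)", bad$time, bad$age), collapse = ", ")
      ))
    }
  }
  obs
}

#' Negative weighted log-likelihood of an observation table
#'
#' Sums [vb_cell_loglik()] over all lattice cells holding data and negates.
#' Weights scale linearly: multiplying every weight by `c` multiplies the
#' result by `c`, leaving the maximum-likelihood estimates unchanged.
#'
#' @param observations A data frame with columns `time`, `age`, `length` and
#'   optionally `weight` (default 1).
#' @param prediction A predicted lattice as returned by [vb_predict()], or a
#'   [vb_params()] object (predicted on the fly).
#' @param non_shrink Passed to [vb_predict()] when `prediction` is a
#'   `vb_params` object.
#' @return A list with `nll` (the negative weighted log-likelihood),
#'   `n_floored` (number of cells whose variance hit the floor) and
#'   `weighted_n` (total weight).
#' @export
vb_nll <- function(observations, prediction, non_shrink = FALSE) {
  if (inherits(prediction, "vb_params")) {
    grid <- prediction$grid
    prediction <- vb_predict(prediction, non_shrink = non_shrink)
  } else {
    stopifnot(is.data.frame(prediction))
    grid <- vb_infer_grid(prediction)
  }
  obs <- vb_check_observations(observations, grid, allow_empty = TRUE)
  if (nrow(obs) == 0L) {
    return(list(nll = 0, n_floored = 0L, weighted_n = 0))
  }
  stats <- vb_cell_stats(obs, grid)
  cells <- dplyr::left_join(stats, prediction, by = c("time", "age"))
  if (anyNA(cells$mean) || anyNA(cells$var)) {
    bad <- cells[is.na(cells$mean) | is.na(cells$var), c("time", "age")]
    abort(paste0(
      "No predicted distribution for observed cell(s): ",
      paste(sprintf("(%d, %d)", bad$time, bad$age), collapse = ", ")
    ))
  }
  v <- pmax(cells$var, VB_VAR_FLOOR)
  ll <- -0.5 * cells$w * log(2 * pi * v) -
    0.5 * (cells$s - 2 * cells$mean * cells$m + cells$w * cells$mean^2) / v
  list(
    nll = -sum(ll),
    n_floored = sum(cells$var < VB_VAR_FLOOR),
    weighted_n = sum(cells$w)
  )
}

#' Likelihood-ratio test for nested model variants
#'
#' Compares a restricted model (e.g. time-constant environmental limitation)
#' against a nesting full model (e.g. year-varying limitation) via the
#' deviance `2 * (nll_restricted - nll_full)`, referred to a chi-square
#' distribution with `df` degrees of freedom.
#'
#' @param nll_restricted,nll_full Negative log-likelihoods at the optima of
#'   the restricted and full models.
#' @param df Difference in free-parameter count (>= 1).
#' @param tol Tolerance for a slightly negative deviance from finite
#'   optimizer precision; beyond it, nesting is considered violated.
#' @return A tibble with `statistic` (deviance), `df` and `p_value`.
#' @examples
#' vb_lr_test(105, 100, df = 2)
#' @export
vb_lr_test <- function(nll_restricted, nll_full, df, tol = 1e-6) {
  if (df < 1 || df != round(df)) abort("`df` must be a positive integer.")
  dev <- 2 * (nll_restricted - nll_full)
  if (dev < -tol * max(1, abs(nll_full))) {
    abort("Restricted model fits better than the full model: nesting violated.")
  }
  dev <- max(dev, 0)
  tibble::tibble(
    statistic = dev,
    df = as.integer(df),
    p_value = pchisq(dev, df = df, lower.tail = FALSE)
  )
}

#' Model-fit statistics
#'
#' @param nll Negative weighted log-likelihood at the optimum.
#' @param k Free-parameter count ([vb_param_count()]).
#' @param weighted_n Total observation weight.
#' @param n_floored Number of variance-floored cells.
#' @return A tibble row with `nll`, `k`, `aic = 2 k + 2 nll`, `weighted_n`
#'   and `n_floored`.
#' @export
vb_fit_statistics <- function(nll, k, weighted_n, n_floored = 0L) {
  tibble::tibble(
    nll = nll,
    k = as.integer(k),
    aic = 2 * k + 2 * nll,
    weighted_n = weighted_n,
    n_floored = as.integer(n_floored)
  )
}
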