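#' Define the discrete time-by-age lattice on which cohorts are tracked
#'
#' A survey design samples a population at (approximately) regular occasions
#' and assigns each individual to an integer age class. Cohorts — individuals
#' born in the same inter-sampling interval — then move along the diagonals of
#' a time-by-age lattice: an individual in cell `(time, age)` is found in cell
#' `(time + 1, age + 1)` one occasion later. All model predictions and fits
#' are indexed on this lattice.
#'
#' @param t_min Integer index of the first sampling occasion (e.g. `0`, or a
#'   calendar year such as `1990`).
#' @param n_t Number of sampling occasions (at least 2).
#' @param a_min First observed age class (integer, at least 0).
#' @param n_a Number of age classes (at least 2).
#'
#' @return An object of class `vb_grid`: a list with elements `t_min`, `n_t`,
#'   `a_min`, `n_a`.
#'
#' @details Occasions run `t_min, ..., t_min + n_t - 1` and age classes run
#'   `a_min, ..., a_min + n_a - 1`. The `n_t - 1` inter-occasion intervals
#'   `[T, T + 1)` carry the environmental-limitation parameters. At least two
#'   occasions and two age classes are required; otherwise there is no
#'   interval or cohort structure to model.
#'
#' @examples
#' g <- vb_grid(t_min = 1990, n_t = 32, a_min = 0, n_a = 10)
#' g
#' vb_times(g)
#' vb_ages(g)
#' @export
vb_grid <- function(t_min, n_t, a_min, n_a) {
  t_min <- vb_int_scalar(t_min, "t_min")
  n_t <- vb_int_scalar(n_t, "n_t")
  a_min <- vb_int_scalar(a_min, "a_min")
  n_a <- vb_int_scalar(n_a, "n_a")
  if (n_t < 2L) abort("`n_t` must be at least 2: one occasion has no interval structure.")
  if (n_a < 2L) abort("`n_a` must be at least 2: one age class has no cohort structure.")
  if (a_min < 0L) abort("`a_min` must be a non-negative integer age class.")
  structure(
    list(t_min = t_min, n_t = n_t, a_min = a_min, n_a = n_a),
    class = "vb_grid"
  )
}

vb_int_scalar <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x != round(x)) {
    abort(sprintf("`%s` must be a single finite integer.", name))
  }
  as.integer(x)
}

#' @export
print.vb_grid <- function(x, ...) {
  cat(sprintf(
    "<vb_grid> %d occasions (%d..%d) x %d age classes (%d..%d); %d intervals\n",
    x$n_t, x$t_min, x$t_min + x$n_t - 1L,
    x$n_a, x$a_min, x$a_min + x$n_a - 1L,
    x$n_t - 1L
  ))
  invisible(x)
}

#' Occasion, age-class and interval indices of a lattice
#'
#' @param grid A [vb_grid()].
#' @return `vb_times()` and `vb_ages()` return integer vectors of occasion and
#'   age-class labels; `vb_intervals()` returns the starting occasions of the
#'   `n_t - 1` inter-occasion intervals.
#' @export
vb_times <- function(grid) {
  stopifnot(inherits(grid, "vb_grid"))
  grid$t_min + seq_len(grid$n_t) - 1L
}

#' @rdname vb_times
#' @export
vb_ages <- function(grid) {
  stopifnot(inherits(grid, "vb_grid"))
  grid$a_min + seq_len(grid$n_a) - 1L
}

#' @rdname vb_times
#' @export
vb_intervals <- function(grid) {
  stopifnot(inherits(grid, "vb_grid"))
  grid$t_min + seq_len(grid$n_t - 1L) - 1L
}

#' Infer the bounding lattice of an observation table
#'
#' @param observations A data frame with integer `time` and `age` columns.
#' @return A [vb_grid()] spanning the observed times and ages.
#' @export
vb_infer_grid <- function(observations) {
  stopifnot(is.data.frame(observations), all(c("time", "age") %in% names(observations)))
  if (nrow(observations) == 0L) abort("Cannot infer a grid from an empty table.")
  vb_grid(
    t_min = min(observations$time),
    n_t = diff(range(observations$time)) + 1L,
    a_min = min(observations$age),
    n_a = diff(range(observations$age)) + 1L
  )
}
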