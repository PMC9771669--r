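#' Split a population into ecological groups by age or by cohort mean length
#'
#' Populations may be environmentally segregated by life stage — e.g. flatfish
#' moving offshore as they grow — so the environmental limitation can be
#' estimated separately for a small number of age or length classes. A cohort
#' is classified as a whole, by its age or by its *predicted mean* length at
#' the start of each inter-occasion interval; individuals are never classified
#' one by one, so all members of a cohort always share one group.
#'
#' @param mode `"age"` or `"mean_length"`.
#' @param boundaries Strictly ascending cut points; `n` boundaries define
#'   `n + 1` groups as lower-closed, upper-open intervals: values below the
#'   first boundary fall in group 1, values equal to a boundary fall in the
#'   group above it. Zero boundaries give a single all-encompassing group.
#'
#' @return An object of class `vb_groups` with elements `mode`, `boundaries`
#'   and `n_groups`.
#'
#' @examples
#' # ages up to 3, 4 to 7, and over 7 (boundaries at 4 and 8):
#' grp <- vb_groups("age", c(4, 8))
#' vb_assign_group(age = c(3, 4, 7, 8), groups = grp)
#' @export
vb_groups <- function(mode = c("age", "mean_length"), boundaries) {
  mode <- match.arg(mode)
  boundaries <- as.numeric(boundaries)
  if (anyNA(boundaries) || any(!is.finite(boundaries))) {
    abort("`boundaries` must be finite cut points.")
  }
  if (is.unsorted(boundaries, strictly = TRUE)) {
    abort("`boundaries` must be strictly ascending.")
  }
  # zero boundaries -> one all-encompassing class
  structure(
    list(mode = mode, boundaries = boundaries, n_groups = length(boundaries) + 1L),
    class = "vb_groups"
  )
}

#' @export
print.vb_groups <- function(x, ...) {
  cat(sprintf(
    "<vb_groups> %d groups by %s; boundaries: %s\n",
    x$n_groups, x$mode, paste(x$boundaries, collapse = ", ")
  ))
  invisible(x)
}

#' Assign cohorts to groups
#'
#' @param age Cohort age(s) at the start of the interval (used when
#'   `groups$mode == "age"`).
#' @param mean_length Predicted cohort mean length(s) at the start of the
#'   interval (used when `groups$mode == "mean_length"`).
#' @param groups A [vb_groups()] object, or `NULL` for a single group.
#' @return Integer group indices starting at 1. A value exactly equal to a
#'   boundary belongs to the upper group.
#' @export
vb_assign_group <- function(age = NULL, mean_length = NULL, groups = NULL) {
  if (is.null(groups)) {
    n <- max(length(age), length(mean_length), 1L)
    return(rep(1L, n))
  }
  stopifnot(inherits(groups, "vb_groups"))
  x <- if (groups$mode == "age") age else mean_length
  if (is.null(x)) {
    abort(sprintf("`%s` values are required for %s-based groups.",
                  if (groups$mode == "age") "age" else "mean_length", groups$mode))
  }
  # lower-closed, upper-open classes; below the first boundary -> group 1
  findInterval(x, groups$boundaries, left.open = FALSE) + 1L
}
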