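#' Tidy a fitted cohort growth model
#'
#' One row per free parameter, in the layout of [tidy.vb_params()]. When the
#' fit was given a species maximum asymptotic length `l_inf`, environmental
#' terms also carry a `scaled` column: the dimensionless limitation mean
#' `mu_linf / l_inf` and variance `sigma2_linf2 / l_inf^2`.
#'
#' @param x A `vb_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `time`, `age`, `interval`, `group`,
#'   `estimate` and (with `l_inf`) `scaled`.
#' @export
tidy.vb_fit <- function(x, ...) {
  out <- tidy(x$params)
  if (!is.null(x$l_inf)) {
    out$scaled <- dplyr::case_when(
      out$term == "mu_linf" ~ out$estimate / x$l_inf,
      out$term == "sigma2_linf2" ~ out$estimate / x$l_inf^2,
      TRUE ~ NA_real_
    )
  }
  out
}

#' One-row summary of a fitted cohort growth model
#'
#' @param x A `vb_fit`.
#' @param ... Unused.
#' @return A tibble with `variant`, `nll`, `k`, `aic`, `weighted_n`,
#'   `n_floored`, `r_b`, `converged`, `n_eval`.
#' @export
glance.vb_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(variant = vb_variant_label(x)),
    x$stats,
    tibble::tibble(r_b = x$params$r_b, converged = x$converged,
                   n_eval = x$n_eval)
  )
}

#' Augment observations with fitted cell distributions
#'
#' @param x A `vb_fit`.
#' @param data Observation table (defaults to refusing silently absent data —
#'   pass the table the model was fitted to).
#' @param ... Unused.
#' @return `data` with columns `.mean`, `.var` (fitted cell distribution),
#'   `.resid` (`length - .mean`) and `.std_resid`
#'   (`.resid / sqrt(.var)`).
#' @export
augment.vb_fit <- function(x, data, ...) {
  obs <- vb_check_observations(data, x$grid)
  pred <- predict(x)
  out <- dplyr::left_join(obs, pred[, c("time", "age", "mean", "var")],
                          by = c("time", "age"))
  dplyr::mutate(out,
    .mean = .data$mean, .var = .data$var,
    .resid = .data$length - .data$mean,
    .std_resid = .data$.resid / sqrt(.data$var),
    mean = NULL, var = NULL
  )
}

#' Plot the estimated environmental limitation through time
#'
#' The trajectory of the per-interval mean asymptotic length (or, when the
#' fit carries `l_inf`, the dimensionless limitation), with a ribbon of plus
#' or minus two long-term asymptotic standard deviations derived from the
#' fitted variance products — the spread individual fish would reach under
#' each interval's variability.
#'
#' @param object A `vb_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vb_fit <- function(object, ...) {
  grid <- object$grid
  tbl <- vb_env_tbl(object$params, grid)
  n_int <- nrow(object$params$mu_linf)
  s2 <- as.vector(object$params$sigma2_linf2)
  tbl$sd_inf <- sqrt(asymptotic_variance(object$params$r_b, s2))
  if (n_int == 1L) {
    tbl <- tidyr::expand_grid(interval = vb_intervals(grid),
                              tbl[, c("group", "mu_linf", "sd_inf")])
  }
  scale <- object$l_inf %||% 1
  ylab <- if (is.null(object$l_inf)) {
    "mean asymptotic length (mm)"
  } else {
    "environmental limitation"
  }
  tbl$group <- factor(tbl$group)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$interval, y = .data$mu_linf / scale,
                                    group = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = (.data$mu_linf - 2 * .data$sd_inf) / scale,
      ymax = (.data$mu_linf + 2 * .data$sd_inf) / scale,
      fill = .data$group
    ), alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$group)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
    ggplot2::labs(x = "interval start", y = ylab,
                  title = sprintf("Estimated environmental limitation (%s)",
                                  vb_variant_label(object))) +
    ggplot2::theme_minimal()
}

#' Plot predicted cohort growth curves
#'
#' Mean length-at-age of every cohort on the lattice, coloured by cohort
#' (birth occasion), with an optional plus/minus two standard deviation band
#' for a highlighted cohort.
#'
#' @param fit A `vb_fit` (or a [vb_params()] object).
#' @param highlight Optional cohort (birth occasion) to single out with its
#'   length-distribution band.
#' @return A ggplot.
#' @export
plot_cohort_curves <- function(fit, highlight = NULL) {
  pred <- if (inherits(fit, "vb_fit")) predict(fit) else vb_predict(fit)
  p <- ggplot2::ggplot(pred, ggplot2::aes(x = .data$time, y = .data$mean,
                                          group = .data$cohort,
                                          colour = .data$cohort)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "occasion", y = "mean length (mm)",
                  colour = "cohort") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    hl <- pred[pred$cohort == highlight, ]
    p <- p +
      ggplot2::geom_ribbon(
        data = hl,
        ggplot2::aes(ymin = .data$mean - 2 * sqrt(.data$var),
                     ymax = .data$mean + 2 * sqrt(.data$var)),
        alpha = 0.2, colour = NA
      ) +
      ggplot2::geom_line(data = hl, linewidth = 1.2)
  }
  p
}

#' Plot jackknife sensitivity of the environmental limitation
#'
#' @param object A [vb_jackknife()] result.
#' @param ... Unused.
#' @return A ggplot: one line of per-interval limitation estimates per
#'   omitted occasion, over the full-data estimate in black.
#' @export
autoplot.vb_jackknife <- function(object, ...) {
  d <- object$deltas
  full <- dplyr::distinct(d, .data$interval, .data$group, .data$mu_linf_full)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$interval, y = .data$mu_linf_jack,
                                  group = .data$omitted,
                                  colour = factor(.data$omitted))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_line(data = full,
                       mapping = ggplot2::aes(x = .data$interval,
                                              y = .data$mu_linf_full,
                                              group = .data$group),
                       colour = "black", linewidth = 1,
                       inherit.aes = FALSE) +
    ggplot2::labs(x = "interval start", y = "mean asymptotic length (mm)",
                  colour = "omitted occasion") +
    ggplot2::theme_minimal()
}
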