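#' Leave-one-occasion-out jackknife of the environmental limitation
#'
#' Refits the model once per sampling occasion with that occasion's rows
#' removed, to show how strongly each survey year drives the estimated
#' environmental limitation and how robust the method is to missing years.
#' The lattice is kept unchanged — the omitted occasion's boundary cells
#' simply lose their data and its boundary parameters become weakly
#' identified — so the per-interval limitation estimates stay aligned across
#' refits and can be differenced against the full-data fit directly. Each
#' refit recomputes starting values on its reduced data and uses the same
#' optimizer settings as the full fit.
#'
#' @inheritParams vb_fit
#' @param occasions Occasions to omit (default: every occasion present).
#'   The data must retain at least two occasions with rows after an omission.
#' @param full_fit Optional precomputed full-data `vb_fit` with matching
#'   variant and settings; fitted here when `NULL`.
#' @return An object of class `vb_jackknife`: a list with `full_fit`,
#'   `fits` (one per omission) and `deltas`, a tibble with columns
#'   `omitted`, `interval`, `group`, `mu_linf_full`, `mu_linf_jack` and
#'   `delta` (jackknife minus full, mm).
#' @export
vb_jackknife <- function(observations, grid = NULL,
                         env = c("varying", "constant"), groups = NULL,
                         non_shrink = FALSE, l_inf = NULL,
                         control = vb_control(), occasions = NULL,
                         full_fit = NULL) {
  env <- match.arg(env)
  grid <- grid %||% vb_infer_grid(observations)
  obs <- vb_check_observations(observations, grid)
  present <- sort(unique(obs$time))
  if (length(present) < 3L) abort("Jackknife needs at least 3 occasions with data.")
  occasions <- occasions %||% present

  full_fit <- full_fit %||% vb_fit(obs, grid, env = env, groups = groups,
                                   non_shrink = non_shrink, l_inf = l_inf,
                                   control = control)
  fits <- vector("list", length(occasions))
  deltas <- vector("list", length(occasions))
  full_mu <- vb_env_tbl(full_fit$params, grid)

  for (i in seq_along(occasions)) {
    omit <- occasions[i]
    reduced <- obs[obs$time != omit, ]
    if (length(unique(reduced$time)) < 2L) {
      abort(sprintf("Omitting occasion %d leaves fewer than 2 occasions with data.", omit))
    }
    jfit <- suppressWarnings(
      vb_fit(reduced, grid, env = env, groups = groups,
             non_shrink = non_shrink, l_inf = l_inf, control = control)
    )
    fits[[i]] <- jfit
    jack_mu <- vb_env_tbl(jfit$params, grid)
    deltas[[i]] <- tibble::tibble(
      omitted = omit,
      interval = full_mu$interval,
      group = full_mu$group,
      mu_linf_full = full_mu$mu_linf,
      mu_linf_jack = jack_mu$mu_linf,
      delta = jack_mu$mu_linf - full_mu$mu_linf
    )
  }
  structure(
    list(full_fit = full_fit, fits = setNames(fits, occasions),
         deltas = dplyr::bind_rows(deltas)),
    class = "vb_jackknife"
  )
}

# long table of the per-interval mean-asymptotic-length estimates
vb_env_tbl <- function(params, grid) {
  n_int <- nrow(params$mu_linf)
  n_groups <- ncol(params$mu_linf)
  ints <- if (n_int == 1L) NA_integer_ else vb_intervals(grid)
  tibble::tibble(
    interval = rep(ints, times = n_groups),
    group = rep(seq_len(n_groups), each = n_int),
    mu_linf = as.vector(params$mu_linf)
  )
}

#' @export
print.vb_jackknife <- function(x, ...) {
  cat(sprintf("<vb_jackknife> %d omissions; max |delta mu_linf| = %.3f mm\n",
              length(x$fits), max(abs(x$deltas$delta))))
  invisible(x)
}

#' @export
tidy.vb_jackknife <- function(x, ...) x$deltas

#' Compare fitted model variants by AIC and likelihood-ratio tests
#'
#' @param ... `vb_fit` objects (optionally named), all fitted to the same
#'   observation table.
#' @param lrt If `TRUE` (default), a likelihood-ratio test is reported for
#'   every nested pair among the supplied fits — a constant-environment fit
#'   inside a varying-environment fit with the same groups and shrink
#'   setting.
#' @return A tibble with one row per fit: `variant`, `k`, `nll`, `aic`,
#'   `delta_aic` (against the best AIC), and for nested pairs `lrt_vs`,
#'   `lrt_stat`, `lrt_df`, `lrt_p`.
#' @export
vb_compare <- function(..., lrt = TRUE) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) && !inherits(fits[[1L]], "vb_fit")) {
    fits <- fits[[1L]]
  }
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "vb_fit")))
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, vb_variant_label, "")
    names(fits) <- make.unique(names(fits))
  }
  fps <- lapply(fits, `[[`, "data_fingerprint")
  if (length(fits) > 1L &&
      !all(vapply(fps[-1L], function(f) isTRUE(all.equal(f, fps[[1L]])), TRUE))) {
    abort("All fits must be on the same observation table.")
  }
  tbl <- tibble::tibble(
    variant = names(fits),
    env = unname(vapply(fits, `[[`, "", "env")),
    k = unname(vapply(fits, function(f) f$stats$k, 1L)),
    nll = unname(vapply(fits, function(f) f$stats$nll, 1)),
    aic = unname(vapply(fits, function(f) f$stats$aic, 1))
  )
  tbl$delta_aic <- tbl$aic - min(tbl$aic)
  tbl$lrt_vs <- NA_character_
  tbl$lrt_stat <- tbl$lrt_p <- NA_real_
  tbl$lrt_df <- NA_integer_
  if (lrt && length(fits) > 1L) {
    same_struct <- function(a, b) {
      identical(a$groups, b$groups) && identical(a$non_shrink, b$non_shrink)
    }
    for (i in seq_along(fits)) {
      for (j in seq_along(fits)) {
        if (fits[[i]]$env == "varying" && fits[[j]]$env == "constant" &&
            same_struct(fits[[i]], fits[[j]])) {
          test <- vb_lr_test(fits[[j]]$stats$nll, fits[[i]]$stats$nll,
                             df = fits[[i]]$stats$k - fits[[j]]$stats$k)
          tbl$lrt_vs[i] <- tbl$variant[j]
          tbl$lrt_stat[i] <- test$statistic
          tbl$lrt_df[i] <- test$df
          tbl$lrt_p[i] <- test$p_value
        }
      }
    }
  }
  dplyr::arrange(tbl, .data$aic)
}
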