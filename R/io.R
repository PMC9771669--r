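#' Read an observation table from delimited text
#'
#' Reads one-row-per-individual survey data: sampling occasion, integer age
#' class, body length in mm, and an optional non-negative sampling weight
#' (e.g. inverse catch per unit effort). Comma- or tab-delimited files are
#' auto-detected from the header line. Rows failing validation (non-positive
#' length, non-integer time or age, negative or non-finite weight) are
#' dropped with a message listing the reasons; pre-processing of raw survey
#' exports (e.g. trawl-survey exchange formats) into these columns is left
#' to the caller.
#'
#' @param path Path to a delimited text file with a header.
#' @param columns Named character vector mapping the required names to the
#'   file's column names, e.g.
#'   `c(time = "Year", age = "Age", length = "LngtClass", weight = "CPUE_inv")`.
#' @return A tibble with columns `time`, `age`, `length`, `weight` (1 when
#'   absent from the file), carrying attributes `grid` (the inferred
#'   [vb_grid()]) and `rejected` (tibble of dropped rows with a `reason`
#'   column).
#' @export
read_observations <- function(path, columns = NULL) {
  delim <- vb_sniff_delim(path)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(columns)) {
    for (std in names(columns)) {
      if (!columns[[std]] %in% names(raw)) {
        abort(sprintf("Mapped column `%s` not found in file.", columns[[std]]))
      }
      names(raw)[names(raw) == columns[[std]]] <- std
    }
  }
  need <- c("time", "age", "length")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(paste0("Input lacks required column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"weight" %in% names(raw)) raw$weight <- 1
  raw <- raw[, c("time", "age", "length", "weight")]

  reason <- rep(NA_character_, nrow(raw))
  bad_num <- !is.finite(raw$length) | raw$length <= 0
  reason[bad_num] <- "non-positive length"
  bad_int <- !is.finite(raw$time) | !is.finite(raw$age) |
    raw$time != round(raw$time) | raw$age != round(raw$age) | raw$age < 0
  reason[is.na(reason) & bad_int] <- "non-integer time/age"
  bad_w <- !is.finite(raw$weight) | raw$weight < 0
  reason[is.na(reason) & bad_w] <- "invalid weight"

  rejected <- raw[!is.na(reason), ]
  rejected$reason <- reason[!is.na(reason)]
  obs <- raw[is.na(reason), ]
  if (nrow(rejected)) {
    inform(sprintf("Dropped %d invalid row(s): %s.", nrow(rejected),
                   paste(unique(rejected$reason), collapse = "; ")))
  }
  if (nrow(obs) == 0L) abort("No valid observations remain after validation.")
  obs$time <- as.integer(obs$time)
  obs$age <- as.integer(obs$age)
  obs <- tibble::as_tibble(obs)
  attr(obs, "grid") <- vb_infer_grid(obs)
  attr(obs, "rejected") <- tibble::as_tibble(rejected)
  obs
}

vb_sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) >
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

# all floating point output uses 12 significant digits for reproducibility
vb_fmt <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.12g", x))
}

#' Write and re-read fitted parameters as CSV
#'
#' `vb_write_params()` serialises a [vb_params()] object (plus grid and
#' variant metadata) to a plain CSV with 12 significant digits;
#' `vb_read_params()` reconstructs it, so a lattice predicted from the
#' re-read parameters matches the original to near machine precision.
#'
#' @param params A [vb_params()].
#' @param path Output/input CSV path.
#' @return `vb_write_params()` returns `path` invisibly; `vb_read_params()`
#'   returns the `vb_params` object.
#' @export
vb_write_params <- function(params, path) {
  stopifnot(inherits(params, "vb_params"))
  g <- params$grid
  header <- tibble::tibble(
    term = "meta",
    time = NA_integer_, age = NA_integer_, interval = NA_integer_,
    group = NA_integer_,
    estimate = NA_real_,
    meta = sprintf(
      "t_min=%d;n_t=%d;a_min=%d;n_a=%d;env=%s;group_mode=%s;boundaries=%s",
      g$t_min, g$n_t, g$a_min, g$n_a, params$env,
      if (is.null(params$groups)) "none" else params$groups$mode,
      if (is.null(params$groups)) "" else
        paste(params$groups$boundaries, collapse = "|")
    )
  )
  body <- tidy(params)
  body$meta <- NA_character_
  out <- dplyr::bind_rows(header, body)
  out$estimate <- vb_fmt(out$estimate)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname vb_write_params
#' @export
vb_read_params <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- tbl$meta[tbl$term == "meta"][1L]
  kv <- strsplit(strsplit(meta, ";")[[1L]], "=")
  vals <- setNames(vapply(kv, function(x) if (length(x) > 1L) x[2L] else "", ""),
                   vapply(kv, `[[`, "", 1L))
  grid <- vb_grid(as.integer(vals[["t_min"]]), as.integer(vals[["n_t"]]),
                  as.integer(vals[["a_min"]]), as.integer(vals[["n_a"]]))
  groups <- if (vals[["group_mode"]] == "none") NULL else {
    vb_groups(vals[["group_mode"]],
              as.numeric(strsplit(vals[["boundaries"]], "\\|")[[1L]]))
  }
  env <- vals[["env"]]
  body <- tbl[tbl$term != "meta", ]
  grab <- function(term) as.numeric(body$estimate[body$term == term])
  n_groups <- if (is.null(groups)) 1L else groups$n_groups
  n_int <- if (env == "constant") 1L else grid$n_t - 1L
  vb_params(
    grid = grid,
    r_b = grab("r_b"),
    e_first_age = grab("e_first_age"),
    v_first_age = grab("v_first_age"),
    e_first_time = grab("e_first_time"),
    v_first_time = grab("v_first_time"),
    mu_linf = matrix(grab("mu_linf"), n_int, n_groups),
    sigma2_linf2 = matrix(grab("sigma2_linf2"), n_int, n_groups),
    env = env,
    groups = groups
  )
}

#' Write an observation table (and optional truth sidecar) as delimited text
#'
#' @param observations Observation tibble.
#' @param path Output CSV path. When the table carries a `truth` attribute
#'   (see [vb_generate_dataset()]), the generating parameters are written
#'   alongside as `<path>.truth.csv`.
#' @return `path`, invisibly.
#' @export
vb_write_observations <- function(observations, path) {
  out <- tibble::as_tibble(observations)
  out$length <- vb_fmt(out$length)
  out$weight <- vb_fmt(out$weight)
  readr::write_csv(out, path)
  truth <- attr(observations, "truth")
  if (!is.null(truth)) vb_write_params(truth, paste0(path, ".truth.csv"))
  invisible(path)
}

#' Serialise a fit to an output directory
#'
#' Writes the parameter CSV, the per-cell predicted lattice CSV, and a JSON
#' run summary (variant, statistics, convergence, optimizer settings).
#'
#' @param fit A `vb_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
vb_write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "vb_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vb_write_params(fit$params, file.path(dir, "parameters.csv"))
  pred <- predict(fit)
  pred$mean <- vb_fmt(pred$mean)
  pred$var <- vb_fmt(pred$var)
  readr::write_csv(pred, file.path(dir, "predictions.csv"))
  summary <- list(
    variant = vb_variant_label(fit),
    env = fit$env,
    non_shrink = fit$non_shrink,
    l_inf = fit$l_inf,
    stats = as.list(fit$stats),
    converged = fit$converged,
    n_eval = fit$n_eval,
    start_nll = fit$start_nll,
    optimizer = fit$control$optimizer,
    reltol = fit$control$reltol,
    grid = unclass(fit$grid)
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
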