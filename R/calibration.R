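#' Fit the liquid-gas linear correction from in-house standards
#'
#' Ordinary least squares of true (liquid) standard values on measured (gas
#' phase) means, per tracer. Applying the fitted affine map to the measured
#' standard means reproduces the true values within the residual standard
#' deviation.
#'
#' @param measured Data frame with one row per standard: columns
#'   `standard_id`, `d2H`, `d18O` (measured means).
#' @param truth Data frame with the same `standard_id`s and the calibrated
#'   true values, columns `d2H`, `d18O`.
#' @return An object of class `linear_correction`: per-tracer slope,
#'   intercept, R squared and residual SD.
#' @examples
#' meas <- data.frame(standard_id = c("a", "b", "c"),
#'                    d2H = c(-96.12, -60.40, -0.62) * 0.95 - 1,
#'                    d18O = c(-24.44, -17.98, -14.80) * 0.95 - 1)
#' tru <- data.frame(standard_id = c("a", "b", "c"),
#'                   d2H = c(-96.12, -60.40, -0.62),
#'                   d18O = c(-24.44, -17.98, -14.80))
#' fit_linear_correction(meas, tru)
#' @export
fit_linear_correction <- function(measured, truth) {
  stopifnot(is.data.frame(measured), is.data.frame(truth))
  m <- dplyr::inner_join(measured, truth, by = "standard_id",
                         suffix = c("_meas", "_true"))
  if (nrow(m) < 2) stop("need at least 2 standards", call. = FALSE)
  fits <- lapply(c("d2H", "d18O"), function(tr) {
    x <- m[[paste0(tr, "_meas")]]
    y <- m[[paste0(tr, "_true")]]
    if (max(x) - min(x) < 1e-12) {
      stop("degenerate standards: identical measured ", tr, " values", call. = FALSE)
    }
    f <- lm(y ~ x)
    s <- summary(f)
    list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
         r_squared = s$r.squared, residual_sd = s$sigma)
  })
  names(fits) <- c("d2H", "d18O")
  structure(list(tracers = fits, n_standards = nrow(m)),
            class = "linear_correction")
}

#' Apply a fitted linear correction to measured values
#'
#' @param data Data frame with columns `d2H` and/or `d18O`.
#' @param correction A `linear_correction` from [fit_linear_correction()].
#' @return `data` with the affine map applied to each tracer column.
#' @export
apply_correction <- function(data, correction) {
  stopifnot(inherits(correction, "linear_correction"))
  for (tr in intersect(c("d2H", "d18O"), names(data))) {
    co <- correction$tracers[[tr]]
    data[[tr]] <- co$intercept + co$slope * data[[tr]]
  }
  tibble::as_tibble(data)
}

#' @export
print.linear_correction <- function(x, ...) {
  cat("Liquid-gas linear correction (", x$n_standards, " standards)\n", sep = "")
  for (tr in names(x$tracers)) {
    co <- x$tracers[[tr]]
    cat(sprintf("  %-5s slope %.5f  intercept %.4f  R2 %.5f  resid SD %.4f\n",
                tr, co$slope, co$intercept, co$r_squared, co$residual_sd))
  }
  invisible(x)
}

#' @method tidy linear_correction
#' @export
tidy.linear_correction <- function(x, ...) {
  purrr::imap_dfr(x$tracers, function(co, tr) {
    tibble::tibble(tracer = tr, slope = co$slope, intercept = co$intercept,
                   r_squared = co$r_squared, residual_sd = co$residual_sd)
  })
}

#' Additive drift correction from repeated standard runs
#'
#' Standards measured at known times define per-tracer residuals
#' (measured - true); the residual is linearly interpolated in time and
#' subtracted from the raw readings. Readings outside the bracketing standard
#' runs are not silently corrected: they are returned as `NA` with the
#' `out_of_bracket` flag set.
#'
#' @param series Data frame of raw readings: `timestamp` (POSIXct or Date),
#'   `d2H`, `d18O`.
#' @param standard_runs Data frame of timestamped standard measurements:
#'   `timestamp`, `standard_id`, `d2H`, `d18O` (measured).
#' @param truth Data frame with `standard_id` and true `d2H`, `d18O`.
#' @return `series` with drift-corrected tracer columns and a logical
#'   `out_of_bracket` column.
#' @export
drift_correct <- function(series, standard_runs, truth) {
  runs <- dplyr::inner_join(standard_runs, truth, by = "standard_id",
                            suffix = c("_meas", "_true"))
  if (nrow(runs) < 2) stop("need at least 2 bracketing standard runs", call. = FALSE)
  t_runs <- as.numeric(runs$timestamp)
  t_ser <- as.numeric(series$timestamp)
  out <- tibble::as_tibble(series)
  out$out_of_bracket <- t_ser < min(t_runs) | t_ser > max(t_runs)
  if (any(out$out_of_bracket)) {
    warning(sum(out$out_of_bracket),
            " reading(s) outside the bracketing standard runs set to NA", call. = FALSE)
  }
  for (tr in intersect(c("d2H", "d18O"), names(series))) {
    resid <- runs[[paste0(tr, "_meas")]] - runs[[paste0(tr, "_true")]]
    drift <- approx(t_runs, resid, xout = t_ser, method = "linear", rule = 1,
                    ties = mean)$y
    out[[tr]] <- series[[tr]] - drift
    out[[tr]][out$out_of_bracket] <- NA_real_
  }
  out
}

#' Read a standards file
#'
#' CSV with columns `standard_id`, `true_d2H`, `true_d18O`, `timestamp`,
#' `meas_d2H`, `meas_d18O`.
#'
#' @param path Path to the CSV.
#' @return A list with `truth` (one row per standard) and `runs`
#'   (timestamped measurements), both tibbles.
#' @export
read_standards <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    standard_id = readr::col_character(),
    timestamp = readr::col_datetime(format = ""),
    .default = readr::col_double()), progress = FALSE)
  truth <- raw |>
    dplyr::distinct(.data$standard_id, .data$true_d2H, .data$true_d18O) |>
    dplyr::rename(d2H = "true_d2H", d18O = "true_d18O")
  runs <- raw |>
    dplyr::select("standard_id", "timestamp", d2H = "meas_d2H", d18O = "meas_d18O")
  list(truth = truth, runs = runs)
}

#' Full raw-to-liquid calibration of an analyser series
#'
#' Convenience wrapper applying, in order, the additive drift correction from
#' repeated standard runs and then the liquid-gas affine map fitted on the
#' drift-corrected standard means. An optional water-concentration correction
#' hook (an affine function of measured H2O ppm) is applied first; the default
#' is the identity.
#'
#' @param series Raw readings (`timestamp`, `d2H`, `d18O`, optional `h2o_ppm`).
#' @param standards List as returned by [read_standards()].
#' @param h2o_correction Optional function `(value, h2o_ppm, tracer) -> value`.
#' @return Calibrated tibble with `out_of_bracket` flags.
#' @export
calibrate_series <- function(series, standards, h2o_correction = NULL) {
  out <- tibble::as_tibble(series)
  if (!is.null(h2o_correction) && "h2o_ppm" %in% names(out)) {
    for (tr in intersect(c("d2H", "d18O"), names(out))) {
      out[[tr]] <- h2o_correction(out[[tr]], out$h2o_ppm, tr)
    }
  }
  drifted <- drift_correct(out, standards$runs, standards$truth)
  # standard means after drift correction define the liquid-gas map
  runs_corr <- drift_correct(standards$runs, standards$runs, standards$truth)
  means <- runs_corr |>
    dplyr::group_by(.data$standard_id) |>
    dplyr::summarise(d2H = mean(.data$d2H, na.rm = TRUE),
                     d18O = mean(.data$d18O, na.rm = TRUE), .groups = "drop")
  corr <- fit_linear_correction(means, standards$truth)
  apply_correction(drifted, corr)
}
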