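#' Read a table of calibrated isotope observations
#'
#' Reads a long-format CSV of water stable-isotope observations (one row per
#' sample) and validates it row by row. Columns are `date` (ISO-8601), `id`
#' (tree or profile identifier), `depth` (m, soil pools only), `d2H`, `d18O`
#' (per mil vs VSMOW) and optionally `sd2H`, `sd18O` (per mil). Missing
#' analytical standard deviations are filled with the in-situ probe accuracy
#' defaults of 2 permil for d2H and 1 permil for d18O.
#'
#' @param path Path to a CSV file.
#' @param pool_kind One of `"xylem"` or `"soil"`. Soil tables must carry a
#'   `depth` column whose values belong to `depths`.
#' @param depths Admissible soil measurement depths in metres; strictly
#'   positive and strictly increasing.
#' @param default_sd Named numeric vector with elements `d2H` and `d18O`, the
#'   analytical standard deviations used when the file does not state them.
#' @return A tibble with columns `date`, `id`, `depth` (soil only), `d2H`,
#'   `d18O`, `sd2H`, `sd18O` and `pool`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("date,id,depth,d2H,d18O,sd2H,sd18O",
#'              "2022-06-10,T1,,-58.0,-8.1,,"), f)
#' read_isotope_table(f, "xylem")
#' @export
read_isotope_table <- function(path, pool_kind = c("xylem", "soil"),
                               depths = c(0.05, 0.20, 0.40, 0.90),
                               default_sd = c(d2H = 2.0, d18O = 1.0)) {
  pool_kind <- match.arg(pool_kind)
  check_depth_grid(depths)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    warning("empty isotope table: ", path, call. = FALSE)
    return(tibble::tibble(date = as.Date(character()), id = character(),
                          depth = numeric(), d2H = numeric(), d18O = numeric(),
                          sd2H = numeric(), sd18O = numeric(), pool = character()))
  }
  need <- c("date", "id", "d2H", "d18O")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("isotope table is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  date <- parse_iso_date(raw$date)
  d2H <- suppressWarnings(as.numeric(raw$d2H))
  d18O <- suppressWarnings(as.numeric(raw$d18O))
  sd2H <- parse_optional_numeric(raw, "sd2H", default_sd[["d2H"]])
  sd18O <- parse_optional_numeric(raw, "sd18O", default_sd[["d18O"]])
  depth <- if (pool_kind == "soil") {
    suppressWarnings(as.numeric(raw$depth %||% rep(NA_character_, nrow(raw))))
  } else {
    rep(NA_real_, nrow(raw))
  }

  bad <- is.na(date) | !is.finite(d2H) | !is.finite(d18O) |
    !is.finite(sd2H) | sd2H < 0 | !is.finite(sd18O) | sd18O < 0
  if (pool_kind == "soil") {
    bad <- bad | is.na(depth) | !depth_in_grid(depth, depths)
  }
  if (any(bad)) {
    stop("invalid rows in ", path, " (row numbers exclude the header): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(date = date, id = as.character(raw$id),
                        depth = depth, d2H = d2H, d18O = d18O,
                        sd2H = sd2H, sd18O = sd18O, pool = pool_kind)
  if (pool_kind == "xylem") out$depth <- NULL
  out
}

#' Read a table of precipitation events
#'
#' Columns: `event_id`, `start_date`, `end_date` (ISO), `amount_mm`,
#' `d2H`, `d18O`, and optionally `label` (logical; deuterium-labelled
#' irrigation pulses). The age of a multi-day event is always counted from its
#' first day.
#'
#' @param path Path to a CSV file.
#' @param default_sd Analytical sds attached to event source signatures.
#' @return A tibble of events ordered by `start_date`.
#' @export
read_precip_events <- function(path, default_sd = c(d2H = 2.0, d18O = 1.0)) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    warning("empty precipitation event table: ", path, call. = FALSE)
    return(tibble::tibble(event_id = character(), start_date = as.Date(character()),
                          end_date = as.Date(character()), amount_mm = numeric(),
                          d2H = numeric(), d18O = numeric(), sd2H = numeric(),
                          sd18O = numeric(), label = logical()))
  }
  need <- c("event_id", "start_date", "end_date", "amount_mm", "d2H", "d18O")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("event table is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    event_id = as.character(raw$event_id),
    start_date = parse_iso_date(raw$start_date),
    end_date = parse_iso_date(raw$end_date),
    amount_mm = suppressWarnings(as.numeric(raw$amount_mm)),
    d2H = suppressWarnings(as.numeric(raw$d2H)),
    d18O = suppressWarnings(as.numeric(raw$d18O)),
    sd2H = parse_optional_numeric(raw, "sd2H", default_sd[["d2H"]]),
    sd18O = parse_optional_numeric(raw, "sd18O", default_sd[["d18O"]]),
    label = tolower(raw$label %||% rep("false", nrow(raw))) %in% c("true", "t", "1", "yes")
  )
  bad <- is.na(out$start_date) | is.na(out$end_date) | !is.finite(out$amount_mm) |
    out$amount_mm < 0 | !is.finite(out$d2H) | !is.finite(out$d18O) |
    out$end_date < out$start_date
  if (any(bad)) {
    stop("invalid rows in ", path, " (row numbers exclude the header): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  dplyr::arrange(out, .data$start_date)
}

#' Read a daily environmental table
#'
#' Columns: `date`, `precip_mm`, `vpd_kpa`, `ppfd`, and one `vwc_<depth>`
#' column per soil depth (volumetric water content, percent).
#'
#' @param path Path to a CSV file.
#' @return A tibble with a `date` column and numeric environmental columns.
#' @export
read_env_table <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    date = readr::col_date(), .default = readr::col_double()), progress = FALSE)
  vwc_cols <- grep("^vwc_", names(out), value = TRUE)
  for (cc in vwc_cols) {
    v <- out[[cc]]
    if (any(v < 0 | v > 100, na.rm = TRUE)) {
      stop("vwc outside [0, 100] in column ", cc, call. = FALSE)
    }
  }
  for (cc in intersect(c("precip_mm", "vpd_kpa", "ppfd"), names(out))) {
    if (any(out[[cc]] < 0, na.rm = TRUE)) stop("negative values in ", cc, call. = FALSE)
  }
  tibble::as_tibble(out)
}

#' Write an isotope table to CSV
#'
#' Values round-trip through [read_isotope_table()] to at least six decimals.
#'
#' @param data Tibble as returned by [read_isotope_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isotope_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Align isotope series to a daily grid with conservative gap-filling
#'
#' Sub-daily observations are averaged to daily means per replicate (tree or
#' soil profile), replicates are then averaged per pool (the per-replicate mode
#' is kept behind `aggregate = "none"`), and interior gaps of at most
#' `max_gap_days` days are filled by linear interpolation, independently for
#' each tracer. Longer gaps stay missing and are flagged; the series is never
#' extrapolated beyond its first or last observation.
#'
#' @param samples Tibble from [read_isotope_table()] (columns `date`, `id`,
#'   optional `depth`, `d2H`, `d18O`, `sd2H`, `sd18O`, `pool`).
#' @param max_gap_days Longest interior gap (days) that is interpolated.
#' @param aggregate `"mean"` (default) averages replicates per pool before
#'   interpolation; `"none"` aligns each replicate separately.
#' @return A tibble with one row per pool and calendar day: columns `pool`,
#'   `depth` (soil), `id` (`"mean"` under the default aggregation), `date`,
#'   `d2H`, `d18O`, `sd2H`, `sd18O`, `interpolated` (logical), `gap` (logical,
#'   TRUE where a too-long gap was left missing).
#' @export
align_daily <- function(samples, max_gap_days = 7,
                        aggregate = c("mean", "none")) {
  aggregate <- match.arg(aggregate)
  if (nrow(samples) == 0) return(samples)
  has_depth <- "depth" %in% names(samples)
  key_cols <- c("pool", if (has_depth) "depth", "id")

  daily <- samples |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(key_cols, "date")))) |>
    dplyr::summarise(d2H = mean(.data$d2H), d18O = mean(.data$d18O),
                     sd2H = mean(.data$sd2H), sd18O = mean(.data$sd18O),
                     .groups = "drop")

  if (aggregate == "mean") {
    key_cols <- c("pool", if (has_depth) "depth")
    daily <- daily |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(key_cols, "date")))) |>
      dplyr::summarise(d2H = mean(.data$d2H), d18O = mean(.data$d18O),
                       sd2H = mean(.data$sd2H), sd18O = mean(.data$sd18O),
                       .groups = "drop") |>
      dplyr::mutate(id = "mean")
  }

  groups <- dplyr::group_split(dplyr::group_by(
    daily, dplyr::across(dplyr::all_of(c(key_cols, "id")))))
  out <- purrr::map(groups, function(g) {
    if (nrow(g) < 2) {
      warning("pool with fewer than 2 observations skipped: ",
              paste(unlist(g[1, c(key_cols, "id")]), collapse = "/"), call. = FALSE)
      return(NULL)
    }
    grid <- tibble::tibble(date = seq(min(g$date), max(g$date), by = "day"))
    full <- dplyr::left_join(grid, g, by = "date")
    observed <- !is.na(full$d2H) | !is.na(full$d18O)
    for (tr in c("d2H", "d18O", "sd2H", "sd18O")) {
      full[[tr]] <- interp_max_gap(full$date, full[[tr]], max_gap_days)
    }
    for (kc in c(key_cols, "id")) full[[kc]] <- g[[kc]][1]
    full$interpolated <- !observed & !is.na(full$d2H)
    full$gap <- !observed & is.na(full$d2H)
    full
  })
  dplyr::bind_rows(out) |>
    dplyr::relocate(dplyr::all_of(c(key_cols, "id", "date")))
}

# Linear interpolation of interior gaps no longer than max_gap days;
# no extrapolation outside the observed span.
interp_max_gap <- function(dates, values, max_gap) {
  obs <- which(!is.na(values))
  if (length(obs) < 2) return(values)
  t <- as.numeric(dates)
  filled <- approx(t[obs], values[obs], xout = t, method = "linear",
                   rule = 1)$y
  # re-open gaps that exceed the cap
  runs <- rle(is.na(values))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (i in seq_along(runs$lengths)) {
    if (runs$values[i] && runs$lengths[i] > max_gap) {
      filled[starts[i]:ends[i]] <- NA_real_
    }
  }
  filled[is.na(values) & (t < min(t[obs]) | t > max(t[obs]))] <- NA_real_
  filled
}

parse_iso_date <- function(x) as.Date(x, format = "%Y-%m-%d", optional = TRUE)

parse_optional_numeric <- function(raw, col, default) {
  if (!col %in% names(raw)) return(rep(default, nrow(raw)))
  v <- suppressWarnings(as.numeric(raw[[col]]))
  v[is.na(raw[[col]]) | raw[[col]] == ""] <- default
  v
}

check_depth_grid <- function(depths) {
  if (length(depths) < 1 || any(depths <= 0) || is.unsorted(depths, strictly = TRUE)) {
    stop("depths must be strictly positive and strictly increasing", call. = FALSE)
  }
  invisible(depths)
}

depth_in_grid <- function(depth, depths, tol = 1e-6) {
  vapply(depth, function(d) any(abs(d - depths) < tol), logical(1))
}
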