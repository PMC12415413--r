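#' Contribution-weighted mean root-water-uptake depth
#'
#' The mean uptake depth is the contribution-weighted mean of the measurement
#' depths, `sum_j p_j * depth_j`. Contributions must lie on the simplex;
#' vectors whose sum is within `tol` of 1 are renormalised, anything further
#' off is an error.
#'
#' @param contributions Either a numeric vector of source contributions, or a
#'   data frame with columns `depth` and `mean` (e.g. a depth-model
#'   [mixture_series()]), in which case one mean depth per `day` (and
#'   `tree_id`, if present) is returned.
#' @param depths Measurement depths (m), matched positionally to a numeric
#'   `contributions` vector.
#' @param tol Allowed deviation of `sum(contributions)` from 1 (default 0.02).
#' @return A single depth (m), or a tibble with a `mean_depth_m` column.
#' @examples
#' mean_rwu_depth(c(0.11, 0.23, 0.60, 0.07) / 1.01, c(0.05, 0.20, 0.40, 0.90))
#' @export
mean_rwu_depth <- function(contributions, depths = c(0.05, 0.20, 0.40, 0.90),
                           tol = 0.02) {
  if (is.data.frame(contributions)) {
    keys <- intersect(c("tree_id", "day"), names(contributions))
    out <- contributions |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(mean_depth_m = mean_rwu_depth(.data$mean, .data$depth,
                                                     tol = tol),
                       .groups = "drop")
    return(out)
  }
  p <- as.numeric(contributions)
  if (length(p) != length(depths)) {
    stop("contributions and depths differ in length", call. = FALSE)
  }
  s <- sum(p)
  if (any(p < -1e-9) || abs(s - 1) > tol) {
    stop("contributions are off the simplex beyond tolerance (sum = ",
         signif(s, 4), ")", call. = FALSE)
  }
  sum(p / s * depths)
}

#' Absolute source-water uptake
#'
#' Multiplies relative source contributions by whole-tree sap flow, giving
#' litres per day taken from each source. By construction the sum over
#' sources equals the whole-tree sap flow on every day.
#'
#' @param contributions Contribution tibble (`day`, `source_id`, `mean`,
#'   optional `tree_id`); contributions are renormalised per day.
#' @param sapflow Tibble with `date`, `sapflow_l_d` (and `tree_id` when
#'   `contributions` has one).
#' @return The contribution tibble with an `uptake_l_d` column.
#' @export
absolute_uptake <- function(contributions, sapflow) {
  if (any(sapflow$sapflow_l_d < 0, na.rm = TRUE)) {
    stop("negative sap flow", call. = FALSE)
  }
  keys <- intersect(c("tree_id", "day"), names(contributions))
  by <- c(day = "date")
  if ("tree_id" %in% keys && "tree_id" %in% names(sapflow)) {
    by <- c(by, "tree_id")
  }
  contributions |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(mean = .data$mean / sum(.data$mean)) |>
    dplyr::ungroup() |>
    dplyr::inner_join(sapflow, by = by) |>
    dplyr::mutate(uptake_l_d = .data$mean * .data$sapflow_l_d)
}

#' Water-age distribution of root water uptake on a day
#'
#' Converts per-event contributions on a focal day into a distribution over
#' water ages (days since each event's first day) and its cumulative curve on
#' an integer-day grid.
#'
#' @param event_contributions Tibble for one day: `source_id`, `mean`
#'   (fractions summing to 1 within `tol`), and either a `first_day` column
#'   or an `events` table to look first days up in.
#' @param day Focal date.
#' @param events Optional event table with `event_id`, `start_date`.
#' @param tol Allowed deviation of the fraction sum from 1 (default 0.02).
#' @return A tibble of class `age_distribution`: `age_days`, `fraction`,
#'   `cum_fraction`, one row per distinct age, increasing in age.
#' @export
age_distribution <- function(event_contributions, day, events = NULL,
                             tol = 0.02) {
  day <- as.Date(day)
  ec <- event_contributions
  if (!"first_day" %in% names(ec)) {
    if (is.null(events)) stop("need first_day column or an events table", call. = FALSE)
    ec <- dplyr::left_join(ec, dplyr::select(events, source_id = "event_id",
                                             first_day = "start_date"),
                           by = "source_id")
  }
  if (abs(sum(ec$mean) - 1) > tol) {
    stop("event fractions sum to ", signif(sum(ec$mean), 4), call. = FALSE)
  }
  ec$age_days <- as.numeric(day - as.Date(ec$first_day))
  if (any(ec$age_days < 0)) {
    stop("event dated after the focal day (causality violated)", call. = FALSE)
  }
  out <- ec |>
    dplyr::mutate(fraction = .data$mean / sum(.data$mean)) |>
    dplyr::group_by(age_days = as.integer(round(.data$age_days))) |>
    dplyr::summarise(fraction = sum(.data$fraction), .groups = "drop") |>
    dplyr::arrange(.data$age_days) |>
    dplyr::mutate(cum_fraction = cumsum(.data$fraction))
  attr(out, "day") <- day
  class(out) <- c("age_distribution", class(out))
  out
}

#' Evaluate a cumulative age curve on an integer-day grid
#'
#' @param dist An [age_distribution()].
#' @param ages Integer grid; default `0:max(age)`.
#' @return Tibble `age_days`, `cum_fraction` (a nondecreasing step function
#'   ending at 1).
#' @export
cumulative_age_curve <- function(dist, ages = NULL) {
  if (is.null(ages)) ages <- 0:max(dist$age_days)
  cf <- vapply(ages, function(a) sum(dist$fraction[dist$age_days <= a]),
               numeric(1))
  tibble::tibble(age_days = ages, cum_fraction = cf)
}

#' Transit time of a precipitation event in xylem water
#'
#' The time during which an event contributes at least `threshold` to root
#' water uptake. Under the default `"span"` rule this is the inclusive span
#' from the first to the last day at or above the threshold (re-emergence
#' counts); `"total"` counts qualifying days only. An event that never
#' reaches the threshold has transit time 0.
#'
#' @param contributions Daily contribution fractions for one event, ordered
#'   in time starting at the event's first day; or a data frame with columns
#'   `day` and `mean` (sorted by day internally).
#' @param threshold Contribution threshold (default 0.10).
#' @param rule `"span"` (default) or `"total"`.
#' @return Transit time in days (integer-valued numeric).
#' @examples
#' transit_time(c(0.2, 0.15, 0.05, 0.12, 0.08))  # 4
#' @export
transit_time <- function(contributions, threshold = 0.10,
                         rule = c("span", "total")) {
  rule <- match.arg(rule)
  if (is.data.frame(contributions)) {
    contributions <- contributions[order(contributions$day), ]$mean
  }
  hit <- which(!is.na(contributions) & contributions >= threshold)
  if (length(hit) == 0) return(0)
  if (rule == "span") max(hit) - min(hit) + 1 else length(hit)
}

#' Fit the asymptotic precipitation-uptake curve
#'
#' Fits `y(t) = a - (a - b) * exp(-c t)` to the cumulative fraction of an
#' event's water taken up by day `t` since the event: `a` is the maximum
#' fraction the tree can use, `b` the fraction used on day 0 and `c` the
#' uptake rate constant (day^-1). The fit is constrained nonlinear least
#' squares (`a` in [0, 1], `b` in [0, a] via `b = a q`, `c >= 0`) with a
#' deterministic grid-search fallback when the optimiser fails; fallback
#' results carry `converged = FALSE`.
#'
#' @param data Data frame with columns `t` (days since the event, >= 0) and
#'   `uptake` (cumulative fraction in [0, 1]); or two vectors via `t`.
#' @param t Optional time vector when `data` is a numeric uptake vector.
#' @return Object of class `uptake_curve` with elements `coef` (a, b, c),
#'   `vcov` (delta-method covariance of (a, b, c)), `fitted`, `residual_sd`,
#'   `converged`, `diagnostics`.
#' @export
fit_uptake_curve <- function(data, t = NULL) {
  if (is.data.frame(data)) {
    tt <- data$t; y <- data$uptake
  } else {
    y <- as.numeric(data); tt <- t
  }
  keep <- is.finite(tt) & is.finite(y)
  tt <- tt[keep]; y <- y[keep]
  if (length(y) < 4) stop("need at least 4 time points", call. = FALSE)
  if (any(y < -1e-6 | y > 1 + 1e-6)) stop("uptake must lie in [0, 1]", call. = FALSE)
  y <- pmin(pmax(y, 0), 1)

  model <- function(a, q, c) a - (a - a * q) * exp(-c * tt)
  sse <- function(par) sum((y - model(par[1], par[2], par[3]))^2)

  # flat-series degeneracy: a = b = level, c unidentified
  if (max(y) - min(y) < 1e-10) {
    level <- mean(y)
    co <- c(a = level, b = level, c = 0)
    return(new_uptake_curve(co, matrix(NA_real_, 3, 3,
                                       dimnames = list(names(co), names(co))),
                            fitted = rep(level, length(y)), y = y, t = tt,
                            converged = FALSE,
                            note = "constant series: c unidentified"))
  }

  starts <- expand.grid(a = unique(pmin(pmax(c(max(y), max(y) * 1.2, 0.9), 0.05), 1)),
                        q = c(0.05, 0.3, 0.7),
                        c = c(0.05, 0.2, 0.5, 1.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a - (a - a * q) * exp(-c * tt),
                        start = as.list(starts[i, ]),
                        lower = c(a = 1e-8, q = 0, c = 0),
                        upper = c(a = 1, q = 1, c = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      if (is.null(best) || sum(resid(fit)^2) < sum(resid(best)^2)) best <- fit
    }
  }

  if (is.null(best)) {
    # deterministic coarse grid fallback
    grd <- expand.grid(a = seq(0.02, 1, by = 0.02), q = seq(0, 1, by = 0.05),
                       c = c(seq(0.02, 2, by = 0.04), seq(2.2, 8, by = 0.4)))
    ss <- apply(grd, 1, sse)
    p <- as.numeric(grd[which.min(ss), ])
    co <- c(a = p[1], b = p[1] * p[2], c = p[3])
    return(new_uptake_curve(co, matrix(NA_real_, 3, 3,
                                       dimnames = list(names(co), names(co))),
                            fitted = model(p[1], p[2], p[3]), y = y, t = tt,
                            converged = FALSE, note = "grid-search fallback"))
  }

  est <- coef(best)
  co <- c(a = unname(est["a"]), b = unname(est["a"] * est["q"]),
          c = unname(est["c"]))
  V_aqc <- tryCatch(vcov(best), error = function(e) matrix(NA_real_, 3, 3))
  # delta method to (a, b, c): b = a q
  Jm <- rbind(a = c(1, 0, 0), b = c(est["q"], est["a"], 0), c = c(0, 0, 1))
  V <- Jm %*% V_aqc %*% t(Jm)
  dimnames(V) <- list(c("a", "b", "c"), c("a", "b", "c"))
  new_uptake_curve(co, V, fitted = fitted(best), y = y, t = tt,
                  converged = TRUE)
}

new_uptake_curve <- function(co, V, fitted, y, t, converged, note = NULL) {
  r <- y - fitted
  n <- length(y)
  rsd <- sqrt(sum(r^2) / max(n - 3, 1))
  rs <- if (rsd > 0) r / rsd else r
  ks <- if (rsd > 0 && n >= 5) {
    suppressWarnings(ks.test(rs, "pnorm")$p.value)
  } else NA_real_
  diagnostics <- tibble::tibble(
    residual_sd = rsd,
    dispersion = if (rsd > 0) var(rs) else NA_real_,
    n_outliers = sum(abs(rs) > 2.5),
    ks_p = ks)
  structure(list(coef = co, vcov = V, fitted = fitted, observed = y, t = t,
                 residual_sd = rsd, converged = converged, note = note,
                 diagnostics = diagnostics),
            class = "uptake_curve")
}

#' @export
print.uptake_curve <- function(x, ...) {
  cat("Asymptotic uptake curve y = a - (a - b) exp(-c t)\n")
  cat(sprintf("  a = %.4f  b = %.4f  c = %.4f /day  (resid SD %.4f)%s\n",
              x$coef["a"], x$coef["b"], x$coef["c"], x$residual_sd,
              if (x$converged) "" else "  ** not converged"))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @rdname fit_uptake_curve
#' @param x An `uptake_curve`.
#' @param conf_level Confidence level for Wald intervals.
#' @param ... Unused.
#' @method tidy uptake_curve
#' @export
tidy.uptake_curve <- function(x, conf_level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  zc <- qt(1 - (1 - conf_level) / 2, df = max(length(x$observed) - 3, 1))
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                 std_error = unname(se),
                 conf_low = unname(x$coef - zc * se),
                 conf_high = unname(x$coef + zc * se))
}

#' @rdname fit_uptake_curve
#' @method glance uptake_curve
#' @export
glance.uptake_curve <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(converged = x$converged,
                                  n = length(x$observed)), x$diagnostics)
}

#' Compare the uptake rate constant between two fitted curves
#'
#' Wald test of equal rate constants `c` between two [fit_uptake_curve()]
#' fits (e.g. two drought periods).
#'
#' @param curve1,curve2 `uptake_curve` objects.
#' @return Tibble with the difference, its SE, z statistic and p value.
#' @export
compare_uptake_rate <- function(curve1, curve2) {
  d <- curve1$coef["c"] - curve2$coef["c"]
  se <- sqrt(curve1$vcov["c", "c"] + curve2$vcov["c", "c"])
  z <- d / se
  tibble::tibble(delta_c = unname(d), se = unname(se), statistic = unname(z),
                 p_value = unname(2 * stats::pnorm(-abs(z))))
}

#' Regression of maximum event use on event size
#'
#' Least-squares fit of the asymptotic maximum `a` on precipitation amount,
#' per period; periods with fewer than 3 events are skipped.
#'
#' @param curves Tibble with one row per event: `a`, `amount_mm` and
#'   optionally `period`.
#' @param conf_level Confidence level.
#' @return Tibble per period: `slope`, `se`, `conf_low`, `conf_high`,
#'   `p_value`, `n_events`.
#' @export
max_use_vs_amount <- function(curves, conf_level = 0.95) {
  if (!"period" %in% names(curves)) curves$period <- "all"
  curves |>
    dplyr::group_by(.data$period) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 3) {
        warning("period ", key$period, " skipped: fewer than 3 events",
                call. = FALSE)
        return(tibble::tibble())
      }
      f <- lm(a ~ amount_mm, data = g)
      s <- summary(f)$coefficients
      ci <- stats::confint(f, "amount_mm", level = conf_level)
      tibble::tibble(slope = s["amount_mm", 1], se = s["amount_mm", 2],
                     conf_low = ci[1], conf_high = ci[2],
                     p_value = s["amount_mm", 4], n_events = nrow(g))
    }) |>
    dplyr::ungroup()
}

#' Segment a campaign into hydrological periods
#'
#' Rule-based segmentation of the study span into ordered wet, dry-down,
#' dry, (optional post-label,) recovery and final-wet periods from daily mean
#' shallow-soil water content and precipitation:
#' * wet: from the start while VWC stays at or above `wet_vwc` and inter-event
#'   gaps stay short;
#' * dry-down: VWC persistently below `wet_vwc`, declining;
#' * dry: VWC below `dry_vwc` with infrequent events;
#' * recovery: from the first event larger than `recovery_event_mm` after
#'   which VWC rises by at least `rise_min` within `rise_window` days;
#' * final wet: VWC re-stabilised at or above `final_vwc` (7-day mean).
#'
#' @param env Daily tibble: `date`, `precip_mm` and either `vwc` or
#'   `vwc_<depth>` columns (the mean over depths <= 0.40 m is used).
#' @param wet_vwc,dry_vwc,final_vwc VWC thresholds in percent (defaults 15,
#'   13, 16; the dry threshold follows the observed drought definition of
#'   VWC below 13%).
#' @param recovery_event_mm Event size (mm) that can trigger recovery
#'   (default 10).
#' @param rise_min,rise_window Required VWC rise (percentage points) within a
#'   window (days) after the trigger event.
#' @param persist Days a threshold crossing must persist (default 5).
#' @param label_date Optional date splitting the dry period into `dry` and
#'   `post_label`.
#' @return Tibble of class `period_segmentation`: `period`, `start`, `end`,
#'   `rule`; the intervals partition the covered span in order. Spans too
#'   short to contain all periods give a partial segmentation with a warning.
#' @export
segment_periods <- function(env, wet_vwc = 15, dry_vwc = 13, final_vwc = 16,
                            recovery_event_mm = 10, rise_min = 2,
                            rise_window = 14, persist = 5,
                            label_date = NULL) {
  env <- dplyr::arrange(env, .data$date)
  vwc <- if ("vwc" %in% names(env)) env$vwc else {
    cols <- grep("^vwc_", names(env), value = TRUE)
    depths <- as.numeric(sub("vwc_", "", cols))
    shallow <- cols[depths <= 0.40]
    rowMeans(as.matrix(env[, shallow, drop = FALSE]), na.rm = TRUE)
  }
  precip <- env$precip_mm
  dates <- env$date
  n <- length(dates)

  below_persist <- function(i, thr) {
    idx <- i:min(i + persist - 1, n)
    all(vwc[idx] < thr, na.rm = TRUE)
  }
  first_below <- function(thr, from = 1) {
    for (i in from:n) if (!is.na(vwc[i]) && vwc[i] < thr && below_persist(i, thr)) return(i)
    NA_integer_
  }

  bounds <- list()
  t1 <- first_below(wet_vwc)           # end of wet
  t2 <- if (!is.na(t1)) first_below(dry_vwc, from = t1) else NA_integer_
  t3 <- NA_integer_                    # recovery onset
  if (!is.na(t2)) {
    cand <- which(precip > recovery_event_mm & seq_len(n) >= t2)
    for (i in cand) {
      upto <- min(i + rise_window, n)
      if (max(vwc[i:upto], na.rm = TRUE) - vwc[i] >= rise_min) { t3 <- i; break }
    }
  }
  t4 <- NA_integer_                    # final wet onset
  if (!is.na(t3)) {
    roll <- zoo::rollmean(vwc, k = min(7, n), fill = NA, align = "right")
    for (i in (t3 + 1):n) {
      if (!is.na(roll[i]) && roll[i] >= final_vwc) { t4 <- i; break }
    }
  }

  add <- function(period, i0, i1, rule) {
    if (is.na(i0) || is.na(i1) || i1 < i0) return()
    bounds[[length(bounds) + 1]] <<- tibble::tibble(
      period = period, start = dates[i0], end = dates[i1], rule = rule)
  }
  end1 <- if (!is.na(t1)) t1 - 1 else n
  add("wet", 1, end1, sprintf("VWC >= %.1f%% with frequent events", wet_vwc))
  if (!is.na(t1)) {
    end2 <- if (!is.na(t2)) t2 - 1 else n
    add("dry_down", t1, end2, sprintf("VWC declining below %.1f%%", wet_vwc))
  }
  if (!is.na(t2)) {
    end3 <- if (!is.na(t3)) t3 - 1 else n
    li <- if (!is.null(label_date)) which(dates == as.Date(label_date)) else integer(0)
    if (length(li) == 1 && li > t2 && li <= end3) {
      add("dry", t2, li - 1, sprintf("VWC < %.1f%%, events infrequent", dry_vwc))
      add("post_label", li, end3, "after the labelling pulse, still dry")
    } else {
      add("dry", t2, end3, sprintf("VWC < %.1f%%, events infrequent", dry_vwc))
    }
  }
  if (!is.na(t3)) {
    end4 <- if (!is.na(t4)) t4 - 1 else n
    add("recovery", t3, end4,
        sprintf("event > %.0f mm followed by VWC rise >= %.1f", recovery_event_mm, rise_min))
  }
  if (!is.na(t4)) {
    add("final_wet", t4, n, sprintf("7-day mean VWC >= %.1f%%", final_vwc))
  }
  out <- dplyr::bind_rows(bounds)
  expected <- c("wet", "dry_down", "dry", "recovery", "final_wet")
  if (!all(expected %in% out$period)) {
    warning("partial segmentation: missing period(s) ",
            paste(setdiff(expected, out$period), collapse = ", "), call. = FALSE)
  }
  class(out) <- c("period_segmentation", class(out))
  out
}

#' Summarise derived quantities per posterior draw
#'
#' Propagates posterior uncertainty into a derived statistic by evaluating it
#' on every posterior draw of a [fit_mixture()] result and summarising.
#'
#' @param fit A `mixture_fit`.
#' @param statistic Function mapping one contribution vector to a scalar
#'   (e.g. `function(p) sum(p * depths)`).
#' @return Tibble with `mean`, `sd`, `q2.5`, `q97.5` of the statistic.
#' @export
posterior_statistic <- function(fit, statistic) {
  vals <- apply(fit$draws, 1, statistic)
  tibble::tibble(mean = mean(vals), sd = sd(vals),
                 q2.5 = quantile(vals, 0.025), q97.5 = quantile(vals, 0.975))
}
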