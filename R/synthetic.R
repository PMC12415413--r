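#' Configuration for a synthetic field campaign
#'
#' Defines the study conditions a generated campaign emulates: a 194-day
#' growing season (late April to the end of October) with wet, dry-down,
#' dry, recovery and final wet phases, precipitation sampled from the
#' preceding November onward (winter events as monthly composite samples),
#' four soil measurement depths, nine trees in three profiles, analytical
#' noise of 2 permil (d2H) and 1 permil (d18O), and two deuterium labelling
#' pulses (+1017.08 permil at 7 mm; +801.15 permil at 23 mm).
#'
#' @param start,end Campaign span (isotope/sap-flow observation days).
#' @param spinup_start First day of the precipitation record feeding the
#'   soil model.
#' @param n_trees,n_profiles Numbers of trees and soil profiles.
#' @param depths Soil measurement depths (m).
#' @param event_periods Tibble defining the event process per phase: `name`,
#'   `start`, `end`, `gap_days` (mean inter-event gap), `amount_mean` (mm).
#' @param iso Precipitation isotope process: seasonal sinusoid of d18O
#'   (`d18O_mean`, `d18O_amp`, `peak_doy`, `d18O_noise`) and the local
#'   meteoric water line (`lmwl_slope` in (4, 10), `lmwl_intercept`,
#'   `d2H_noise`).
#' @param labels Tibble of labelling pulses: `date`, `amount_mm`, `d2H`,
#'   `d18O`.
#' @param soil Per-layer soil model parameters: `thickness_m`, `infil_frac`
#'   (event recharge fractions, summing to <= 1), `lag_days` (tracer arrival
#'   delay), `vwc_init`, `vwc_fc`, `vwc_wilt` (percent), `drain_rate`
#'   (day^-1), `evap_d18O_rate` (topsoil enrichment, permil/day at VPD = 2
#'   kPa) and `evap_slope` (evaporation-line slope d2H/d18O).
#' @param rwu Root-water-uptake rule: `pref` (depth preference weights) and
#'   `exponent` on plant-available water; contributions are
#'   `pref_l * ((vwc_l - wilt_l)_+ + 0.25)^exponent`, normalised.
#' @param sap Sap-flow rule: `qmax_l_d` (well-watered whole-tree flow),
#'   `vpd_halfsat` (kPa), `soil_lo`/`soil_hi` (VWC percent bracketing the
#'   drought down-regulation), `offset_sd` (per-tree probe misalignment,
#'   cm/h), `noise_sd` (velocity noise, cm/h).
#' @param noise_sd Analytical isotope noise, named `d2H`, `d18O` (permil).
#' @param missing_frac Fraction of campaign days without isotope
#'   observations (probe downtime), shared between xylem and soil.
#' @param tree_kappa Dirichlet concentration of tree-to-tree contribution
#'   scatter around the daily stand mean.
#' @param sapflow_cfg A [sapflow_config()] used both to invert velocities
#'   into heat-pulse observables and by the recovery pipeline.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(
    start = as.Date("2022-04-20"), end = as.Date("2022-10-30"),
    spinup_start = as.Date("2021-11-01"),
    n_trees = 9, n_profiles = 3,
    depths = c(0.05, 0.20, 0.40, 0.90),
    event_periods = NULL,
    iso = list(d18O_mean = -8.5, d18O_amp = 3.0, peak_doy = 135,
               d18O_noise = 0.8, lmwl_slope = 7.8, lmwl_intercept = 8,
               d2H_noise = 4),
    labels = tibble::tibble(
      date = as.Date(c("2022-06-10", "2022-08-02")),
      amount_mm = c(7, 23), d2H = c(1017.08, 801.15), d18O = c(-8, -8)),
    soil = list(thickness_m = c(0.10, 0.20, 0.30, 0.50),
                infil_frac = c(0.50, 0.30, 0.15, 0.05),
                lag_days = c(0, 1, 2, 4),
                vwc_init = c(22, 21, 20, 19),
                vwc_fc = c(26, 25, 24, 23),
                vwc_wilt = c(6, 8, 9, 10),
                drain_rate = c(0.060, 0.035, 0.018, 0.006),
                evap_d18O_rate = 0.03, evap_slope = 3.2),
    rwu = list(pref = c(0.18, 0.26, 0.46, 0.10), exponent = 2),
    sap = list(qmax_l_d = 85, vpd_halfsat = 0.8, soil_lo = 9, soil_hi = 18,
               offset_sd = 1.0, noise_sd = 0.3),
    noise_sd = c(d2H = 2.0, d18O = 1.0),
    missing_frac = 0.35,
    tree_kappa = 300,
    sapflow_cfg = sapflow_config()) {
  start <- as.Date(start); end <- as.Date(end); spinup_start <- as.Date(spinup_start)
  if (is.null(event_periods)) {
    event_periods <- tibble::tibble(
      name = c("spinup_winter", "spinup_spring", "wet", "dry_down", "dry",
               "recovery", "final_wet"),
      start = as.Date(c("2021-11-01", "2022-04-01", "2022-04-20", "2022-06-19",
                        "2022-07-09", "2022-08-17", "2022-09-16")),
      end = as.Date(c("2022-03-31", "2022-04-19", "2022-06-18", "2022-07-08",
                      "2022-08-16", "2022-09-15", "2022-10-30")),
      gap_days = c(30, 7, 4, 10, 20, 6, 5),
      amount_mean = c(60, 8, 7, 3, 2, 14, 8))
  }
  stopifnot(iso$lmwl_slope > 4, iso$lmwl_slope < 10,
            all(soil$infil_frac >= 0), sum(soil$infil_frac) <= 1,
            all(rwu$pref >= 0), rwu$exponent >= 0,
            missing_frac >= 0, missing_frac < 1)
  structure(list(start = start, end = end, spinup_start = spinup_start,
                 n_trees = n_trees, n_profiles = n_profiles, depths = depths,
                 event_periods = event_periods, iso = iso, labels = labels,
                 soil = soil, rwu = rwu, sap = sap, noise_sd = noise_sd,
                 missing_frac = missing_frac, tree_kappa = tree_kappa,
                 sapflow_cfg = sapflow_cfg),
            class = "scenario_config")
}

event_iso_value <- function(dates, iso) {
  doy <- as.numeric(format(dates, "%j"))
  d18O <- iso$d18O_mean + iso$d18O_amp * cos(2 * pi * (doy - iso$peak_doy) / 365) +
    rnorm(length(dates), 0, iso$d18O_noise)
  d2H <- iso$lmwl_slope * d18O + iso$lmwl_intercept +
    rnorm(length(dates), 0, iso$d2H_noise)
  tibble::tibble(d18O = d18O, d2H = d2H)
}

#' Simulate the precipitation event record
#'
#' Event amounts are gamma-distributed, spacing follows the per-phase mean
#' gap, d18O follows the seasonal sinusoid and d2H the local meteoric water
#' line, both with event-level noise. Labelling pulses from the scenario are
#' injected as flagged events on their fixed dates with their exact enriched
#' d2H values.
#'
#' @param cfg A [scenario_config()]. Uses the current RNG state; call
#'   `set.seed()` (or [simulate_campaign()]) for reproducibility.
#' @return An event tibble in [read_precip_events()] format.
#' @export
simulate_precipitation <- function(cfg) {
  evs <- purrr::pmap(cfg$event_periods, function(name, start, end, gap_days,
                                                 amount_mean, ...) {
    day <- start + round(runif(1, 0, gap_days / 2))
    rows <- list()
    while (day <= end) {
      dur <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
      amount <- rgamma(1, shape = 1.5, scale = amount_mean / 1.5)
      rows[[length(rows) + 1]] <- tibble::tibble(
        start_date = day, end_date = min(day + dur - 1, end),
        amount_mm = round(amount, 1))
      gap <- max(1, round(rgamma(1, shape = 2, scale = gap_days / 2)))
      day <- day + dur - 1 + gap
    }
    dplyr::bind_rows(rows)
  }) |> dplyr::bind_rows()
  iso <- event_iso_value(evs$start_date, cfg$iso)
  evs$d2H <- iso$d2H; evs$d18O <- iso$d18O
  evs$label <- FALSE
  if (nrow(cfg$labels) > 0) {
    lab <- tibble::tibble(start_date = cfg$labels$date,
                          end_date = cfg$labels$date,
                          amount_mm = cfg$labels$amount_mm,
                          d2H = cfg$labels$d2H, d18O = cfg$labels$d18O,
                          label = TRUE)
    evs <- dplyr::bind_rows(evs, lab)
  }
  evs |>
    dplyr::arrange(.data$start_date) |>
    dplyr::mutate(event_id = sprintf("ev%03d", dplyr::row_number()),
                  sd2H = cfg$noise_sd[["d2H"]], sd18O = cfg$noise_sd[["d18O"]]) |>
    dplyr::select("event_id", "start_date", "end_date", "amount_mm",
                  "d2H", "d18O", "sd2H", "sd18O", "label")
}

#' Simulate daily atmospheric forcing
#'
#' Daily VPD follows a seasonal bell peaking in high summer with day-to-day
#' noise and suppression on rain days; PPFD scales with the same seasonality.
#' Hourly series carry a diurnal shape that is dark and demand-free between
#' 02:00 and 04:00 (the zero-flow window).
#'
#' @param cfg A [scenario_config()].
#' @param events Event tibble from [simulate_precipitation()].
#' @return List with `daily` (`date`, `precip_mm`, `vpd_kpa`, `ppfd`) and
#'   `hourly` (`timestamp`, `vpd_kpa`, `ppfd`) over the campaign span.
#' @export
simulate_env <- function(cfg, events) {
  dates <- seq(cfg$spinup_start, cfg$end, by = "day")
  doy <- as.numeric(format(dates, "%j"))
  precip <- daily_precip(events, dates)
  vpd <- pmax(0.05, 0.5 + 2.8 * exp(-((doy - 205) / 55)^2) +
                rnorm(length(dates), 0, 0.25))
  vpd[precip > 0] <- vpd[precip > 0] * 0.6
  ppfd_peak <- pmax(100, 900 + 1100 * exp(-((doy - 180) / 70)^2) +
                      rnorm(length(dates), 0, 100))
  daily <- tibble::tibble(date = dates, precip_mm = precip, vpd_kpa = vpd,
                          ppfd = round(ppfd_peak))
  camp <- daily[daily$date >= cfg$start, ]
  hours <- 0:23
  shape_sun <- ifelse(hours >= 6 & hours <= 20,
                      pmax(0, sin(pi * (hours - 6) / 14)), 0)
  hourly <- tidyr::expand_grid(date = camp$date, hour = hours) |>
    dplyr::left_join(camp, by = "date") |>
    dplyr::mutate(
      timestamp = as.POSIXct(paste0(format(.data$date), " ",
                                    sprintf("%02d:00:00", .data$hour)),
                             tz = "UTC"),
      sun = shape_sun[.data$hour + 1],
      vpd_kpa = pmax(0.002, .data$vpd_kpa * (0.002 + 0.998 * .data$sun)),
      ppfd = .data$ppfd * .data$sun) |>
    dplyr::select("timestamp", "vpd_kpa", "ppfd")
  list(daily = daily, hourly = hourly)
}

daily_precip <- function(events, dates) {
  precip <- rep(0, length(dates))
  for (i in seq_len(nrow(events))) {
    span <- seq(events$start_date[i], events$end_date[i], by = "day")
    idx <- match(span, dates)
    idx <- idx[!is.na(idx)]
    if (length(idx) > 0) precip[idx] <- precip[idx] + events$amount_mm[i] / length(span)
  }
  precip
}

#' Simulate the soil water and tracer cascade
#'
#' A per-layer lagged mixing cascade: volumetric water content follows an
#' exponential drain toward wilting, driven by atmospheric demand, with
#' event recharge attenuated by depth and arriving after a per-layer lag.
#' Each layer's isotopic state is a convex mixture over past events, updated
#' by the recharge fraction of stored water; the topsoil additionally drifts
#' along an evaporation line during rain-free spells.
#'
#' @param cfg A [scenario_config()].
#' @param events Event tibble.
#' @param env Forcing list from [simulate_env()].
#' @return List: `daily` (tibble `date`, `depth`, `vwc`, `d2H`, `d18O` of the
#'   true layer state), `composition` (array day x event x layer of each
#'   layer's event make-up) and `event_ids`.
#' @export
simulate_soil <- function(cfg, events, env) {
  dates <- seq(cfg$spinup_start, cfg$end, by = "day")
  nd <- length(dates); L <- length(cfg$depths); E <- nrow(events)
  s <- cfg$soil
  vwc <- matrix(NA_real_, nd, L)
  comp <- array(0, dim = c(nd, E, L))
  enrich18 <- matrix(0, nd, L)  # cumulative evaporative enrichment, d18O scale

  # recharge schedule: event water reaches layer l at start + lag_l
  arrive <- matrix(0, nd, L)
  arrive_ev <- vector("list", nd)
  for (i in seq_len(nd)) arrive_ev[[i]] <- list()
  for (e in seq_len(E)) {
    for (l in seq_len(L)) {
      d <- match(events$start_date[e] + s$lag_days[l], dates)
      if (!is.na(d)) {
        arrive[d, l] <- arrive[d, l] + s$infil_frac[l] * events$amount_mm[e]
        arrive_ev[[d]][[length(arrive_ev[[d]]) + 1]] <-
          c(e, l, s$infil_frac[l] * events$amount_mm[e])
      }
    }
  }

  env_idx <- match(dates, env$daily$date)
  vpd <- env$daily$vpd_kpa[env_idx]
  precip <- env$daily$precip_mm[env_idx]

  state_vwc <- s$vwc_init
  state_comp <- matrix(0, E, L)
  first_ev <- which(events$start_date <= cfg$spinup_start + 15)[1]
  if (is.na(first_ev)) first_ev <- 1
  state_comp[first_ev, ] <- 1  # spin-up initial water: earliest winter event
  state_enr <- rep(0, L)

  for (i in seq_len(nd)) {
    demand <- min(vpd[i] / 2, 2)
    state_vwc <- state_vwc - s$drain_rate * pmax(state_vwc - s$vwc_wilt, 0) * demand
    for (rec in arrive_ev[[i]]) {
      e <- rec[1]; l <- rec[2]; mm <- rec[3]
      store <- state_vwc[l] * 10 * s$thickness_m[l]  # mm of stored water
      m <- mm / (mm + store)
      state_comp[, l] <- (1 - m) * state_comp[, l]
      state_comp[e, l] <- state_comp[e, l] + m
      state_enr[l] <- (1 - m) * state_enr[l]
      state_vwc[l] <- min(state_vwc[l] + mm / (10 * s$thickness_m[l]), s$vwc_fc[l])
    }
    if (precip[i] == 0) {
      state_enr[1] <- state_enr[1] + s$evap_d18O_rate * demand
    }
    vwc[i, ] <- state_vwc
    comp[i, , ] <- state_comp
    enrich18[i, ] <- state_enr
  }

  iso_d2H <- matrix(NA_real_, nd, L)
  iso_d18O <- matrix(NA_real_, nd, L)
  for (l in seq_len(L)) {
    cl <- matrix(comp[, , l], nrow = nd, ncol = E)
    iso_d2H[, l] <- cl %*% events$d2H + s$evap_slope * enrich18[, l]
    iso_d18O[, l] <- cl %*% events$d18O + enrich18[, l]
  }
  daily <- tidyr::expand_grid(date = dates, depth = cfg$depths) |>
    dplyr::mutate(
      vwc = as.vector(t(vwc)),
      d2H = as.vector(t(iso_d2H)),
      d18O = as.vector(t(iso_d18O)))
  list(daily = daily, composition = comp, event_ids = events$event_id,
       dates = dates)
}

rwu_contributions <- function(vwc_row, cfg) {
  s <- cfg$soil; r <- cfg$rwu
  avail <- pmax(vwc_row - s$vwc_wilt, 0) + 0.25
  w <- r$pref * avail^r$exponent
  w / sum(w)
}

#' Simulate xylem isotopes, heat-pulse records and ground truth
#'
#' The daily true contribution vector follows the scenario's root-water-
#' uptake rule on layer moisture; xylem isotope observations are the
#' contribution-weighted mixture of layer states plus analytical noise, per
#' tree (tree-level contributions scatter around the stand mean with
#' Dirichlet concentration `tree_kappa`). Whole-tree sap flow follows the
#' VPD-driven rule with drought down-regulation and is emitted as hourly
#' heat-pulse temperature ratios and times-to-maximum inverted from the
#' heat-ratio and Tmax formulas, so the processing pipeline can be tested
#' end to end against the prescribed flows.
#'
#' @param cfg A [scenario_config()].
#' @param soil Output of [simulate_soil()].
#' @param env Output of [simulate_env()].
#' @return List: `xylem_obs`, `heat_pulse`, `truth` (list with `p_depth`,
#'   `event_contributions`, `tree_sapflow`, `transpiration`, `offsets`).
#' @export
simulate_xylem_and_sapflow <- function(cfg, soil, env) {
  camp_days <- seq(cfg$start, cfg$end, by = "day")
  di <- match(camp_days, soil$dates)
  L <- length(cfg$depths)
  E <- dim(soil$composition)[2]

  soil_wide <- soil$daily |>
    dplyr::filter(.data$date %in% camp_days)
  vwc_mat <- matrix(soil_wide$vwc, ncol = L, byrow = TRUE)
  d2H_mat <- matrix(soil_wide$d2H, ncol = L, byrow = TRUE)
  d18O_mat <- matrix(soil_wide$d18O, ncol = L, byrow = TRUE)

  p_true <- t(apply(vwc_mat, 1, rwu_contributions, cfg = cfg))
  xylem_true <- cbind(rowSums(p_true * d2H_mat), rowSums(p_true * d18O_mat))

  # true event make-up of xylem water: depth mixture of layer compositions
  ev_contrib <- matrix(0, length(camp_days), E)
  for (i in seq_along(camp_days)) {
    ci <- matrix(soil$composition[di[i], , ], nrow = E, ncol = L)
    ev_contrib[i, ] <- ci %*% p_true[i, ]
  }

  trees <- sprintf("T%d", seq_len(cfg$n_trees))
  xylem_obs <- purrr::map(seq_along(camp_days), function(i) {
    ptree <- rdirichlet_rows(cfg$n_trees, cfg$tree_kappa * pmax(p_true[i, ], 1e-4))
    tibble::tibble(
      date = camp_days[i], id = trees,
      d2H = as.vector(ptree %*% d2H_mat[i, ]) +
        rnorm(cfg$n_trees, 0, cfg$noise_sd[["d2H"]]),
      d18O = as.vector(ptree %*% d18O_mat[i, ]) +
        rnorm(cfg$n_trees, 0, cfg$noise_sd[["d18O"]]),
      sd2H = cfg$noise_sd[["d2H"]], sd18O = cfg$noise_sd[["d18O"]],
      pool = "xylem")
  }) |> dplyr::bind_rows()

  # sap flow: whole-tree daily flow and its hourly heat-pulse emission
  env_day <- env$daily[match(camp_days, env$daily$date), ]
  soil_g <- pmin(pmax((rowMeans(vwc_mat[, cfg$depths <= 0.40, drop = FALSE]) -
                         cfg$sap$soil_lo) /
                        (cfg$sap$soil_hi - cfg$sap$soil_lo), 0.15), 1)
  f_vpd <- 1 - exp(-env_day$vpd_kpa / cfg$sap$vpd_halfsat)
  qmax_tree <- cfg$sap$qmax_l_d * runif(cfg$n_trees, 0.85, 1.15)
  offsets <- rnorm(cfg$n_trees, 0, cfg$sap$offset_sd)

  scfg <- cfg$sapflow_cfg
  hours <- 0:23
  sun <- ifelse(hours >= 6 & hours <= 20, pmax(0, sin(pi * (hours - 6) / 14)), 0)
  sun_sum <- sum(sun)
  asw <- scfg$sapwood_area

  hp <- list(); q_truth <- list()
  for (tr in seq_len(cfg$n_trees)) {
    q_day <- qmax_tree[tr] * f_vpd * soil_g              # L d^-1, truth
    v_peak <- q_day / (10 * asw * sun_sum)               # cm h^-1
    v_true <- outer(v_peak, sun)                         # day x hour
    v_obs <- v_true + offsets[tr] +
      matrix(rnorm(length(v_true), 0, cfg$sap$noise_sd), nrow(v_true))
    ts <- rep(camp_days, each = length(hours))
    tstamp <- as.POSIXct(paste0(format(ts), sprintf(" %02d:00:00", rep(hours, length(camp_days)))),
                         tz = "UTC")
    v_vec <- as.vector(t(v_obs))
    v_ms <- v_vec / M_S_TO_CM_H
    ratio <- exp(v_ms * scfg$x / scfg$k)
    tmax_s <- ifelse(v_vec > 1,
                     (-2 * scfg$k + sqrt(4 * scfg$k^2 + v_ms^2 * scfg$x^2)) / (v_ms^2),
                     NA_real_)
    hp[[tr]] <- tibble::tibble(
      timestamp = rep(tstamp, 2),
      tree_id = trees[tr],
      depth_mm = rep(c(10, 20), each = length(tstamp)),
      dT_down = rep(0.4 * ratio, 2), dT_up = 0.4,
      t_max = rep(tmax_s, 2))
    q_truth[[tr]] <- tibble::tibble(tree_id = trees[tr], date = camp_days,
                                    sapflow_l_d = q_day)
  }
  tree_sapflow <- dplyr::bind_rows(q_truth)
  transp <- tree_sapflow |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(transpiration_mm_d = sum(.data$sapflow_l_d) / scfg$ground_area,
                     .groups = "drop")

  truth <- list(
    p_depth = tibble::tibble(
      day = rep(camp_days, each = L),
      depth = rep(cfg$depths, length(camp_days)),
      contribution = as.vector(t(p_true))),
    event_contributions = tibble::tibble(
      day = rep(camp_days, each = E),
      event_id = rep(soil$event_ids, length(camp_days)),
      contribution = as.vector(t(ev_contrib))),
    tree_sapflow = tree_sapflow,
    transpiration = transp,
    offsets = tibble::tibble(tree_id = trees, offset = offsets))

  list(xylem_obs = xylem_obs, heat_pulse = dplyr::bind_rows(hp), truth = truth)
}

rdirichlet_rows <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Generate a complete synthetic campaign
#'
#' Orchestrates [simulate_precipitation()], [simulate_env()],
#' [simulate_soil()] and [simulate_xylem_and_sapflow()] under one seed.
#' Observation tables carry analytical noise and the configured fraction of
#' missing days; the `truth` element holds the exact generating quantities.
#'
#' @param cfg A [scenario_config()].
#' @param seed Integer seed; fixing it fixes every emitted value.
#' @return A list of class `campaign`: `events`, `env_daily`, `env_hourly`,
#'   `soil_obs`, `xylem_obs`, `heat_pulse`, `truth`, `config`, `seed`.
#' @export
simulate_campaign <- function(cfg = scenario_config(), seed = 1) {
  set.seed(seed)
  events <- simulate_precipitation(cfg)
  env <- simulate_env(cfg, events)
  soil <- simulate_soil(cfg, events, env)
  xs <- simulate_xylem_and_sapflow(cfg, soil, env)

  camp_days <- seq(cfg$start, cfg$end, by = "day")
  n_miss <- round(cfg$missing_frac * length(camp_days))
  missing_days <- sort(sample(camp_days, n_miss))

  profiles <- sprintf("P%d", seq_len(cfg$n_profiles))
  soil_camp <- soil$daily |> dplyr::filter(.data$date >= cfg$start)
  soil_obs <- tidyr::expand_grid(id = profiles,
                                 soil_camp) |>
    dplyr::mutate(
      d2H = .data$d2H + rnorm(dplyr::n(), 0, cfg$noise_sd[["d2H"]]),
      d18O = .data$d18O + rnorm(dplyr::n(), 0, cfg$noise_sd[["d18O"]]),
      sd2H = cfg$noise_sd[["d2H"]], sd18O = cfg$noise_sd[["d18O"]],
      pool = "soil") |>
    dplyr::select("date", "id", "depth", "d2H", "d18O", "sd2H", "sd18O", "pool")

  soil_obs <- dplyr::filter(soil_obs, !.data$date %in% missing_days)
  xylem_obs <- dplyr::filter(xs$xylem_obs, !.data$date %in% missing_days)

  env_daily <- env$daily |>
    dplyr::left_join(
      soil_camp |>
        dplyr::mutate(col = sprintf("vwc_%.2f", .data$depth)) |>
        dplyr::select("date", "col", "vwc") |>
        tidyr::pivot_wider(names_from = "col", values_from = "vwc"),
      by = "date")

  structure(list(events = events, env_daily = env_daily,
                 env_hourly = env$hourly, soil_obs = soil_obs,
                 xylem_obs = xylem_obs, heat_pulse = xs$heat_pulse,
                 soil_truth = soil_camp,
                 truth = xs$truth, config = cfg, seed = seed),
            class = "campaign")
}

#' Write a campaign to CSV files
#'
#' Emits the CSV dialects the reading functions consume, plus a
#' `truth/` subdirectory with the generating quantities.
#'
#' @param campaign A [simulate_campaign()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  wr <- function(x, name) readr::write_csv(x, file.path(dir, name), progress = FALSE)
  wr(campaign$events, "precip_events.csv")
  wr(campaign$env_daily, "env_daily.csv")
  wr(campaign$env_hourly, "env_hourly.csv")
  wr(campaign$soil_obs, "soil_isotopes.csv")
  wr(campaign$xylem_obs, "xylem_isotopes.csv")
  wr(campaign$heat_pulse, "heat_pulse.csv")
  wr(campaign$truth$p_depth, file.path("truth", "p_depth.csv"))
  wr(campaign$truth$event_contributions, file.path("truth", "event_contributions.csv"))
  wr(campaign$truth$tree_sapflow, file.path("truth", "tree_sapflow.csv"))
  wr(campaign$truth$transpiration, file.path("truth", "transpiration.csv"))
  invisible(dir)
}

#' Simulate a cumulative uptake curve from known kinetics
#'
#' Draws `y(t) = a - (a - b) exp(-c t) + noise`, clipped to [0, 1]; the
#' construct-and-invert fixture for [fit_uptake_curve()].
#'
#' @param a,b,c Curve parameters (`a` in [0,1], `b` in [0,a], `c >= 0`).
#' @param t Time grid (days).
#' @param noise_sd Observation noise SD.
#' @return Tibble `t`, `uptake`.
#' @export
simulate_uptake_curve <- function(a, b, c, t = 0:30, noise_sd = 0) {
  y <- a - (a - b) * exp(-c * t) + rnorm(length(t), 0, noise_sd)
  tibble::tibble(t = t, uptake = pmin(pmax(y, 0), 1))
}
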