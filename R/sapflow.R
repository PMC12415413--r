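#' Sap-flow processing configuration
#'
#' Probe geometry, thermal properties and scaling areas for the heat-pulse
#' dual-method computation.
#'
#' @param probe_spacing_m Distance between the heater and each measurement
#'   needle (m). Default 0.006 m.
#' @param thermal_diffusivity Thermal diffusivity of fresh sapwood k
#'   (m^2 s^-1). Default 2.5e-7.
#' @param crossover_cm_h Heat-pulse velocity (cm h^-1) at which the dual
#'   method hands over from the heat ratio method (below) to the Tmax method
#'   (above). Not a physical constant; tune per installation.
#' @param wound_coefficients Numeric triple `(c0, c1, c2)` of the polynomial
#'   wound-correction multiplier `c0 + c1 v + c2 v^2` applied to velocities;
#'   the default `(1, 0, 0)` is the identity.
#' @param sapwood_area_m2 Active sapwood area per tree (m^2); scalar or named
#'   by tree id.
#' @param ground_area_m2 Forest-floor area represented by the measured trees
#'   (m^2).
#' @param ring_weights Weights of the 10- and 20-mm radial measurement depths
#'   in the sapwood-area-weighted mean velocity; default equal.
#' @return A list of class `sapflow_config`.
#' @export
sapflow_config <- function(probe_spacing_m = 0.006,
                           thermal_diffusivity = 2.5e-7,
                           crossover_cm_h = 30,
                           wound_coefficients = c(1, 0, 0),
                           sapwood_area_m2 = 0.03,
                           ground_area_m2 = 480,
                           ring_weights = c(`10` = 0.5, `20` = 0.5)) {
  stopifnot(probe_spacing_m > 0, thermal_diffusivity > 0,
            all(sapwood_area_m2 > 0), ground_area_m2 > 0,
            length(wound_coefficients) == 3)
  structure(list(x = probe_spacing_m, k = thermal_diffusivity,
                 crossover = crossover_cm_h, wound = wound_coefficients,
                 sapwood_area = sapwood_area_m2, ground_area = ground_area_m2,
                 ring_weights = ring_weights / sum(ring_weights)),
            class = "sapflow_config")
}

M_S_TO_CM_H <- 3.6e5

#' Heat ratio method velocity
#'
#' `v = (k / x) * ln(dT_down / dT_up)`, converted to cm per hour. The sign of
#' the velocity follows the sign of the log temperature-rise ratio; reverse
#' flow yields negative values. Non-positive temperature rises give `NA`.
#'
#' @param dT_down,dT_up Post-pulse temperature rises (degrees C) at the
#'   downstream and upstream thermistors.
#' @param cfg A [sapflow_config()].
#' @return Heat-pulse velocity in cm h^-1 (vectorised).
#' @examples
#' cfg <- sapflow_config()
#' hrm_velocity(exp(1), 1, cfg)  # 15 cm/h at default geometry
#' @export
hrm_velocity <- function(dT_down, dT_up, cfg = sapflow_config()) {
  bad <- !is.finite(dT_down) | !is.finite(dT_up) | dT_down <= 0 | dT_up <= 0
  ratio <- ifelse(bad, 1, dT_down / dT_up)
  v <- (cfg$k / cfg$x) * log(ratio) * M_S_TO_CM_H
  v[bad] <- NA_real_
  v
}

#' Tmax method velocity
#'
#' `v = sqrt(x^2 - 4 k t_max) / t_max`, converted to cm per hour. Times to
#' maximum for which the discriminant is negative correspond to velocities
#' below the resolution of the method and give `NA`.
#'
#' @param t_max Time (s) to the maximum downstream temperature.
#' @param cfg A [sapflow_config()].
#' @return Heat-pulse velocity in cm h^-1 (vectorised, nonnegative).
#' @export
tmax_velocity <- function(t_max, cfg = sapflow_config()) {
  disc <- cfg$x^2 - 4 * cfg$k * t_max
  v <- sqrt(pmax(disc, 0)) / t_max * M_S_TO_CM_H
  v[!is.finite(t_max) | t_max <= 0 | disc < 0] <- NA_real_
  v
}

#' Dual-method velocity selection
#'
#' The heat ratio method resolves low and reverse flows; the Tmax method is
#' reliable at high flows. Velocities below the crossover use HRM, above it
#' Tmax, with fall-back to whichever method is available.
#'
#' @param hrm_v,tmax_v Velocities (cm h^-1) from [hrm_velocity()] and
#'   [tmax_velocity()]; `NA` where unavailable.
#' @param cfg A [sapflow_config()].
#' @return A tibble with `velocity` (cm h^-1) and `method` provenance
#'   (`"hrm"`, `"tmax"` or `NA`).
#' @export
dual_method <- function(hrm_v, tmax_v, cfg = sapflow_config()) {
  n <- max(length(hrm_v), length(tmax_v))
  hrm_v <- rep_len(hrm_v, n); tmax_v <- rep_len(tmax_v, n)
  use_tmax <- (!is.na(hrm_v) & hrm_v >= cfg$crossover & !is.na(tmax_v)) |
    (is.na(hrm_v) & !is.na(tmax_v))
  v <- ifelse(use_tmax, tmax_v, hrm_v)
  method <- dplyr::case_when(use_tmax ~ "tmax", !is.na(v) ~ "hrm",
                             TRUE ~ NA_character_)
  tibble::tibble(velocity = v, method = method)
}

wound_multiplier <- function(v, cfg) {
  cfg$wound[1] + cfg$wound[2] * v + cfg$wound[3] * v^2
}

#' Per-record heat-pulse velocities for a raw sensor table
#'
#' Computes HRM and Tmax velocities for every record, selects via the dual
#' method, applies the wound correction, and averages the radial measurement
#' depths with the configured ring weights.
#'
#' @param records Tibble with columns `timestamp` (POSIXct), `tree_id`,
#'   `depth_mm`, `dT_down`, `dT_up`, `t_max`.
#' @param cfg A [sapflow_config()].
#' @return Tibble per tree and timestamp: `velocity` (cm h^-1) and the
#'   dominant `method`.
#' @export
heat_pulse_velocities <- function(records, cfg = sapflow_config()) {
  rec <- records |>
    dplyr::mutate(
      hrm = hrm_velocity(.data$dT_down, .data$dT_up, cfg),
      tmax = tmax_velocity(.data$t_max, cfg)
    )
  sel <- dual_method(rec$hrm, rec$tmax, cfg)
  rec$velocity <- sel$velocity * wound_multiplier(sel$velocity, cfg)
  rec$method <- sel$method
  w <- cfg$ring_weights
  rec |>
    dplyr::mutate(ring_w = unname(w[as.character(.data$depth_mm)])) |>
    dplyr::group_by(.data$tree_id, .data$timestamp) |>
    dplyr::summarise(
      velocity = sum(.data$velocity * .data$ring_w) / sum(.data$ring_w),
      method = .data$method[which.max(.data$ring_w)],
      .groups = "drop")
}

#' Zero-flow night correction
#'
#' Nocturnal sap flow between 02:00 and 04:00 under negligible atmospheric
#' demand is defined as zero; the per-tree median velocity over qualifying
#' windows is an additive offset (probe misalignment) subtracted everywhere.
#' `velocity_transp` additionally clips small negatives to zero for
#' transpiration scaling while the raw corrected velocity is kept.
#'
#' @param velocities Tibble from [heat_pulse_velocities()] (`tree_id`,
#'   `timestamp`, `velocity`).
#' @param env Tibble with `timestamp`, `vpd_kpa`, `ppfd` at the same (or
#'   coarser, joined by nearest hour) resolution.
#' @param vpd_max Window qualifies when VPD < `vpd_max` (kPa). Default 0.01.
#' @param par_limit PPFD criterion bound (umol m^-2 s^-1). Default 5.
#' @param par_rule `"below"` (darkness, default) requires PPFD < `par_limit`;
#'   `"above"` selects the opposite inequality.
#' @return `velocities` with columns `velocity` (corrected), `velocity_raw`,
#'   `velocity_transp` and an attribute `offsets` (per-tree tibble).
#' @export
zero_flow_correct <- function(velocities, env, vpd_max = 0.01, par_limit = 5,
                              par_rule = c("below", "above")) {
  par_rule <- match.arg(par_rule)
  env_q <- env |>
    dplyr::mutate(qualifies = .data$vpd_kpa < vpd_max &
                    (if (par_rule == "below") .data$ppfd < par_limit
                     else .data$ppfd > par_limit))
  v <- dplyr::left_join(velocities, dplyr::select(env_q, "timestamp", "qualifies"),
                        by = "timestamp")
  hr <- as.integer(format(v$timestamp, "%H"))
  v$in_window <- hr >= 2 & hr < 4 & !is.na(v$qualifies) & v$qualifies
  offsets <- v |>
    dplyr::group_by(.data$tree_id) |>
    dplyr::summarise(
      n_window = sum(.data$in_window & !is.na(.data$velocity)),
      offset = if (sum(.data$in_window & !is.na(.data$velocity)) > 0)
        median(.data$velocity[.data$in_window], na.rm = TRUE) else 0,
      .groups = "drop")
  if (any(offsets$n_window == 0)) {
    warning("no qualifying zero-flow windows for tree(s): ",
            paste(offsets$tree_id[offsets$n_window == 0], collapse = ", "),
            "; offset 0 used", call. = FALSE)
  }
  out <- v |>
    dplyr::left_join(dplyr::select(offsets, "tree_id", "offset"), by = "tree_id") |>
    dplyr::mutate(velocity_raw = .data$velocity,
                  velocity = .data$velocity - .data$offset,
                  velocity_transp = pmax(.data$velocity, 0)) |>
    dplyr::select(-"qualifies", -"in_window")
  attr(out, "offsets") <- offsets
  out
}

#' Sap flux density, whole-tree sap flow and stand transpiration
#'
#' Sap flux density is taken as `J_S = 10 * v` litres per m^2 sapwood per
#' hour for `v` in cm h^-1 (a 1 cm h^-1 front through 1 m^2 of sapwood moves
#' 10 L h^-1). Whole-tree flow integrates `J_S * A_sapwood` over each calendar
#' day; stand transpiration divides the summed daily flows by the ground
#' area, using the identity 1 L m^-2 = 1 mm.
#'
#' @param velocities Corrected velocity tibble ([zero_flow_correct()] output);
#'   the `velocity_transp` column is used.
#' @param cfg A [sapflow_config()].
#' @return A list with `tree_daily` (tibble: `tree_id`, `date`,
#'   `sapflow_l_d`) and `stand_daily` (tibble: `date`,
#'   `transpiration_mm_d`).
#' @export
scale_to_transpiration <- function(velocities, cfg = sapflow_config()) {
  if (cfg$ground_area <= 0) stop("ground area must be positive", call. = FALSE)
  asw <- cfg$sapwood_area
  get_asw <- function(id) {
    if (length(asw) == 1 && is.null(names(asw))) return(asw)
    unname(asw[as.character(id)])
  }
  v <- velocities |>
    dplyr::arrange(.data$tree_id, .data$timestamp) |>
    dplyr::group_by(.data$tree_id) |>
    dplyr::mutate(dt_h = step_hours(.data$timestamp)) |>
    dplyr::ungroup() |>
    dplyr::mutate(date = as.Date(.data$timestamp),
                  js = 10 * .data$velocity_transp,
                  flow_l = .data$js * get_asw(.data$tree_id) * .data$dt_h)
  tree_daily <- v |>
    dplyr::group_by(.data$tree_id, .data$date) |>
    dplyr::summarise(sapflow_l_d = sum(.data$flow_l, na.rm = TRUE), .groups = "drop")
  stand_daily <- tree_daily |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(transpiration_mm_d = sum(.data$sapflow_l_d) / cfg$ground_area,
                     .groups = "drop")
  list(tree_daily = tree_daily, stand_daily = stand_daily)
}

# time step per record in hours, assuming a regular grid per tree
step_hours <- function(ts) {
  d <- diff(as.numeric(ts)) / 3600
  if (length(d) == 0) return(24)
  rep(median(d), length(d) + 1)
}

#' Full sap-flow pipeline from raw heat-pulse records
#'
#' @param records Raw sensor tibble (see [heat_pulse_velocities()]).
#' @param env Environmental tibble with `timestamp`, `vpd_kpa`, `ppfd`.
#' @param cfg A [sapflow_config()].
#' @inheritParams zero_flow_correct
#' @return As [scale_to_transpiration()], plus the corrected velocity series
#'   under `velocities`.
#' @export
compute_sapflow <- function(records, env, cfg = sapflow_config(),
                            vpd_max = 0.01, par_limit = 5,
                            par_rule = c("below", "above")) {
  vel <- heat_pulse_velocities(records, cfg)
  corr <- zero_flow_correct(vel, env, vpd_max = vpd_max, par_limit = par_limit,
                            par_rule = par_rule)
  out <- scale_to_transpiration(corr, cfg)
  out$velocities <- corr
  out
}
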