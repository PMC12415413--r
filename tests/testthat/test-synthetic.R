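test_that("fixing the seed fixes every emitted file byte for byte", {
  cfg <- small_scenario()
  d1 <- file.path(tempdir(), "camp_a"); d2 <- file.path(tempdir(), "camp_b")
  write_campaign(simulate_campaign(cfg, seed = 5), d1)
  write_campaign(simulate_campaign(cfg, seed = 5), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) >= 8)
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  # a different seed changes the draw
  d3 <- file.path(tempdir(), "camp_c")
  write_campaign(simulate_campaign(cfg, seed = 6), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "xylem_isotopes.csv"))),
                         unname(tools::md5sum(file.path(d3, "xylem_isotopes.csv")))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("precipitation isotopes follow the seasonal line and the labels are injected exactly", {
  cfg <- scenario_config()
  set.seed(31)
  ev <- simulate_precipitation(cfg)
  lab <- ev[ev$label, ]
  expect_equal(lab$d2H, c(1017.08, 801.15))
  expect_equal(lab$amount_mm, c(7, 23))
  expect_equal(lab$start_date, as.Date(c("2022-06-10", "2022-08-02")))
  nat <- ev[!ev$label, ]
  expect_true(all(nat$d2H > -100 & nat$d2H < 10))
  expect_true(all(nat$amount_mm >= 0))
  # zero amplitude and noise: every event shares the mean isotope value
  cfg0 <- scenario_config(iso = list(d18O_mean = -8, d18O_amp = 0, peak_doy = 135,
                                     d18O_noise = 0, lmwl_slope = 7.8,
                                     lmwl_intercept = 8, d2H_noise = 0),
                          labels = tibble::tibble(date = as.Date(character()),
                                                  amount_mm = numeric(),
                                                  d2H = numeric(), d18O = numeric()))
  set.seed(32)
  ev0 <- simulate_precipitation(cfg0)
  expect_true(all(abs(ev0$d18O - -8) < 1e-12))
  expect_true(all(abs(ev0$d2H - (7.8 * -8 + 8)) < 1e-12))
})

test_that("the soil cascade keeps mass sane and attenuates a labelled pulse with depth", {
  cfg <- scenario_config()
  set.seed(33)
  ev <- simulate_precipitation(cfg)
  env <- simulate_env(cfg, ev)
  soil <- simulate_soil(cfg, ev, env)
  expect_true(all(soil$daily$vwc >= 0))
  expect_true(all(soil$daily$vwc <= max(cfg$soil$vwc_fc) + 1e-9))
  expect_lte(sum(cfg$soil$infil_frac), 1)
  # compositions stay on the simplex
  cs <- apply(soil$composition, c(1, 3), sum)
  expect_true(all(abs(cs - 1) < 1e-9))
  # peak d2H after the big labelling pulse is ordered by depth
  lab2 <- ev$event_id[ev$label][2]
  after <- soil$dates >= as.Date("2022-08-02") & soil$dates <= as.Date("2022-09-01")
  peaks <- vapply(seq_along(cfg$depths), function(l) {
    max(soil$composition[after, which(ev$event_id == lab2), l])
  }, numeric(1))
  expect_true(all(diff(peaks) <= 1e-12))
})

test_that("without events the soil only dries and only the topsoil drifts isotopically", {
  cfg <- small_scenario(event_periods = tibble::tibble(
    name = "init", start = as.Date("2021-11-01"), end = as.Date("2021-11-02"),
    gap_days = 1, amount_mean = 20),
    labels = tibble::tibble(date = as.Date(character()), amount_mm = numeric(),
                            d2H = numeric(), d18O = numeric()))
  set.seed(34)
  ev <- simulate_precipitation(cfg)
  env <- simulate_env(cfg, ev)
  soil <- simulate_soil(cfg, ev, env)
  late <- soil$daily[soil$daily$date >= as.Date("2022-01-01"), ]
  for (d in cfg$depths) {
    v <- late$vwc[late$depth == d]
    expect_true(all(diff(v) <= 1e-12))
  }
  # deep layers keep their event mixture value; topsoil drifts by evaporation
  for (d in cfg$depths[-1]) {
    x <- late$d18O[late$depth == d]
    expect_lt(max(x) - min(x), 1e-9)
  }
  top <- late$d18O[late$depth == cfg$depths[1]]
  expect_gt(max(top) - min(top), 0.5)
})

test_that("emitted heat pulses invert back to the prescribed velocities", {
  cfg <- small_scenario(sap = list(qmax_l_d = 85, vpd_halfsat = 0.8, soil_lo = 9,
                                   soil_hi = 18, offset_sd = 0, noise_sd = 0))
  camp <- cached_campaign(35, cfg)
  scfg <- cfg$sapflow_cfg
  hp <- camp$heat_pulse[camp$heat_pulse$depth_mm == 10, ]
  v_hrm <- hrm_velocity(hp$dT_down, hp$dT_up, scfg)
  # HRM inversion is exact everywhere the ratio is finite
  q <- dplyr::inner_join(
    dplyr::summarise(
      dplyr::group_by(dplyr::mutate(hp, date = as.Date(timestamp), v = v_hrm),
                      tree_id, date),
      q = sum(10 * v * scfg$sapwood_area), .groups = "drop"),
    camp$truth$tree_sapflow, by = c("tree_id", "date"))
  expect_equal(q$q, q$sapflow_l_d, tolerance = 1e-9)
  # Tmax inversion agrees with HRM where defined
  ok <- !is.na(hp$t_max)
  expect_equal(tmax_velocity(hp$t_max[ok], scfg), v_hrm[ok], tolerance = 1e-6)
})

test_that("drought in the default campaign deepens the true uptake profile", {
  camp <- cached_campaign(36)
  tr <- camp$truth$p_depth |>
    dplyr::group_by(day) |>
    dplyr::summarise(md = sum(contribution * depth), .groups = "drop")
  wet <- mean(tr$md[tr$day <= as.Date("2022-06-18")])
  dry <- mean(tr$md[tr$day >= as.Date("2022-07-09") & tr$day <= as.Date("2022-08-16")])
  expect_gt(dry, wet)
  # contributions on the simplex by construction
  sums <- camp$truth$p_depth |>
    dplyr::group_by(day) |> dplyr::summarise(s = sum(contribution))
  expect_true(all(abs(sums$s - 1) < 1e-9))
  # fixed p vertex: xylem equals that layer exactly when noise is off
  p <- rwu_p <- c(0, 0, 1, 0)
  lay <- camp$soil_truth[camp$soil_truth$date == as.Date("2022-06-01"), ]
  expect_equal(sum(p * lay$d2H), lay$d2H[3])
})

test_that("the observation tables reflect the configured missingness and noise", {
  camp <- cached_campaign(36)
  n_days <- as.numeric(camp$config$end - camp$config$start) + 1
  obs_days <- length(unique(camp$xylem_obs$date))
  expect_equal(obs_days / n_days, 1 - camp$config$missing_frac, tolerance = 0.02)
  expect_true(all(c("sd2H", "sd18O") %in% names(camp$xylem_obs)))
  expect_equal(unique(camp$xylem_obs$sd2H), 2)
  expect_equal(length(unique(camp$xylem_obs$id)), camp$config$n_trees)
})
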