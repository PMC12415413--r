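cfg <- sapflow_config()  # x = 0.006 m, k = 2.5e-7 m2/s, crossover 30 cm/h

test_that("heat ratio velocity matches hand arithmetic and its symmetries", {
  expect_equal(hrm_velocity(1, 1, cfg), 0)
  # k/x * ln(e) = 2.5e-7/0.006 m/s = 15 cm/h
  expect_equal(hrm_velocity(exp(1), 1, cfg), 15, tolerance = 1e-9)
  expect_true(hrm_velocity(0.8, 1, cfg) < 0)  # reverse flow
  # antisymmetry under swapping the thermistors
  set.seed(5)
  a <- runif(50, 0.1, 2); b <- runif(50, 0.1, 2)
  expect_equal(hrm_velocity(a, b, cfg), -hrm_velocity(b, a, cfg), tolerance = 1e-12)
  expect_true(is.na(hrm_velocity(-0.1, 1, cfg)))
})

test_that("Tmax velocity matches hand arithmetic, is zero at the domain boundary and decreasing", {
  # sqrt(3.6e-5 - 2e-5)/20 m/s = 72 cm/h
  expect_equal(tmax_velocity(20, cfg), 72, tolerance = 1e-9)
  t_edge <- cfg$x^2 / (4 * cfg$k)  # discriminant exactly zero
  expect_equal(tmax_velocity(t_edge, cfg), 0)
  expect_true(is.na(tmax_velocity(t_edge * 1.01, cfg)))
  tt <- seq(5, t_edge, length.out = 40)
  v <- tmax_velocity(tt, cfg)
  expect_true(all(diff(v) < 0))
  expect_true(is.na(tmax_velocity(Inf, cfg)))
})

test_that("the dual method hands over at the crossover with provenance", {
  sel <- dual_method(c(10, 50, NA, 10, 50), c(40, 55, 40, NA, NA), cfg)
  expect_equal(sel$velocity, c(10, 55, 40, 10, 50))
  expect_equal(sel$method, c("hrm", "tmax", "tmax", "hrm", "hrm"))
  expect_true(is.na(dual_method(NA, NA, cfg)$velocity))
})

test_that("zero-flow night correction recovers an injected probe offset", {
  hours <- rep(0:23, 4)
  ts <- as.POSIXct("2022-06-01 00:00", tz = "UTC") + 3600 * seq_len(96) - 3600
  true_v <- ifelse(hours >= 6 & hours <= 20, 25 * sin(pi * (hours - 6) / 14), 0)
  env <- tibble::tibble(timestamp = ts,
                        vpd_kpa = ifelse(true_v > 0, 1.5, 0.005),
                        ppfd = ifelse(true_v > 0, 1500, 0))
  vel <- tibble::tibble(timestamp = ts, tree_id = "T1", velocity = true_v + 2)
  corr <- zero_flow_correct(vel, env)
  off <- attr(corr, "offsets")
  expect_equal(off$offset, 2, tolerance = 1e-12)
  night <- as.integer(format(corr$timestamp, "%H")) %in% c(2, 3)
  expect_equal(mean(corr$velocity[night]), 0, tolerance = 1e-12)
  # already-zero nights: nothing changes
  corr0 <- zero_flow_correct(dplyr::mutate(vel, velocity = true_v), env)
  expect_equal(corr0$velocity, true_v, tolerance = 1e-12)
  # criteria never met: offset zero with a warning
  env_bad <- dplyr::mutate(env, vpd_kpa = 2)
  expect_warning(zero_flow_correct(vel, env_bad), "no qualifying")
})

test_that("stand scaling follows the L m-2 = mm identity and area laws", {
  ts <- as.POSIXct("2022-06-01 00:00", tz = "UTC") + 3600 * (0:23)
  # constant J_S * A = 1 L/h for 24 h -> 24 L/d; over 24 m2 ground -> 1 mm/d
  v <- tibble::tibble(timestamp = rep(ts, 1), tree_id = "T1",
                      velocity_transp = 1 / (10 * 0.03))
  cfg1 <- sapflow_config(sapwood_area_m2 = 0.03, ground_area_m2 = 24)
  out <- scale_to_transpiration(v, cfg1)
  expect_equal(out$tree_daily$sapflow_l_d, 24, tolerance = 1e-9)
  expect_equal(out$stand_daily$transpiration_mm_d, 1, tolerance = 1e-9)
  cfg2 <- sapflow_config(sapwood_area_m2 = 0.03, ground_area_m2 = 48)
  expect_equal(scale_to_transpiration(v, cfg2)$stand_daily$transpiration_mm_d,
               0.5, tolerance = 1e-9)
  expect_error(sapflow_config(ground_area_m2 = 0))
})

test_that("a three-tree stand matches the brute-force sum", {
  ts <- as.POSIXct("2022-06-01 00:00", tz = "UTC") + 3600 * (0:23)
  set.seed(8)
  vals <- lapply(1:3, function(i) pmax(rnorm(24, 10, 5), 0))
  v <- dplyr::bind_rows(lapply(1:3, function(i) {
    tibble::tibble(timestamp = ts, tree_id = paste0("T", i),
                   velocity_transp = vals[[i]])
  }))
  cfgs <- sapflow_config(sapwood_area_m2 = 0.025, ground_area_m2 = 100)
  out <- scale_to_transpiration(v, cfgs)
  hand <- sum(vapply(vals, function(x) sum(10 * x * 0.025), numeric(1))) / 100
  expect_equal(out$stand_daily$transpiration_mm_d, hand, tolerance = 1e-9)
})

test_that("the full pipeline recovers prescribed transpiration from noise-free heat pulses", {
  cfg_n <- small_scenario(sap = list(qmax_l_d = 85, vpd_halfsat = 0.8, soil_lo = 9,
                                     soil_hi = 18, offset_sd = 1.0, noise_sd = 0))
  camp <- simulate_campaign(cfg_n, seed = 21)
  sf <- compute_sapflow(camp$heat_pulse, camp$env_hourly, cfg_n$sapflow_cfg)
  cmp <- dplyr::inner_join(sf$tree_daily, camp$truth$tree_sapflow,
                           by = c("tree_id", "date"), suffix = c("_est", "_true"))
  rel <- abs(cmp$sapflow_l_d_est - cmp$sapflow_l_d_true) /
    pmax(cmp$sapflow_l_d_true, 0.5)
  expect_lt(max(rel), 0.05)
})
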