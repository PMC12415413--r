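depths4 <- c(0.05, 0.20, 0.40, 0.90)

test_that("mean uptake depth is the contribution-weighted depth", {
  expect_equal(mean_rwu_depth(c(1, 0, 0, 0), depths4), 0.05)
  expect_equal(mean_rwu_depth(c(0.11, 0.23, 0.60, 0.07) / 1.01, depths4),
               0.3545 / 1.01, tolerance = 1e-9)
  expect_equal(mean_rwu_depth(rep(0.25, 4), depths4), 0.3875)
  # permutation invariance of (depth, contribution) pairs
  p <- c(0.11, 0.23, 0.59, 0.07); p <- p / sum(p)
  o <- sample(4)
  expect_equal(mean_rwu_depth(p[o], depths4[o]), mean_rwu_depth(p, depths4))
  # bounded by the depth range
  set.seed(11)
  for (i in 1:20) {
    pp <- {w <- rgamma(4, 1); w / sum(w)}
    md <- mean_rwu_depth(pp, depths4)
    expect_gte(md, 0.05); expect_lte(md, 0.90)
  }
  expect_error(mean_rwu_depth(c(0.5, 0.2, 0.1, 0.1), depths4), "simplex")
})

test_that("absolute uptake conserves whole-tree sap flow", {
  contrib <- tidyr::expand_grid(day = as.Date("2022-06-01") + 0:5,
                                source_id = paste0("d", 1:4)) |>
    dplyr::mutate(mean = rep({set.seed(1); w <- matrix(rgamma(24, 1), 6)
                              as.vector(t(w / rowSums(w)))}, 1))
  sf <- tibble::tibble(date = as.Date("2022-06-01") + 0:5,
                       sapflow_l_d = c(60, 55, 40, 30, 20, 35))
  up <- absolute_uptake(contrib, sf)
  tot <- up |> dplyr::group_by(day) |> dplyr::summarise(s = sum(uptake_l_d))
  expect_equal(tot$s, sf$sapflow_l_d, tolerance = 1e-9)
  expect_equal(up$uptake_l_d[1], up$mean[1] * 60, tolerance = 1e-9)
  expect_error(absolute_uptake(contrib, dplyr::mutate(sf, sapflow_l_d = -1)),
               "negative")
})

test_that("age distributions map event fractions onto water ages correctly", {
  ec <- tibble::tibble(source_id = c("a", "b"), mean = c(0.6, 0.4),
                       first_day = as.Date(c("2022-06-05", "2022-05-11")))
  d <- age_distribution(ec, as.Date("2022-06-10"))
  expect_equal(d$age_days, c(5, 30))
  expect_equal(d$fraction, c(0.6, 0.4))
  curve <- cumulative_age_curve(d)
  expect_equal(curve$cum_fraction[curve$age_days == 4], 0)
  expect_true(all(curve$cum_fraction[curve$age_days %in% 5:29] == 0.6))
  expect_equal(curve$cum_fraction[curve$age_days == 30], 1)
  # nondecreasing, terminating at 1
  expect_true(all(diff(curve$cum_fraction) >= 0))
  expect_equal(max(curve$cum_fraction), 1, tolerance = 1e-9)
  # point mass
  one <- age_distribution(tibble::tibble(source_id = "a", mean = 1,
                                         first_day = as.Date("2022-05-31")),
                          as.Date("2022-06-10"))
  expect_equal(one$age_days, 10)
  expect_equal(one$cum_fraction, 1)
  # causality
  future <- tibble::tibble(source_id = "a", mean = 1,
                           first_day = as.Date("2022-06-12"))
  expect_error(age_distribution(future, as.Date("2022-06-10")), "causality")
})

test_that("transit time follows the inclusive-span rule and is monotone in the threshold", {
  expect_equal(transit_time(c(0.2, 0.15, 0.05, 0.12, 0.08)), 4)
  expect_equal(transit_time(c(0.2, 0.15, 0.05, 0.12, 0.08), rule = "total"), 3)
  expect_equal(transit_time(c(0.05, 0.08, 0.02)), 0)
  expect_equal(transit_time(rep(0.5, 30)), 30)
  set.seed(12)
  for (i in 1:20) {
    x <- runif(40, 0, 0.4)
    th <- sort(runif(5, 0.01, 0.35))
    tts <- vapply(th, function(t) transit_time(x, threshold = t), numeric(1))
    expect_true(all(diff(tts) <= 0))
  }
})

test_that("the asymptotic uptake curve is recovered exactly from clean data", {
  dat <- simulate_uptake_curve(0.8, 0.05, 0.3, 0:30, 0)
  fit <- fit_uptake_curve(dat)
  expect_true(fit$converged)
  expect_equal(unname(fit$coef), c(0.8, 0.05, 0.3), tolerance = 1e-6)
  # fitted curve strictly increasing toward a for c > 0
  expect_true(all(diff(fit$fitted) > 0))
  expect_lt(max(fit$fitted), fit$coef[["a"]] + 1e-9)
})

test_that("a constant series flags the unidentifiable rate", {
  fit <- fit_uptake_curve(tibble::tibble(t = 0:10, uptake = 0.3))
  expect_false(fit$converged)
  expect_equal(unname(fit$coef[c("a", "b")]), c(0.3, 0.3), tolerance = 1e-9)
})

test_that("curves differing only in rate are distinguished", {
  set.seed(13)
  d1 <- simulate_uptake_curve(0.7, 0.05, 0.15, 0:30, 0.02)
  d2 <- simulate_uptake_curve(0.7, 0.05, 0.60, 0:30, 0.02)
  cmp <- compare_uptake_rate(fit_uptake_curve(d2), fit_uptake_curve(d1))
  expect_gt(cmp$delta_c, 0)
  expect_lt(cmp$p_value, 0.01)
})

test_that("maximum event use regresses on event size per period", {
  set.seed(14)
  curves <- tibble::tibble(period = rep(c("wet", "recovery"), each = 5),
                           amount_mm = rep(c(2, 5, 10, 20, 40), 2),
                           a = c(0.9 - 0.015 * c(2, 5, 10, 20, 40) + rnorm(5, 0, 0.01),
                                 rep(0.4, 5)))
  out <- max_use_vs_amount(curves)
  expect_lt(out$slope[out$period == "wet"], 0)
  expect_equal(out$slope[out$period == "recovery"], 0, tolerance = 1e-9)
  expect_warning(max_use_vs_amount(curves[c(1, 6:10), ]), "skipped")
})

test_that("period segmentation finds the five phases in order on a built trace", {
  days <- as.Date("2022-04-20") + 0:190
  n <- length(days)
  vwc <- c(seq(20, 19, length.out = 50),          # wet
           seq(18, 12.5, length.out = 25),        # dry-down
           seq(12.5, 10, length.out = 45),        # dry
           seq(10.5, 15.5, length.out = 30),      # recovery
           seq(16.5, 18, length.out = 41))        # final wet
  precip <- rep(0, n)
  precip[seq(3, 70, by = 6)] <- 8
  precip[c(90, 110)] <- 3
  precip[seq(121, 150, by = 7)] <- 15
  precip[seq(151, 191, by = 6)] <- 9
  env <- tibble::tibble(date = days, precip_mm = precip, vwc = vwc)
  seg <- segment_periods(env)
  expect_equal(seg$period, c("wet", "dry_down", "dry", "recovery", "final_wet"))
  # intervals partition the span without overlap
  expect_equal(seg$start[1], days[1])
  expect_equal(seg$end[nrow(seg)], days[n])
  expect_true(all(seg$start[-1] == seg$end[-nrow(seg)] + 1))
  # a label date inside the dry phase splits it
  seg_l <- segment_periods(env, label_date = seg$start[3] + 10)
  expect_true("post_label" %in% seg_l$period)
  # constant wet trace: a single wet period, with a warning about the rest
  envw <- tibble::tibble(date = days, precip_mm = precip, vwc = 20)
  expect_warning(segw <- segment_periods(envw), "partial")
  expect_equal(segw$period, "wet")
})

test_that("segmentation boundaries move monotonically with the dry threshold", {
  days <- as.Date("2022-04-20") + 0:120
  vwc <- seq(20, 8, length.out = length(days))
  env <- tibble::tibble(date = days, precip_mm = 0, vwc = vwc)
  onsets <- vapply(c(11, 13, 15), function(thr) {
    seg <- suppressWarnings(segment_periods(env, dry_vwc = thr))
    as.numeric(seg$start[seg$period == "dry"])
  }, numeric(1))
  expect_true(all(diff(onsets) <= 0))  # higher threshold -> earlier dry onset
})

test_that("posterior uncertainty propagates into derived statistics", {
  src <- two_source_set()
  obs <- data.frame(d2H = -55, d18O = -7.8, sd2H = 2, sd18O = 1)
  set.seed(15)
  f <- fit_mixture(obs, src)
  stat <- posterior_statistic(f, function(p) sum(p * c(0.05, 0.40)))
  expect_true(stat$q2.5 <= stat$mean && stat$mean <= stat$q97.5)
  expect_gte(stat$mean, 0.05)
  expect_lte(stat$mean, 0.40)
})
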