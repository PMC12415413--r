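test_that("depth sources carry the root-density prior and skip incomplete days", {
  soil <- tidyr::expand_grid(date = as.Date("2022-06-01") + 0:1,
                             depth = c(0.05, 0.20, 0.40, 0.90)) |>
    dplyr::mutate(d2H = -60 + 10 * depth, d18O = -9 + depth, sd2H = 2, sd18O = 1)
  src <- build_depth_sources(soil)
  expect_equal(unique(round(src$prior_weight[src$depth == 0.05], 4)), 0.2772)
  expect_equal(sum(src$prior_weight[src$day == src$day[1]]), 1, tolerance = 1e-9)
  # uniform densities give a uniform prior
  srcu <- build_depth_sources(soil, root_density = rep(1, 4))
  expect_true(all(abs(srcu$prior_weight - 0.25) < 1e-12))
  # one depth missing -> the day is skipped
  expect_message(src2 <- build_depth_sources(soil[-1, ]), "skipped")
  expect_equal(unique(src2$day), as.Date("2022-06-02"))
})

test_that("event sources weight amount over elapsed time from the first event day", {
  ev <- tibble::tibble(event_id = c("a", "b", "c"),
                       start_date = as.Date(c("2022-06-05", "2022-05-31", "2022-06-20")),
                       end_date = start_date + c(0, 2, 0),
                       amount_mm = c(10, 10, 5),
                       d2H = c(-50, -60, -40), d18O = c(-7, -8, -6),
                       sd2H = 2, sd18O = 1, label = FALSE)
  src <- build_event_sources(ev, as.Date("2022-06-10"))
  # 10 mm 5 days ago vs 10 mm 10 days ago -> weights 2:1; future event excluded
  expect_equal(src$prior_weight[src$source_id == "a"], 2 / 3, tolerance = 1e-12)
  expect_equal(src$prior_weight[src$source_id == "b"], 1 / 3, tolerance = 1e-12)
  expect_false("c" %in% src$source_id)
  # multi-day event b: age measured from its FIRST day
  expect_equal(src$age_days[src$source_id == "b"], 10)
  # same-day event: elapsed 0 maps to 1 -> 10/1 against 10/5 five days on
  src0 <- build_event_sources(ev, as.Date("2022-06-05"))
  expect_equal(src0$prior_weight[src0$source_id == "a"] /
                 src0$prior_weight[src0$source_id == "b"], 5, tolerance = 1e-12)
  expect_error(build_event_sources(ev[1, ], as.Date("2022-06-10")), "fewer than 2")
  expect_error(build_event_sources(ev, as.Date("2022-06-10"), lookback_days = 2),
               "fewer than 2")
})

test_that("a symmetric two-source problem has a symmetric posterior", {
  src <- two_source_set()
  obs <- data.frame(d2H = -60, d18O = -8.5, sd2H = 2, sd18O = 1)
  set.seed(1)
  f <- fit_mixture(obs, src, mcmc = mix_mcmc(iter = 4000, warmup = 1500))
  expect_equal(f$summary$mean, c(0.5, 0.5), tolerance = 0.02,
               ignore_attr = TRUE)
  # flat prior + symmetric sources: invariant under source relabeling
  src_r <- src[2:1, ]
  set.seed(1)
  f_r <- fit_mixture(obs, src_r, mcmc = mix_mcmc(iter = 4000, warmup = 1500))
  expect_equal(f$summary$mean[1], f_r$summary$mean[2], tolerance = 0.02)
})

test_that("posterior means match the simplex grid oracle within MC error", {
  set.seed(42)
  for (rep in 1:6) {
    J <- sample(2:3, 1)
    mode <- sample(c("dual", "d2H_only"), 1)
    mu2 <- sort(runif(J, -90, -25))
    src <- tibble::tibble(source_id = paste0("s", 1:J),
                          mean_d2H = mu2, mean_d18O = (mu2 - 8) / 7.8,
                          sd_d2H = 2, sd_d18O = 1,
                          prior_weight = rep(1 / J, J))
    p <- {w <- rgamma(J, 2); w / sum(w)}
    obs <- data.frame(d2H = sum(p * src$mean_d2H),
                      d18O = sum(p * src$mean_d18O), sd2H = 2, sd18O = 1)
    g <- mixture_grid_posterior(obs, src, tracer_mode = mode)
    f <- fit_mixture(obs, src, tracer_mode = mode, fix_errors = TRUE,
                     mcmc = mix_mcmc(chains = 4, iter = 6000, warmup = 2000))
    expect_equal(unname(f$summary$mean), unname(g$mean), tolerance = 0.02)
  }
})

test_that("an observation at a well-separated vertex is attributed to that source", {
  src <- tibble::tibble(source_id = c("a", "b", "c"),
                        mean_d2H = c(-90, -50, -10),
                        mean_d18O = c(-12, -7, -2),
                        sd_d2H = 2, sd_d18O = 1, prior_weight = rep(1 / 3, 3))
  obs <- data.frame(d2H = -90, d18O = -12, sd2H = 2, sd18O = 1)
  g <- mixture_grid_posterior(obs, src)
  expect_gt(g$mean[["a"]], 0.9)
  set.seed(2)
  f <- fit_mixture(obs, src, fix_errors = TRUE,
                   mcmc = mix_mcmc(iter = 6000, warmup = 2000))
  expect_gt(f$summary$mean[f$summary$source_id == "a"], 0.9)
})

test_that("an observation outside the source hull inflates the error-scale posterior", {
  src <- two_source_set()
  inside <- data.frame(d2H = -60, d18O = -8.5, sd2H = 2, sd18O = 1)
  outside <- data.frame(d2H = -130, d18O = -17, sd2H = 2, sd18O = 1)
  set.seed(3)
  f_in <- fit_mixture(inside, src, mcmc = mix_mcmc(iter = 4000, warmup = 1500))
  f_out <- fit_mixture(outside, src, mcmc = mix_mcmc(iter = 4000, warmup = 1500))
  expect_gt(mean(f_out$xi), mean(f_in$xi))
  expect_gt(mean(f_out$summary$sd), mean(f_in$summary$sd))
})

test_that("every posterior draw lies on the simplex", {
  set.seed(4)
  src <- two_source_set(d2H = c(-80, -40, -20), d18O = c(-11, -6, -3),
                        w = c(0.2, 0.5, 0.3))
  obs <- data.frame(d2H = -55, d18O = -7.5, sd2H = 2, sd18O = 1)
  f <- fit_mixture(obs, src)
  expect_true(all(f$draws >= 0))
  expect_equal(rowSums(f$draws), rep(1, nrow(f$draws)), tolerance = 1e-9)
  expect_equal(sum(f$summary$mean), 1, tolerance = 1e-9)
  expect_true(all(f$summary$sd >= 0))
})

test_that("a deuterium-labelled source is pinned more precisely than natural sources", {
  # matched two-source geometry: only the separation differs
  natural <- two_source_set(d2H = c(-70, -40), d18O = c(-8, -8))
  labelled <- two_source_set(d2H = c(800, -40), d18O = c(-8, -8))
  obs_nat <- data.frame(d2H = 0.3 * -70 + 0.7 * -40, d18O = -8, sd2H = 2, sd18O = 1)
  obs_lab <- data.frame(d2H = 0.3 * 800 + 0.7 * -40, d18O = -8, sd2H = 2, sd18O = 1)
  set.seed(5)
  f_nat <- fit_mixture(obs_nat, natural, mcmc = mix_mcmc(iter = 4000, warmup = 1500))
  f_lab <- fit_mixture(obs_lab, labelled, mcmc = mix_mcmc(iter = 4000, warmup = 1500))
  expect_lt(f_lab$summary$sd[1], f_nat$summary$sd[1])
  expect_equal(f_lab$summary$mean[1], 0.3, tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("parameter recovery holds at analytical noise for well-separated sources", {
  set.seed(6)
  errs <- replicate(20, {
    J <- 3
    mu2 <- c(-80, -55, -30)  # >= 20 permil apart
    src <- tibble::tibble(source_id = paste0("s", 1:J),
                          mean_d2H = mu2, mean_d18O = (mu2 - 8) / 7.8,
                          sd_d2H = 2, sd_d18O = 1, prior_weight = rep(1 / J, J))
    p <- {w <- rgamma(J, 2); w / sum(w)}
    obs <- data.frame(d2H = sum(p * src$mean_d2H) + rnorm(1, 0, 2),
                      d18O = sum(p * src$mean_d18O) + rnorm(1, 0, 1),
                      sd2H = 2, sd18O = 1)
    f <- fit_mixture(obs, src, mcmc = mix_mcmc(chains = 2, iter = 3000, warmup = 1000))
    mean(abs(f$summary$mean - p))
  })
  expect_lte(mean(errs), 0.10)
})

test_that("a mixture series is constant for constant inputs and fills day gaps on the simplex", {
  days <- as.Date("2022-06-01") + 0:9
  soil <- tidyr::expand_grid(date = days, depth = c(0.05, 0.20, 0.40, 0.90)) |>
    dplyr::mutate(d2H = c(-40, -55, -70, -85)[match(depth, c(0.05, 0.2, 0.4, 0.9))],
                  d18O = (d2H - 8) / 7.8, sd2H = 2, sd18O = 1)
  src <- build_depth_sources(soil)
  xylem <- tibble::tibble(date = days[c(1:4, 8:10)],  # days 5..7 unobserved
                          d2H = -60, d18O = (-60 - 8) / 7.8, sd2H = 2, sd18O = 1)
  set.seed(7)
  ser <- mixture_series(xylem, src, mcmc = mix_mcmc(chains = 2, iter = 2000, warmup = 800))
  expect_equal(sort(unique(ser$day)), days)
  sums <- ser |> dplyr::group_by(day) |> dplyr::summarise(s = sum(mean))
  expect_true(all(abs(sums$s - 1) < 1e-9))
  expect_true(all(ser$interpolated[ser$day == days[6]]))
  # stationarity: interpolated day means match the fitted-day means closely
  m_fit <- ser$mean[ser$day == days[4]]
  m_gap <- ser$mean[ser$day == days[6]]
  expect_equal(m_gap, m_fit, tolerance = 0.05)
})

test_that("non-convergence is reported, never silent", {
  src <- two_source_set()
  obs <- data.frame(d2H = -60, d18O = -8.5, sd2H = 2, sd18O = 1)
  set.seed(8)
  f <- fit_mixture(obs, src, mcmc = mix_mcmc(chains = 4, iter = 30, warmup = 10))
  expect_false(is.null(f$converged))
  expect_true(all(c("rhat", "ess") %in% names(f$summary)))
})
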