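#' MCMC settings for the mixing model
#'
#' @param chains Number of independent chains.
#' @param iter Iterations per chain (including warmup).
#' @param warmup Warmup (adaptation) iterations discarded per chain.
#' @param thin Thinning interval for saved draws.
#' @return A list of class `mix_mcmc`.
#' @export
mix_mcmc <- function(chains = 4, iter = 2000, warmup = floor(iter / 2), thin = 1) {
  stopifnot(chains >= 1, iter > warmup, warmup >= 1, thin >= 1)
  structure(list(chains = chains, iter = iter, warmup = warmup, thin = thin),
            class = "mix_mcmc")
}

#' Build per-day soil-depth source sets with root-density priors
#'
#' One source per measurement depth and day, with Dirichlet prior weights
#' proportional to the root-density distribution. The default densities place
#' 28%, 30% and 42% of roots at 0.05, 0.20 and 0.40 m (scaled by 0.99) plus
#' an assumed 1% at 0.90 m, i.e. (0.2772, 0.2970, 0.4158, 0.0100) after
#' renormalisation.
#'
#' @param soil_daily Aligned daily soil tibble ([align_daily()] output for the
#'   soil pool): columns `date`, `depth`, `d2H`, `d18O`, `sd2H`, `sd18O`.
#' @param root_density Named (by depth) or positionally matched nonnegative
#'   weights, one per configured depth.
#' @param depths Depth grid (m).
#' @return Tibble with one row per day and source: `day`, `source_id`,
#'   `depth`, `mean_d2H`, `mean_d18O`, `sd_d2H`, `sd_d18O`, `prior_weight`.
#'   Days missing any depth are dropped with a message.
#' @export
build_depth_sources <- function(soil_daily,
                                root_density = default_root_density(),
                                depths = c(0.05, 0.20, 0.40, 0.90)) {
  check_depth_grid(depths)
  if (length(root_density) != length(depths) || any(root_density < 0)) {
    stop("root_density must be nonnegative, one value per depth", call. = FALSE)
  }
  w <- root_density / sum(root_density)
  prior <- tibble::tibble(depth = depths, prior_weight = unname(w),
                          source_id = sprintf("depth_%.2f", depths))
  src <- soil_daily |>
    dplyr::filter(!is.na(.data$d2H), !is.na(.data$d18O)) |>
    dplyr::inner_join(prior, by = "depth") |>
    dplyr::transmute(day = .data$date, source_id = .data$source_id,
                     depth = .data$depth, mean_d2H = .data$d2H,
                     mean_d18O = .data$d18O, sd_d2H = .data$sd2H,
                     sd_d18O = .data$sd18O, prior_weight = .data$prior_weight)
  complete_days <- src |>
    dplyr::count(.data$day) |>
    dplyr::filter(.data$n == length(depths))
  dropped <- dplyr::n_distinct(src$day) - nrow(complete_days)
  if (dropped > 0) {
    message(dropped, " day(s) skipped: not all depths present")
  }
  dplyr::semi_join(src, complete_days, by = "day") |>
    dplyr::arrange(.data$day, .data$depth)
}

#' Default root-density prior weights
#'
#' Relative root density of 28/30/42% in the upper 0.40 m (at 0.05, 0.20 and
#' 0.40 m) scaled by 0.99, plus an assumed 1% at 0.90 m.
#'
#' @return Named numeric vector over the four depths, summing to 1.
#' @export
default_root_density <- function() {
  c(`0.05` = 0.2772, `0.20` = 0.2970, `0.40` = 0.4158, `0.90` = 0.0100)
}

#' Build a precipitation-event source set for one day
#'
#' Events are weighted by amount divided by elapsed time: the prior weight of
#' event j is proportional to `amount_j / max(day - first_day_j, 1)` in days.
#' The age of a multi-day event is counted from its first day; only events
#' whose first day is on or before `day` are eligible (causality).
#'
#' @param events Event tibble ([read_precip_events()] format).
#' @param day Focal date.
#' @param lookback_days Events older than this are excluded; `NULL` (default)
#'   keeps the whole record.
#' @return Tibble: `day`, `source_id`, `first_day`, `amount_mm`, `age_days`,
#'   `mean_d2H`, `mean_d18O`, `sd_d2H`, `sd_d18O`, `prior_weight`, `label`.
#' @export
build_event_sources <- function(events, day, lookback_days = NULL) {
  day <- as.Date(day)
  el <- events |>
    dplyr::mutate(age_days = as.numeric(day - .data$start_date)) |>
    dplyr::filter(.data$age_days >= 0)
  if (!is.null(lookback_days)) {
    el <- dplyr::filter(el, .data$age_days <= lookback_days)
  }
  if (nrow(el) < 2) {
    stop("fewer than 2 eligible precipitation events on ", format(day), call. = FALSE)
  }
  el |>
    dplyr::mutate(prior_weight = .data$amount_mm / pmax(.data$age_days, 1),
                  prior_weight = .data$prior_weight / sum(.data$prior_weight)) |>
    dplyr::transmute(day = day, source_id = .data$event_id,
                     first_day = .data$start_date, amount_mm = .data$amount_mm,
                     age_days = .data$age_days,
                     mean_d2H = .data$d2H, mean_d18O = .data$d18O,
                     sd_d2H = .data$sd2H, sd_d18O = .data$sd18O,
                     prior_weight = .data$prior_weight, label = .data$label)
}

#' Fit the Bayesian mixing model for one day
#'
#' Infers the posterior of the source contribution vector p (on the simplex)
#' for one or more xylem observations, under the observation model
#' `x ~ Normal(sum_j p_j mu_j, xi * sum_j p_j^2 sigma_j^2 + tau^2)` per
#' tracer (process error scaled by the fitted factor xi plus an additive
#' residual variance) and a Dirichlet prior `p ~ Dir(alpha * w)` with `w` the
#' normalised prior weights. Sampling is by adaptive Metropolis-within-Gibbs
#' on softmax-transformed contributions; split-chain R-hat and effective
#' sample size are reported and the fit is flagged when R-hat exceeds
#' `rhat_max`.
#'
#' @param xylem Data frame of xylem observations for the day (columns `d2H`
#'   and, in dual mode, `d18O`; optional `sd2H`, `sd18O` setting the residual
#'   prior medians; defaults 2 and 1 per mil).
#' @param sources Source set tibble (one day) as built by
#'   [build_depth_sources()] or [build_event_sources()].
#' @param tracer_mode `"dual"` (both tracers) or `"d2H_only"`.
#' @param alpha Dirichlet concentration; the prior is `Dir(alpha * w)`.
#'   Default: the number of sources (informative mean, weak strength).
#' @param mcmc A [mix_mcmc()] settings object.
#' @param fix_errors If `TRUE`, fix the error scales at `xi` and `tau`
#'   instead of sampling them (used e.g. for exact comparison against the
#'   deterministic grid posterior).
#' @param xi,tau Fixed error scales when `fix_errors = TRUE` (`tau` per
#'   tracer; defaults to the residual prior medians).
#' @param rhat_max Convergence flag threshold for split-chain R-hat.
#' @return An object of class `mixture_fit`.
#' @export
fit_mixture <- function(xylem, sources, tracer_mode = c("dual", "d2H_only"),
                        alpha = NULL, mcmc = mix_mcmc(),
                        fix_errors = FALSE, xi = 1, tau = NULL,
                        rhat_max = 1.05) {
  tracer_mode <- match.arg(tracer_mode)
  stopifnot(inherits(mcmc, "mix_mcmc"))
  if (nrow(sources) < 2) stop("need at least 2 sources", call. = FALSE)
  xylem <- as.data.frame(xylem)
  if (nrow(xylem) < 1) stop("need at least 1 xylem observation", call. = FALSE)
  tracers <- if (tracer_mode == "dual") c("d2H", "d18O") else "d2H"
  K <- length(tracers)
  J <- nrow(sources)

  x <- as.matrix(xylem[, tracers, drop = FALSE])
  if (any(!is.finite(x))) stop("non-finite xylem observation", call. = FALSE)
  mu <- as.matrix(sources[, paste0("mean_", tracers), drop = FALSE])
  s2 <- as.matrix(sources[, paste0("sd_", tracers), drop = FALSE])^2
  if (any(s2 <= 0)) stop("source sds must be positive", call. = FALSE)

  tau0 <- vapply(tracers, function(tr) {
    cc <- paste0("sd", sub("d", "", tr))  # sd2H / sd18O
    if (cc %in% names(xylem)) mean(xylem[[cc]]) else c(d2H = 2, d18O = 1)[[tr]]
  }, numeric(1))
  if (is.null(tau)) tau <- tau0
  w <- sources$prior_weight / sum(sources$prior_weight)
  if (is.null(alpha)) alpha <- J
  alpha_vec <- alpha * w

  draws <- mix_sampler_cpp(x, mu, s2, alpha_vec, tau0, fix_errors,
                           xi, tau, mcmc$chains, mcmc$iter, mcmc$warmup,
                           mcmc$thin)
  p_arr <- draws$p  # n_save x J x chains
  n_save <- dim(p_arr)[1]
  rhat <- vapply(seq_len(J), function(j) split_rhat(p_arr[, j, , drop = TRUE]),
                 numeric(1))
  ess <- vapply(seq_len(J), function(j) ess_mean(p_arr[, j, , drop = TRUE]),
                numeric(1))
  # pool chains: reorder to (draw, chain, source) before flattening
  pooled <- matrix(aperm(p_arr, c(1, 3, 2)), nrow = n_save * mcmc$chains,
                   ncol = J)
  colnames(pooled) <- sources$source_id
  summary <- tibble::tibble(
    source_id = sources$source_id,
    prior_weight = w,
    mean = colMeans(pooled),
    sd = apply(pooled, 2, sd),
    q2.5 = apply(pooled, 2, quantile, 0.025),
    q97.5 = apply(pooled, 2, quantile, 0.975),
    rhat = rhat, ess = ess)
  converged <- all(is.finite(rhat)) && max(rhat, na.rm = TRUE) < rhat_max
  structure(list(
    summary = summary, draws = pooled, draws_chains = p_arr,
    xi = as.matrix(draws$xi), tau = draws$tau, lp = draws$lp,
    accept = draws$accept, sources = sources, tracers = tracers,
    mcmc = mcmc, fix_errors = fix_errors, converged = converged,
    rhat_max = rhat_max), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Bayesian mixing model fit (", length(x$tracers), " tracer(s), ",
      nrow(x$summary), " sources, ", nrow(x$draws), " draws)\n", sep = "")
  if (!x$converged) cat("** convergence flag: max R-hat ",
                        round(max(x$summary$rhat), 3), " >= ", x$rhat_max, "\n", sep = "")
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}

#' @rdname fit_mixture
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @method tidy mixture_fit
#' @export
tidy.mixture_fit <- function(x, ...) x$summary

#' @rdname fit_mixture
#' @method glance mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(
    n_sources = nrow(x$summary), n_draws = nrow(x$draws),
    n_chains = x$mcmc$chains,
    xi_mean = if (x$fix_errors) NA_real_ else mean(x$xi),
    max_rhat = max(x$summary$rhat), min_ess = min(x$summary$ess),
    accept_rate = mean(x$accept), converged = x$converged)
}

#' Deterministic grid-integration posterior for the mixing model
#'
#' Integrates the same likelihood and Dirichlet prior as [fit_mixture()]
#' (with the error scales held fixed) over a regular simplex grid, giving a
#' sampler-free posterior mean of the contributions. Grid points sit half a
#' cell inside the simplex (midpoint rule), avoiding the boundary, where the
#' Dirichlet density may be unbounded, while still covering vertex-adjacent
#' mass. Intended for few sources (~`(1/resolution)^(J-1)` points).
#'
#' @inheritParams fit_mixture
#' @param resolution Grid spacing on the simplex (default 0.01).
#' @return A list: `mean` (posterior-mean contributions), `grid` (tibble of
#'   grid points and normalised posterior weights).
#' @export
mixture_grid_posterior <- function(xylem, sources,
                                   tracer_mode = c("dual", "d2H_only"),
                                   alpha = NULL, xi = 1, tau = NULL,
                                   resolution = 0.01) {
  tracer_mode <- match.arg(tracer_mode)
  tracers <- if (tracer_mode == "dual") c("d2H", "d18O") else "d2H"
  xylem <- as.data.frame(xylem)
  J <- nrow(sources)
  x <- as.matrix(xylem[, tracers, drop = FALSE])
  mu <- as.matrix(sources[, paste0("mean_", tracers), drop = FALSE])
  s2 <- as.matrix(sources[, paste0("sd_", tracers), drop = FALSE])^2
  if (is.null(tau)) {
    tau <- vapply(tracers, function(tr) c(d2H = 2, d18O = 1)[[tr]], numeric(1))
  }
  w <- sources$prior_weight / sum(sources$prior_weight)
  if (is.null(alpha)) alpha <- J
  alpha_vec <- alpha * w

  P <- simplex_grid(J, resolution)
  loglik <- rep(0, nrow(P))
  for (k in seq_along(tracers)) {
    m <- as.vector(P %*% mu[, k])
    v <- xi * as.vector(P^2 %*% s2[, k]) + tau[k]^2
    for (i in seq_len(nrow(x))) {
      loglik <- loglik + dnorm(x[i, k], m, sqrt(v), log = TRUE)
    }
  }
  logprior <- as.vector(log(P) %*% (alpha_vec - 1))
  lw <- loglik + logprior
  wts <- exp(lw - max(lw))
  wts <- wts / sum(wts)
  mean <- as.vector(t(P) %*% wts)
  names(mean) <- sources$source_id
  grid <- tibble::as_tibble(as.data.frame(P))
  names(grid) <- sources$source_id
  grid$weight <- wts
  list(mean = mean, grid = grid, resolution = resolution)
}

# midpoint-rule grid: compositions of N shifted half a cell into the
# interior, so vertex-adjacent mass is covered without touching the boundary
simplex_grid <- function(J, resolution) {
  N <- round(1 / resolution)
  if (J == 2) {
    n1 <- 0:N
    P <- cbind(n1, N - n1)
  } else {
    parts <- function(total, j) {
      if (j == 1) return(matrix(total, ncol = 1))
      out <- lapply(0:total, function(n1) {
        rest <- parts(total - n1, j - 1)
        cbind(n1, rest)
      })
      do.call(rbind, out)
    }
    P <- parts(N, J)
  }
  unname((P + 0.5) / (N + J / 2))
}

#' Fit the mixing model day by day over a campaign
#'
#' Runs [fit_mixture()] for every day with xylem observations and an
#' available source set, then linearly interpolates the posterior-mean
#' contributions across days without fits and re-projects them onto the
#' simplex (renormalisation). Interpolated rows carry `interpolated = TRUE`
#' and no convergence diagnostics.
#'
#' @param xylem_daily Aligned daily xylem tibble (columns `date`, `d2H`,
#'   `d18O`, `sd2H`, `sd18O`); one row per day (or per tree and day if a
#'   `tree_id` column is present, fitted independently).
#' @param sources Either a source tibble with a `day` column covering many
#'   days, or a function `function(day)` returning the source set for a day
#'   (or `NULL`/error to skip it).
#' @param days Days to cover in the output grid; default the full span of
#'   `xylem_daily`.
#' @inheritParams fit_mixture
#' @param pool_trees If `TRUE` and a `tree_id` column is present, all trees'
#'   observations on a day enter one pooled likelihood instead of independent
#'   per-tree fits.
#' @param verbose Print a progress message every 25 days.
#' @return A tibble of class `mixture_series`: one row per day and source
#'   with posterior `mean`, `sd`, `rhat`, `ess`, `converged`, `interpolated`.
#' @export
mixture_series <- function(xylem_daily, sources, days = NULL,
                           tracer_mode = c("dual", "d2H_only"), alpha = NULL,
                           mcmc = mix_mcmc(), fix_errors = FALSE, xi = 1,
                           tau = NULL, rhat_max = 1.05, pool_trees = FALSE,
                           verbose = FALSE) {
  tracer_mode <- match.arg(tracer_mode)
  if (is.null(days)) {
    days <- seq(min(xylem_daily$date), max(xylem_daily$date), by = "day")
  }
  if (!pool_trees && "tree_id" %in% names(xylem_daily) &&
      dplyr::n_distinct(xylem_daily$tree_id) > 1) {
    out <- xylem_daily |>
      dplyr::group_split(.data$tree_id) |>
      purrr::map(function(g) {
        mixture_series(dplyr::select(g, -"tree_id"), sources, days = days,
                       tracer_mode = tracer_mode, alpha = alpha, mcmc = mcmc,
                       fix_errors = fix_errors, xi = xi, tau = tau,
                       rhat_max = rhat_max, pool_trees = pool_trees,
                       verbose = verbose) |>
          dplyr::mutate(tree_id = g$tree_id[1], .before = 1)
      }) |>
      dplyr::bind_rows()
    class(out) <- c("mixture_series", class(out))
    return(out)
  }
  get_sources <- if (is.function(sources)) {
    function(d) tryCatch(sources(d), error = function(e) NULL)
  } else {
    function(d) {
      s <- dplyr::filter(sources, .data$day == d)
      if (nrow(s) >= 2) s else NULL
    }
  }
  have_obs <- !is.na(xylem_daily$d2H)
  if (tracer_mode == "dual") have_obs <- have_obs & !is.na(xylem_daily$d18O)
  if ("interpolated" %in% names(xylem_daily)) {
    have_obs <- have_obs & !xylem_daily$interpolated
  }
  obs_days <- sort(unique(xylem_daily$date[have_obs]))
  obs_days <- obs_days[obs_days %in% days]

  fits <- purrr::map(seq_along(obs_days), function(i) {
    d <- obs_days[i]
    if (verbose && i %% 25 == 0) message("  day ", i, "/", length(obs_days))
    src <- get_sources(d)
    if (is.null(src)) return(NULL)
    obs <- xylem_daily[xylem_daily$date == d & have_obs, ]
    fit <- fit_mixture(obs, src, tracer_mode = tracer_mode, alpha = alpha,
                       mcmc = mcmc, fix_errors = fix_errors, xi = xi,
                       tau = tau, rhat_max = rhat_max)
    fit$summary |>
      dplyr::mutate(day = d, converged = fit$converged, .before = 1)
  })
  fitted <- dplyr::bind_rows(fits)
  if (nrow(fitted) == 0) stop("no day could be fitted", call. = FALSE)

  out <- interpolate_contributions(fitted, days)
  class(out) <- c("mixture_series", class(out))
  out
}

# linear interpolation of posterior means over a daily grid, then simplex
# re-projection; sds interpolated alongside for continuity of uncertainty
interpolate_contributions <- function(fitted, days) {
  full <- tidyr::expand_grid(day = as.Date(days),
                             source_id = unique(fitted$source_id)) |>
    dplyr::left_join(fitted, by = c("day", "source_id")) |>
    dplyr::arrange(.data$source_id, .data$day)
  full <- full |>
    dplyr::group_by(.data$source_id) |>
    dplyr::mutate(
      interpolated = is.na(.data$mean),
      mean = interp_no_cap(.data$day, .data$mean),
      sd = interp_no_cap(.data$day, .data$sd)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$mean))
  full |>
    dplyr::group_by(.data$day) |>
    dplyr::mutate(mean = .data$mean / sum(.data$mean)) |>
    dplyr::ungroup()
}

interp_no_cap <- function(dates, values) {
  obs <- which(!is.na(values))
  if (length(obs) < 2) return(values)
  approx(as.numeric(dates)[obs], values[obs], xout = as.numeric(dates),
         method = "linear", rule = 1, ties = mean)$y
}

# ---- convergence diagnostics ------------------------------------------------

# split-chain potential scale reduction factor
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(xs); nn <- nrow(xs)
  means <- colMeans(xs)
  vars <- apply(xs, 2, var)
  if (all(vars < 1e-300)) return(1)
  B <- nn * var(means)
  W <- mean(vars)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# effective sample size for the mean, pooled over chains, with Geyer-style
# truncation at the first negative paired autocorrelation
ess_mean <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(NA_real_)
  acfs <- apply(x, 2, function(ch) {
    if (var(ch) < 1e-300) return(rep(0, min(n - 1, 200)))
    as.numeric(stats::acf(ch, lag.max = min(n - 1, 200), plot = FALSE,
                          demean = TRUE)$acf)[-1]
  })
  rho <- rowMeans(as.matrix(acfs))
  s <- 0
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  max(m * n / (1 + 2 * s), 1)
}
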