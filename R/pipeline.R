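#' Pipeline configuration
#'
#' One structured configuration for an end-to-end run: synthetic-campaign
#' scenario (or an input directory of previously written campaign CSVs),
#' MCMC settings, mixing modes and derivation options.
#'
#' @param scenario A [scenario_config()] for the simulate stage; ignored when
#'   `input_dir` is given.
#' @param input_dir Optional directory of campaign CSVs ([write_campaign()]
#'   layout) to analyse instead of simulating.
#' @param mcmc A [mix_mcmc()].
#' @param modes Mixing configurations to run: subset of `"depth"`, `"events"`.
#' @param tracer_mode Passed to [mixture_series()].
#' @param lookback_days Event-source lookback; `NULL` keeps the whole record.
#' @param transit_threshold Contribution threshold for transit times.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = scenario_config(), input_dir = NULL,
                            mcmc = mix_mcmc(chains = 2, iter = 1500, warmup = 500),
                            modes = c("depth", "events"),
                            tracer_mode = "dual", lookback_days = NULL,
                            transit_threshold = 0.10) {
  modes <- match.arg(modes, several.ok = TRUE)
  structure(list(scenario = scenario, input_dir = input_dir, mcmc = mcmc,
                 modes = modes, tracer_mode = tracer_mode,
                 lookback_days = lookback_days,
                 transit_threshold = transit_threshold),
            class = "pipeline_config")
}

#' Read pipeline options from a YAML file
#'
#' Recognised top-level keys mirror the [pipeline_config()] and
#' [scenario_config()] arguments (`n_trees`, `start`, `end`, `missing_frac`,
#' `chains`, `iter`, `warmup`, `modes`, `input_dir`, `lookback_days`,
#' `transit_threshold`). Unknown keys are an error, so a malformed
#' configuration fails before any stage runs.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("n_trees", "start", "end", "missing_frac", "chains", "iter",
             "warmup", "modes", "input_dir", "lookback_days",
             "transit_threshold")
  bad <- setdiff(names(y), known)
  if (length(bad) > 0) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sc_args <- y[intersect(names(y), c("n_trees", "start", "end", "missing_frac"))]
  scenario <- do.call(scenario_config, sc_args)
  mc <- mix_mcmc(chains = y$chains %||% 2, iter = y$iter %||% 1500,
                 warmup = y$warmup %||% 500)
  pipeline_config(scenario = scenario, input_dir = y$input_dir, mcmc = mc,
                  modes = y$modes %||% c("depth", "events"),
                  lookback_days = y$lookback_days,
                  transit_threshold = y$transit_threshold %||% 0.10)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> validate -> sap flow -> mixing -> derived
#' quantities as one reproducible run. Each stage's outputs land under a
#' run-scoped directory; a failing stage halts everything downstream, with
#' partial outputs retained and the failure recorded in the manifest. No
#' stage mutates its inputs.
#'
#' @param config A [pipeline_config()] or path to a YAML file.
#' @param out_dir Run directory (created; must not exist or be empty other
#'   than previous runs' files, which are overwritten).
#' @param seed Integer seed for the simulate and sampling stages.
#' @return A list: `manifest` (tibble: stage, status, elapsed_s, detail),
#'   `results` (in-memory stage outputs), `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run"),
                         seed = 1) {
  if (is.character(config)) config <- pipeline_config_yaml(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  results <- list()
  failed <- FALSE

  stage <- function(name, fun) {
    if (failed) {
      manifest[[length(manifest) + 1]] <<- tibble::tibble(
        stage = name, status = "skipped", elapsed_s = 0, detail = "upstream failure")
      return(invisible(NULL))
    }
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) structure(list(msg = conditionMessage(e)),
                                                         class = "stage_error"))
    el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(res, "stage_error")) {
      failed <<- TRUE
      manifest[[length(manifest) + 1]] <<- tibble::tibble(
        stage = name, status = "failed", elapsed_s = round(el, 2), detail = res$msg)
    } else {
      results[[name]] <<- res
      manifest[[length(manifest) + 1]] <<- tibble::tibble(
        stage = name, status = "ok", elapsed_s = round(el, 2), detail = "")
    }
    invisible(res)
  }

  input_dir <- config$input_dir
  stage("simulate", function() {
    if (!is.null(input_dir)) return("inputs supplied")
    camp <- simulate_campaign(config$scenario, seed = seed)
    d <- file.path(out_dir, "inputs")
    write_campaign(camp, d)
    input_dir <<- d
    camp
  })

  stage("validate", function() {
    list(
      xylem = read_isotope_table(file.path(input_dir, "xylem_isotopes.csv"), "xylem"),
      soil = read_isotope_table(file.path(input_dir, "soil_isotopes.csv"), "soil"),
      events = read_precip_events(file.path(input_dir, "precip_events.csv")),
      env_daily = read_env_table(file.path(input_dir, "env_daily.csv")),
      env_hourly = readr::read_csv(file.path(input_dir, "env_hourly.csv"),
                                   col_types = readr::cols(
                                     timestamp = readr::col_datetime(format = ""),
                                     .default = readr::col_double()),
                                   progress = FALSE),
      heat_pulse = readr::read_csv(file.path(input_dir, "heat_pulse.csv"),
                                   col_types = readr::cols(
                                     timestamp = readr::col_datetime(format = ""),
                                     tree_id = readr::col_character(),
                                     .default = readr::col_double()),
                                   progress = FALSE))
  })

  stage("sapflow", function() {
    v <- results$validate
    scfg <- if (is.list(results$simulate)) results$simulate$config$sapflow_cfg
            else sapflow_config()
    sf <- compute_sapflow(v$heat_pulse, v$env_hourly, scfg)
    readr::write_csv(sf$tree_daily, file.path(out_dir, "sapflow_tree_daily.csv"),
                     progress = FALSE)
    readr::write_csv(sf$stand_daily, file.path(out_dir, "transpiration_daily.csv"),
                     progress = FALSE)
    sf
  })

  stage("align", function() {
    v <- results$validate
    list(xylem = align_daily(v$xylem), soil = align_daily(v$soil))
  })

  if ("depth" %in% config$modes) {
    stage("mix_depth", function() {
      al <- results$align
      src <- build_depth_sources(al$soil)
      set.seed(seed + 1)
      ser <- mixture_series(al$xylem, src, tracer_mode = config$tracer_mode,
                            mcmc = config$mcmc)
      readr::write_csv(ser, file.path(out_dir, "contributions_depth.csv"),
                       progress = FALSE)
      ser
    })
  }

  if ("events" %in% config$modes) {
    stage("mix_events", function() {
      al <- results$align
      ev <- results$validate$events
      builder <- function(day) build_event_sources(ev, day, config$lookback_days)
      set.seed(seed + 2)
      ser <- mixture_series(al$xylem, builder, tracer_mode = config$tracer_mode,
                            mcmc = config$mcmc)
      readr::write_csv(ser, file.path(out_dir, "contributions_events.csv"),
                       progress = FALSE)
      ser
    })
  }

  stage("derive", function() {
    out <- list()
    sf <- results$sapflow
    if (!is.null(results$mix_depth)) {
      dep <- results$mix_depth |>
        dplyr::mutate(depth = as.numeric(sub("depth_", "", .data$source_id)))
      out$mean_depth <- mean_rwu_depth(dep)
      readr::write_csv(out$mean_depth, file.path(out_dir, "mean_rwu_depth.csv"),
                       progress = FALSE)
      stand <- sf$tree_daily |>
        dplyr::group_by(.data$date) |>
        dplyr::summarise(sapflow_l_d = mean(.data$sapflow_l_d), .groups = "drop")
      out$absolute_uptake <- absolute_uptake(dep, stand)
      readr::write_csv(out$absolute_uptake,
                       file.path(out_dir, "absolute_uptake_depth.csv"),
                       progress = FALSE)
    }
    if (!is.null(results$mix_events)) {
      ev <- results$validate$events
      out$transit_times <- results$mix_events |>
        dplyr::left_join(dplyr::select(ev, source_id = "event_id",
                                       "start_date", "amount_mm"),
                         by = "source_id") |>
        dplyr::filter(.data$day >= .data$start_date) |>
        dplyr::group_by(.data$source_id, .data$amount_mm) |>
        dplyr::summarise(
          transit_days = transit_time(dplyr::pick("day", "mean"),
                                      threshold = config$transit_threshold),
          .groups = "drop")
      readr::write_csv(out$transit_times, file.path(out_dir, "transit_times.csv"),
                       progress = FALSE)
    }
    env <- results$validate$env_daily |>
      dplyr::filter(.data$date >= min(results$align$xylem$date))
    out$periods <- tryCatch(segment_periods(env), warning = function(w) {
      suppressWarnings(segment_periods(env))
    })
    readr::write_csv(out$periods, file.path(out_dir, "periods.csv"),
                     progress = FALSE)
    out
  })

  manifest <- dplyr::bind_rows(manifest)
  inv <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  inv <- inv[grepl("\\.csv$", inv)]
  digests <- tibble::tibble(file = sub(paste0("^", out_dir, "/?"), "", inv),
                            md5 = unname(tools::md5sum(inv)))
  manifest_out <- manifest
  manifest_out$seed <- seed
  readr::write_csv(manifest_out, file.path(out_dir, "manifest.csv"), progress = FALSE)
  readr::write_csv(digests, file.path(out_dir, "digests.csv"), progress = FALSE)
  list(manifest = manifest, digests = digests, results = results,
       out_dir = out_dir, seed = seed)
}
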