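# Shared fixtures, built in code.

# a short, light campaign for integration-style tests
small_scenario <- function(...) {
  scenario_config(
    start = as.Date("2022-06-01"), end = as.Date("2022-07-20"),
    n_trees = 3, n_profiles = 2, missing_frac = 0.2,
    ...
  )
}

# memoise campaigns within a test run (simulation is deterministic per seed)
.camp_cache <- new.env(parent = emptyenv())
cached_campaign <- function(seed, cfg = scenario_config()) {
  key <- paste0("s", seed, "_", substr(digest_cfg(cfg), 1, 8))
  if (is.null(.camp_cache[[key]])) {
    .camp_cache[[key]] <- simulate_campaign(cfg, seed = seed)
  }
  .camp_cache[[key]]
}
digest_cfg <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f)
  unname(tools::md5sum(f))
}

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

two_source_set <- function(d2H = c(-80, -40), d18O = c(-11, -6),
                           sd2H = 2, sd18O = 1, w = c(0.5, 0.5)) {
  tibble::tibble(source_id = paste0("s", seq_along(d2H)),
                 mean_d2H = d2H, mean_d18O = d18O,
                 sd_d2H = sd2H, sd_d18O = sd18O,
                 prior_weight = w / sum(w))
}
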