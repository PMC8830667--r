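test_that("the worked-example fixture runs end to end to its frozen estimate", {
  wx <- worked_example()
  run <- run_scenario(worked_scenario_config())
  expect_equal(nrow(run$results), 1)
  expect_equal(run$results$coverage, wx$coverage)
  expect_equal(run$aggregate$coverage, wx$coverage)
  expect_true(run$results$valid)
  # audit trail carries every calibration intermediate
  expect_true(all(c("test_uncal", "calib_uncal", "worst_uncal", "slope",
                    "intercept", "floor_coverage", "headroom", "residual")
                  %in% names(run$audit)))
  expect_equal(run$audit$slope, wx$slope)
  expect_equal(run$audit$residual, wx$residual)
  # provenance logs the priority used per barrier
  expect_equal(run$provenance$priority_used, c(1L, 1L))
})

test_that("testing the calibration presentation itself yields zero gain", {
  config <- worked_scenario_config()
  config$tests <- "calib"
  run <- run_scenario(config)
  expect_equal(run$aggregate$delta_pp, 0, tolerance = 1e-9)

  synth <- synthetic_scenario_config(synthetic_spec(n_countries = 5, seed = 21))
  synth$tests <- "calibration_sc"
  run_synth <- run_scenario(synth)
  expect_equal(run_synth$aggregate$delta_pp, 0, tolerance = 1e-7)
})

test_that("a perfect single-dose presentation reaches each region's threshold", {
  synth <- synthetic_scenario_config(synthetic_spec(n_countries = 5, seed = 22))
  barriers <- synth$barriers
  synth$presentations$perfect <- vaccine_presentation(
    rep(1, length(barriers)), doses = 1, barrier_ids = barriers)
  synth$tests <- "perfect"
  run <- run_scenario(synth)
  expect_equal(run$results$coverage, synth$regions$max_coverage,
               tolerance = 1e-12)
})

test_that("scenario runs are deterministic given identical inputs", {
  config <- synthetic_scenario_config(synthetic_spec(n_countries = 6, seed = 9))
  run1 <- run_scenario(config)
  run2 <- run_scenario(config)
  expect_identical(run1$results, run2$results)
  expect_identical(run1$audit, run2$audit)
})

test_that("config validation rejects incomplete or oversized setups", {
  config <- worked_scenario_config()
  config$regions <- NULL
  expect_error(run_scenario(config), "missing field",
               class = "vaximpact_validation_error")
  config2 <- worked_scenario_config()
  config2$sensitivity <- list(a = 1, b = 1, c = 1, d = 1)
  expect_error(run_scenario(config2), "at most 3",
               class = "vaximpact_validation_error")
  config3 <- worked_scenario_config()
  config3$tests <- "nonexistent"
  expect_error(run_scenario(config3), "nonexistent",
               class = "vaximpact_validation_error")
})

test_that("configs round-trip through YAML with relative paths", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(n_countries = 4, seed = 31)
  generate_dataset(spec, dir = dir)
  config_path <- file.path(dir, "scenario.yaml")
  yaml::write_yaml(list(
    barriers = spec$barrier_ids,
    rubric = "default",
    regions = "regions.csv",
    indicators = "indicators.csv",
    presentations = "presentations.csv",
    doses = "presentation_doses.csv",
    calibration = "calibration_sc",
    tests = list("test_minimum", "test_optimal"),
    d_worst = 4), config_path)
  config <- read_scenario_config(config_path)
  run <- run_scenario(config, out_dir = file.path(dir, "out"))
  expect_equal(nrow(run$results), 8)
  for (f in c("results.csv", "ranking.csv", "equity.csv", "provenance.csv",
              "aggregate.json", "audit.json")) {
    expect_true(file.exists(file.path(dir, "out", f)), info = f)
  }
  aggregate <- jsonlite::read_json(file.path(dir, "out", "aggregate.json"),
                                   simplifyVector = TRUE)
  expect_equal(aggregate$coverage, run$aggregate$coverage)
})

test_that("sensitivity sweeps cover the parameter grid in long format", {
  config <- synthetic_scenario_config(synthetic_spec(n_countries = 5, seed = 41))
  config$sensitivity <- list(d_worst = c(4L, 6L),
                             routine_share = c(0.7, 0.8, 0.9))
  sweep <- sensitivity_sweep(config)
  # 2 x 3 grid, two test presentations per combination
  expect_equal(nrow(sweep), 12)
  expect_true(all(c("d_worst", "routine_share") %in% names(sweep)))

  # raising the maximum-coverage threshold never lowers the aggregate
  config$sensitivity <- list(max_coverage = c(0.96, 0.98, 1.0))
  sweep_m <- sensitivity_sweep(config)
  for (id in unique(sweep_m$presentation_id)) {
    cov <- sweep_m$coverage[sweep_m$presentation_id == id]
    expect_true(all(diff(cov) >= -1e-12))
  }

  # sweeping the dose count of the worst case cannot change the estimate:
  # it cancels between the headroom and the residual risk
  config$sensitivity <- list(d_worst = c(2L, 4L, 8L))
  sweep_d <- sensitivity_sweep(config)
  for (id in unique(sweep_d$presentation_id)) {
    cov <- sweep_d$coverage[sweep_d$presentation_id == id]
    expect_equal(max(cov) - min(cov), 0, tolerance = 1e-12)
  }

  config$sensitivity <- list()
  expect_error(sensitivity_sweep(config), "no `sensitivity`",
               class = "vaximpact_validation_error")
  config$sensitivity <- list(d_worst = numeric(0))
  expect_error(sensitivity_sweep(config), "empty sensitivity grid",
               class = "vaximpact_validation_error")
})

test_that("the command-line interface dispatches and signals validation failures", {
  dir <- withr::local_tempdir()
  generate_dataset(synthetic_spec(n_countries = 3, seed = 51), dir = dir)
  config_path <- file.path(dir, "scenario.yaml")
  yaml::write_yaml(list(
    barriers = synthetic_spec(seed = 1)$barrier_ids,
    regions = "regions.csv", indicators = "indicators.csv",
    presentations = "presentations.csv", doses = "presentation_doses.csv",
    calibration = "calibration_sc", tests = "test_optimal"), config_path)
  out <- file.path(dir, "out")
  expect_output(status <- vaximpact_cli(c("estimate", "--config", config_path,
                                          "--out", out)))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(out, "results.csv")))

  expect_message(bad <- vaximpact_cli(c("estimate", "--config", "no_such.yaml",
                                        "--out", out)),
                 "error:")
  expect_equal(bad, 2L)
  expect_message(unknown <- vaximpact_cli("frobnicate"), "unknown command")
  expect_equal(unknown, 2L)
})
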