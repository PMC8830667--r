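# Synthetic multi-country fixtures emulating the structure of the real
# inputs (WHO/UNICEF-style coverage, survey-style barrier proxies, birth
# cohorts, channel splits), plus an agent-level Monte-Carlo simulator used
# as an independent check of the analytic coverage product.

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic multi-country dataset
#'
#' All generated quantities are drawn uniformly within the stated bounds;
#' with no distributional guidance for the real inputs, uniform draws
#' maximize coverage of edge configurations. The same spec and seed always
#' produce identical tables.
#'
#' @param n_countries Number of countries (default 73, the size of the
#'   Gavi-eligible country group used as the reference population).
#' @param subregions_per_country Regions per country (default 1 =
#'   national-level analysis; use >= 2 to exercise the equity index).
#' @param p_bounds Bounds for per-barrier failure prevalences.
#' @param calib_coverage_bounds Bounds for observed calibration-vaccine
#'   coverage.
#' @param headroom_bounds Bounds for the gap between the maximum-coverage
#'   threshold and the calibration coverage; the threshold is capped at 1.
#' @param births_bounds Bounds for the annual birth cohort per region.
#' @param routine_share_bounds Bounds for the share of the cohort served by
#'   the routine channel (the campaign channel takes the complement).
#' @param missing_rate Per-priority probability that an indicator value is
#'   missing; the last priority is always present so every barrier resolves.
#' @param barrier_ids Barrier set (defaults to the shipped rubric's barriers).
#' @param seed Integer seed; fixed seed implies identical output.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_countries = 73L,
                           subregions_per_country = 1L,
                           p_bounds = c(0.01, 0.5),
                           calib_coverage_bounds = c(0.4, 0.95),
                           headroom_bounds = c(0.02, 0.15),
                           births_bounds = c(5e4, 5e6),
                           routine_share_bounds = c(0.6, 1),
                           missing_rate = c(0.3, 0),
                           barrier_ids = c("schedule", "temperature",
                                           "administration", "acceptability",
                                           "doses_per_container"),
                           seed = 1L) {
  stopifnot(n_countries >= 1, subregions_per_country >= 1)
  for (b in list(p_bounds, calib_coverage_bounds, headroom_bounds,
                 routine_share_bounds)) {
    if (length(b) != 2 || b[1] > b[2] || b[1] < 0 || b[2] > 1) {
      validation_error("bounds must be ordered pairs within [0, 1]")
    }
  }
  check_probability(missing_rate, "missing_rate")
  structure(list(n_countries = as.integer(n_countries),
                 subregions_per_country = as.integer(subregions_per_country),
                 p_bounds = p_bounds,
                 calib_coverage_bounds = calib_coverage_bounds,
                 headroom_bounds = headroom_bounds,
                 births_bounds = births_bounds,
                 routine_share_bounds = routine_share_bounds,
                 missing_rate = missing_rate,
                 barrier_ids = barrier_ids,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default synthetic presentation specifications
#'
#' Three synthetic stand-in presentations in the shipped rubric's terms: a
#' calibration-like presentation (multi-dose vial, strict cold chain,
#' nurse-administered injectable), and two test presentations of increasing
#' technological ambition ("minimum" and "optimal"), loosely patterned on a
#' micro-array-patch target product profile. They are fixture content, not
#' real product data.
#'
#' @return A list: `specs` (tibble: presentation_id, barrier_id, variant,
#'   level) and `doses` (tibble: presentation_id, doses_required).
#' @export
synthetic_presentations <- function() {
  row <- function(id, barrier, variant, level) {
    tibble::tibble(presentation_id = id, barrier_id = barrier,
                   variant = variant, level = level)
  }
  specs <- dplyr::bind_rows(
    row("calibration_sc", "schedule", "generic", "Medium-High"),
    row("calibration_sc", "temperature", "generic", "Medium-Low"),
    row("calibration_sc", "administration", "generic", "Medium-Low"),
    row("calibration_sc", "acceptability", "pork_product", "Medium-Low"),
    row("calibration_sc", "doses_per_container", "generic", "Medium-Low"),
    row("test_minimum", "schedule", "generic", "Medium-High"),
    row("test_minimum", "temperature", "generic", "Medium"),
    row("test_minimum", "administration", "generic", "Medium"),
    row("test_minimum", "acceptability", "pork_product", "Medium-High"),
    row("test_minimum", "doses_per_container", "generic", "Medium-High"),
    row("test_optimal", "schedule", "generic", "Medium-High"),
    row("test_optimal", "temperature", "generic", "Medium-High"),
    row("test_optimal", "administration", "generic", "High"),
    row("test_optimal", "acceptability", "pork_product", "High"),
    row("test_optimal", "doses_per_container", "generic", "High"))
  doses <- tibble::tibble(
    presentation_id = c("calibration_sc", "test_minimum", "test_optimal"),
    doses_required = c(2L, 2L, 1L))
  list(specs = specs, doses = doses)
}

runif_within <- function(n, bounds) stats::runif(n, bounds[1], bounds[2])

#' Generate a synthetic multi-country dataset
#'
#' Produces internally consistent regions, indicators and presentations
#' tables in the CSV dialects consumed by the scenario runner: every barrier
#' resolves at some priority, calibration coverage never exceeds the
#' maximum-coverage threshold, and the presentation set contains a
#' calibration-like and two test presentations.
#'
#' Priority-1 indicator values are the generating prevalences themselves;
#' priority-2 values are coarse fallbacks (the prevalence plus uniform noise
#' of up to +/-0.05, clamped to \[0, 1\]), mimicking sub-regional averages.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional directory; when given, writes `regions.csv`,
#'   `indicators.csv`, `presentations.csv`, `presentation_doses.csv`.
#' @return A list of tibbles: `regions`, `indicators`, `presentations`,
#'   `doses`, plus `truth` (the generating prevalences, for parameter-
#'   recovery checks).
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    countries <- sprintf("C%03d", seq_len(spec$n_countries))
    regions_per <- spec$subregions_per_country
    region_id <- if (regions_per == 1) {
      countries
    } else {
      as.vector(t(outer(countries, sprintf("R%02d", seq_len(regions_per)),
                        paste, sep = "_")))
    }
    n <- length(region_id)
    calib_coverage <- runif_within(n, spec$calib_coverage_bounds)
    max_coverage <- pmin(1, calib_coverage + runif_within(n, spec$headroom_bounds))
    regions <- tibble::tibble(
      region_id = region_id,
      country_id = rep(countries, each = regions_per),
      births = round(runif_within(n, spec$births_bounds)),
      calib_coverage = calib_coverage,
      max_coverage = max_coverage,
      routine_share = runif_within(n, spec$routine_share_bounds))

    n_b <- length(spec$barrier_ids)
    truth <- tibble::tibble(
      region_id = rep(region_id, each = n_b),
      barrier_id = rep(spec$barrier_ids, times = n),
      p = runif_within(n * n_b, spec$p_bounds))
    n_priorities <- length(spec$missing_rate)
    indicators <- dplyr::bind_rows(lapply(seq_len(n_priorities), function(pr) {
      noise <- if (pr == 1) 0 else stats::runif(nrow(truth), -0.05, 0.05)
      value <- pmin(1, pmax(0, truth$p + noise))
      missing <- stats::runif(nrow(truth)) < spec$missing_rate[pr] &
        pr < n_priorities
      tibble::tibble(
        region_id = truth$region_id,
        barrier_id = truth$barrier_id,
        priority = pr,
        value = ifelse(missing, NA_real_, value),
        source = if (pr == 1) "synthetic_survey" else "synthetic_subregion_average",
        complement = 0L)
    }))
    pres <- synthetic_presentations()
    out <- list(regions = regions, indicators = indicators,
                presentations = pres$specs, doses = pres$doses, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      readr::write_csv(out$regions, file.path(dir, "regions.csv"), na = "")
      readr::write_csv(out$indicators, file.path(dir, "indicators.csv"), na = "")
      readr::write_csv(out$presentations, file.path(dir, "presentations.csv"), na = "")
      readr::write_csv(out$doses, file.path(dir, "presentation_doses.csv"), na = "")
    }
    out
  })
}

#' Scenario configuration for a synthetic dataset
#'
#' Convenience wrapper: generates a dataset and returns a ready-to-run config
#' holding the tables in memory (or pointing at `dir` when written to disk).
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional directory passed to [generate_dataset()].
#' @param ... Config overrides (e.g. `d_worst`, `channels`, `sensitivity`).
#' @return A scenario config list.
#' @export
synthetic_scenario_config <- function(spec, dir = NULL, ...) {
  data <- generate_dataset(spec, dir = dir)
  pres <- read_presentations_from_tables(data$presentations, data$doses,
                                         barrier_ids = spec$barrier_ids)
  config <- list(
    barriers = spec$barrier_ids,
    regions = data$regions,
    indicators = data$indicators,
    presentations = pres,
    doses = data$doses,
    calibration = "calibration_sc",
    tests = c("test_minimum", "test_optimal"),
    d_worst = 4L)
  utils::modifyList(config, list(...))
}

read_presentations_from_tables <- function(specs, doses, rubric = default_rubric(),
                                           barrier_ids = NULL) {
  ids <- unique(specs$presentation_id)
  out <- lapply(ids, function(id) {
    score_presentation(specs[specs$presentation_id == id, ],
                       doses = doses$doses_required[match(id, doses$presentation_id)],
                       rubric = rubric, barrier_ids = barrier_ids)
  })
  stats::setNames(out, ids)
}

#' Agent-level Monte-Carlo simulation of the barrier model
#'
#' Simulates individual agents who must pass every technology-addressable
#' barrier for each of the presentation's doses; barrier-dose trials are
#' independent Bernoulli events with pass probability `1 - p_i (1 - v_i)` at
#' `correlation = 0`. At `correlation > 0`, failures are coupled through a
#' single shared latent factor per agent (Gaussian latent thresholds), a
#' one-parameter device for probing the independence assumption; it is a
#' testing instrument, not part of the analytic model.
#'
#' @param profile A [population_profile()].
#' @param presentation A [vaccine_presentation()].
#' @param n_agents Number of simulated agents (>= 1).
#' @param seed Optional integer seed.
#' @param correlation Shared-factor coupling in \[0, 1\] (0 = independent).
#' @return A list: `fraction` (empirical vaccinated fraction), `analytic`
#'   (the model's uncalibrated coverage), `se` (binomial standard error at
#'   the analytic mean), `n_agents`, `correlation`, `seed`.
#' @export
simulate_agents <- function(profile, presentation, n_agents, seed = NULL,
                            correlation = 0) {
  check_alignment(profile, presentation)
  if (n_agents < 1) validation_error("`n_agents` must be >= 1")
  check_probability(correlation, "correlation")
  fail_prob <- profile$p * (1 - presentation$v)
  n_trials <- length(fail_prob) * presentation$doses
  run <- function() {
    fail_all <- rep(fail_prob, times = presentation$doses)
    if (n_trials == 0 || all(fail_all == 0)) {
      return(rep(TRUE, n_agents))
    }
    if (correlation == 0) {
      draws <- matrix(stats::runif(n_agents * n_trials), nrow = n_agents)
      passes <- sweep(draws, 2, fail_all, `>=`)
    } else {
      shared <- stats::rnorm(n_agents)
      eps <- matrix(stats::rnorm(n_agents * n_trials), nrow = n_agents)
      latent <- sqrt(correlation) * shared + sqrt(1 - correlation) * eps
      passes <- sweep(latent, 2, stats::qnorm(fail_all), `>=`)
    }
    rowSums(passes) == n_trials
  }
  vaccinated <- if (is.null(seed)) run() else with_local_seed(seed, run())
  analytic <- uncalibrated_coverage(profile, presentation)
  list(fraction = mean(vaccinated),
       analytic = analytic,
       se = sqrt(analytic * (1 - analytic) / n_agents),
       n_agents = as.integer(n_agents),
       correlation = correlation,
       seed = seed)
}
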