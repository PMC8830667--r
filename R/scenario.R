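# Config-driven scenario runner mirroring a four-step workflow: analysis
# setup (barrier set, presentations, regions), scenario inputs (tables),
# calculation (per region x channel), and scenario outputs (aggregate table,
# ranking, equity, audit log). Sensitivity sweeps rerun the whole scenario
# over a small grid of input overrides.

#' Read and validate a scenario configuration
#'
#' The configuration is YAML or JSON with fields:
#' \describe{
#'   \item{barriers}{ordered list of technology-addressable barrier ids
#'     (excluding dose requirements, which enter via dose counts)}
#'   \item{rubric}{path to a rubric CSV, or `"default"`}
#'   \item{regions, indicators, presentations, doses}{paths to the input CSVs,
#'     relative to the config file}
#'   \item{calibration}{presentation id of the calibration vaccine}
#'   \item{tests}{presentation id(s) under evaluation}
#'   \item{d_worst}{dose count of the least-desirable presentation (default 4)}
#'   \item{channels}{optional list of channels, each with `id`, `share`
#'     (a number or the name of a regions column), and optional `barriers`
#'     (applicable barrier ids; omitted = all). Default: a routine channel
#'     taking its share from the `routine_share` column and an SIA channel
#'     with the complement, both with all barriers applicable.}
#'   \item{sensitivity}{optional named list of value grids for
#'     [sensitivity_sweep()], at most 3 parameters}
#'   \item{top_k}{size of the ranking (default 10)}
#' }
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated config list with paths resolved.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) validation_error("config file not found: %s", path)
  config <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(normalizePath(path))
  for (field in c("regions", "indicators", "presentations", "doses", "rubric")) {
    value <- config[[field]]
    if (is.character(value) && !identical(value, "default") &&
        !file.exists(value)) {
      config[[field]] <- file.path(base, value)
    }
  }
  validate_scenario_config(config)
}

validate_scenario_config <- function(config) {
  required <- c("barriers", "regions", "indicators", "presentations", "doses",
                "calibration", "tests")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    validation_error("scenario config is missing field(s): %s",
                     paste(missing, collapse = ", "))
  }
  config$barriers <- as.character(unlist(config$barriers))
  config$tests <- as.character(unlist(config$tests))
  if (is.null(config$d_worst)) config$d_worst <- 4L
  config$d_worst <- check_doses(config$d_worst, "d_worst")
  if (is.null(config$rubric)) config$rubric <- "default"
  if (is.null(config$top_k)) config$top_k <- 10L
  if (is.null(config$channels)) {
    config$channels <- list(
      list(id = "routine", share = "routine_share"),
      list(id = "sia", share = "complement"))
  }
  if (!is.null(config$sensitivity) && length(config$sensitivity) > 3) {
    validation_error("at most 3 sensitivity parameters may vary (got %d)",
                     length(config$sensitivity))
  }
  for (field in c("regions", "indicators", "presentations", "doses")) {
    value <- config[[field]]
    if (is.character(value) && !file.exists(value)) {
      validation_error("config field `%s`: file not found: %s", field, value)
    }
  }
  config
}

load_scenario_inputs <- function(config) {
  rubric <- if (identical(config$rubric, "default")) {
    default_rubric()
  } else if (is.character(config$rubric)) {
    read_rubric(config$rubric)
  } else {
    config$rubric
  }
  as_table <- function(x, reader) if (is.character(x)) reader(x) else tibble::as_tibble(x)
  regions <- as_table(config$regions, read_regions)
  indicators <- as_table(config$indicators, read_indicators)
  presentations <- if (is.character(config$presentations)) {
    read_presentations(config$presentations, config$doses, rubric = rubric,
                       barrier_ids = config$barriers)
  } else {
    config$presentations  # pre-scored list of vaccine_presentation objects
  }
  wanted <- c(config$calibration, config$tests)
  absent <- setdiff(wanted, names(presentations))
  if (length(absent) > 0) {
    validation_error("presentation id(s) not found: %s",
                     paste(absent, collapse = ", "))
  }
  list(rubric = rubric, regions = regions, indicators = indicators,
       presentations = presentations)
}

region_channels <- function(config, region) {
  specs <- config$channels
  shares <- numeric(length(specs))
  for (i in seq_along(specs)) {
    sh <- specs[[i]]$share
    shares[i] <- if (is.numeric(sh)) {
      sh
    } else if (identical(sh, "complement")) {
      NA_real_
    } else if (is.character(sh) && sh %in% names(region)) {
      region[[sh]]
    } else {
      validation_error("channel `%s`: share `%s` is neither a number nor a regions column",
                       specs[[i]]$id, sh)
    }
  }
  if (anyNA(shares)) {
    if (sum(is.na(shares)) > 1) {
      validation_error("only one channel may take the complement share")
    }
    shares[is.na(shares)] <- 1 - sum(shares, na.rm = TRUE)
  }
  purrr::map2(specs, shares, function(spec, share) {
    channel_spec(spec$id, share,
                 barriers = if (is.null(spec$barriers)) NULL else as.character(unlist(spec$barriers)))
  })
}

#' Run a coverage scenario end to end
#'
#' For every region and every test presentation: builds the population
#' profile from proxy indicators, runs the channel-blended coverage estimate
#' against the calibration vaccine, and assembles per-region results, the
#' population-weighted aggregate (with exclusions reported), the top-k
#' ranking, the per-country equity index (where a country has 2 or more
#' regions), an audit table of all calibration intermediates, and the
#' indicator provenance log.
#'
#' @param config A config list from [read_scenario_config()], or an
#'   equivalent list whose table fields hold data frames / pre-scored
#'   presentations directly.
#' @param out_dir Optional directory; when given, outputs are written via
#'   [write_scenario_outputs()].
#' @return A `scenario_result` list: `results`, `aggregate`, `ranking`,
#'   `equity`, `audit`, `provenance` tibbles.
#' @export
run_scenario <- function(config, out_dir = NULL) {
  config <- validate_scenario_config(config)
  inputs <- load_scenario_inputs(config)
  regions <- inputs$regions
  calib <- inputs$presentations[[config$calibration]]

  profiles <- lapply(seq_len(nrow(regions)), function(i) {
    build_profile(regions$region_id[i], config$barriers, inputs$indicators)
  })
  provenance <- dplyr::bind_rows(lapply(profiles, attr, "provenance"))

  per_test <- lapply(config$tests, function(test_id) {
    test <- inputs$presentations[[test_id]]
    rows <- lapply(seq_len(nrow(regions)), function(i) {
      region <- regions[i, ]
      channels <- region_channels(config, region)
      est <- channel_blend(profiles[[i]], test, calib, channels,
                           max_coverage = region$max_coverage,
                           calib_coverage = region$calib_coverage,
                           d_worst = config$d_worst)
      audit <- purrr::imap_dfr(est$channels, function(ch, ch_id) {
        tibble::tibble(
          presentation_id = test_id, region_id = region$region_id,
          channel_id = ch_id, share = est$channel_shares[[ch_id]],
          test_uncal = ch$test_uncal, calib_uncal = ch$calib_uncal,
          worst_uncal = ch$worst_uncal, slope = ch$slope,
          intercept = ch$intercept, floor_coverage = ch$floor_coverage,
          headroom = ch$headroom, residual = ch$residual,
          coverage = ch$coverage)
      })
      result <- tibble::tibble(
        presentation_id = test_id,
        region_id = region$region_id,
        country_id = region$country_id,
        calib_coverage = region$calib_coverage,
        coverage = est$coverage,
        delta_pp = (est$coverage - region$calib_coverage) * 100,
        births = region$births,
        additional_vaccinated = (est$coverage - region$calib_coverage) * region$births,
        valid = est$valid,
        exclusion_reason = if (est$valid) NA_character_ else "estimate exceeds 100%")
      list(result = result, audit = audit)
    })
    list(results = dplyr::bind_rows(purrr::map(rows, "result")),
         audit = dplyr::bind_rows(purrr::map(rows, "audit")))
  })
  results <- dplyr::bind_rows(purrr::map(per_test, "results"))
  audit <- dplyr::bind_rows(purrr::map(per_test, "audit"))

  aggregate <- dplyr::bind_rows(lapply(config$tests, function(test_id) {
    agg <- aggregate_regions(results[results$presentation_id == test_id, ])
    tibble::tibble(
      presentation_id = test_id,
      coverage = agg$coverage,
      calib_coverage = agg$calib_coverage,
      delta_pp = agg$delta_pp,
      additional_vaccinated = agg$additional_vaccinated,
      n_regions = agg$n_regions,
      n_valid = agg$n_valid,
      excluded_regions = paste(agg$excluded_regions, collapse = ";"),
      excluded_cohort_share = agg$excluded_cohort_share)
  }))

  ranking <- results %>%
    dplyr::group_by(.data$presentation_id) %>%
    dplyr::group_modify(~ rank_regions(.x, k = config$top_k)) %>%
    dplyr::ungroup()

  equity <- results %>%
    dplyr::filter(.data$valid) %>%
    dplyr::group_by(.data$presentation_id, .data$country_id) %>%
    dplyr::summarise(
      n_regions = dplyr::n(),
      equity = if (dplyr::n() >= 2) equity_index(.data$coverage) else NA_real_,
      .groups = "drop") %>%
    dplyr::filter(.data$n_regions >= 2)

  out <- structure(list(results = results, aggregate = aggregate,
                        ranking = ranking, equity = equity, audit = audit,
                        provenance = provenance),
                   class = "scenario_result")
  if (!is.null(out_dir)) write_scenario_outputs(out, out_dir)
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>\n")
  for (i in seq_len(nrow(x$aggregate))) {
    row <- x$aggregate[i, ]
    cat(sprintf(
      "  %s: coverage %s (%+.1f pp vs calibration), %s additional vaccinated, %d/%d regions valid\n",
      row$presentation_id, format_percent(row$coverage), row$delta_pp,
      format(round(row$additional_vaccinated), big.mark = ","),
      row$n_valid, row$n_regions))
  }
  invisible(x)
}

#' Write scenario outputs to a directory
#'
#' Writes `results.csv`, `ranking.csv`, `equity.csv`, `provenance.csv`,
#' `aggregate.json` and `audit.json`. Percentages in the CSVs are fractions;
#' formatting to percent strings is left to report consumers.
#'
#' @param run A `scenario_result` from [run_scenario()].
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_scenario_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$results, file.path(out_dir, "results.csv"), na = "")
  readr::write_csv(run$ranking, file.path(out_dir, "ranking.csv"), na = "")
  readr::write_csv(run$equity, file.path(out_dir, "equity.csv"), na = "")
  readr::write_csv(run$provenance, file.path(out_dir, "provenance.csv"), na = "")
  jsonlite::write_json(run$aggregate, file.path(out_dir, "aggregate.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  jsonlite::write_json(run$audit, file.path(out_dir, "audit.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(out_dir)
}

sweep_override <- function(config, inputs_regions, param, value) {
  allowed <- c("d_worst", "max_coverage", "calib_coverage", "routine_share")
  if (!param %in% allowed) {
    validation_error("unknown sensitivity parameter `%s` (supported: %s)",
                     param, paste(allowed, collapse = ", "))
  }
  if (param == "d_worst") {
    config$d_worst <- check_doses(value, "d_worst")
  } else {
    inputs_regions[[param]] <- value
  }
  list(config = config, regions = inputs_regions)
}

#' Sensitivity sweep over scenario inputs
#'
#' Re-runs the full scenario once per combination of the configured
#' sensitivity grids (at most 3 parameters; supported: `d_worst`, and
#' region-wide overrides of `max_coverage`, `calib_coverage`,
#' `routine_share`) and returns the aggregate summaries in long format keyed
#' by the parameter values.
#'
#' @param config Scenario config whose `sensitivity` field is a named list of
#'   value grids, e.g. `list(d_worst = c(1, 4), max_coverage = c(0.85, 0.9))`.
#' @param out_dir Optional directory; when given, the sweep table is written
#'   to `sweep.csv` there.
#' @return A tibble: one row per grid combination x test presentation, with
#'   the swept parameter values and the aggregate columns.
#' @export
sensitivity_sweep <- function(config, out_dir = NULL) {
  config <- validate_scenario_config(config)
  grids <- config$sensitivity
  if (is.null(grids) || length(grids) == 0) {
    validation_error("config has no `sensitivity` grids")
  }
  if (any(lengths(grids) == 0)) {
    validation_error("empty sensitivity grid for parameter(s): %s",
                     paste(names(grids)[lengths(grids) == 0], collapse = ", "))
  }
  regions <- if (is.character(config$regions)) {
    read_regions(config$regions)
  } else {
    tibble::as_tibble(config$regions)
  }
  combos <- tidyr::expand_grid(!!!grids)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cfg <- config
    reg <- regions
    for (param in names(combos)) {
      over <- sweep_override(cfg, reg, param, combos[[param]][i])
      cfg <- over$config
      reg <- over$regions
    }
    cfg$regions <- reg
    cfg$sensitivity <- NULL
    run <- run_scenario(cfg)
    dplyr::bind_cols(tibble::as_tibble(combos[i, , drop = FALSE]), run$aggregate)
  })
  sweep <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(sweep, file.path(out_dir, "sweep.csv"), na = "")
  }
  sweep
}

#' Bar chart of the regions with the largest coverage gains
#'
#' @param ranking A ranking tibble from [run_scenario()] (columns
#'   `region_id`, `delta_pp`, optionally `presentation_id`).
#' @return A ggplot object.
#' @export
plot_ranking <- function(ranking) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    validation_error("plot_ranking() needs the ggplot2 package")
  }
  ranking <- tibble::as_tibble(ranking)
  p <- ggplot2::ggplot(ranking,
                       ggplot2::aes(x = stats::reorder(.data$region_id, .data$delta_pp),
                                    y = .data$delta_pp)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Coverage gain vs calibration vaccine (pp)")
  if ("presentation_id" %in% names(ranking) &&
      length(unique(ranking$presentation_id)) > 1) {
    p <- p + ggplot2::facet_wrap(~presentation_id, scales = "free_y")
  }
  p
}
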