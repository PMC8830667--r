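# Blending of the two delivery channels (routine immunization vs.
# supplementary immunization activities), population-weighted aggregation of
# regional estimates with the extreme-value exclusion rule, the coverage
# equity index, and ranking of regions by coverage gain.

#' Define a vaccination channel
#'
#' A channel (e.g. routine immunization, or campaign-based supplementary
#' immunization activities) serves a share of the vaccine-eligible population
#' and may render some technology-addressable barriers irrelevant (a campaign
#' that brings vaccinators to the household removes the facility-access
#' component of the administration barrier, for instance).
#'
#' @param channel_id Label, e.g. `"routine"` or `"sia"`.
#' @param share Share of the vaccine-eligible population served, in \[0, 1\].
#' @param barriers Character vector of barrier ids applicable in this
#'   channel, or `NULL` (default) for all barriers.
#' @return A `channel_spec` list.
#' @export
channel_spec <- function(channel_id, share, barriers = NULL) {
  check_probability(share, "share")
  structure(list(channel_id = channel_id, share = share, barriers = barriers),
            class = "channel_spec")
}

mask_profile <- function(profile, barriers) {
  if (is.null(barriers)) {
    return(profile)
  }
  unknown <- setdiff(barriers, profile$barrier_ids)
  if (length(unknown) > 0) {
    validation_error("channel mask names unknown barrier(s): %s",
                     paste(unknown, collapse = ", "))
  }
  p <- ifelse(profile$barrier_ids %in% barriers, profile$p, 0)
  out <- population_profile(p, barrier_ids = profile$barrier_ids)
  attr(out, "provenance") <- attr(profile, "provenance")
  out
}

#' Blend coverage estimates across vaccination channels
#'
#' Runs the full coverage estimate separately for each channel — with
#' barriers not applicable in a channel treated as absent from its population
#' (prevalence 0, a property of the channel's population rather than of the
#' vaccine) — and combines the channel estimates as a weighted average by the
#' channels' population shares. The blended estimate is valid only if every
#' channel estimate is.
#'
#' @inheritParams estimate_coverage
#' @param channels List of [channel_spec()] objects; shares must sum to 1
#'   (tolerance 1e-9).
#' @return A `coverage_estimate` whose `coverage` is the share-weighted
#'   average, with the per-channel estimates in `$channels`.
#' @export
channel_blend <- function(profile, test, calib, channels, max_coverage,
                          calib_coverage, d_worst = 4L) {
  stopifnot(length(channels) >= 1)
  shares <- vapply(channels, `[[`, numeric(1), "share")
  if (abs(sum(shares) - 1) > 1e-9) {
    validation_error("channel shares must sum to 1 (got %g)", sum(shares))
  }
  per_channel <- lapply(channels, function(ch) {
    estimate_coverage(mask_profile(profile, ch$barriers), test, calib,
                      max_coverage, calib_coverage, d_worst)
  })
  names(per_channel) <- vapply(channels, `[[`, character(1), "channel_id")
  blended <- per_channel[[1]]
  blended$coverage <- sum(shares * vapply(per_channel, `[[`, numeric(1), "coverage"))
  blended$valid <- all(vapply(per_channel, `[[`, logical(1), "valid")) &&
    blended$coverage <= 1
  blended$channels <- per_channel
  blended$channel_shares <- stats::setNames(shares, names(per_channel))
  blended
}

#' Aggregate regional results into a population-weighted summary
#'
#' Computes the birth-cohort-weighted mean estimated and calibration coverage
#' over *valid* regions, the total additional children vaccinated per year,
#' and the share of the total birth cohort belonging to excluded (invalid)
#' regions. Regions whose estimate exceeded 100% are excluded before
#' weighting; their cohort share is always reported so the exclusion is
#' visible in the output.
#'
#' @param results Data frame with columns `region_id`, `coverage`,
#'   `calib_coverage`, `births`, `valid` (logical).
#' @return A list: `coverage`, `calib_coverage`, `delta_pp` (percentage
#'   points), `additional_vaccinated`, `n_regions`, `n_valid`,
#'   `excluded_regions`, `excluded_cohort_share`.
#' @export
aggregate_regions <- function(results) {
  results <- tibble::as_tibble(results)
  valid <- results[results$valid, ]
  if (nrow(valid) == 0) {
    validation_error("no valid regional results to aggregate")
  }
  total_births <- sum(results$births)
  coverage <- stats::weighted.mean(valid$coverage, valid$births)
  calib <- stats::weighted.mean(valid$calib_coverage, valid$births)
  list(
    coverage = coverage,
    calib_coverage = calib,
    delta_pp = (coverage - calib) * 100,
    additional_vaccinated = sum((valid$coverage - valid$calib_coverage) * valid$births),
    n_regions = nrow(results),
    n_valid = nrow(valid),
    excluded_regions = results$region_id[!results$valid],
    excluded_cohort_share = if (total_births > 0) {
      sum(results$births[!results$valid]) / total_births
    } else {
      0
    })
}

#' Equity of coverage across subnational regions
#'
#' One minus the summed shortfall of each region's estimated coverage from
#' the best-covered region, divided by the number of regions minus one.
#' Equals 1 when all regions have identical coverage and decreases as
#' coverage becomes more uneven.
#'
#' @param coverages Numeric vector of regional coverage estimates (length >= 2).
#' @return The equity index, at most 1.
#' @export
equity_index <- function(coverages) {
  r <- length(coverages)
  if (r < 2) {
    validation_error("equity index needs at least 2 regions (got %d)", r)
  }
  check_probability(coverages, "coverages", allow_gt1 = TRUE)
  1 - sum(max(coverages) - coverages) / (r - 1)
}

#' Rank regions by coverage gain
#'
#' Top-`k` valid regions by percentage-point change relative to the
#' calibration vaccine, descending; ties broken by `region_id` so the
#' ordering is deterministic.
#'
#' @param results Data frame with columns `region_id`, `delta_pp`, `valid`.
#' @param k Number of regions to keep (default 10).
#' @return The top rows of `results`, ranked.
#' @export
rank_regions <- function(results, k = 10L) {
  if (k < 1) validation_error("`k` must be >= 1")
  results <- tibble::as_tibble(results)
  valid <- results[results$valid, ]
  ranked <- valid[order(-valid$delta_pp, valid$region_id), ]
  utils::head(ranked, k)
}
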