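# Population barrier scores are rarely observed directly; they are resolved
# from a hierarchy of proxy indicators (priority 1 = closest to the ideal
# definition, then increasingly coarse fallbacks such as sub-regional
# averages). Missingness is an explicit marker: a recorded 0 means the
# barrier is absent, which is informative, not missing.

#' Resolve one population score from prioritized proxy indicators
#'
#' Given all indicator records for one region-barrier pair, returns the value
#' from the best-priority (smallest number) source that is non-missing,
#' together with provenance. A record whose `complement` flag is 1 is stored
#' as a probability of *overcoming* the barrier and is complemented
#' (`1 - value`) on resolution; all resolved scores are probabilities of
#' *not* overcoming the barrier.
#'
#' @param records Data frame with columns `priority`, `value`, and optionally
#'   `source` and `complement` (0/1), all for a single region-barrier pair.
#' @return A list: `value`, `priority_used`, `source`.
#' @export
resolve_score <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    validation_error("no indicator records supplied")
  }
  if (!"complement" %in% names(records)) records$complement <- 0
  if (!"source" %in% names(records)) records$source <- NA_character_
  if (any(records$priority < 1 | records$priority != as.integer(records$priority))) {
    validation_error("indicator priorities must be positive integers")
  }
  if (anyDuplicated(records$priority)) {
    validation_error("duplicate indicator priority level(s): %s",
                     paste(unique(records$priority[duplicated(records$priority)]),
                           collapse = ", "))
  }
  present <- records[!is.na(records$value), ]
  if (nrow(present) == 0) {
    validation_error("all indicator values missing (tried priorities %s)",
                     paste(sort(records$priority), collapse = ", "))
  }
  best <- present[which.min(present$priority), ]
  value <- if (best$complement %in% 1) 1 - best$value else best$value
  check_probability(value, "resolved population score")
  list(value = value,
       priority_used = as.integer(best$priority),
       source = best$source)
}

#' Population-weighted average of sub-region scores
#'
#' Used when a score is only available for sub-regions (or when a sub-regional
#' average is itself the fallback proxy): the regional score is the average of
#' sub-region values weighted by their population.
#'
#' @param values Probabilities in \[0, 1\].
#' @param weights Non-negative population counts, same length, not all zero.
#' @return The weighted mean.
#' @export
subregion_weighted_average <- function(values, weights) {
  if (length(values) != length(weights)) {
    validation_error("values (%d) and weights (%d) differ in length",
                     length(values), length(weights))
  }
  check_probability(values, "values")
  if (any(weights < 0) || anyNA(weights)) {
    validation_error("weights must be non-negative")
  }
  if (sum(weights) == 0) {
    validation_error("weights sum to zero")
  }
  sum(values * weights) / sum(weights)
}

#' Build a population profile from an indicator table
#'
#' Resolves every barrier of the analysis barrier set for one region through
#' the priority-fallback hierarchy and assembles the ordered prevalence
#' vector. Per-barrier provenance (priority used, source label) is attached
#' as the `"provenance"` attribute, a tibble.
#'
#' @param region_id Region to build the profile for.
#' @param barrier_ids Ordered barrier set of the analysis.
#' @param indicators Data frame with columns `region_id`, `barrier_id`,
#'   `priority`, `value`, and optionally `source`, `complement`.
#' @return A [population_profile()] with a `provenance` attribute.
#' @export
build_profile <- function(region_id, barrier_ids, indicators) {
  indicators <- tibble::as_tibble(indicators)
  rows <- indicators[indicators$region_id == region_id, ]
  resolved <- lapply(barrier_ids, function(b) {
    sub <- rows[rows$barrier_id == b, ]
    if (nrow(sub) == 0) {
      return(NULL)
    }
    tryCatch(resolve_score(sub), vaximpact_validation_error = function(e) NULL)
  })
  failed <- barrier_ids[vapply(resolved, is.null, logical(1))]
  if (length(failed) > 0) {
    validation_error("region `%s`: no resolvable indicator for barrier(s): %s",
                     region_id, paste(failed, collapse = ", "))
  }
  profile <- population_profile(vapply(resolved, `[[`, numeric(1), "value"),
                                barrier_ids = barrier_ids)
  attr(profile, "provenance") <- tibble::tibble(
    region_id = region_id,
    barrier_id = barrier_ids,
    value = profile$p,
    priority_used = vapply(resolved, `[[`, integer(1), "priority_used"),
    source = vapply(resolved, `[[`, character(1), "source"))
  profile
}

#' Read the regions table
#'
#' @param path CSV with columns `region_id`, `country_id`, `births`,
#'   `calib_coverage`, `max_coverage`, `routine_share`.
#' @return A tibble, validated.
#' @export
read_regions <- function(path) {
  regions <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("region_id", "country_id", "births", "calib_coverage",
                "max_coverage", "routine_share")
  missing <- setdiff(required, names(regions))
  if (length(missing) > 0) {
    validation_error("regions table is missing column(s): %s",
                     paste(missing, collapse = ", "))
  }
  if (anyDuplicated(regions$region_id)) {
    validation_error("duplicate region_id(s) in regions table")
  }
  check_probability(regions$calib_coverage, "calib_coverage", allow_gt1 = TRUE)
  check_probability(regions$max_coverage, "max_coverage", allow_gt1 = TRUE)
  check_probability(regions$routine_share, "routine_share")
  if (any(regions$births < 0)) validation_error("births must be non-negative")
  bad <- regions$region_id[regions$calib_coverage > regions$max_coverage]
  if (length(bad) > 0) {
    validation_error(
      "calib_coverage exceeds max_coverage for region(s): %s",
      paste(bad, collapse = ", "))
  }
  tibble::as_tibble(regions)
}

#' Read the indicators table
#'
#' @param path CSV with columns `region_id`, `barrier_id`, `priority`,
#'   `value` (possibly empty = missing), and optionally `source`,
#'   `complement`.
#' @return A tibble.
#' @export
read_indicators <- function(path) {
  ind <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("region_id", "barrier_id", "priority", "value")
  missing <- setdiff(required, names(ind))
  if (length(missing) > 0) {
    validation_error("indicators table is missing column(s): %s",
                     paste(missing, collapse = ", "))
  }
  tibble::as_tibble(ind)
}
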