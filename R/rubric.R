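# Five-level rubric mapping categorical presentation characteristics (cold
# chain needs, who may administer, doses per vial, acceptability, schedule
# fit) to numeric technology scores in [0, 1]. The shipped default scores are
# an expert judgement and are deliberately data (CSV), not code, so users can
# revise them.

#' Rubric level labels, from least to most favourable
#' @export
rubric_levels <- c("Low", "Medium-Low", "Medium", "Medium-High", "High")

#' Read a technology-score rubric
#'
#' A rubric maps, per barrier (and optionally per named variant of a barrier,
#' e.g. a generic acceptability scale vs. one specific to the presence of a
#' pork product), each of the five levels Low, Medium-Low, Medium,
#' Medium-High, High to a score in \[0, 1\].
#'
#' @param path CSV with columns `barrier_id`, `variant`, `level`, `score`.
#'   A missing `variant` column is treated as a single `"generic"` variant.
#' @return A tibble of class `rubric_table`.
#' @seealso [default_rubric()] for the shipped scores.
#' @export
read_rubric <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!"variant" %in% names(tab)) tab$variant <- "generic"
  required <- c("barrier_id", "variant", "level", "score")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    validation_error("rubric is missing column(s): %s", paste(missing, collapse = ", "))
  }
  rubric <- tibble::as_tibble(tab[required])
  report <- validate_rubric(rubric)
  if (nrow(report) > 0) {
    validation_error("invalid rubric:\n%s",
                     paste("-", report$message, collapse = "\n"))
  }
  class(rubric) <- c("rubric_table", class(rubric))
  rubric
}

#' Shipped default rubric scores
#'
#' The default five-level scores for the six technology-addressable barriers
#' (vaccine schedule fit, temperature storage requirements, administration
#' requirements, acceptability of the presentation in a generic and a
#' pork-product variant, and doses per container). Dose requirements enter
#' the model as a dose count, not a rubric row.
#'
#' @return A `rubric_table` tibble.
#' @export
default_rubric <- function() {
  read_rubric(system.file("extdata", "rubric_default.csv",
                          package = "vaximpact", mustWork = TRUE))
}

#' Validate a rubric table
#'
#' Checks that every barrier/variant has exactly the five levels, that scores
#' lie in \[0, 1\] and are non-decreasing from Low to High.
#'
#' @param rubric A rubric tibble (columns `barrier_id`, `variant`, `level`,
#'   `score`).
#' @return A tibble of violations (`barrier_id`, `variant`, `message`); zero
#'   rows when the rubric is valid.
#' @export
validate_rubric <- function(rubric) {
  rubric %>%
    dplyr::group_by(.data$barrier_id, .data$variant) %>%
    dplyr::group_modify(function(rows, key) {
      msgs <- character()
      bad_level <- setdiff(rows$level, rubric_levels)
      if (length(bad_level) > 0) {
        msgs <- c(msgs, sprintf("unknown level label(s): %s",
                                paste(bad_level, collapse = ", ")))
      }
      if (!setequal(rows$level, rubric_levels) || nrow(rows) != 5L) {
        msgs <- c(msgs, sprintf("expected exactly the 5 levels %s, got %d row(s)",
                                paste(rubric_levels, collapse = "/"), nrow(rows)))
      }
      out_of_range <- rows$score < 0 | rows$score > 1
      if (any(out_of_range, na.rm = TRUE) || anyNA(rows$score)) {
        msgs <- c(msgs, sprintf("score(s) outside [0, 1]: %s",
                                paste(rows$score[out_of_range | is.na(rows$score)],
                                      collapse = ", ")))
      }
      ord <- match(rubric_levels, rows$level)
      if (!anyNA(ord) && !anyNA(rows$score)) {
        s <- rows$score[ord]
        drops <- which(diff(s) < 0)
        for (d in drops) {
          msgs <- c(msgs, sprintf("scores not non-decreasing: %s (%g) > %s (%g)",
                                  rubric_levels[d], s[d], rubric_levels[d + 1], s[d + 1]))
        }
      }
      tibble::tibble(message = msgs)
    }) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(message = sprintf("%s/%s: %s", .data$barrier_id,
                                    .data$variant, .data$message))
}

rubric_score <- function(rubric, barrier_id, variant, level) {
  rows <- rubric[rubric$barrier_id == barrier_id & rubric$variant == variant, ]
  if (nrow(rows) == 0) {
    has_barrier <- any(rubric$barrier_id == barrier_id)
    if (!has_barrier) {
      validation_error("barrier `%s` not found in rubric", barrier_id)
    }
    validation_error("unknown variant `%s` for barrier `%s` (available: %s)",
                     variant, barrier_id,
                     paste(unique(rubric$variant[rubric$barrier_id == barrier_id]),
                           collapse = ", "))
  }
  hit <- rows$score[rows$level == level]
  if (length(hit) != 1) {
    validation_error("unknown level `%s` for barrier `%s` (levels are %s)",
                     level, barrier_id, paste(rubric_levels, collapse = ", "))
  }
  hit
}

#' Score a vaccine presentation against a rubric
#'
#' Turns the categorical description of a presentation (one rubric level per
#' barrier, plus the required dose count) into the numeric technology-score
#' vector used by the coverage model.
#'
#' @param spec A data frame with columns `barrier_id`, `level` and optionally
#'   `variant` (default `"generic"`), one row per barrier.
#' @param doses Integer dose count required for full protection.
#' @param rubric A rubric table; defaults to [default_rubric()].
#' @param barrier_ids Barrier order for the returned vector; defaults to the
#'   order of `spec`. Every requested barrier must appear in `spec`.
#' @return A [vaccine_presentation()].
#' @examples
#' spec <- data.frame(
#'   barrier_id = c("temperature", "administration"),
#'   level = c("Medium-High", "Medium-Low"))
#' score_presentation(spec, doses = 1)
#' @export
score_presentation <- function(spec, doses = 1L, rubric = default_rubric(),
                               barrier_ids = NULL) {
  spec <- tibble::as_tibble(spec)
  if (!"variant" %in% names(spec)) spec$variant <- "generic"
  if (is.null(barrier_ids)) barrier_ids <- spec$barrier_id
  missing <- setdiff(barrier_ids, spec$barrier_id)
  if (length(missing) > 0) {
    validation_error("presentation spec is missing barrier(s): %s",
                     paste(missing, collapse = ", "))
  }
  if (anyDuplicated(spec$barrier_id)) {
    validation_error("presentation spec lists barrier(s) more than once: %s",
                     paste(unique(spec$barrier_id[duplicated(spec$barrier_id)]),
                           collapse = ", "))
  }
  spec <- spec[match(barrier_ids, spec$barrier_id), ]
  v <- purrr::pmap_dbl(spec[c("barrier_id", "variant", "level")],
                       function(barrier_id, variant, level) {
                         rubric_score(rubric, barrier_id, variant, level)
                       })
  vaccine_presentation(v, doses = doses, barrier_ids = barrier_ids)
}

#' Read presentation specifications from CSV
#'
#' @param path CSV with columns `presentation_id`, `barrier_id`, `level` and
#'   optionally `variant` (one row per presentation-barrier pair).
#' @param doses_path CSV with columns `presentation_id`, `doses_required`.
#' @param rubric A rubric table.
#' @param barrier_ids Barrier order for the score vectors.
#' @return A named list of [vaccine_presentation()] objects, one per
#'   `presentation_id`.
#' @export
read_presentations <- function(path, doses_path, rubric = default_rubric(),
                               barrier_ids = NULL) {
  specs <- readr::read_csv(path, show_col_types = FALSE)
  doses <- readr::read_csv(doses_path, show_col_types = FALSE)
  if (!all(c("presentation_id", "doses_required") %in% names(doses))) {
    validation_error("doses table must have columns presentation_id, doses_required")
  }
  ids <- unique(specs$presentation_id)
  no_doses <- setdiff(ids, doses$presentation_id)
  if (length(no_doses) > 0) {
    validation_error("no doses_required entry for presentation(s): %s",
                     paste(no_doses, collapse = ", "))
  }
  out <- lapply(ids, function(id) {
    score_presentation(specs[specs$presentation_id == id, ],
                       doses = doses$doses_required[match(id, doses$presentation_id)],
                       rubric = rubric, barrier_ids = barrier_ids)
  })
  stats::setNames(out, ids)
}
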