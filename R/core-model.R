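# Barrier-probability coverage model: per-barrier pass probabilities are
# multiplied under independence, raised to the dose count, then mapped to
# observed coverage through a linear calibration anchored at the calibration
# vaccine and at the maximum-coverage threshold.

validation_error <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...),
               class = c("vaximpact_validation_error", "vaximpact_error"))
}

check_probability <- function(x, what, allow_gt1 = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    validation_error("`%s` must be numeric with no missing values", what)
  }
  hi <- if (allow_gt1) Inf else 1
  if (any(x < 0 | x > hi)) {
    validation_error("`%s` must lie in [0, %s]; got %s", what,
                     if (allow_gt1) "Inf" else "1",
                     paste(signif(x[x < 0 | x > hi], 6), collapse = ", "))
  }
  invisible(x)
}

check_doses <- function(doses, what = "doses") {
  if (length(doses) != 1L || is.na(doses) || !is.numeric(doses) ||
      doses < 1 || doses != as.integer(doses)) {
    validation_error("`%s` must be a single integer >= 1", what)
  }
  as.integer(doses)
}

#' Population barrier profile
#'
#' Bundles, for one region (or one region-channel combination), the prevalence
#' of each technology-addressable barrier: the probability that an individual
#' does *not* overcome the barrier absent any helpful vaccine technology.
#' Dose requirements are not a profile entry; they enter through the dose
#' count of a [vaccine_presentation()].
#'
#' @param p Numeric vector of per-barrier failure prevalences, each in
#'   \[0, 1\]. Names are used as barrier identifiers when `barrier_ids` is not
#'   given.
#' @param barrier_ids Character vector of barrier identifiers, same length and
#'   order as `p`. The order is shared with any presentation the profile is
#'   combined with.
#' @return An object of class `population_profile`.
#' @examples
#' population_profile(c(access = 0.2, cold_chain = 0.5))
#' @export
population_profile <- function(p, barrier_ids = names(p)) {
  if (is.null(barrier_ids)) {
    barrier_ids <- paste0("barrier_", seq_along(p))
  }
  if (length(barrier_ids) != length(p)) {
    validation_error("`barrier_ids` must match `p` in length")
  }
  check_probability(p, "p")
  structure(list(barrier_ids = as.character(barrier_ids), p = unname(as.numeric(p))),
            class = "population_profile")
}

#' Vaccine presentation scores
#'
#' Bundles the technology scores of one vaccine presentation: for each barrier,
#' the degree (0 = no help, 1 = barrier fully neutralized) to which the
#' presentation helps individuals overcome it, plus the number of doses
#' required for full protection.
#'
#' @param v Numeric vector of per-barrier technology scores in \[0, 1\], in the
#'   same barrier order as the population profile it will be combined with.
#' @param doses Integer number of doses required for full protection (>= 1).
#' @param barrier_ids Character vector of barrier identifiers.
#' @return An object of class `vaccine_presentation`.
#' @examples
#' vaccine_presentation(c(access = 1, cold_chain = 0.6), doses = 1)
#' @export
vaccine_presentation <- function(v, doses = 1L, barrier_ids = names(v)) {
  if (is.null(barrier_ids)) {
    barrier_ids <- paste0("barrier_", seq_along(v))
  }
  if (length(barrier_ids) != length(v)) {
    validation_error("`barrier_ids` must match `v` in length")
  }
  check_probability(v, "v")
  structure(list(barrier_ids = as.character(barrier_ids),
                 v = unname(as.numeric(v)),
                 doses = check_doses(doses)),
            class = "vaccine_presentation")
}

#' @export
print.population_profile <- function(x, ...) {
  cat("<population_profile>", length(x$p), "barriers\n")
  print(stats::setNames(x$p, x$barrier_ids))
  invisible(x)
}

#' @export
print.vaccine_presentation <- function(x, ...) {
  cat("<vaccine_presentation>", length(x$v), "barriers,", x$doses, "dose(s)\n")
  print(stats::setNames(x$v, x$barrier_ids))
  invisible(x)
}

check_alignment <- function(profile, presentation) {
  stopifnot(inherits(profile, "population_profile"),
            inherits(presentation, "vaccine_presentation"))
  if (!identical(profile$barrier_ids, presentation$barrier_ids)) {
    validation_error(
      "barrier ids of profile (%s) and presentation (%s) do not align",
      paste(profile$barrier_ids, collapse = ", "),
      paste(presentation$barrier_ids, collapse = ", "))
  }
  invisible(TRUE)
}

#' Uncalibrated coverage of a presentation in a population
#'
#' Probability that an individual overcomes every technology-addressable
#' barrier for all required doses. Per barrier, the pass probability is
#' `1 - p_i * (1 - v_i)`; barriers are treated as independent, and each of the
#' `D` doses as an independent repetition, so the result is
#' `(prod_i [1 - p_i (1 - v_i)])^D`.
#'
#' @param profile A [population_profile()].
#' @param presentation A [vaccine_presentation()] with matching barrier ids.
#' @return A single probability in \[0, 1\].
#' @examples
#' prof <- population_profile(c(a = 0.2, b = 0.5, c = 0.5))
#' uncalibrated_coverage(prof, vaccine_presentation(c(a = 0, b = 0, c = 0)))
#' @export
uncalibrated_coverage <- function(profile, presentation) {
  check_alignment(profile, presentation)
  pass <- 1 - profile$p * (1 - presentation$v)
  prod(pass)^presentation$doses
}

#' Uncalibrated coverage of the least-desirable presentation
#'
#' The least-desirable presentation offers no technological help (all scores 0)
#' and requires the highest number of doses of any vaccine considered
#' (`d_worst`, default 4). Its uncalibrated coverage anchors the bottom of the
#' calibration line.
#'
#' @param profile A [population_profile()].
#' @param d_worst Dose count of the least-desirable presentation (integer >= 1).
#' @return A single probability in \[0, 1\].
#' @export
least_desirable_coverage <- function(profile, d_worst = 4L) {
  worst <- vaccine_presentation(rep(0, length(profile$p)),
                                doses = check_doses(d_worst, "d_worst"),
                                barrier_ids = profile$barrier_ids)
  uncalibrated_coverage(profile, worst)
}

#' Fit the linear calibration between uncalibrated and observed coverage
#'
#' Fits `C = S * U + intercept` through two anchor points: the hypothetical
#' ideal presentation (uncalibrated coverage 1, observed coverage
#' `max_coverage`) and the calibration vaccine (uncalibrated coverage
#' `calib_uncal`, observed coverage `calib_coverage`). The slope soaks up
#' non-technology-addressable barriers and violations of the independence
#' assumption; the intercept is the coverage the least-desirable presentation
#' would attain at uncalibrated coverage 0.
#'
#' `max_coverage` may exceed 1: reported administrative coverage rates used to
#' set the threshold sometimes do. Estimates above 1 are flagged invalid
#' downstream rather than clamped.
#'
#' @param max_coverage Maximum coverage threshold attainable through vaccine
#'   technology alone (probability; values > 1 allowed but flagged downstream).
#' @param calib_coverage Observed coverage of the calibration vaccine,
#'   must not exceed `max_coverage`.
#' @param calib_uncal Uncalibrated coverage of the calibration vaccine
#'   (strictly below 1).
#' @param worst_uncal Uncalibrated coverage of the least-desirable
#'   presentation, at most `calib_uncal`.
#' @return A `calibration_context`: list with `slope`, `intercept`, and the
#'   four inputs.
#' @examples
#' fit_calibration(0.9, 0.8, calib_uncal = 0.6, worst_uncal = 0.01)
#' @export
fit_calibration <- function(max_coverage, calib_coverage, calib_uncal, worst_uncal) {
  check_probability(max_coverage, "max_coverage", allow_gt1 = TRUE)
  check_probability(calib_coverage, "calib_coverage", allow_gt1 = TRUE)
  check_probability(calib_uncal, "calib_uncal")
  check_probability(worst_uncal, "worst_uncal")
  if (calib_uncal >= 1) {
    validation_error(paste0(
      "degenerate calibration: the calibration vaccine has uncalibrated ",
      "coverage 1, so the calibration line is undefined; ",
      "choose a calibration vaccine that faces at least one barrier"))
  }
  if (calib_coverage > max_coverage) {
    validation_error(
      "invalid threshold: calib_coverage (%g) exceeds max_coverage (%g)",
      calib_coverage, max_coverage)
  }
  if (worst_uncal > calib_uncal) {
    validation_error(
      "worst_uncal (%g) exceeds calib_uncal (%g): the least-desirable presentation cannot outperform the calibration vaccine",
      worst_uncal, calib_uncal)
  }
  slope <- (max_coverage - calib_coverage) / (1 - calib_uncal)
  structure(list(slope = slope,
                 intercept = calib_coverage - slope * calib_uncal,
                 max_coverage = max_coverage,
                 calib_coverage = calib_coverage,
                 calib_uncal = calib_uncal,
                 worst_uncal = worst_uncal),
            class = "calibration_context")
}

#' Map uncalibrated to calibrated coverage
#'
#' Applies the fitted linear calibration `S * U + intercept`. By construction
#' the calibration vaccine maps to its observed coverage and an uncalibrated
#' coverage of 1 maps to the maximum-coverage threshold.
#'
#' @param uncal Uncalibrated coverage (probability).
#' @param ctx A `calibration_context` from [fit_calibration()].
#' @return Calibrated coverage.
#' @export
calibrate <- function(uncal, ctx) {
  stopifnot(inherits(ctx, "calibration_context"))
  check_probability(uncal, "uncal")
  ctx$slope * uncal + ctx$intercept
}

#' Residual failure probability of a test presentation
#'
#' Probability that an individual still fails at least one
#' technology-addressable barrier under the test presentation, renormalized
#' against the least-desirable baseline: individuals who would have been
#' vaccinated even under the least-desirable presentation are not counted as
#' avertable.
#'
#' @param test_uncal Uncalibrated coverage of the test presentation.
#' @param worst_uncal Uncalibrated coverage of the least-desirable
#'   presentation; must not exceed `test_uncal` and must be < 1.
#' @return `1 - (test_uncal - worst_uncal) / (1 - worst_uncal)`, in \[0, 1\].
#' @export
residual_risk <- function(test_uncal, worst_uncal) {
  check_probability(test_uncal, "test_uncal")
  check_probability(worst_uncal, "worst_uncal")
  if (worst_uncal >= 1) {
    validation_error("degenerate baseline: worst_uncal must be < 1")
  }
  if (test_uncal < worst_uncal) {
    validation_error(
      "test_uncal (%g) is below worst_uncal (%g): the test presentation cannot be worse than the least-desirable one",
      test_uncal, worst_uncal)
  }
  1 - (test_uncal - worst_uncal) / (1 - worst_uncal)
}

#' Calibrated coverage estimate for a test presentation
#'
#' End-to-end estimate for one population: computes uncalibrated coverages of
#' the test, calibration and least-desirable presentations, fits the linear
#' calibration, and returns `C_t = M - k * x_t`, where `M` is the
#' maximum-coverage threshold, `k = M - C_l` the coverage headroom addressable
#' by technology (with `C_l` the calibrated coverage of the least-desirable
#' presentation), and `x_t` the residual failure probability of the test
#' presentation.
#'
#' Estimates above 1 (possible when `max_coverage` itself exceeds 1, e.g. from
#' administrative coverage reports) are returned unclamped with
#' `valid = FALSE`, signalling that the calibration vaccine is poorly matched
#' to the threshold; aggregation excludes such regions and reports their
#' cohort share.
#'
#' @param profile A [population_profile()].
#' @param test A [vaccine_presentation()]: the presentation under evaluation.
#' @param calib A [vaccine_presentation()]: the already-deployed calibration
#'   vaccine.
#' @param max_coverage Maximum coverage threshold (see [fit_calibration()]).
#' @param calib_coverage Observed coverage of the calibration vaccine.
#' @param d_worst Dose count of the least-desirable presentation (default 4).
#' @return A `coverage_estimate`: list with `coverage` (the estimate),
#'   `valid`, and all audit intermediates (`test_uncal`, `calib_uncal`,
#'   `worst_uncal`, `slope`, `intercept`, `floor_coverage`, `headroom`,
#'   `residual`, plus the inputs `max_coverage`, `calib_coverage`, `d_worst`).
#' @examples
#' prof <- population_profile(c(a = 0.2, b = 0.5))
#' est <- estimate_coverage(prof,
#'   test  = vaccine_presentation(c(a = 1, b = 0.8)),
#'   calib = vaccine_presentation(c(a = 0.5, b = 0.5)),
#'   max_coverage = 0.9, calib_coverage = 0.8)
#' est$coverage
#' @export
estimate_coverage <- function(profile, test, calib, max_coverage, calib_coverage,
                              d_worst = 4L) {
  test_uncal  <- uncalibrated_coverage(profile, test)
  calib_uncal <- uncalibrated_coverage(profile, calib)
  worst_uncal <- least_desirable_coverage(profile, d_worst)
  ctx <- fit_calibration(max_coverage, calib_coverage, calib_uncal, worst_uncal)
  floor_coverage <- calibrate(worst_uncal, ctx)
  headroom <- max_coverage - floor_coverage
  residual <- residual_risk(test_uncal, worst_uncal)
  coverage <- max_coverage - headroom * residual
  structure(list(coverage = coverage,
                 valid = coverage <= 1,
                 test_uncal = test_uncal,
                 calib_uncal = calib_uncal,
                 worst_uncal = worst_uncal,
                 slope = ctx$slope,
                 intercept = ctx$intercept,
                 floor_coverage = floor_coverage,
                 headroom = headroom,
                 residual = residual,
                 max_coverage = max_coverage,
                 calib_coverage = calib_coverage,
                 d_worst = as.integer(d_worst)),
            class = "coverage_estimate")
}

#' @export
print.coverage_estimate <- function(x, ...) {
  cat(sprintf("<coverage_estimate> %s (calibration vaccine: %s)%s\n",
              format_percent(x$coverage), format_percent(x$calib_coverage),
              if (x$valid) "" else " [INVALID: estimate > 100%]"))
  cat(sprintf("  headroom %s, residual failure probability %.4f\n",
              format_percent(x$headroom), x$residual))
  invisible(x)
}

#' Format a probability as a percentage string
#'
#' Probabilities are carried as fractions in \[0, 1\] throughout the model;
#' percent formatting (one decimal place) happens only at the reporting layer.
#'
#' @param x Numeric vector of probabilities.
#' @param digits Decimal places (default 1).
#' @return Character vector like `"83.8%"`.
#' @export
format_percent <- function(x, digits = 1) {
  sprintf(paste0("%.", digits, "f%%"), 100 * x)
}
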