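# Independent oracles and shared fixtures.

# Enumeration oracle for the coverage product: per barrier-dose trial,
# enumerate the four joint outcomes of "blocked by the barrier" (prob p_i)
# and "technology overcomes it" (prob v_i); a trial passes unless blocked and
# not overcome. Trials are independent, doses are repeated trials. This
# derives the pass probability as (1-p)v + (1-p)(1-v) + pv by outcome
# enumeration rather than using the model's 1 - p(1-v) expression.
enumerate_coverage <- function(p, v, doses) {
  outcomes <- expand.grid(blocked = c(TRUE, FALSE), helped = c(TRUE, FALSE))
  trial_pass <- function(pi, vi) {
    prob <- ifelse(outcomes$blocked, pi, 1 - pi) *
      ifelse(outcomes$helped, vi, 1 - vi)
    sum(prob[!outcomes$blocked | outcomes$helped])
  }
  pass <- vapply(seq_along(p), function(i) trial_pass(p[i], v[i]), numeric(1))
  prod(rep(pass, times = doses))
}

# Full-joint enumeration over all 2^m pass/fail patterns of the m = n * doses
# trials: checks the pattern probabilities sum to 1 and returns the all-pass
# pattern's probability. Only feasible for small m.
enumerate_joint <- function(p, v, doses) {
  fail <- rep(p * (1 - v), times = doses)
  m <- length(fail)
  stopifnot(m <= 12)
  patterns <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  probs <- apply(patterns, 1, function(w) {
    prod(ifelse(w == 1, 1 - fail, fail))
  })
  stopifnot(abs(sum(probs) - 1) < 1e-9)
  probs[which(rowSums(patterns) == m)]
}

# Single-region fixture with hand-traceable arithmetic: p = (0.2, 0.5),
# calibration presentation v = (0.5, 0.5) with 1 dose, test v = (1, 0.8) with
# 1 dose, M = 0.9, observed calibration coverage 0.8, worst case 4 doses.
worked_example <- function() {
  barriers <- c("a", "b")
  list(
    barriers = barriers,
    profile = population_profile(c(0.2, 0.5), barrier_ids = barriers),
    calib = vaccine_presentation(c(0.5, 0.5), doses = 1, barrier_ids = barriers),
    test = vaccine_presentation(c(1, 0.8), doses = 1, barrier_ids = barriers),
    max_coverage = 0.9,
    calib_coverage = 0.8,
    d_worst = 4L,
    # frozen exact expectations (rational arithmetic):
    calib_uncal = 0.675,          # 0.9 * 0.75
    worst_uncal = 0.0256,         # 0.4^4
    test_uncal = 0.9,             # 1 * 0.9
    slope = 4 / 13,               # 0.1 / 0.325
    intercept = 7.7 / 13,         # 0.8 - (4/13) * 0.675
    floor_coverage = 7.8024 / 13,
    headroom = 3.8976 / 13,
    residual = 0.1 / 0.9744,
    coverage = 56.5 / 65)         # 0.9 - (4/13) * 0.1
}

# In-memory scenario config for the worked example: one region, one routine
# channel, indicators resolving to p = (0.2, 0.5), pre-scored presentations.
worked_scenario_config <- function() {
  wx <- worked_example()
  list(
    barriers = wx$barriers,
    regions = tibble::tibble(
      region_id = "R1", country_id = "R1", births = 1000,
      calib_coverage = wx$calib_coverage, max_coverage = wx$max_coverage,
      routine_share = 1),
    indicators = tibble::tibble(
      region_id = "R1", barrier_id = wx$barriers, priority = 1L,
      value = c(0.2, 0.5), source = "fixture", complement = 0L),
    presentations = list(calib = wx$calib, test = wx$test),
    doses = tibble::tibble(presentation_id = c("calib", "test"),
                           doses_required = c(1L, 1L)),
    calibration = "calib",
    tests = "test",
    d_worst = wx$d_worst,
    channels = list(list(id = "routine", share = 1)))
}

# Random valid calibration setting; returns the pieces needed by the
# identity/property tests. Assumes the calibration presentation needs no
# more doses than the least-desirable one, so its uncalibrated coverage
# dominates the worst case by construction.
random_setting <- function(n_barriers = sample(1:5, 1)) {
  ids <- paste0("b", seq_len(n_barriers))
  profile <- population_profile(runif(n_barriers, 0.01, 0.95), barrier_ids = ids)
  calib <- vaccine_presentation(runif(n_barriers), doses = sample(1:3, 1),
                                barrier_ids = ids)
  calib_coverage <- runif(1, 0.2, 0.9)
  list(profile = profile,
       calib = calib,
       calib_coverage = calib_coverage,
       max_coverage = calib_coverage + runif(1) * (1 - calib_coverage),
       d_worst = sample(4:6, 1))
}
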