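test_that("uncalibrated coverage reproduces the worked barrier products", {
  prof3 <- population_profile(c(0.20, 0.50, 0.50), barrier_ids = c("x", "y", "z"))
  none <- vaccine_presentation(c(0, 0, 0), barrier_ids = c("x", "y", "z"))
  some <- vaccine_presentation(c(1.0, 0.6, 0), barrier_ids = c("x", "y", "z"))
  expect_equal(uncalibrated_coverage(prof3, none), 0.20)
  expect_equal(uncalibrated_coverage(prof3, some), 0.40)

  perfect <- vaccine_presentation(c(1, 1, 1), doses = 7, barrier_ids = c("x", "y", "z"))
  expect_equal(uncalibrated_coverage(prof3, perfect), 1.0)

  prof2 <- population_profile(c(0.3, 0.1), barrier_ids = c("x", "y"))
  two_dose <- vaccine_presentation(c(0.5, 0.5), doses = 2, barrier_ids = c("x", "y"))
  expect_equal(uncalibrated_coverage(prof2, two_dose), (0.85 * 0.95)^2)
  expect_equal(uncalibrated_coverage(prof2, two_dose), 0.65205625)
})

test_that("profile/presentation validation names the offending field", {
  expect_error(population_profile(c(0.2, 1.4)), "`p`",
               class = "vaximpact_validation_error")
  expect_error(vaccine_presentation(c(0.2, -0.1)), "`v`",
               class = "vaximpact_validation_error")
  expect_error(vaccine_presentation(0.5, doses = 0), "`doses`",
               class = "vaximpact_validation_error")
  expect_error(vaccine_presentation(0.5, doses = 1.5), "`doses`",
               class = "vaximpact_validation_error")
  prof <- population_profile(c(a = 0.2, b = 0.3))
  pres <- vaccine_presentation(c(b = 0.2, a = 0.3))
  expect_error(uncalibrated_coverage(prof, pres), "do not align",
               class = "vaximpact_validation_error")
})

test_that("least-desirable coverage is the zero-score, max-dose case", {
  prof <- population_profile(c(0.2, 0.5), barrier_ids = c("a", "b"))
  expect_equal(least_desirable_coverage(prof, 4), 0.4^4)
  expect_equal(least_desirable_coverage(prof, 4), 0.0256)
  expect_equal(least_desirable_coverage(population_profile(c(0, 0, 0)), 9), 1.0)
  expect_equal(
    least_desirable_coverage(population_profile(c(1, 0.5), barrier_ids = c("a", "b")), 1),
    0.0)
})

test_that("calibration line fits through the two anchor points", {
  ctx <- fit_calibration(0.9, 0.8, calib_uncal = 0.6, worst_uncal = 0.1)
  expect_equal(ctx$slope, 0.25)
  expect_equal(ctx$intercept, 0.65)
  expect_equal(calibrate(0.0256, ctx), 0.6564)
  # anchor identities
  expect_equal(calibrate(0.6, ctx), 0.8, tolerance = 1e-12)
  expect_equal(calibrate(1, ctx), 0.9, tolerance = 1e-12)
  # no headroom: slope collapses to zero
  expect_equal(fit_calibration(0.8, 0.8, 0.5, 0.2)$slope, 0)
  expect_error(fit_calibration(0.9, 0.8, calib_uncal = 1, worst_uncal = 0.5),
               "degenerate", class = "vaximpact_validation_error")
  expect_error(fit_calibration(0.7, 0.8, calib_uncal = 0.5, worst_uncal = 0.2),
               "exceeds max_coverage", class = "vaximpact_validation_error")
})

test_that("residual risk renormalizes against the least-desirable baseline", {
  expect_equal(residual_risk(0.37, 0.37), 1.0)
  expect_equal(residual_risk(1, 0.37), 0.0)
  expect_equal(residual_risk(0.5, 0.0256), 1 - 0.4744 / 0.9744)
  expect_error(residual_risk(0.1, 0.2), "cannot be worse",
               class = "vaximpact_validation_error")
  expect_error(residual_risk(1, 1), "degenerate",
               class = "vaximpact_validation_error")
})

test_that("the full estimate reproduces the hand-traced fixture", {
  wx <- worked_example()
  est <- estimate_coverage(wx$profile, wx$test, wx$calib,
                           wx$max_coverage, wx$calib_coverage, wx$d_worst)
  expect_equal(est$calib_uncal, wx$calib_uncal)
  expect_equal(est$worst_uncal, wx$worst_uncal)
  expect_equal(est$test_uncal, wx$test_uncal)
  expect_equal(est$slope, wx$slope)
  expect_equal(est$intercept, wx$intercept)
  expect_equal(est$floor_coverage, wx$floor_coverage)
  expect_equal(est$headroom, wx$headroom)
  expect_equal(est$residual, wx$residual)
  expect_equal(est$coverage, wx$coverage)
  expect_true(est$valid)
})

test_that("estimating the calibration vaccine returns its observed coverage", {
  wx <- worked_example()
  est <- estimate_coverage(wx$profile, wx$calib, wx$calib,
                           wx$max_coverage, wx$calib_coverage, wx$d_worst)
  expect_equal(est$coverage, wx$calib_coverage, tolerance = 1e-12)
  perfect <- vaccine_presentation(c(1, 1), doses = 1, barrier_ids = wx$barriers)
  est_m <- estimate_coverage(wx$profile, perfect, wx$calib,
                             wx$max_coverage, wx$calib_coverage, wx$d_worst)
  expect_equal(est_m$coverage, wx$max_coverage, tolerance = 1e-12)
  expect_equal(est_m$residual, 0)
})

test_that("coverage product stays in range and is monotone in its inputs", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(1:5, 1)
    ids <- paste0("b", seq_len(n))
    p <- runif(n)
    v <- runif(n)
    doses <- sample(1:5, 1)
    prof <- population_profile(p, barrier_ids = ids)
    pres <- vaccine_presentation(v, doses = doses, barrier_ids = ids)
    u <- uncalibrated_coverage(prof, pres)
    expect_gte(u, 0)
    expect_lte(u, 1)

    i <- sample(n, 1)
    v_up <- v; v_up[i] <- min(1, v[i] + runif(1))
    expect_gte(uncalibrated_coverage(prof, vaccine_presentation(v_up, doses, ids)), u)
    p_up <- p; p_up[i] <- min(1, p[i] + runif(1))
    expect_lte(uncalibrated_coverage(population_profile(p_up, ids), pres), u)
    expect_lte(uncalibrated_coverage(prof, vaccine_presentation(v, doses + 1L, ids)), u)
  }
})

test_that("estimate boundaries collapse as the model predicts", {
  set.seed(7)
  for (rep in 1:50) {
    s <- random_setting()
    n <- length(s$profile$p)
    ids <- s$profile$barrier_ids
    # test equal to the worst case: estimate collapses to the coverage floor
    worst <- vaccine_presentation(rep(0, n), doses = s$d_worst, barrier_ids = ids)
    est <- estimate_coverage(s$profile, worst, s$calib,
                             s$max_coverage, s$calib_coverage, s$d_worst)
    expect_equal(est$coverage, est$floor_coverage, tolerance = 1e-9)
    expect_equal(est$residual, 1)
    # perfect test: estimate hits the maximum-coverage threshold
    perfect <- vaccine_presentation(rep(1, n), doses = 1, barrier_ids = ids)
    est_m <- estimate_coverage(s$profile, perfect, s$calib,
                               s$max_coverage, s$calib_coverage, s$d_worst)
    expect_equal(est_m$coverage, s$max_coverage, tolerance = 1e-12)
    # estimate is monotone in each test technology score
    v <- runif(n)
    base <- estimate_coverage(s$profile,
                              vaccine_presentation(v, s$d_worst, ids),
                              s$calib, s$max_coverage, s$calib_coverage,
                              s$d_worst)
    i <- sample(n, 1)
    v[i] <- min(1, v[i] + runif(1))
    up <- estimate_coverage(s$profile,
                            vaccine_presentation(v, s$d_worst, ids),
                            s$calib, s$max_coverage, s$calib_coverage,
                            s$d_worst)
    expect_gte(up$coverage, base$coverage - 1e-12)
  }
})

test_that("estimates above 100% are flagged invalid, not clamped", {
  # an administrative maximum-coverage threshold above 1 combined with a
  # strong test presentation pushes the estimate past 100%
  prof <- population_profile(c(0.3, 0.4), barrier_ids = c("a", "b"))
  calib <- vaccine_presentation(c(0.2, 0.2), doses = 1, barrier_ids = c("a", "b"))
  test <- vaccine_presentation(c(1, 1), doses = 1, barrier_ids = c("a", "b"))
  est <- estimate_coverage(prof, test, calib, max_coverage = 1.2,
                           calib_coverage = 0.5, d_worst = 4)
  expect_false(est$valid)
  expect_gt(est$coverage, 1)
})

test_that("percent formatting is one decimal place at the reporting layer", {
  expect_identical(format_percent(0.838), "83.8%")
  expect_identical(format_percent(c(0.03, 1)), c("3.0%", "100.0%"))
})
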