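# Series anchored to the published observations: psychrotrophic counts reach
# 7.02 log CFU/g at day 14; putrescine 3.28 -> 409.97 mg/kg over days 1-14.
psychro_observed <- function() {
  line <- kw_reference_lines()$psychrotrophic
  days <- c(1, 4, 8, 11, 14, 18)
  v <- line$slope * days + line$intercept
  v[days == 14] <- 7.02   # published observed count
  indicator_series("psychrotrophic", "log CFU/g", days, v)
}

putrescine_observed <- function() {
  am <- kw_amine_series()
  p <- am[am$amine == "putrescine", ]
  indicator_series("putrescine", "mg/kg", p$day, p$value_mg_kg)
}

test_that("indicator series and rules validate their invariants", {
  expect_error(indicator_series("x", "", 1:3, 1:3), "units")
  expect_error(indicator_series("x", "u", c(1, 1, 2), 1:3), "increasing")
  expect_error(indicator_series("x", "u", 1:2, c(1, NA)), "finite")
  expect_error(limit_rule("x", Inf), "finite")
  expect_error(limit_rule("x", 1, "sideways"))
})

test_that("first_crossing_day finds the published limit exceedances", {
  r7 <- limit_rule("psychrotrophic", 7, "at_or_above", units = "log CFU/g")
  expect_equal(first_crossing_day(psychro_observed(), r7), 14)

  # mesophilic counts never reach 7 log within 18 days
  ml <- kw_reference_lines()$mesophilic
  days <- c(1, 4, 8, 11, 14, 18)
  meso <- indicator_series("mesophilic", "log CFU/g", days,
                           ml$slope * days + ml$intercept)
  expect_true(is.na(first_crossing_day(
    meso, limit_rule("mesophilic", 7, "at_or_above", units = "log CFU/g"))))

  # putrescine exceeds the 20 mg/kg low-quality band on day 8 (24.41 mg/kg)
  rule20 <- limit_rule("putrescine", 20, "above", units = "mg/kg")
  expect_equal(first_crossing_day(putrescine_observed(), rule20), 8)

  expect_error(
    first_crossing_day(meso, limit_rule("mesophilic", 7, "at_or_above",
                                        units = "CFU/g")),
    "units mismatch")
})

test_that("raising an at_or_above threshold never returns an earlier day", {
  s <- psychro_observed()
  prev <- -Inf
  for (thr in c(5, 6, 6.5, 7, 7.2)) {
    d <- first_crossing_day(s, limit_rule("psychrotrophic", thr, "at_or_above",
                                          units = "log CFU/g"))
    d <- ifelse(is.na(d), Inf, d)
    expect_gte(d, prev)
    prev <- d
  }
})

test_that("continuous crossing day solves the fitted line", {
  expect_equal(crossing_day_continuous(linear_fit(1, 0),
                                       limit_rule("x", 7, "at_or_above")), 7)
  line <- kw_reference_lines()$psychrotrophic
  d <- crossing_day_continuous(linear_fit(line$slope, line$intercept),
                               limit_rule("psychrotrophic", 7, "at_or_above"))
  expect_equal(d, (7 - 4.5679) / 0.1593, tolerance = 1e-12)
  expect_equal(round(d, 2), 15.27)
  # decreasing line already beyond an at_or_above limit at day 0
  expect_equal(crossing_day_continuous(linear_fit(-0.5, 9),
                                       limit_rule("x", 7, "at_or_above")), 0)
  # moving away from the limit: no crossing
  expect_true(is.na(crossing_day_continuous(linear_fit(-0.5, 3),
                                            limit_rule("x", 7, "at_or_above"))))
  expect_warning(dd <- crossing_day_continuous(linear_fit(0, 3),
                                               limit_rule("x", 7, "at_or_above")),
                 "zero slope")
  expect_true(is.na(dd))
})

test_that("discrete and continuous crossings agree within one sampling step", {
  line <- kw_reference_lines()$psychrotrophic
  days <- c(1, 4, 8, 11, 14, 18)
  s <- indicator_series("psychrotrophic", "log CFU/g", days,
                        line$slope * days + line$intercept)
  rule <- limit_rule("psychrotrophic", 7, "at_or_above", units = "log CFU/g")
  d_disc <- first_crossing_day(s, rule)
  d_cont <- crossing_day_continuous(linear_fit(line$slope, line$intercept), rule)
  expect_equal(d_disc, 18)  # first grid day at/above 7 on the noiseless line
  gap <- max(diff(days))
  expect_lte(abs(d_disc - d_cont), gap)
})

test_that("amine classification partitions concentrations as published", {
  expect_identical(classify_amine(3.28), "fresh")      # day-1 level
  expect_identical(classify_amine(409.97), "low_quality")  # day-14 level
  expect_identical(classify_amine(10), "intermediate")  # boundary inclusive
  expect_identical(classify_amine(20), "intermediate")
  expect_identical(classify_amine(c(0, 9.999, 10.001, 19.99, 20.01)),
                   c("fresh", "fresh", "intermediate", "intermediate",
                     "low_quality"))
  expect_error(classify_amine(-1), ">= 0")
})

test_that("pearson validates inputs and matches known correlations", {
  expect_equal(pearson(1:3, 1:3), 1)
  expect_equal(pearson(1:3, 3:1), -1)
  days <- c(1, 4, 8, 11, 14, 18)
  qi <- 0.9281 * days + 1.3378
  psy <- 0.1593 * days + 4.5679
  expect_equal(pearson(qi, psy), 1, tolerance = 1e-12)
  # invariance under positive affine rescaling
  set.seed(2)
  a <- stats::rnorm(10); b <- stats::rnorm(10)
  expect_equal(pearson(3 * a + 5, b), pearson(a, b), tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), "constant")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("correlation matrix is symmetric, unit-diagonal, day-aligned", {
  pan <- aggregate_panel(
    panel_from_qi(stats::setNames(as.list(c(2, 5, 9, 12, 14, 18)),
                                  c(1, 4, 8, 11, 14, 18)), kw_protocol),
    kw_protocol)
  cm <- correlation_matrix(pan, list(psychro_observed()))
  expect_equal(diag(cm), c(qi = 1, psychrotrophic = 1))
  expect_equal(cm, t(cm))
  expect_gt(cm["qi", "psychrotrophic"], 0.9)

  # an indicator identical to the QI gives off-diagonal 1
  ident <- indicator_series("mirror", "demerit", pan$summary$storage_day,
                            pan$summary$qi_mean)
  cm2 <- correlation_matrix(pan, list(ident))
  expect_equal(cm2["qi", "mirror"], 1, tolerance = 1e-12)

  short <- indicator_series("short", "u", c(1, 4), c(1, 2))
  expect_error(correlation_matrix(pan, list(short)), "common days")
})
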