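toy_X <- matrix(c(0, 1, 2,
                  1, 0, 1,
                  2, 2, 0,
                  3, 1, 3,
                  4, 3, 1,
                  5, 2, 4), nrow = 6, byrow = TRUE)
toy_y <- c(1, 2, 3, 5, 8, 11)

test_that("NIPALS structure: unit-norm weights, orthogonal scores, deflation", {
  m <- fit_pls1(toy_X, toy_y, ncomp = 2)
  expect_equal(colSums(m$weights^2), rep(1, 2), tolerance = 1e-12)
  # score orthogonality
  expect_lt(abs(crossprod(m$scores[, 1], m$scores[, 2])),
            1e-8 * sqrt(sum(m$scores[, 1]^2) * sum(m$scores[, 2]^2)))
  # deflation conserves the Frobenius norm of centred/scaled X
  Xc <- scale(toy_X)
  m3 <- fit_pls1(toy_X, toy_y, ncomp = 3)
  rank1 <- vapply(seq_len(m3$ncomp), function(a)
    sum(tcrossprod(m3$scores[, a], m3$x_loadings[, a])^2), numeric(1))
  resid <- Xc
  for (a in seq_len(m3$ncomp))
    resid <- resid - tcrossprod(m3$scores[, a], m3$x_loadings[, a])
  expect_equal(sum(Xc^2), sum(rank1) + sum(resid^2), tolerance = 1e-8)
})

test_that("one-predictor PLS1 equals simple OLS; full rank equals OLS", {
  x1 <- toy_X[, 1, drop = FALSE]
  m <- fit_pls1(x1, toy_y, ncomp = 1)
  ols <- stats::lm(toy_y ~ x1)
  expect_equal(m$fitted, unname(stats::fitted(ols)), tolerance = 1e-10)

  m3 <- fit_pls1(toy_X, toy_y, ncomp = 3, scale = FALSE)
  ols3 <- stats::lm(toy_y ~ toy_X)
  expect_equal(m3$fitted, unname(stats::fitted(ols3)), tolerance = 1e-8)
  m3s <- fit_pls1(toy_X, toy_y, ncomp = 3, scale = TRUE)
  expect_equal(m3s$fitted, unname(stats::fitted(ols3)), tolerance = 1e-8)
})

test_that("predictions match an independent PLS implementation", {
  # frozen predictions from scikit-learn PLSRegression on this toy set
  sk <- list(
    "1_scaled" = c(1.6557539789, 0.6187540345, 3.5768830551,
                   5.8683692543, 7.9943767390, 10.2858629382),
    "2_scaled" = c(1.5183514366, 0.9587317277, 3.1889187567,
                   6.2136837868, 7.5477746311, 10.5725396611),
    "1_raw" = c(1.0474550191, 1.3071112588, 3.2545330559,
                6.2838558514, 7.5388610096, 10.5681838051),
    "2_raw" = c(0.9030308424, 1.2738341821, 3.4717798960,
                6.1445576942, 7.7670097935, 10.4397875917))
  for (a in 1:2) for (sc in c(TRUE, FALSE)) {
    key <- paste0(a, if (sc) "_scaled" else "_raw")
    m <- fit_pls1(toy_X, toy_y, ncomp = a, scale = sc)
    expect_equal(predict(m, toy_X), sk[[key]], tolerance = 1e-8,
                 info = key)
    expect_equal(m$fitted, sk[[key]], tolerance = 1e-8, info = key)
  }
})

test_that("predict reproduces fitted values, handles the mean row, validates", {
  m <- fit_pls1(toy_X, toy_y, ncomp = 2)
  expect_equal(predict(m, toy_X), m$fitted, tolerance = 1e-12)
  expect_equal(predict(m, matrix(colMeans(toy_X), 1)), mean(toy_y),
               tolerance = 1e-10)
  expect_error(predict(m, toy_X[, 1:2]), "columns")
  expect_error(fit_pls1(toy_X, toy_y, ncomp = 9), "ncomp")
})

test_that("orthonormal-X toy: first weight picks the informative column", {
  # X columns orthonormal after centering; y equal to the first column
  X <- cbind(c(-1, -1, 1, 1) / 2, c(-1, 1, -1, 1) / 2)
  y <- X[, 1]
  m <- fit_pls1(X, y, ncomp = 1, scale = FALSE)
  expect_equal(abs(m$weights[, 1]), c(1, 0), tolerance = 1e-12)
  expect_equal(m$y_loadings[1] * sum(m$scores[, 1]^2),
               sum(y * m$scores[, 1]), tolerance = 1e-12)
  expect_equal(m$fitted, y, tolerance = 1e-12)
})

test_that("VIP normalisation and informative-variable ordering", {
  m1 <- fit_pls1(toy_X[, 1, drop = FALSE], toy_y, ncomp = 1)
  expect_equal(unname(vip_scores(m1)$vip), 1, tolerance = 1e-12)

  for (a in 1:3) {
    m <- fit_pls1(toy_X, toy_y, ncomp = a)
    v <- vip_scores(m)$vip
    expect_equal(sum(v^2), 3, tolerance = 1e-9)   # sum VIP^2 = p
  }

  # y depends only on predictor 1 (noiseless): VIP1 > 1 > VIP2
  set.seed(4)
  X <- cbind(stats::rnorm(20), stats::rnorm(20))
  y <- 2 * X[, 1]
  v <- vip_scores(fit_pls1(X, y, ncomp = 1))$vip
  expect_gt(v[1], 1); expect_lt(v[2], 1)
  expect_identical(vip_scores(fit_pls1(X, y, ncomp = 1))$selected,
                   names(v)[1])
})

test_that("noiseless rank-one data stops early with a warning", {
  X <- cbind(1:6, (1:6) * 2)  # rank 1 after centering
  y <- as.numeric(1:6)
  expect_warning(m <- fit_pls1(X, y, ncomp = 2), "exhausted")
  expect_equal(m$ncomp, 1)
  expect_equal(m$fitted, y, tolerance = 1e-10)
})

test_that("leave-one-out CV finds the single latent factor and is stable", {
  # noiseless rank-one relationship: one component is enough
  n <- 12
  latent <- seq(0, 5, length.out = n)
  X1 <- cbind(latent, 2 * latent)
  cv1 <- suppressWarnings(loo_cv_pls(X1, 3 * latent, ncomp_max = 2))
  expect_lt(cv1$rmsecv[1], 1e-8)
  expect_equal(cv1$chosen_ncomp, 1)

  # default-config panel data carry one latent freshness factor: the chosen
  # component count stays small
  pan <- aggregate_panel(
    simulate_panel_scores(sim_config(seed = 1), kw_protocol), kw_protocol)
  Xp <- as.matrix(pan$parameter_means[, -1])
  cvp <- loo_cv_pls(Xp, pan$parameter_means$storage_day, ncomp_max = 3)
  expect_true(cvp$chosen_ncomp %in% c(1, 2))
  expect_lt(min(cvp$rmsecv), 2)  # days predicted to within a couple of days

  # permutation invariance
  set.seed(8)
  X <- cbind(latent + stats::rnorm(n, 0, 0.05),
             2 * latent + stats::rnorm(n, 0, 0.05),
             stats::rnorm(n))
  y <- 3 * latent + stats::rnorm(n, 0, 0.1)
  cv <- loo_cv_pls(X, y, ncomp_max = 3)
  perm <- sample(n)
  cv2 <- loo_cv_pls(X[perm, ], y[perm], ncomp_max = 3)
  expect_equal(cv2$chosen_ncomp, cv$chosen_ncomp)
  expect_equal(sort(cv2$rmsecv), sort(cv$rmsecv), tolerance = 1e-9)
  expect_error(loo_cv_pls(X[1:2, ], y[1:2], 1), "n >= 3")
})
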