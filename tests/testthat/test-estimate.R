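test_that("rmse basics", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(4, 5, 6), c(1, 2, 3)), 3)
  expect_equal(rmse(c(1, 2, 3), c(2, 2, 2)), sqrt(2 / 3))
  expect_error(rmse(1:3, 1:4), "lengths differ")
})

test_that("polynomial fit: exact interpolation, constants, noise floor", {
  x <- c(-1, 0.5, 2, 3)
  m <- fit_poly(x, x^3)
  expect_equal(m$train_rmse, 0, tolerance = 1e-8)
  expect_equal(unname(m$coefficients[4]), 1, tolerance = 1e-8)

  mc <- fit_poly(1:10, rep(7, 10))
  expect_equal(unname(mc$coefficients), c(7, 0, 0, 0), tolerance = 1e-8)

  # Monte-Carlo oracle: training RMSE of a cubic + N(0, 2) noise sits
  # near sigma * sqrt((n - p) / n); the seed median lands in the stated
  # band and no seed strays far
  set.seed(8)
  rmses <- replicate(50, {
    x <- runif(200, -2, 2)
    y <- 1 + 2 * x - x^2 + 0.5 * x^3 + rnorm(200, sd = 2)
    fit_poly(x, y)$train_rmse
  })
  expect_gt(median(rmses), 2 * 0.8)
  expect_lt(median(rmses), 2 * 1.1)
  expect_true(all(rmses > 2 * 0.7 & rmses < 2 * 1.2))
})

test_that("polynomial fit detects rank deficiency and names the terms", {
  x <- cbind(a = rep(1, 20), b = rnorm(20))   # constant first input
  expect_error(fit_poly(x, rnorm(20)), "deficient")
  expect_error(fit_poly(1:3, 1:3), "at least")
})

test_that("bivariate basis is the full total-degree-3 monomial set", {
  set.seed(2)
  X <- cbind(runif(100, 1, 3), runif(100, 0.01, 0.06))
  y <- rnorm(100, 120, 8)
  m <- fit_poly(X, y)
  expect_length(m$coefficients, 10)
  # nested-basis property: adding a feature cannot raise training RMSE
  m1 <- fit_poly(X[, 1], y)
  expect_lte(m$train_rmse, m1$train_rmse + 1e-10)
})

test_that("predict.poly_model round-trips the design", {
  X <- cbind(runif(50, 1, 4), runif(50, 0, 1))
  y <- 2 + X[, 1] - 3 * X[, 2] + X[, 1] * X[, 2]
  m <- fit_poly(X, y)
  expect_equal(predict(m, X), y, tolerance = 1e-8)
  expect_error(predict(m, X[, 1, drop = FALSE]), "input column")
})

test_that("MLP: null target, representable linear target, determinism", {
  set.seed(3)
  X <- matrix(runif(200, 2, 5), ncol = 1)
  spec <- mlp_spec(seed = 5)

  m0 <- suppressWarnings(fit_mlp(X, rep(0, 200), spec))
  expect_lt(max(abs(predict(m0, X))), 1e-3)

  y <- 3 * X[, 1] + 5
  ml <- suppressWarnings(fit_mlp(X, y, spec))
  expect_lt(rmse(predict(ml, X), y), 0.5)

  ml2 <- suppressWarnings(fit_mlp(X, y, spec))
  expect_identical(ml$theta, ml2$theta)
  expect_identical(predict(ml, X), predict(ml2, X))
})

test_that("MLP cross-validation partitions exactly and avoids leakage", {
  set.seed(13)
  X <- cbind(rnorm(100), rnorm(100))
  y <- rowSums(X) + rnorm(100, sd = 0.1)
  spec <- mlp_spec(seed = 2, max_iters = 50)
  m <- suppressWarnings(fit_mlp(X, y, spec))
  # folds are a disjoint exhaustive partition
  expect_equal(sort(unique(m$fold_assignment)), 1:5)
  expect_equal(length(m$fold_assignment), 100)
  expect_equal(as.vector(table(m$fold_assignment)), rep(20, 5))
  # standardization parameters equal recomputation on training folds only
  tr <- m$fold_assignment != m$best_fold
  expect_equal(m$standardization$mu, colMeans(X[tr, ]))
  expect_equal(m$standardization$sd, apply(X[tr, ], 2, sd))
  expect_equal(m$standardization$y_mu, mean(y[tr]))
})

test_that("evaluation report structure and training-error sanity", {
  coh <- generate_cohort(seed = 19)
  f <- cohort_features(coh)
  rep <- suppressWarnings(
    evaluate_models(f, mlp_spec(seed = 19, max_iters = 60)))
  expect_s3_class(rep, "evaluation_report")
  expect_equal(nrow(rep$results), 6)    # 3 feature sets x 2 targets
  expect_equal(rep$n_train, 175)
  expect_equal(rep$n_test, 25)
  expect_true(all(rep$results$poly_train_rmse >= 0))
  # medicated outlier excluded: 250 readings - 50 = 200 = 175 + 25
  expect_equal(rep$n_train + rep$n_test, 200)
  w <- capture_warnings(
    evaluate_models(f, mlp_spec(seed = 19, max_iters = 5),
                    exclude_subjects = 99))
  expect_true(any(grepl("not present", w)))
})

test_that("zero-noise cohort: K1/K2 recovery and near-exact PWV fit", {
  z <- generate_cohort(noise = zero_noise_spec(), seed = 23)
  f <- cohort_features(z)
  for (sid in c(1, 4)) {
    r <- z$readings[z$readings$subject_id == sid, ]
    fit <- fit_ptt_bp(r$ptt_s, r$dbp_mmhg)
    truth <- z$subjects[[sid]]$bp_params
    expect_equal(fit$K1, truth$K1, tolerance = 1e-6)
    expect_equal(fit$K2, truth$K2, tolerance = 1e-6)
  }
  # DBP is linear in PWV per subject, so a cubic fits it exactly
  s1 <- f[f$subject_id == 1, ]
  m <- fit_poly(s1$pwv_mps, s1$dbp_mmhg)
  expect_lt(m$train_rmse, 0.5)
})

test_that("shuffled labels leave only the variance floor", {
  set.seed(29)
  coh <- generate_cohort(seed = 29)
  f <- cohort_features(coh)
  f <- f[f$subject_id != 3, ]
  y <- sample(f$dbp_mmhg)
  m <- fit_poly(f[, c("pwv_mps", "auc_s")], y)
  expect_lt(abs(m$train_rmse - sd(y)) / sd(y), 0.15)
})
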