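test_that("min-max scaling hits the endpoints and inverts exactly", {
  r <- minmax_fit_transform(c(0, 10))
  expect_equal(as.numeric(r$scaled), c(-1, 1))
  expect_equal(as.numeric(minmax_transform(5, r$state)), 0)

  set.seed(61)
  X <- matrix(runif(200, -50, 70), ncol = 2)
  st <- minmax_fit(X)
  expect_lt(max(abs(minmax_inverse(minmax_transform(X, st), st) - X)), 1e-12)
  expect_error(minmax_fit(rep(3, 10)), "constant")
})

test_that("regression specs enforce the hyperparameter menus", {
  expect_error(regression_spec("nn", nn_hidden = 3), "5..20")
  expect_error(regression_spec("tree", tree_min_leaf = 7), "4, 12, 36")
  expect_error(regression_spec("svm", svm_sigma = 0.5), "0.35")
  expect_silent(regression_spec("svm", svm_kernel = "cubic"))
})

test_that("the NN represents the identity map to high accuracy", {
  x <- seq(-1, 1, length.out = 500)
  m <- train_regressor(regression_spec("nn", nn_hidden = 5, seed = 3), cbind(x), x)
  pred <- predict(m, cbind(x))
  expect_lt(sqrt(mean((pred - x)^2)) / diff(range(x)), 0.01)
})

test_that("a constant offset is removed by the fitted correction", {
  set.seed(62)
  x <- runif(800, -20, 40)
  m <- fit_drift_model(x + 3, x, spec = regression_spec("nn", nn_hidden = 5, seed = 4))
  resid <- apply_correction(m, x + 3) - x
  expect_lt(abs(mean(resid)), 0.1)
})

test_that("leaf and branch minima cap the tree size", {
  set.seed(63)
  X <- matrix(runif(300), ncol = 2)
  y <- rnorm(150)
  fit <- train_regressor(regression_spec("tree", tree_min_leaf = 100), X, y)
  # branch minimum 200 > n: the tree cannot split at all
  expect_lte(nrow(fit$fit$frame), 3L)
})

test_that("all three regressor families learn a noiseless linear relation", {
  set.seed(64)
  x <- runif(600, -1, 1)
  y <- 0.8 * x - 0.1
  for (spec in list(regression_spec("nn", nn_hidden = 5, seed = 1),
                    regression_spec("tree", tree_min_leaf = 4,
                                    tree_min_branch = 10L),
                    regression_spec("svm", svm_kernel = "linear", svm_C = 10))) {
    m <- train_regressor(spec, cbind(x), y)
    pred <- predict(m, cbind(x))
    expect_gt(1 - sum((y - pred)^2) / sum((y - mean(y))^2), 0.95)
  }
})

test_that("cross-validation recovers a perfect relation and rejects pure noise", {
  set.seed(65)
  t <- seq(0, 30, length.out = 2000)
  ref <- 10 * sin(2 * pi * t)
  test <- ref * 1.05 + 2
  spec <- regression_spec("nn", nn_hidden = 5, seed = 5)
  cv <- cross_validate(spec, cbind(test), ref)
  expect_gte(cv$mean_r2, 0.99)

  Xn <- matrix(runif(10000, -1, 1), ncol = 2)
  yn <- runif(5000, -1, 1)
  cvn <- cross_validate(spec, Xn, yn)
  expect_lte(abs(cvn$mean_r2), 0.1)

  cv2 <- cross_validate(spec, cbind(test), ref)
  expect_identical(cv, cv2)  # seeded determinism
})

test_that("subject-wise folds keep the fit user-independent", {
  set.seed(66)
  n_per <- 600
  subj <- rep(1:5, each = n_per)
  t <- rep(seq(0, 6, length.out = n_per), 5)
  ref <- 10 * sin(2 * pi * t) + rep(runif(5, -3, 3), each = n_per)
  test <- ref + rep(runif(5, -5, 5), each = n_per) + 0.05 * t
  vel <- 20 * pi * cos(2 * pi * t)
  cv <- cross_validate(regression_spec("nn", nn_hidden = 5, seed = 6),
                       cbind(test, vel), ref, subjects = subj)
  expect_gte(cv$mean_r2, 0.8)
})

test_that("correction preserves waveform correlation on drifting data", {
  sc <- drift_scenario()
  m <- fit_drift_model(sc$test, sc$ref, velocity = sc$vel,
                       spec = regression_spec("nn", nn_hidden = 5, seed = 7))
  corr <- apply_correction(m, sc$test, sc$vel)
  expect_gte(pearson_rho(corr, sc$ref), pearson_rho(sc$test, sc$ref))
})

test_that("apply_correction handles edge cases", {
  sc <- drift_scenario(dur = 5)
  m <- fit_drift_model(sc$test, sc$ref, velocity = sc$vel,
                       spec = regression_spec("nn", nn_hidden = 5, seed = 8))
  expect_identical(apply_correction(m, numeric(0)), numeric(0))
  expect_error(apply_correction(m, sc$test), "velocity")

  m0 <- fit_drift_model(sc$ref, sc$ref,
                        spec = regression_spec("nn", nn_hidden = 5, seed = 9))
  near_id <- apply_correction(m0, sc$ref)
  expect_lt(sqrt(mean((near_id - sc$ref)^2)), 0.5)
})
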