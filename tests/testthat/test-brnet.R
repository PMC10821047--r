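test_that("the 85/15 split is seeded, disjoint and exhaustive", {
  ds <- data.frame(i = 1:100)
  sp <- split_dataset(ds, seed = 4)
  expect_equal(nrow(sp$train), 85L)
  expect_equal(nrow(sp$test), 15L)
  expect_setequal(c(sp$train$i, sp$test$i), 1:100)
  sp2 <- split_dataset(ds, seed = 4)
  expect_identical(sp$train$i, sp2$train$i)
  expect_warning(sp1 <- split_dataset(data.frame(i = 1), seed = 1), "empty")
  expect_equal(nrow(sp1$train), 1L)
  expect_equal(nrow(sp1$test), 0L)
})

test_that("analytic Jacobian matches central differences", {
  for (spec in list(c(3, 4, 2), c(3, 5, 1), c(3, 0, 1))) {
    shape <- mlp_shape(spec[1], spec[2], spec[3])
    set.seed(spec[2] + 1)
    w <- runif(shape$k, -0.8, 0.8)
    X <- matrix(rnorm(7 * spec[1]), 7, spec[1])
    expect_lt(max(abs(mlp_jacobian(w, X, shape) -
                        numeric_jacobian(w, X, shape))), 1e-5)
  }
})

test_that("linear mode with fixed hyperparameters matches the ridge closed form", {
  set.seed(77)
  for (i in 1:5) {
    n <- 40
    X <- matrix(rnorm(n * 3), n, 3)
    y <- cbind(X, 1) %*% rnorm(4) + rnorm(n, sd = 0.05)
    a <- runif(1, 0.01, 1)
    b <- runif(1, 0.5, 5)
    fit <- brnet(X, y, hidden = 0, alpha = a, beta = b,
                 max_epochs = 100, grad_tol = 1e-12)
    Xa <- cbind(X, 1)
    w_ridge <- solve(b * crossprod(Xa) + a * diag(4), b * crossprod(Xa, y))
    expect_lt(max(abs(fit$weights - w_ridge) / pmax(abs(w_ridge), 1e-8)),
              1e-3)
  }
})

test_that("objective is non-increasing across accepted steps (fixed hyper)", {
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3)
  y <- sin(X[, 1]) + 0.5 * X[, 2]
  fit <- brnet(X, y, hidden = 4, alpha = 0.01, beta = 1, max_epochs = 80,
               seed = 1)
  expect_true(all(diff(fit$history) <= 1e-12))
})

test_that("a noise-free realizable target is memorized to E_D below 1e-6", {
  set.seed(11)
  X <- matrix(runif(60 * 3, -1, 1), 60, 3)
  shape <- mlp_shape(3, 5, 1)
  w_teacher <- runif(shape$k, -0.6, 0.6)
  y <- mlp_forward(w_teacher, X, shape)
  # LM is a local optimizer: allow a few seeded restarts
  best <- min(vapply(1:3, function(s) {
    brnet(X, y, hidden = 5, alpha = 0, beta = 1, max_epochs = 500,
          grad_tol = 1e-13, seed = s)$E_D
  }, numeric(1)))
  expect_lt(best, 1e-6)
})

test_that("Bayesian updates keep alpha, beta positive and gamma within [0, k]", {
  set.seed(21)
  for (s in 1:4) {
    X <- matrix(runif(80 * 3), 80, 3)
    y <- X %*% c(1, -0.5, 0.2) + rnorm(80, sd = 0.05)
    fit <- brnet(X, y, hidden = 5, max_epochs = 60, seed = s)
    expect_gt(fit$alpha, 0)
    expect_gt(fit$beta, 0)
    expect_gte(fit$gamma, 0)
    expect_lte(fit$gamma, fit$shape$k)
  }
})

test_that("prediction refuses to run without normalization parameters", {
  set.seed(5)
  X <- matrix(runif(90), 30, 3)
  fit <- brnet(X, rowSums(X), hidden = 3, max_epochs = 10, seed = 1)
  expect_error(predict(fit, data.frame(dv1 = 1, dv2 = 1, dv3 = 1)),
               "normalization")
})

test_that("an all-zero network predicts the de-normalized zero offset", {
  ds <- quadratic_dataset()
  np <- fit_normalization(ds, targets = "mass_kg")
  fit <- brnet(matrix(runif(90), 30, 3), runif(30), hidden = 3,
               max_epochs = 5, seed = 1, normalization = np,
               target_names = "mass_kg")
  fit$weights[] <- 0
  p <- predict(fit, data.frame(dv1 = 0.01, dv2 = 0.01, dv3 = 0.01))
  # normalized output 0 maps back to the output-range minimum (5 kg)
  expect_equal(unname(p[1, 1]), 5)
})

test_that("prediction is a pure function of network and reading", {
  bundle <- quick_bundle(seed = 2, max_epochs = 15)
  rd <- data.frame(dv1 = 0.05, dv2 = 0.06, dv3 = 0.04)
  p1 <- predict(bundle$medial_load, rd)
  p2 <- predict(bundle$medial_load, rd)
  expect_identical(p1, p2)
})

test_that("a perfectly fit network reproduces its training targets", {
  set.seed(13)
  X <- matrix(runif(45, 0, 1), 15, 3)
  shape <- mlp_shape(3, 4, 1)
  w_teacher <- runif(shape$k, -0.5, 0.5)
  y <- mlp_forward(w_teacher, X, shape)
  fit <- brnet(X, y, hidden = 4, alpha = 0, beta = 1, max_epochs = 400,
               grad_tol = 1e-13, seed = 2)
  expect_equal(as.vector(mlp_forward(fit$weights, X, fit$shape)),
               as.vector(y), tolerance = 1e-3)
})

test_that("the bundle holds four compartment-consistent networks", {
  bundle <- quick_bundle(seed = 3, max_epochs = 15)
  expect_s3_class(bundle, "sensor_bundle")
  expect_length(bundle, 4L)
  expect_named(bundle, c("medial_load", "medial_location",
                         "lateral_load", "lateral_location"))
  expect_equal(bundle$medial_load$shape$hidden, 5L)
  expect_equal(bundle$medial_location$shape$hidden, 10L)
  expect_equal(bundle$medial_location$shape$n_out, 2L)
  # medial networks were trained on medial records only
  expect_equal(bundle$medial_load$meta$compartment, "medial")
  expect_equal(bundle$lateral_load$meta$compartment, "lateral")
  # 72 measured + 4 extrapolated, 1 augmented copy, 85% split
  expect_equal(bundle$medial_load$meta$n_records, 152L)
  expect_equal(bundle$medial_load$n_train, round(0.85 * 152))
})

test_that("a serialized bundle reproduces its predictions", {
  bundle <- quick_bundle(seed = 4, max_epochs = 15)
  path <- withr::local_tempfile(fileext = ".json")
  write_bundle(bundle, path)
  back <- read_bundle(path)
  set.seed(6)
  readings <- data.frame(
    compartment = sample(c("medial", "lateral"), 100, replace = TRUE),
    dv1 = runif(100, 0, 0.3), dv2 = runif(100, 0, 0.3),
    dv3 = runif(100, 0, 0.3))
  expect_equal(predict(back, readings), predict(bundle, readings),
               tolerance = 1e-12)
})

test_that("training rejects mismatched or non-finite inputs", {
  expect_error(brnet(matrix(1:6, 2), 1:3), "row counts")
  expect_error(brnet(matrix(c(1, NA, 2, 3), 2), c(1, 2)), "finite")
  expect_error(brnet(matrix(runif(30), 10, 3), runif(10), alpha = 1),
               "both alpha and beta")
})
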