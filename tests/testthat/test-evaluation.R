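test_that("load accuracy follows the systematic-error formula", {
  expect_equal(load_accuracy_pct(rep(13, 10), 13), 100)
  expect_equal(load_accuracy_pct(rep(12, 10), 13), 100 * (1 - 1 / 13))
  expect_equal(load_accuracy_pct(rep(26, 10), 13), 0)
  expect_error(load_accuracy_pct(c(1, 2), 0), "undefined")
})

test_that("location accuracy scales distance by the farthest surface vertex", {
  square <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4))
  expect_equal(location_accuracy_pct(rbind(c(1, 1)), c(1, 1), square), 100)
  expect_equal(location_accuracy_pct(rbind(c(1, 2)), c(1, 1), square),
               100 * (1 - 1 / sqrt(18)))
  far <- c(1, 1) + sqrt(18) * c(1, 1) / sqrt(2)  # distance d_max away
  expect_equal(location_accuracy_pct(rbind(far), c(1, 1), square), 0)
  expect_error(location_accuracy_pct(rbind(c(0, 0)), c(9, 9), square),
               "outside")
})

test_that("precision is the sample standard deviation of the differences", {
  expect_equal(precision(rep(0.3, 5)), 0)
  expect_equal(precision(c(1, -1)), sqrt(2), tolerance = 1e-4)
  expect_equal(precision(c(0.1, 0.2, 0.3)), 0.1)
  expect_error(precision(1), "two values")
})

test_that("mse is the mean of squared differences", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(0, 0), c(1, 2)), 2.5)
  expect_equal(mse(5, 8), 9)
  expect_error(mse(1:3, 1:2), "equal length")
})

test_that("r_squared matches its defining ratio", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1.1, 1.9, 3.2)), 0.97)
  expect_error(r_squared(c(2, 2), c(1, 3)), "constant")
})

test_that("metrics agree with brute-force recomputation on random inputs", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    actual <- runif(n, 1, 30)
    pred <- actual + rnorm(n)
    expect_equal(mse(actual, pred), sum((actual - pred)^2) / n)
    expect_equal(precision(pred - actual),
                 sqrt(sum(((pred - actual) - mean(pred - actual))^2) /
                        (n - 1)))
    a0 <- actual[1]
    expect_equal(load_accuracy_pct(pred, a0),
                 max(0, 100 - 100 * abs(sum(pred) / n - a0) / a0))
    expect_equal(r_squared(actual, pred),
                 1 - sum((actual - pred)^2) /
                   sum((actual - mean(actual))^2))
  }
})

test_that("group comparison is a Welch t-test at the 0.05 level", {
  same <- c(1, 2, 3, 4)
  res <- compare_groups(same, same)
  expect_false(res$significant)
  expect_gt(res$p_value, 0.9)

  set.seed(41)
  a <- rnorm(10, 0, 0.01)
  b <- rnorm(10, 10, 0.01)
  expect_true(compare_groups(a, b)$significant)

  # hand-coded Welch oracle
  x <- rnorm(10)
  y <- rnorm(10, 0.4)
  res <- compare_groups(x, y)
  vx <- var(x) / 10
  vy <- var(y) / 10
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / 9 + vy^2 / 9)
  p_hand <- 2 * pt(-abs(tstat), df)
  expect_equal(res$p_value, p_hand, tolerance = 1e-6)
  expect_error(compare_groups(1, c(1, 2)), "two values")
})

test_that("the experiment report has the protocol's structure", {
  cfg <- default_experiment_config()
  cfg$max_epochs <- 30L
  cfg$aug_copies <- 1L
  rep <- run_experiment(cfg, seed = 10)
  expect_s3_class(rep, "experiment_report")
  expect_equal(nrow(rep$cells), 30L)  # 2 compartments x 5 points x 3 loads
  expect_equal(nrow(rep$trials), 300L)
  expect_named(rep$groups, c("compartment", "sensing_area",
                             "training_range"))
  expect_length(rep$groups, 3L)
  for (g in rep$groups) {
    expect_true(g$load$p_value >= 0 && g$load$p_value <= 1)
    expect_true(g$location$p_value >= 0 && g$location$p_value <= 1)
  }
  # every cell belongs to exactly one group of each grouping
  expect_equal(sum(rep$cells$compartment == "medial") +
                 sum(rep$cells$compartment == "lateral"), 30L)
  expect_equal(sum(rep$cells$inside) + sum(!rep$cells$inside), 30L)
  expect_equal(sum(rep$cells$mass_kg < 5) + sum(rep$cells$mass_kg > 5), 30L)
  expect_true(all(is.finite(unlist(rep$overall))))
  expect_true(all(abs(unlist(rep$r_squared)) <= 1))
  md <- format_report_md(rep)
  expect_match(md, "mean load accuracy")
})

test_that("the shipped YAML config reproduces the default configuration", {
  path <- system.file("extdata", "default_config.yaml", package = "kneesense")
  cfg <- read_config(path)
  def <- default_experiment_config()
  expect_equal(cfg$sim_params$linear_gain, def$sim_params$linear_gain)
  expect_equal(cfg$sim_params$crosstalk, def$sim_params$crosstalk)
  expect_equal(cfg$layouts$medial$gauge_positions,
               def$layouts$medial$gauge_positions)
  expect_equal(cfg$layouts$lateral$surface_polygon,
               def$layouts$lateral$surface_polygon)
  expect_equal(cfg$test_reps, def$test_reps)
  expect_equal(cfg$aug_frac, def$aug_frac)
})

test_that("AI path keeps near-parity inside vs outside; triangulation does not", {
  rep <- run_experiment(seed = 202)
  cells <- rep$cells
  ai_gap <- mean(cells$load_accuracy_pct[cells$inside]) -
    mean(cells$load_accuracy_pct[!cells$inside])
  tri_gap <- mean(cells$tri_load_accuracy_pct[cells$inside]) -
    mean(cells$tri_load_accuracy_pct[!cells$inside])
  expect_lt(abs(ai_gap), 10)
  expect_gt(tri_gap, abs(ai_gap))
})
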