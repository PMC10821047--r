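test_that("extrapolation reproduces a linear channel exactly", {
  ds <- quadratic_dataset(coefs = list(c(0, 2e-3, 0), c(1e-4, 1e-3, 0),
                                       c(0, 5e-4, 0)))
  out <- extrapolate_high_loads(ds, target_kg = 25,
                                point_filter = c("a", "b"))
  ex <- out[out$provenance == "extrapolated" & out$point_id == "a", ]
  expect_equal(nrow(ex), 1L)
  expect_equal(ex$dv1, 2e-3 * 245, tolerance = 1e-9)
  expect_equal(ex$dv2, 1e-4 + 1e-3 * 245, tolerance = 1e-9)
})

test_that("extrapolation evaluates the generating quadratic at 245 N", {
  coefs <- list(c(0, 2e-3, -5e-7), c(1e-4, 1.5e-3, 3e-7), c(0, 1e-3, 0))
  ds <- quadratic_dataset(coefs)
  out <- extrapolate_high_loads(ds, target_kg = 25,
                                point_filter = c("a", "b"))
  for (i in 1:2) {
    pid <- c("a", "b")[i]
    ex <- out[out$provenance == "extrapolated" & out$point_id == pid, ]
    for (ch in 1:3) {
      cf <- coefs[[ch]]
      expected <- (cf[1] + cf[2] * 245 + cf[3] * 245^2) * i
      expect_equal(ex[[paste0("dv", ch)]], expected, tolerance = 1e-9)
    }
  }
})

test_that("extrapolation leaves the dataset unchanged for an empty filter", {
  ds <- quadratic_dataset()
  expect_identical(extrapolate_high_loads(ds, point_filter = character(0)), ds)
})

test_that("extrapolation refuses points with fewer than 3 load levels", {
  ds <- quadratic_dataset()
  thin <- kneesense:::new_calib_dataset(
    as.data.frame(ds[ds$mass_kg %in% c(5, 10), ]))
  expect_error(extrapolate_high_loads(thin, point_filter = "a"),
               "fewer than 3")
})

test_that("default extrapolation filter selects interior grid nodes", {
  lay <- default_layout("medial")
  grid <- build_training_grid(grid_spec("medial"))
  ds <- collect_dataset(grid, build_load_schedule("training"), reps = 1,
                        layout = lay, params = quiet_params(), seed = 1)
  out <- extrapolate_high_loads(ds)
  ex <- out[out$provenance == "extrapolated", ]
  # interior of the 3 x 6 grid: x = 1, y = 1..4
  expect_equal(nrow(ex), 4L)
  expect_true(all(ex$x == 1 & ex$y %in% 1:4))
  expect_true(all(ex$mass_kg == 25))
})

test_that("normalization maps endpoints to 0 and 1 and round-trips", {
  ds <- quadratic_dataset()
  np <- fit_normalization(ds)
  tn <- apply_normalization(ds, np)
  for (q in c("dv1", "dv2", "dv3", "mass_kg", "x", "y")) {
    expect_equal(min(tn[[q]]), 0)
    expect_equal(max(tn[[q]]), 1)
    expect_equal(invert_normalization(tn[[q]], np, q), ds[[q]],
                 tolerance = 1e-12)
  }
})

test_that("apply then invert is the identity on random values", {
  ds <- quadratic_dataset()
  np <- fit_normalization(ds)
  set.seed(1)
  v <- runif(100, -3, 3)
  for (q in c("dv1", "mass_kg", "y")) {
    r <- c(np$inputs, np$outputs)[[q]]
    expect_equal(invert_normalization((v - r[1]) / (r[2] - r[1]), np, q), v,
                 tolerance = 1e-12)
  }
})

test_that("values outside the fitted range map outside [0, 1] unclipped", {
  # mass fitted on 5..20 kg here: a 3 kg test mass goes negative
  ds <- quadratic_dataset()
  np <- fit_normalization(ds)
  r <- np$outputs$mass_kg
  expect_equal(r, c(5, 20))
  expect_equal((3 - r[1]) / (r[2] - r[1]), -2 / 15)
  tn <- apply_normalization(transform(as.data.frame(ds), mass_kg = 3), np)
  expect_true(all(tn$mass_kg < 0))
})

test_that("constant channels cannot be normalized", {
  ds <- as.data.frame(quadratic_dataset())
  ds$dv3 <- 1
  expect_error(fit_normalization(ds), "dv3")
})

test_that("noise augmentation preserves targets and bounds the perturbation", {
  lay <- default_layout("medial")
  grid <- build_training_grid(grid_spec("medial"))
  ds <- collect_dataset(grid, build_load_schedule("training"), reps = 2,
                        layout = lay, params = sim_params(), seed = 2)
  out <- augment_noise(ds, frac = 0.05, copies = 70, seed = 9)
  src <- as.data.frame(ds)
  aug <- out[out$provenance == "augmented", ]
  expect_equal(nrow(aug), 70L * nrow(src))
  expect_gt(nrow(aug), 1e4)
  for (ch in c("dv1", "dv2", "dv3")) {
    ratio <- aug[[ch]] / rep(src[[ch]], 70)
    expect_true(all(abs(ratio - 1) <= 0.05 + 1e-12))
  }
  # targets unchanged
  expect_equal(aug$mass_kg, rep(src$mass_kg, 70))
  expect_equal(aug$x, rep(src$x, 70))
})

test_that("zero-width augmentation duplicates records exactly", {
  ds <- quadratic_dataset()
  out <- augment_noise(ds, frac = 0, copies = 1, seed = 1)
  aug <- out[out$provenance == "augmented", ]
  expect_equal(aug$dv1, ds$dv1)
  expect_equal(aug$dv2, ds$dv2)
})

test_that("augmentation count arithmetic: 2 copies of 72 records gives 216", {
  lay <- default_layout("medial")
  grid <- build_training_grid(grid_spec("medial"))
  ds <- collect_dataset(grid, build_load_schedule("training"), reps = 1,
                        layout = lay, params = quiet_params(), seed = 1)
  out <- augment_noise(ds, frac = 0.05, copies = 2, seed = 1)
  expect_equal(nrow(out), 216L)
})

test_that("preprocessing does not mutate its input and provenance partitions", {
  ds <- quadratic_dataset()
  snapshot <- as.data.frame(ds)
  out <- augment_noise(extrapolate_high_loads(ds, point_filter = "a"),
                       copies = 2, seed = 1)
  expect_identical(as.data.frame(ds), snapshot)
  expect_setequal(unique(out$provenance),
                  c("measured", "extrapolated", "augmented"))
  expect_equal(sum(out$provenance == "measured"), nrow(ds))
})
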