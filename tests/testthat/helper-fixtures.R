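# shared fixtures: all synthetic, built in code at test time

# noise-free, strictly linear simulator (invertible by triangulation)
quiet_params <- function() linear_sim_params()

# a small non-default layout handy for geometry edge cases
unit_triangle_layout <- function() {
  gauge_layout("medial",
               gauge_positions = rbind(c(0, 0), c(2, 0), c(0, 2)),
               surface_polygon = rbind(c(-1, -1), c(3, -1), c(3, 3),
                                       c(-1, 3)))
}

# random load points uniformly over the layout's surface bounding box
random_loads <- function(layout, n, max_kg = 20) {
  poly <- layout$surface_polygon
  data.frame(x = runif(n, min(poly[, 1]), max(poly[, 1])),
             y = runif(n, min(poly[, 2]), max(poly[, 2])),
             mass_kg = runif(n, 0.5, max_kg))
}

# small measured dataset with an exactly quadratic voltage/force law,
# bypassing the simulator, for extrapolation oracles
quadratic_dataset <- function(coefs = list(c(0, 2e-3, -5e-7),
                                           c(1e-4, 1.5e-3, 3e-7),
                                           c(0, 1e-3, 0))) {
  masses <- c(5, 10, 15, 20)
  forces <- masses * 9.8
  pts <- data.frame(point_id = c("a", "b"), x = c(0, 2), y = c(2, 3))
  rows <- list()
  for (i in 1:2) {
    for (j in seq_along(masses)) {
      dv <- vapply(coefs, function(cf) {
        cf[1] + cf[2] * forces[j] + cf[3] * forces[j]^2
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        compartment = "medial", point_id = pts$point_id[i],
        x = pts$x[i], y = pts$y[i], mass_kg = masses[j],
        force_N = forces[j], rep = 1L,
        dv1 = dv[1] * i, dv2 = dv[2] * i, dv3 = dv[3] * i,
        provenance = "measured", stringsAsFactors = FALSE)
    }
  }
  kneesense:::new_calib_dataset(do.call(rbind, rows))
}

# central-difference Jacobian of the network outputs, the independent
# oracle for mlp_jacobian
numeric_jacobian <- function(w, X, shape, h = 1e-6) {
  k <- length(w)
  f0 <- as.vector(mlp_forward(w, X, shape))
  J <- matrix(0, length(f0), k)
  for (j in seq_len(k)) {
    wp <- w; wp[j] <- wp[j] + h
    wm <- w; wm[j] <- wm[j] - h
    J[, j] <- (as.vector(mlp_forward(wp, X, shape)) -
                 as.vector(mlp_forward(wm, X, shape))) / (2 * h)
  }
  J
}

# quick bundle on tiny data for structural tests (not for accuracy claims)
quick_bundle <- function(seed = 1, max_epochs = 25L) {
  set.seed(seed)
  cfg <- default_experiment_config()
  calib <- lapply(c(medial = "medial", lateral = "lateral"), function(comp) {
    collect_dataset(build_training_grid(cfg$grids[[comp]]),
                    build_load_schedule("training"), reps = 1L,
                    layout = cfg$layouts[[comp]], params = cfg$sim_params)
  })
  train_bundle(calib$medial, calib$lateral, copies = 1L,
               max_epochs = max_epochs)
}
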