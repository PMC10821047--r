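#' kneesense: load and centre-of-pressure sensing for instrumented tibial inserts
#'
#' Tools to simulate, calibrate and evaluate a two-compartment strain-gauge
#' tibial insert that reports contact load and location during total knee
#' replacement. The sensing core is a set of four small feed-forward neural
#' networks trained with Bayesian regularization (see [brnet()]); a classical
#' three-point load-cell triangulation estimator ([triangulate()]) serves as
#' the baseline against which the network predictions are compared inside and
#' outside the triangular sensing area.
#'
#' All in-plane coordinates are expressed in grid units (1 unit = 5 mm of the
#' calibration grid); masses are in kilograms, forces in newtons with
#' g = 9.8 m/s^2, and bridge outputs in volts.
#'
#' @docType package
#' @name kneesense-package
#' @aliases kneesense
#' @importFrom stats rnorm runif sd lm predict coef t.test wilcox.test residuals setNames
#' @importFrom utils read.csv write.csv
#' @importFrom graphics abline plot points legend lines
"_PACKAGE"

GRAVITY <- 9.8

## ---------------------------------------------------------------------------
## geometry primitives shared across modules
## ---------------------------------------------------------------------------

# even-odd point-in-polygon test; points on an edge or vertex count as inside
point_in_polygon <- function(p, poly, tol = 1e-9) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- (xj - xi) * (p[2] - yi) - (yj - yi) * (p[1] - xi)
    if (abs(cross) <= tol &&
        p[1] >= min(xi, xj) - tol && p[1] <= max(xi, xj) + tol &&
        p[2] >= min(yi, yj) - tol && p[2] <= max(yi, yj) + tol) {
      return(TRUE)
    }
    if ((yi > p[2]) != (yj > p[2])) {
      xint <- xi + (p[2] - yi) * (xj - xi) / (yj - yi)
      if (p[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

triangle_area2 <- function(tri) {
  # twice the signed area
  (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
    (tri[3, 1] - tri[1, 1]) * (tri[2, 2] - tri[1, 2])
}

# barycentric coordinates of p with respect to a 3x2 triangle matrix
barycentric_coords <- function(tri, p) {
  a2 <- triangle_area2(tri)
  if (abs(a2) < 1e-12) {
    stop("gauge triangle is degenerate (collinear positions)", call. = FALSE)
  }
  A <- rbind(rep(1, 3), t(tri))
  as.vector(solve(A, c(1, p[1], p[2])))
}

## ---------------------------------------------------------------------------
## domain types
## ---------------------------------------------------------------------------

#' Strain-gauge layout of one compartment
#'
#' Describes where the three gauges sit on the insert surface and the usable
#' surface outline. Coordinates are in grid units (1 unit = 5 mm). The true
#' gauge coordinates of the physical device are not published; the defaults
#' returned by [default_layout()] are synthetic fixtures.
#'
#' @param compartment `"medial"` or `"lateral"`.
#' @param gauge_positions 3x2 numeric matrix of gauge coordinates (grid units).
#'   Must be non-collinear and lie inside `surface_polygon`.
#' @param surface_polygon m x 2 numeric matrix of ordered polygon vertices
#'   bounding the usable insert surface.
#' @return An object of class `gauge_layout`.
#' @seealso [default_layout()], [solve_reactions()], [sensing_region()]
#' @export
gauge_layout <- function(compartment = c("medial", "lateral"),
                         gauge_positions, surface_polygon) {
  compartment <- match.arg(compartment)
  gauge_positions <- as.matrix(gauge_positions)
  surface_polygon <- as.matrix(surface_polygon)
  storage.mode(gauge_positions) <- "double"
  storage.mode(surface_polygon) <- "double"
  if (!identical(dim(gauge_positions), c(3L, 2L))) {
    stop("gauge_positions must be a 3x2 matrix", call. = FALSE)
  }
  if (ncol(surface_polygon) != 2L || nrow(surface_polygon) < 3L) {
    stop("surface_polygon must be an m x 2 matrix with m >= 3", call. = FALSE)
  }
  if (abs(triangle_area2(gauge_positions)) < 1e-12) {
    stop("gauge positions are collinear: triangle has zero area", call. = FALSE)
  }
  for (i in 1:3) {
    if (!point_in_polygon(gauge_positions[i, ], surface_polygon)) {
      stop("gauge position ", i, " lies outside the surface polygon",
           call. = FALSE)
    }
  }
  structure(list(compartment = compartment,
                 gauge_positions = gauge_positions,
                 surface_polygon = surface_polygon),
            class = "gauge_layout")
}

#' Default synthetic gauge layouts
#'
#' Fixture layouts for the two compartments, constructed (not measured) so
#' that the standard test points are classified inside/outside the triangular
#' sensing area as reported for the physical device: medial points 1, 4 and 5
#' outside; lateral points 1 and 4 outside.
#'
#' @param compartment `"medial"` or `"lateral"`.
#' @return A [gauge_layout()] object.
#' @export
default_layout <- function(compartment = c("medial", "lateral")) {
  compartment <- match.arg(compartment)
  if (compartment == "medial") {
    gauge_layout("medial",
                 gauge_positions = rbind(c(0, 1), c(0, 4), c(2, 2.5)),
                 surface_polygon = rbind(c(-0.5, -0.5), c(3, -0.5),
                                         c(3, 6), c(-0.5, 6)))
  } else {
    gauge_layout("lateral",
                 gauge_positions = rbind(c(0, 2), c(1.5, 6), c(3, 2.5)),
                 surface_polygon = rbind(c(-0.5, -0.5), c(3.5, -0.5),
                                         c(3.5, 6), c(-0.5, 6)))
  }
}

#' Forward-model parameters for the synthetic sensor
#'
#' The physical sensor has no closed-form voltage/load relationship, so the
#' synthetic stand-in uses a mildly nonlinear gauge response: each channel
#' converts its reaction force to volts through a linear gain plus a quadratic
#' softening term, channels mix through a crosstalk matrix, and zero-mean
#' Gaussian noise with a signal-proportional scale plus a floor is added.
#'
#' @param linear_gain per-channel sensitivity, volts per newton (> 0).
#' @param quad_coeff per-channel quadratic coefficient, volts per newton^2.
#' @param crosstalk 3x3 dimensionless mixing matrix; diagonal must equal 1.
#' @param noise_frac relative noise scale (standard deviation as a fraction of
#'   the absolute noise-free signal); >= 0.
#' @param noise_floor additive noise floor in volts; >= 0.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(linear_gain = c(2.0e-3, 2.2e-3, 1.8e-3),
                       quad_coeff = c(-6e-7, -5e-7, -7e-7),
                       crosstalk = default_crosstalk(),
                       noise_frac = 0.01,
                       noise_floor = 5e-5) {
  linear_gain <- as.numeric(linear_gain)
  quad_coeff <- as.numeric(quad_coeff)
  crosstalk <- as.matrix(crosstalk)
  if (length(linear_gain) != 3L || any(linear_gain <= 0)) {
    stop("linear_gain must be three positive values", call. = FALSE)
  }
  if (length(quad_coeff) != 3L) {
    stop("quad_coeff must have three values", call. = FALSE)
  }
  if (!identical(dim(crosstalk), c(3L, 3L)) ||
      any(abs(diag(crosstalk) - 1) > 1e-12)) {
    stop("crosstalk must be 3x3 with unit diagonal", call. = FALSE)
  }
  if (noise_frac < 0 || noise_floor < 0) {
    stop("noise_frac and noise_floor must be non-negative", call. = FALSE)
  }
  structure(list(linear_gain = linear_gain, quad_coeff = quad_coeff,
                 crosstalk = crosstalk, noise_frac = noise_frac,
                 noise_floor = noise_floor),
            class = "sim_params")
}

default_crosstalk <- function(off = 0.02) {
  m <- matrix(off, 3, 3)
  diag(m) <- 1
  m
}

#' Noise-free, strictly linear simulator parameters
#'
#' Convenience constructor for the linear mode in which the voltage map is
#' exactly invertible by the triangulation baseline: zero quadratic term,
#' identity crosstalk, zero noise.
#'
#' @param linear_gain per-channel volts per newton.
#' @return A [sim_params()] object.
#' @export
linear_sim_params <- function(linear_gain = c(2.0e-3, 2.2e-3, 1.8e-3)) {
  sim_params(linear_gain = linear_gain, quad_coeff = c(0, 0, 0),
             crosstalk = diag(3), noise_frac = 0, noise_floor = 0)
}

#' Point load applied to one compartment
#'
#' @param compartment `"medial"` or `"lateral"`.
#' @param mass_kg applied mass in kilograms (>= 0). Exactly one of `mass_kg`
#'   and `force_N` may be omitted; the other is derived with g = 9.8 m/s^2.
#' @param force_N applied force in newtons.
#' @param x,y load coordinates in grid units.
#' @return An object of class `point_load`.
#' @export
point_load <- function(compartment = c("medial", "lateral"),
                       mass_kg = NULL, force_N = NULL, x, y) {
  compartment <- match.arg(compartment)
  if (is.null(mass_kg) && is.null(force_N)) {
    stop("one of mass_kg or force_N is required", call. = FALSE)
  }
  if (is.null(force_N)) force_N <- mass_kg * GRAVITY
  if (is.null(mass_kg)) mass_kg <- force_N / GRAVITY
  if (mass_kg < 0) stop("mass_kg must be >= 0", call. = FALSE)
  if (abs(force_N - mass_kg * GRAVITY) > 1e-12 * max(1, force_N)) {
    stop("force_N inconsistent with mass_kg (g = 9.8)", call. = FALSE)
  }
  structure(list(compartment = compartment, mass_kg = mass_kg,
                 force_N = force_N, x = as.numeric(x), y = as.numeric(y)),
            class = "point_load")
}

#' Three-channel bridge reading
#'
#' The voltage deltas observed on the three Wheatstone half-bridges of one
#' compartment.
#'
#' @param compartment `"medial"` or `"lateral"`.
#' @param dv numeric vector of three voltage deltas (volts), all finite.
#' @return An object of class `bridge_reading`.
#' @export
bridge_reading <- function(compartment = c("medial", "lateral"), dv) {
  compartment <- match.arg(compartment)
  dv <- as.numeric(dv)
  if (length(dv) != 3L || any(!is.finite(dv))) {
    stop("dv must be three finite voltages", call. = FALSE)
  }
  structure(list(compartment = compartment, dv = dv), class = "bridge_reading")
}

## ---------------------------------------------------------------------------
## forward model
## ---------------------------------------------------------------------------

#' Reaction forces at the three gauges under a point load
#'
#' Solves the rigid-plate equilibrium for a vertical point load supported at
#' the three gauge positions: vertical force balance plus the two moment
#' balances about the load point, a 3x3 linear system whose solution equals
#' the barycentric coordinates of the load point times the applied force.
#' Loads outside the gauge triangle give negative reactions (clamped-plate
#' behaviour); no clipping is applied, so there is usable signal over the
#' whole surface.
#'
#' @param layout a [gauge_layout()].
#' @param load a [point_load()] in the same compartment.
#' @return Numeric vector of three reaction forces in newtons; their sum
#'   equals `load$force_N`.
#' @export
solve_reactions <- function(layout, load) {
  stopifnot(inherits(layout, "gauge_layout"), inherits(load, "point_load"))
  if (load$force_N < 0) stop("force must be >= 0", call. = FALSE)
  lambda <- barycentric_coords(layout$gauge_positions, c(load$x, load$y))
  lambda * load$force_N
}

#' Simulate the bridge response to a point load
#'
#' Forward model of one compartment:
#' `dv = C (g * r + q * r^2) + eps`, where `r` are the gauge reactions from
#' [solve_reactions()], `g` and `q` the per-channel linear and quadratic
#' coefficients, `C` the crosstalk matrix and `eps` zero-mean Gaussian noise
#' with standard deviation `noise_frac * |signal| + noise_floor` per channel.
#' With [linear_sim_params()] the map is exactly linear in force at fixed
#' location and noise-free.
#'
#' Randomness is drawn from the session RNG; pass `seed` for a reproducible
#' reading.
#'
#' @param layout a [gauge_layout()].
#' @param params a [sim_params()].
#' @param load a [point_load()].
#' @param seed optional integer seed.
#' @return A [bridge_reading()].
#' @export
simulate_response <- function(layout, params, load, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  r <- solve_reactions(layout, load)
  signal <- as.vector(params$crosstalk %*%
                        (params$linear_gain * r + params$quad_coeff * r^2))
  noise_sd <- params$noise_frac * abs(signal) + params$noise_floor
  dv <- signal + rnorm(3, mean = 0, sd = noise_sd)
  bridge_reading(load$compartment, dv)
}

#' @export
print.gauge_layout <- function(x, ...) {
  cat("Gauge layout (", x$compartment, " compartment)\n", sep = "")
  cat("  gauges (grid units):\n")
  print(x$gauge_positions)
  cat("  surface polygon:", nrow(x$surface_polygon), "vertices\n")
  invisible(x)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic sensor parameters\n")
  cat("  linear gain  [V/N]  :", format(x$linear_gain), "\n")
  cat("  quad coeff   [V/N^2]:", format(x$quad_coeff), "\n")
  cat("  noise: frac =", x$noise_frac, ", floor =", x$noise_floor, "V\n")
  invisible(x)
}
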