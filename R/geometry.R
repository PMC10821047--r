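#' Triangular sensing region of a compartment
#'
#' The classical sensing area of a three-point load cell is the triangle
#' spanned by the gauges: only inside it is the force-balance estimate of
#' load location well-posed for a device that cannot register negative
#' reactions. The AI path is compared against this baseline inside and
#' outside the triangle.
#'
#' @param layout a [gauge_layout()].
#' @return An object of class `sensing_region` holding the gauge triangle.
#' @export
sensing_region <- function(layout) {
  stopifnot(inherits(layout, "gauge_layout"))
  structure(list(triangle = layout$gauge_positions,
                 compartment = layout$compartment),
            class = "sensing_region")
}

#' Triangulation estimate of load and centre of pressure
#'
#' The standard three-point load-cell solution: the total load is the sum of
#' the three reaction forces and the contact location is their force-weighted
#' centroid,
#' \deqn{F = \sum_i f_i, \qquad (x, y) = \sum_i f_i p_i / F.}
#' Composed with [solve_reactions()] this is an exact inverse for any load
#' point (inside or outside the triangle) in noise-free linear simulation.
#'
#' @param region a [sensing_region()].
#' @param forces numeric vector of three reaction forces (newtons).
#' @return Named numeric vector `c(force_N, x, y)`.
#' @export
triangulate <- function(region, forces) {
  stopifnot(inherits(region, "sensing_region"))
  forces <- as.numeric(forces)
  if (length(forces) != 3L || any(!is.finite(forces))) {
    stop("forces must be three finite values", call. = FALSE)
  }
  total <- sum(forces)
  if (total == 0) {
    stop("degenerate load: total reaction force is zero", call. = FALSE)
  }
  loc <- colSums(forces * region$triangle) / total
  c(force_N = total, x = loc[1], y = loc[2])
}

#' Is a point inside the triangular sensing area?
#'
#' Standard point-in-triangle test through barycentric coordinates; points
#' on an edge or vertex count as inside. With the default layouts the
#' standard test points split exactly as on the physical device: medial
#' points 1, 4 and 5 and lateral points 1 and 4 fall outside.
#'
#' @param region a [sensing_region()].
#' @param p numeric vector `c(x, y)` in grid units.
#' @param tol boundary tolerance.
#' @return `TRUE` if the point is inside or on the triangle.
#' @export
point_in_sensing_area <- function(region, p, tol = 1e-9) {
  stopifnot(inherits(region, "sensing_region"))
  lambda <- barycentric_coords(region$triangle, as.numeric(p))
  all(lambda >= -tol)
}

#' Recover gauge reactions from voltages under the linear model
#'
#' Baseline inverse used by the triangulation path: ignores the quadratic
#' term and inverts the linear gain and crosstalk,
#' `r = (C diag(g))^{-1} dv`. Exact in linear mode; biased under the
#' nonlinear simulator, which is precisely the hardware imperfection the
#' neural-network path is meant to absorb.
#'
#' @param params a [sim_params()].
#' @param dv numeric vector of three voltage deltas, or a
#'   [bridge_reading()].
#' @return Numeric vector of three estimated reaction forces (newtons).
#' @export
reactions_from_voltages <- function(params, dv) {
  stopifnot(inherits(params, "sim_params"))
  if (inherits(dv, "bridge_reading")) dv <- dv$dv
  as.vector(solve(params$crosstalk %*% diag(params$linear_gain),
                  as.numeric(dv)))
}
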