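#' Calibration grid specification
#'
#' The calibration protocol applies loads on a 3 x 6 Cartesian grid with 5 mm
#' spacing per compartment. Coordinates are in grid units; the origin sits at
#' the rightmost grid point on the X axis, with X increasing across columns
#' away from it and Y across rows. The lateral grid uses 17 of the 18 nodes;
#' by default the excluded node is the grid corner farthest from the lateral
#' gauge triangle.
#'
#' @param compartment `"medial"` or `"lateral"`.
#' @param n_cols,n_rows grid dimensions (defaults 3 and 6).
#' @param spacing_mm physical spacing of one grid unit (default 5 mm).
#' @param excluded_points optional 2-column matrix / data.frame of (x, y) grid
#'   nodes to drop. Defaults: none for medial, `(0, 0)` for lateral.
#' @param origin_convention free-text tag describing the origin.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(compartment = c("medial", "lateral"),
                      n_cols = 3L, n_rows = 6L, spacing_mm = 5,
                      excluded_points = NULL,
                      origin_convention = "rightmost point on the X-axis") {
  compartment <- match.arg(compartment)
  if (is.null(excluded_points)) {
    excluded_points <- if (compartment == "lateral") {
      matrix(c(0, 0), ncol = 2)
    } else {
      matrix(numeric(0), ncol = 2)
    }
  }
  excluded_points <- as.matrix(excluded_points)
  if (length(excluded_points) && ncol(excluded_points) != 2L) {
    stop("excluded_points must have two columns (x, y)", call. = FALSE)
  }
  structure(list(compartment = compartment, n_cols = as.integer(n_cols),
                 n_rows = as.integer(n_rows), spacing_mm = spacing_mm,
                 excluded_points = excluded_points,
                 origin_convention = origin_convention),
            class = "grid_spec")
}

#' Build the training grid of a compartment
#'
#' Enumerates the integer grid nodes row-major (X varying fastest) and drops
#' the excluded nodes. With the default specifications the medial grid has 18
#' points and the lateral grid 17.
#'
#' @param spec a [grid_spec()].
#' @return `data.frame` with columns `point_id`, `x`, `y` (grid units).
#' @export
build_training_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  pts <- expand.grid(x = seq_len(spec$n_cols) - 1L,
                     y = seq_len(spec$n_rows) - 1L,
                     KEEP.OUT.ATTRS = FALSE)
  keep <- rep(TRUE, nrow(pts))
  ex <- spec$excluded_points
  if (length(ex)) {
    for (i in seq_len(nrow(ex))) {
      hit <- pts$x == ex[i, 1] & pts$y == ex[i, 2]
      if (!any(hit)) {
        stop("excluded point (", ex[i, 1], ", ", ex[i, 2],
             ") is not a grid node", call. = FALSE)
      }
      keep[hit] <- FALSE
    }
  }
  pts <- pts[keep, , drop = FALSE]
  data.frame(point_id = sprintf("g%02d", seq_len(nrow(pts))),
             x = as.numeric(pts$x), y = as.numeric(pts$y),
             stringsAsFactors = FALSE)
}

#' Load schedules of the calibration and test protocols
#'
#' Training applies 5, 15, 10 and 20 kg (49, 147, 98, 196 N) in that order at
#' every grid node; testing applies 3, 13 and 23 kg (29.4, 127.4, 225.4 N).
#' A custom schedule can be built from arbitrary masses.
#'
#' @param kind `"training"`, `"testing"`, or `"custom"`.
#' @param masses_kg numeric masses, required when `kind = "custom"`.
#' @return `data.frame` with columns `mass_kg`, `force_N` (g = 9.8).
#' @export
build_load_schedule <- function(kind = c("training", "testing", "custom"),
                                masses_kg = NULL) {
  kind <- match.arg(kind)
  masses <- switch(kind,
                   training = c(5, 15, 10, 20),
                   testing = c(3, 13, 23),
                   custom = {
                     if (is.null(masses_kg)) {
                       stop("masses_kg required for a custom schedule",
                            call. = FALSE)
                     }
                     as.numeric(masses_kg)
                   })
  data.frame(mass_kg = masses, force_N = masses * GRAVITY)
}

#' Standard test points of each compartment
#'
#' Five labelled points per compartment, chosen to cover the insert surface
#' inside and outside the triangular sensing area; coordinates in grid units.
#'
#' @param compartment `"medial"` or `"lateral"`.
#' @return `data.frame` with columns `point_id` (labels `"1"`..`"5"`),
#'   `x`, `y`.
#' @export
build_test_points <- function(compartment = c("medial", "lateral")) {
  compartment <- match.arg(compartment)
  if (compartment == "medial") {
    xy <- rbind(c(1.5, 0.5), c(0.5, 1.5), c(1.0, 3.0), c(2.5, 2.5),
                c(1.5, 5.5))
  } else {
    xy <- rbind(c(1.5, 0.5), c(0.5, 2.5), c(2.0, 3.0), c(3.0, 4.0),
                c(1.5, 5.5))
  }
  data.frame(point_id = as.character(1:5), x = xy[, 1], y = xy[, 2],
             stringsAsFactors = FALSE)
}

CALIB_COLUMNS <- c("compartment", "point_id", "x", "y", "mass_kg", "force_N",
                   "rep", "dv1", "dv2", "dv3", "provenance")

new_calib_dataset <- function(df, metadata = list()) {
  missing <- setdiff(CALIB_COLUMNS, names(df))
  if (length(missing)) {
    stop("calibration table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, CALIB_COLUMNS, drop = FALSE]
  rownames(df) <- NULL
  if (anyNA(df)) stop("calibration table contains missing values",
                      call. = FALSE)
  bad <- setdiff(unique(df$provenance),
                 c("measured", "extrapolated", "augmented"))
  if (length(bad)) {
    stop("unknown provenance tag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(df, metadata = metadata,
            class = c("calib_dataset", "data.frame"))
}

#' Collect a calibration dataset from the synthetic sensor
#'
#' Applies every load of the schedule at every point, `reps` times, and
#' records the simulated bridge voltages. One record per
#' (point, load, repetition); all records carry provenance `"measured"`.
#'
#' @param points `data.frame` with columns `point_id`, `x`, `y`
#'   (e.g. from [build_training_grid()] or [build_test_points()]).
#' @param schedule `data.frame` from [build_load_schedule()].
#' @param reps number of repetitions per (point, load); >= 1.
#' @param layout a [gauge_layout()].
#' @param params a [sim_params()].
#' @param seed optional integer seed for reproducibility.
#' @return A `calib_dataset` (a `data.frame` with the calibration schema).
#' @export
collect_dataset <- function(points, schedule, reps = 1L, layout,
                            params = sim_params(), seed = NULL) {
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(points) * nrow(schedule) * reps
  out <- vector("list", n)
  k <- 0L
  for (i in seq_len(nrow(points))) {
    for (j in seq_len(nrow(schedule))) {
      for (r in seq_len(reps)) {
        load <- point_load(layout$compartment,
                           mass_kg = schedule$mass_kg[j],
                           x = points$x[i], y = points$y[i])
        rd <- simulate_response(layout, params, load)
        k <- k + 1L
        out[[k]] <- data.frame(
          compartment = layout$compartment,
          point_id = points$point_id[i],
          x = points$x[i], y = points$y[i],
          mass_kg = schedule$mass_kg[j], force_N = schedule$force_N[j],
          rep = r, dv1 = rd$dv[1], dv2 = rd$dv[2], dv3 = rd$dv[3],
          provenance = "measured", stringsAsFactors = FALSE)
      }
    }
  }
  new_calib_dataset(do.call(rbind, out),
                    metadata = list(compartment = layout$compartment,
                                    reps = reps, seed = seed))
}

#' Read and write calibration CSV files
#'
#' The on-disk schema is a plain CSV with the exact header
#' `compartment,point_id,x,y,mass_kg,force_N,rep,dv1,dv2,dv3,provenance`.
#' Reading a file with missing columns raises an error naming them.
#'
#' @param ds a `calib_dataset`.
#' @param path file path.
#' @return `read_calibration_csv` returns a `calib_dataset`;
#'   `write_calibration_csv` returns `path` invisibly.
#' @export
write_calibration_csv <- function(ds, path) {
  stopifnot(inherits(ds, "calib_dataset"))
  write.csv(as.data.frame(ds)[, CALIB_COLUMNS], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(point_id = "character"))
  missing <- setdiff(CALIB_COLUMNS, names(df))
  if (length(missing)) {
    stop("calibration CSV is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  new_calib_dataset(df, metadata = list(source = path))
}

#' @export
print.calib_dataset <- function(x, ...) {
  cat("Calibration dataset:", nrow(x), "records,",
      length(unique(x$point_id)), "points,",
      length(unique(x$mass_kg)), "load levels\n")
  tab <- table(x$provenance)
  cat("  provenance:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more records\n")
  invisible(x)
}
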