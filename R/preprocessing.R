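#' Extrapolate higher loads from a best-fit curve
#'
#' For each selected point and voltage channel, fits a least-squares
#' polynomial (default degree 2) of the per-level mean voltage against force
#' and evaluates it at `target_kg`, appending one synthetic record per point
#' with provenance `"extrapolated"`. This extends the training load range
#' beyond the heaviest mass physically applied, mirroring the protocol in
#' which 25 kg was added at points near the centre of the sensor.
#'
#' @param ds a `calib_dataset` of measured records.
#' @param target_kg mass at which to evaluate the fitted curve (default 25).
#' @param point_filter character vector of `point_id`s to extrapolate, or
#'   `NULL` for the default: interior grid nodes (x and y strictly between
#'   the observed extremes). Pass `character(0)` to extrapolate nothing.
#' @param degree polynomial degree of the best-fit curve (default 2).
#' @return A new `calib_dataset` with the extrapolated records appended;
#'   the input is not modified.
#' @export
extrapolate_high_loads <- function(ds, target_kg = 25, point_filter = NULL,
                                   degree = 2L) {
  stopifnot(inherits(ds, "calib_dataset"))
  meas <- ds[ds$provenance == "measured", , drop = FALSE]
  if (is.null(point_filter)) point_filter <- interior_point_ids(meas)
  point_filter <- as.character(point_filter)
  if (!length(point_filter)) return(ds)
  unknown <- setdiff(point_filter, unique(meas$point_id))
  if (length(unknown)) {
    stop("point_filter names unknown point(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  target_force <- target_kg * GRAVITY
  extra <- vector("list", length(point_filter))
  for (k in seq_along(point_filter)) {
    pid <- point_filter[k]
    sub <- meas[meas$point_id == pid, , drop = FALSE]
    forces <- sort(unique(sub$force_N))
    if (length(forces) < 3L) {
      stop("point ", pid, " has fewer than 3 distinct load levels; ",
           "cannot fit an extrapolation curve", call. = FALSE)
    }
    dv_new <- numeric(3)
    for (ch in 1:3) {
      col <- paste0("dv", ch)
      mean_dv <- vapply(forces,
                        function(f) mean(sub[[col]][sub$force_N == f]),
                        numeric(1))
      fit <- lm(mean_dv ~ poly(forces, degree = degree, raw = TRUE))
      dv_new[ch] <- unname(predict(fit, list(forces = target_force)))
    }
    extra[[k]] <- data.frame(
      compartment = sub$compartment[1], point_id = pid,
      x = sub$x[1], y = sub$y[1],
      mass_kg = target_kg, force_N = target_force, rep = 1L,
      dv1 = dv_new[1], dv2 = dv_new[2], dv3 = dv_new[3],
      provenance = "extrapolated", stringsAsFactors = FALSE)
  }
  new_calib_dataset(rbind(as.data.frame(ds), do.call(rbind, extra)),
                    metadata = attr(ds, "metadata"))
}

# interior nodes: strictly between the min and max observed x and y
interior_point_ids <- function(df) {
  pts <- unique(df[, c("point_id", "x", "y")])
  inner <- pts$x > min(pts$x) & pts$x < max(pts$x) &
    pts$y > min(pts$y) & pts$y < max(pts$y)
  pts$point_id[inner]
}

#' Min-max normalization for network inputs and targets
#'
#' Fits per-quantity affine maps sending the observed minimum to 0 and
#' maximum to 1 over the three voltage channels and the requested target
#' columns. The parameters are fitted on training records only, stored with
#' every trained network, and applied identically at prediction time. Values
#' outside the fitted range map outside `[0, 1]` without clipping — a 3 kg
#' test load under parameters fitted on 5–25 kg has a negative normalized
#' value.
#'
#' @param ds a `calib_dataset` (training records).
#' @param targets target columns to normalize alongside the inputs; any of
#'   `"mass_kg"`, `"x"`, `"y"`.
#' @return An object of class `normalization_params`: per-quantity
#'   `(min, max)` pairs.
#' @export
fit_normalization <- function(ds, targets = c("mass_kg", "x", "y")) {
  stopifnot(is.data.frame(ds))
  targets <- match.arg(targets, several.ok = TRUE)
  quantities <- c("dv1", "dv2", "dv3", targets)
  ranges <- lapply(quantities, function(q) {
    r <- range(ds[[q]])
    if (diff(r) <= 0) {
      stop("cannot normalize constant quantity '", q, "' (max equals min)",
           call. = FALSE)
    }
    r
  })
  names(ranges) <- quantities
  structure(list(inputs = ranges[c("dv1", "dv2", "dv3")],
                 outputs = ranges[targets]),
            class = "normalization_params")
}

norm_affine <- function(v, r) (v - r[1]) / (r[2] - r[1])
norm_affine_inv <- function(v, r) v * (r[2] - r[1]) + r[1]

#' Apply or invert a fitted normalization
#'
#' `apply_normalization` returns a copy of the table with the voltage
#' channels and any fitted target columns mapped through their affine
#' `[0, 1]` transforms. `invert_normalization` maps normalized values of one
#' named quantity back to raw units; the two are exact inverses.
#'
#' @param ds data frame with columns `dv1..dv3` (and target columns).
#' @param params a `normalization_params` object from [fit_normalization()].
#' @param values numeric vector/matrix of normalized values.
#' @param quantity name of the quantity to de-normalize (e.g. `"mass_kg"`).
#' @return `apply_normalization`: the normalized table;
#'   `invert_normalization`: raw-unit values.
#' @export
apply_normalization <- function(ds, params) {
  stopifnot(inherits(params, "normalization_params"))
  out <- as.data.frame(ds)
  for (q in names(params$inputs)) {
    out[[q]] <- norm_affine(out[[q]], params$inputs[[q]])
  }
  for (q in names(params$outputs)) {
    if (q %in% names(out)) out[[q]] <- norm_affine(out[[q]], params$outputs[[q]])
  }
  out
}

#' @rdname apply_normalization
#' @export
invert_normalization <- function(values, params, quantity) {
  stopifnot(inherits(params, "normalization_params"))
  all_ranges <- c(params$inputs, params$outputs)
  if (!quantity %in% names(all_ranges)) {
    stop("no normalization fitted for '", quantity, "'", call. = FALSE)
  }
  norm_affine_inv(values, all_ranges[[quantity]])
}

#' Augment a dataset with multiplicative voltage noise
#'
#' Appends `copies` perturbed duplicates of every measured and extrapolated
#' record, multiplying each voltage channel independently by `(1 + u)` with
#' `u` uniform on `[-frac, +frac]`. Targets are unchanged; the duplicates
#' carry provenance `"augmented"`. This is the ±5% synthetic-noise step that
#' helps the networks generalize.
#'
#' @param ds a `calib_dataset`.
#' @param frac half-width of the relative perturbation (default 0.05).
#' @param copies number of perturbed duplicates per source record; >= 0.
#' @param seed optional integer seed.
#' @return A new `calib_dataset`; the input is not modified.
#' @export
augment_noise <- function(ds, frac = 0.05, copies = 3L, seed = NULL) {
  stopifnot(inherits(ds, "calib_dataset"))
  if (frac < 0) stop("frac must be >= 0", call. = FALSE)
  if (copies < 0) stop("copies must be >= 0", call. = FALSE)
  if (copies == 0) return(ds)
  if (!is.null(seed)) set.seed(seed)
  src <- as.data.frame(ds[ds$provenance %in% c("measured", "extrapolated"), ,
                          drop = FALSE])
  out <- vector("list", copies)
  for (cpy in seq_len(copies)) {
    dup <- src
    n <- nrow(dup)
    for (ch in c("dv1", "dv2", "dv3")) {
      dup[[ch]] <- dup[[ch]] * (1 + runif(n, -frac, frac))
    }
    dup$provenance <- "augmented"
    out[[cpy]] <- dup
  }
  new_calib_dataset(rbind(as.data.frame(ds), do.call(rbind, out)),
                    metadata = attr(ds, "metadata"))
}

#' @export
print.normalization_params <- function(x, ...) {
  cat("Min-max normalization parameters\n")
  for (q in names(c(x$inputs, x$outputs))) {
    r <- c(x$inputs, x$outputs)[[q]]
    cat(sprintf("  %-8s [%g, %g]\n", q, r[1], r[2]))
  }
  invisible(x)
}
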