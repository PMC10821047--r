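#' Accuracy of repeated load predictions
#'
#' Accuracy is defined from the systematic error of the mean prediction over
#' the repeated trials:
#' \deqn{100 (1 - |\bar{\hat{m}} - m| / m),}
#' floored at 0% so a prediction more than 100% off does not go negative.
#'
#' @param predictions numeric vector of predicted masses (kg), one per trial.
#' @param actual true applied mass (kg), > 0.
#' @return Accuracy in percent.
#' @export
load_accuracy_pct <- function(predictions, actual) {
  if (length(predictions) < 1L) stop("no predictions", call. = FALSE)
  if (actual <= 0) {
    stop("accuracy undefined for actual load <= 0", call. = FALSE)
  }
  max(0, 100 * (1 - abs(mean(predictions) - actual) / actual))
}

#' Accuracy of repeated location predictions
#'
#' Based on the mean Euclidean distance of the predictions from the actual
#' point, scaled by the farthest point that could still be predicted on the
#' insert surface: `d_max` is the largest distance from the actual point to
#' any vertex of the surface polygon. Accuracy is
#' `100 (1 - mean(d) / d_max)`, floored at 0%.
#'
#' @param predicted n x 2 matrix (or data frame) of predicted `(x, y)`.
#' @param actual numeric `c(x, y)`, must lie on the surface.
#' @param surface_polygon m x 2 matrix of surface vertices.
#' @return Accuracy in percent.
#' @export
location_accuracy_pct <- function(predicted, actual, surface_polygon) {
  predicted <- as.matrix(predicted)
  actual <- as.numeric(actual)
  surface_polygon <- as.matrix(surface_polygon)
  if (!point_in_polygon(actual, surface_polygon)) {
    stop("actual point lies outside the surface polygon", call. = FALSE)
  }
  d <- sqrt((predicted[, 1] - actual[1])^2 + (predicted[, 2] - actual[2])^2)
  d_max <- max(sqrt((surface_polygon[, 1] - actual[1])^2 +
                      (surface_polygon[, 2] - actual[2])^2))
  max(0, 100 * (1 - mean(d) / d_max))
}

#' Precision of repeated predictions
#'
#' The sample standard deviation (n - 1 denominator) of the
#' prediction-minus-truth differences over the repeated trials.
#'
#' @param differences numeric vector of at least two differences.
#' @return Standard deviation in the units of `differences`.
#' @export
precision <- function(differences) {
  if (length(differences) < 2L) {
    stop("precision needs at least two values", call. = FALSE)
  }
  sd(differences)
}

#' Mean squared error
#'
#' The average of the squared differences between actual and estimated
#' values.
#'
#' @param actual,predicted equal-length numeric vectors.
#' @return Mean squared error (squared units).
#' @export
mse <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 1L) {
    stop("actual and predicted must have equal length >= 1", call. = FALSE)
  }
  mean((actual - predicted)^2)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` of predicted against actual values.
#'
#' @param actual,predicted numeric vectors; `actual` must not be constant.
#' @return R-squared (dimensionless).
#' @export
r_squared <- function(actual, predicted) {
  if (length(actual) < 2L || length(actual) != length(predicted)) {
    stop("need >= 2 paired values", call. = FALSE)
  }
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) stop("R^2 undefined for constant actual", call. = FALSE)
  1 - sum((actual - predicted)^2) / ss_tot
}

#' Compare two groups of metric values
#'
#' Welch two-sample t-test (unequal variances) by default, with a
#' Mann-Whitney alternative; a difference is significant when
#' `p < alpha` (protocol significance level 0.05).
#'
#' @param values_a,values_b numeric vectors, each with >= 2 values.
#' @param alpha significance level (default 0.05).
#' @param method `"welch"` or `"wilcoxon"`.
#' @return List with `mean_a`, `mean_b`, `p_value`, `significant`, `method`.
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05,
                           method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least two values", call. = FALSE)
  }
  p <- if (method == "welch") {
    t.test(values_a, values_b, var.equal = FALSE)$p.value
  } else {
    wilcox.test(values_a, values_b, exact = FALSE)$p.value
  }
  list(mean_a = mean(values_a), mean_b = mean(values_b),
       p_value = p, significant = p < alpha, method = method,
       alpha = alpha)
}

## ---------------------------------------------------------------------------
## experiment configuration & runner
## ---------------------------------------------------------------------------

#' Default experiment configuration
#'
#' Bundles the default layouts, grid specifications, simulator parameters and
#' protocol constants of the full experiment: training loads 5/15/10/20 kg on
#' the 3 x 6 grids, extrapolation to 25 kg, ±5% augmentation with 3 copies,
#' 85/15 split, 5/10 hidden units, test loads 3/13/23 kg at the 5 standard
#' points per compartment with 10 repetitions each.
#'
#' @return A nested list; edit fields or load overrides with [read_config()].
#' @export
default_experiment_config <- function() {
  list(
    layouts = list(medial = default_layout("medial"),
                   lateral = default_layout("lateral")),
    grids = list(medial = grid_spec("medial"),
                 lateral = grid_spec("lateral")),
    sim_params = sim_params(),
    train_reps = 1L,
    test_reps = 10L,
    target_kg = 25,
    aug_frac = 0.05,
    aug_copies = 3L,
    train_frac = 0.85,
    hidden_load = 5L,
    hidden_loc = 10L,
    max_epochs = 150L,
    test_method = "welch",
    alpha_level = 0.05
  )
}

#' Load experiment configuration overrides from YAML
#'
#' Reads a YAML file and merges it onto [default_experiment_config()].
#' Recognized blocks: scalar protocol fields (`test_reps`, `aug_frac`, ...),
#' a `sim_params` block, and per-compartment `layouts` blocks with
#' `gauge_positions` and `surface_polygon` given as lists of `(x, y)` rows.
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  cfg <- default_experiment_config()
  raw <- yaml::read_yaml(path)
  scalars <- c("train_reps", "test_reps", "target_kg", "aug_frac",
               "aug_copies", "train_frac", "hidden_load", "hidden_loc",
               "max_epochs", "test_method", "alpha_level")
  for (f in intersect(names(raw), scalars)) cfg[[f]] <- raw[[f]]
  if (!is.null(raw$sim_params)) {
    cfg$sim_params <- do.call(sim_params, lapply(raw$sim_params, function(v) {
      if (is.list(v)) do.call(rbind, v) else unlist(v)
    }))
  }
  if (!is.null(raw$layouts)) {
    for (comp in names(raw$layouts)) {
      blk <- raw$layouts[[comp]]
      cfg$layouts[[comp]] <- gauge_layout(
        comp,
        gauge_positions = do.call(rbind, blk$gauge_positions),
        surface_polygon = do.call(rbind, blk$surface_polygon))
    }
  }
  cfg
}

#' Run the full simulated sensing experiment
#'
#' End-to-end protocol: simulate calibration data on both training grids,
#' preprocess (extrapolate, augment, normalize) and train the four-network
#' bundle; then apply the test loads (3, 13, 23 kg) at the five standard
#' points of each compartment, `test_reps` times each, and evaluate the
#' accuracy / precision / MSE battery per (compartment, point, load) cell,
#' per-compartment R² of predicted vs actual load, and the three group
#' comparisons: medial vs lateral, inside vs outside the sensing area, and
#' below vs within the training load range (3 kg is below because the
#' extrapolated range spans 5–25 kg; 13 and 23 kg are within). The
#' triangulation baseline is evaluated on the same trials.
#'
#' Fully reproducible: the same `seed` gives a byte-identical report.
#'
#' @param config a configuration list, see [default_experiment_config()].
#' @param seed integer seed covering every random stage.
#' @return An object of class `experiment_report`: list with elements
#'   `cells` (30-row metric table), `trials` (per-repetition predictions),
#'   `r_squared`, `groups` (three comparison tables), `overall` summary
#'   means, `bundle`, `config_echo` and `seed`.
#' @export
run_experiment <- function(config = default_experiment_config(), seed = 1L) {
  set.seed(seed)
  stage <- "calibration"
  result <- tryCatch({
    calib <- list()
    for (comp in c("medial", "lateral")) {
      grid <- build_training_grid(config$grids[[comp]])
      sched <- build_load_schedule("training")
      calib[[comp]] <- collect_dataset(grid, sched, reps = config$train_reps,
                                       layout = config$layouts[[comp]],
                                       params = config$sim_params)
    }
    stage <- "training"
    bundle <- train_bundle(calib$medial, calib$lateral,
                           target_kg = config$target_kg,
                           noise_frac = config$aug_frac,
                           copies = config$aug_copies,
                           train_frac = config$train_frac,
                           hidden_load = config$hidden_load,
                           hidden_loc = config$hidden_loc,
                           max_epochs = config$max_epochs)
    stage <- "testing"
    trials <- run_test_protocol(bundle, config)
    stage <- "evaluation"
    summarize_experiment(trials, bundle, config, seed)
  }, error = function(e) {
    stop("experiment failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result
}

# apply the testing schedule and collect per-trial predictions
run_test_protocol <- function(bundle, config) {
  sched <- build_load_schedule("testing")
  rows <- list()
  for (comp in c("medial", "lateral")) {
    layout <- config$layouts[[comp]]
    region <- sensing_region(layout)
    pts <- build_test_points(comp)
    for (i in seq_len(nrow(pts))) {
      inside <- point_in_sensing_area(region, c(pts$x[i], pts$y[i]))
      for (j in seq_len(nrow(sched))) {
        for (r in seq_len(config$test_reps)) {
          load <- point_load(comp, mass_kg = sched$mass_kg[j],
                             x = pts$x[i], y = pts$y[i])
          rd <- simulate_response(layout, config$sim_params, load)
          pred <- predict(bundle, rd)
          tri <- triangulate(region,
                             reactions_from_voltages(config$sim_params, rd))
          rows[[length(rows) + 1L]] <- data.frame(
            compartment = comp, point_id = pts$point_id[i],
            inside = inside, mass_kg = sched$mass_kg[j],
            x = pts$x[i], y = pts$y[i], rep = r,
            pred_kg = pred$mass_kg, pred_x = pred$x, pred_y = pred$y,
            tri_kg = unname(tri["force_N"]) / GRAVITY,
            tri_x = unname(tri["x"]), tri_y = unname(tri["y"]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

cell_metrics <- function(sub, polygon, prefix = "pred") {
  kg <- sub[[paste0(prefix, "_kg")]]
  px <- sub[[paste0(prefix, "_x")]]
  py <- sub[[paste0(prefix, "_y")]]
  actual_kg <- sub$mass_kg[1]
  actual_xy <- c(sub$x[1], sub$y[1])
  d <- sqrt((px - actual_xy[1])^2 + (py - actual_xy[2])^2)
  list(load_acc = load_accuracy_pct(kg, actual_kg),
       load_prec = precision(kg - actual_kg),
       load_mse = mse(rep(actual_kg, length(kg)), kg),
       mean_diff = mean(kg) - actual_kg,
       loc_acc = location_accuracy_pct(cbind(px, py), actual_xy, polygon),
       loc_prec = precision(d),
       loc_mse = mean(d^2))
}

summarize_experiment <- function(trials, bundle, config, seed) {
  cells <- list()
  for (comp in c("medial", "lateral")) {
    polygon <- config$layouts[[comp]]$surface_polygon
    for (pid in unique(trials$point_id[trials$compartment == comp])) {
      for (m in unique(trials$mass_kg)) {
        sub <- trials[trials$compartment == comp & trials$point_id == pid &
                        trials$mass_kg == m, , drop = FALSE]
        ai <- cell_metrics(sub, polygon, "pred")
        tri <- cell_metrics(sub, polygon, "tri")
        cells[[length(cells) + 1L]] <- data.frame(
          compartment = comp, point_id = pid, mass_kg = m,
          inside = sub$inside[1],
          mean_diff_kg = ai$mean_diff,
          load_accuracy_pct = ai$load_acc,
          load_precision_kg = ai$load_prec,
          load_mse = ai$load_mse,
          location_accuracy_pct = ai$loc_acc,
          location_precision_units = ai$loc_prec,
          location_mse = ai$loc_mse,
          tri_load_accuracy_pct = tri$load_acc,
          tri_location_accuracy_pct = tri$loc_acc,
          stringsAsFactors = FALSE)
      }
    }
  }
  cells <- do.call(rbind, cells)

  r2 <- lapply(c(medial = "medial", lateral = "lateral"), function(comp) {
    sub <- trials[trials$compartment == comp, ]
    r_squared(sub$mass_kg, sub$pred_kg)
  })

  grouping <- function(sel_a, sel_b, label_a, label_b) {
    list(groups = c(label_a, label_b),
         n = c(sum(sel_a), sum(sel_b)),
         load = compare_groups(cells$load_accuracy_pct[sel_a],
                               cells$load_accuracy_pct[sel_b],
                               alpha = config$alpha_level,
                               method = config$test_method),
         location = compare_groups(cells$location_accuracy_pct[sel_a],
                                   cells$location_accuracy_pct[sel_b],
                                   alpha = config$alpha_level,
                                   method = config$test_method))
  }
  groups <- list(
    compartment = grouping(cells$compartment == "medial",
                           cells$compartment == "lateral",
                           "medial", "lateral"),
    sensing_area = grouping(cells$inside, !cells$inside,
                            "inside", "outside"),
    training_range = grouping(cells$mass_kg > 5,
                              cells$mass_kg < 5,
                              "within", "below"))

  overall <- list(
    mean_load_accuracy_pct = mean(cells$load_accuracy_pct),
    mean_location_accuracy_pct = mean(cells$location_accuracy_pct),
    mean_load_precision_kg = mean(cells$load_precision_kg),
    mean_location_precision_mm =
      mean(cells$location_precision_units) * 5,
    accuracy_below_range_pct =
      mean(cells$load_accuracy_pct[cells$mass_kg < 5]),
    accuracy_within_range_pct =
      mean(cells$load_accuracy_pct[cells$mass_kg > 5]))

  structure(list(cells = cells, trials = trials, r_squared = r2,
                 groups = groups, overall = overall, bundle = bundle,
                 config_echo = config_echo(config), seed = seed),
            class = "experiment_report")
}

# serializable echo of the configuration (layouts/params as plain lists)
config_echo <- function(config) {
  echo <- config
  echo$layouts <- lapply(config$layouts, function(l) {
    list(compartment = l$compartment,
         gauge_positions = unclass(l$gauge_positions),
         surface_polygon = unclass(l$surface_polygon))
  })
  echo$grids <- lapply(config$grids, unclass)
  echo$sim_params <- unclass(config$sim_params)
  echo
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Simulated load-sensing experiment (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  %d trials, %d summary cells\n",
              nrow(x$trials), nrow(x$cells)))
  cat(sprintf("  mean load accuracy     : %6.2f %%\n",
              x$overall$mean_load_accuracy_pct))
  cat(sprintf("  mean location accuracy : %6.2f %%\n",
              x$overall$mean_location_accuracy_pct))
  cat(sprintf("  load accuracy below / within training range: %.2f %% / %.2f %%\n",
              x$overall$accuracy_below_range_pct,
              x$overall$accuracy_within_range_pct))
  cat(sprintf("  R^2 (load): medial %.4f, lateral %.4f\n",
              x$r_squared$medial, x$r_squared$lateral))
  for (g in names(x$groups)) {
    gr <- x$groups[[g]]
    cat(sprintf("  %-15s %s vs %s: load p = %.3g%s, location p = %.3g%s\n",
                g, gr$groups[1], gr$groups[2],
                gr$load$p_value, if (gr$load$significant) " *" else "",
                gr$location$p_value,
                if (gr$location$significant) " *" else ""))
  }
  invisible(x)
}

#' Plot predicted against actual loads
#'
#' @param x an `experiment_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.experiment_report <- function(x, ...) {
  tr <- x$trials
  plot(jitter(tr$mass_kg, amount = 0.15), tr$pred_kg,
       col = ifelse(tr$compartment == "medial", "steelblue", "firebrick"),
       xlab = "actual mass [kg]", ylab = "predicted mass [kg]", ...)
  abline(0, 1, lty = 2)
  legend("topleft", legend = c("medial", "lateral"), pch = 1,
         col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Write an experiment report to JSON, with a Markdown summary
#'
#' `write_report` serializes the machine-readable report (cells, trials,
#' R², group comparisons, overall summary, configuration echo) to JSON at
#' full precision, so identical seeds give byte-identical files.
#' `format_report_md` renders a short human-readable Markdown summary.
#'
#' @param report an `experiment_report`.
#' @param path output JSON path.
#' @return `write_report`: `path`, invisibly. `format_report_md`: a
#'   character scalar of Markdown.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "experiment_report"))
  payload <- report[c("seed", "overall", "r_squared", "groups", "cells",
                      "trials", "config_echo")]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
format_report_md <- function(report) {
  o <- report$overall
  lines <- c(
    "# Simulated load-sensing experiment",
    "",
    sprintf("- seed: %d, trials: %d", report$seed, nrow(report$trials)),
    sprintf("- mean load accuracy: %.2f%%", o$mean_load_accuracy_pct),
    sprintf("- mean location accuracy: %.2f%%", o$mean_location_accuracy_pct),
    sprintf("- load accuracy below / within training range: %.2f%% / %.2f%%",
            o$accuracy_below_range_pct, o$accuracy_within_range_pct),
    sprintf("- R^2 (load): medial %.4f, lateral %.4f",
            report$r_squared$medial, report$r_squared$lateral),
    "",
    "| grouping | A | B | load p | location p |",
    "|---|---|---|---|---|")
  for (g in names(report$groups)) {
    gr <- report$groups[[g]]
    lines <- c(lines, sprintf("| %s | %s | %s | %.3g | %.3g |", g,
                              gr$groups[1], gr$groups[2],
                              gr$load$p_value, gr$location$p_value))
  }
  paste(lines, collapse = "\n")
}
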