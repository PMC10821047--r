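#' Train the four-network predictor bundle
#'
#' Runs the full preprocessing chain on each compartment's calibration data —
#' best-fit-curve extrapolation to `target_kg`, multiplicative noise
#' augmentation, an 85/15 train/test split, min-max normalization fitted on
#' the training part — and trains four networks independently: a load network
#' (5 hidden units, output in kg) and a location network (10 hidden units,
#' outputs X and Y in grid units) per compartment. Medial networks never see
#' lateral records and vice versa.
#'
#' @param medial,lateral `calib_dataset`s of measured records, one per
#'   compartment.
#' @param target_kg extrapolation target mass (default 25 kg).
#' @param noise_frac augmentation half-width (default 0.05).
#' @param copies augmented copies per record (default 3).
#' @param train_frac training fraction of the split (default 0.85).
#' @param hidden_load,hidden_loc hidden-unit counts (defaults 5 and 10).
#' @param max_epochs LM epoch budget per network.
#' @param extrapolate if `FALSE`, skip the extrapolation step.
#' @param seed optional integer seed covering the whole training run.
#' @return An object of class `sensor_bundle`: a list with elements
#'   `medial_load`, `medial_location`, `lateral_load`, `lateral_location`,
#'   each a fitted [brnet()].
#' @export
train_bundle <- function(medial, lateral, target_kg = 25, noise_frac = 0.05,
                         copies = 3L, train_frac = 0.85,
                         hidden_load = 5L, hidden_loc = 10L,
                         max_epochs = 150L, extrapolate = TRUE, seed = NULL) {
  stopifnot(inherits(medial, "calib_dataset"),
            inherits(lateral, "calib_dataset"))
  if (!all(medial$compartment == "medial")) {
    stop("medial dataset contains non-medial records", call. = FALSE)
  }
  if (!all(lateral$compartment == "lateral")) {
    stop("lateral dataset contains non-lateral records", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  nets <- list()
  for (comp in c("medial", "lateral")) {
    ds <- if (comp == "medial") medial else lateral
    if (extrapolate) ds <- extrapolate_high_loads(ds, target_kg = target_kg)
    ds <- augment_noise(ds, frac = noise_frac, copies = copies)
    sp <- split_dataset(ds, train_frac = train_frac)
    train <- sp$train
    np <- fit_normalization(train, targets = c("mass_kg", "x", "y"))
    tn <- apply_normalization(train, np)
    Xn <- as.matrix(tn[, c("dv1", "dv2", "dv3")])
    key_load <- paste0(comp, "_load")
    key_loc <- paste0(comp, "_location")
    nets[[key_load]] <- tryCatch(
      brnet(Xn, tn$mass_kg, hidden = hidden_load, max_epochs = max_epochs,
            normalization = np, target_names = "mass_kg"),
      error = function(e) stop("training failed for ", key_load, ": ",
                               conditionMessage(e), call. = FALSE))
    nets[[key_loc]] <- tryCatch(
      brnet(Xn, as.matrix(tn[, c("x", "y")]), hidden = hidden_loc,
            max_epochs = max_epochs, normalization = np,
            target_names = c("x", "y")),
      error = function(e) stop("training failed for ", key_loc, ": ",
                               conditionMessage(e), call. = FALSE))
    meta <- list(compartment = comp, n_train = nrow(train),
                 n_records = nrow(ds),
                 provenance = as.list(table(train$provenance)))
    nets[[key_load]]$meta <- meta
    nets[[key_loc]]$meta <- meta
  }
  structure(nets, class = "sensor_bundle")
}

#' Predict load and location for a table of readings
#'
#' Routes each reading to its compartment's load and location networks.
#'
#' @param object a `sensor_bundle` from [train_bundle()].
#' @param newdata data frame with columns `compartment`, `dv1`, `dv2`, `dv3`,
#'   or a single [bridge_reading()].
#' @param ... unused.
#' @return Data frame with columns `mass_kg`, `x`, `y`, one row per reading.
#' @export
predict.sensor_bundle <- function(object, newdata, ...) {
  if (inherits(newdata, "bridge_reading")) {
    newdata <- data.frame(compartment = newdata$compartment,
                          dv1 = newdata$dv[1], dv2 = newdata$dv[2],
                          dv3 = newdata$dv[3])
  }
  nd <- as.data.frame(newdata)
  out <- data.frame(mass_kg = rep(NA_real_, nrow(nd)),
                    x = NA_real_, y = NA_real_)
  for (comp in c("medial", "lateral")) {
    idx <- which(nd$compartment == comp)
    if (!length(idx)) next
    sub <- nd[idx, c("dv1", "dv2", "dv3"), drop = FALSE]
    out$mass_kg[idx] <- predict(object[[paste0(comp, "_load")]], sub)[, 1]
    loc <- predict(object[[paste0(comp, "_location")]], sub)
    out$x[idx] <- loc[, "x"]
    out$y[idx] <- loc[, "y"]
  }
  out
}

#' @export
print.sensor_bundle <- function(x, ...) {
  cat("Sensor predictor bundle (4 networks)\n")
  for (key in names(x)) {
    net <- x[[key]]
    cat(sprintf("  %-16s %d-%d-%d, gamma = %.1f/%d, E_D = %.3g\n", key,
                net$shape$n_in, net$shape$hidden, net$shape$n_out,
                net$gamma, net$shape$k, net$E_D))
  }
  invisible(x)
}

## ---------------------------------------------------------------------------
## JSON serialization
## ---------------------------------------------------------------------------

net_to_list <- function(net) {
  list(shape = net$shape[c("n_in", "hidden", "n_out", "activation")],
       weights = net$weights,
       alpha = net$alpha, beta = net$beta, gamma = net$gamma,
       target_names = net$target_names,
       normalization = list(inputs = net$normalization$inputs,
                            outputs = net$normalization$outputs),
       meta = net$meta)
}

net_from_list <- function(lst) {
  shape <- mlp_shape(lst$shape$n_in, lst$shape$hidden, lst$shape$n_out,
                     lst$shape$activation)
  np <- structure(list(inputs = lapply(lst$normalization$inputs, as.numeric),
                       outputs = lapply(lst$normalization$outputs,
                                        as.numeric)),
                  class = "normalization_params")
  structure(list(weights = as.numeric(lst$weights), shape = shape,
                 alpha = lst$alpha, beta = lst$beta, gamma = lst$gamma,
                 normalization = np,
                 target_names = unlist(lst$target_names),
                 meta = lst$meta),
            class = "brnet")
}

#' Serialize a predictor bundle to JSON and back
#'
#' The model file stores a schema version, and for each of the four networks
#' its shape, packed weight vector, Bayesian hyperparameters (alpha, beta,
#' gamma) and normalization parameters, at full floating-point precision so
#' that a reloaded bundle reproduces its predictions.
#'
#' @param bundle a `sensor_bundle`.
#' @param path JSON file path.
#' @return `read_bundle` returns a `sensor_bundle`; `write_bundle` returns
#'   `path` invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "sensor_bundle"))
  payload <- list(schema = "kneesense-bundle/1",
                  networks = lapply(unclass(bundle), net_to_list))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  if (!identical(payload$schema, "kneesense-bundle/1")) {
    stop("unrecognized bundle schema", call. = FALSE)
  }
  keys <- c("medial_load", "medial_location",
            "lateral_load", "lateral_location")
  if (!setequal(names(payload$networks), keys)) {
    stop("bundle must contain exactly the four networks: ",
         paste(keys, collapse = ", "), call. = FALSE)
  }
  structure(lapply(payload$networks[keys], net_from_list),
            class = "sensor_bundle")
}
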