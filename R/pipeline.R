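#' Pipeline configuration
#'
#' One serialisable document describing a full run: where data live (or
#' how to simulate them), how features are expanded, how the classifier is
#' trained, and how rods are measured and validated. Every run logs the
#' resolved configuration and all seeds.
#'
#' @param images,masks Character vectors of training image/mask paths
#'   (ignored when `simulate = TRUE`).
#' @param validation_image,validation_mask Held-out pair paths.
#' @param magnification Nominal magnification of the input images.
#' @param simulate If `TRUE`, generate the training suite from
#'   `synthetic` instead of reading files.
#' @param synthetic A [synthetic_spec()] (used when `simulate = TRUE`).
#' @param feature_backend `"filterbank"` or `"vgg16"`.
#' @param vgg16_weights Optional path to pretrained weights (RDS).
#' @param layers Layer ids for feature expansion.
#' @param n_trees,subsample_fraction,seed Classifier settings.
#' @param normalize_intensity If `TRUE`, standardise each image to zero
#'   mean and unit variance before expansion (default `FALSE`).
#' @param morphometry A [morphometry_config()].
#' @param registration_tolerance_px Centroid tolerance for validation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(images = character(0), masks = character(0),
                            validation_image = NULL, validation_mask = NULL,
                            magnification = 500,
                            simulate = length(images) == 0L,
                            synthetic = synthetic_spec(),
                            feature_backend = "filterbank",
                            vgg16_weights = NULL,
                            layers = c(1L, 2L),
                            n_trees = 150L,
                            subsample_fraction = 0.02,
                            seed = 1L,
                            normalize_intensity = FALSE,
                            morphometry = morphometry_config(),
                            registration_tolerance_px = 5) {
  structure(
    list(images = images, masks = masks,
         validation_image = validation_image,
         validation_mask = validation_mask,
         magnification = magnification,
         simulate = simulate, synthetic = synthetic,
         feature_backend = feature_backend, vgg16_weights = vgg16_weights,
         layers = sort(unique(as.integer(layers))),
         n_trees = as.integer(n_trees),
         subsample_fraction = subsample_fraction,
         seed = as.integer(seed),
         normalize_intensity = isTRUE(normalize_intensity),
         morphometry = morphometry,
         registration_tolerance_px = registration_tolerance_px),
    class = "pipeline_config"
  )
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @param config A [pipeline_config()].
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- if (!is.null(y$synthetic)) do.call(synthetic_spec, y$synthetic) else synthetic_spec()
  mor <- if (!is.null(y$morphometry)) do.call(morphometry_config, y$morphometry) else morphometry_config()
  args <- y[setdiff(names(y), c("synthetic", "morphometry"))]
  args <- args[names(args) %in% names(formals(pipeline_config))]
  for (f in c("images", "masks")) {
    if (!is.null(args[[f]])) args[[f]] <- as.character(unlist(args[[f]]))
  }
  do.call(pipeline_config, c(args, list(synthetic = syn, morphometry = mor)))
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  y$synthetic <- unclass(y$synthetic)
  y$morphometry <- unclass(y$morphometry)
  yaml::write_yaml(y, path)
  invisible(path)
}

config_hash <- function(config) {
  rlang::hash(unclass(config))
}

stage_abort <- function(stage, msg) {
  abort(sprintf("[%s] %s", stage, msg), class = "rodseg_stage_error")
}

#' Run the full segmentation and morphometry workflow
#'
#' Executes the pipeline end to end: simulate (or load) the training
#' suite, normalise magnification, apply flip augmentation, expand
#' features, train the forest, predict the held-out image, despeckle,
#' extract rod morphometrics, build the cross-band pitch profile, and
#' validate against ground truth. All artifacts are written to
#' `output_dir` with the configuration hash as provenance; re-running with
#' an identical configuration reproduces identical CSV outputs.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory for run artifacts (created if needed); set
#'   `NULL` to skip writing.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the trained `classifier`, predicted
#'   mask, `rod_table`, `profile`, `report` ([evaluate_segmentation()]
#'   result), `truth_table`, `config`, and `config_hash`.
#' @export
run_end_to_end <- function(config, output_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  # ---- data stage -----------------------------------------------------
  if (config$simulate) {
    say("[simulate] generating synthetic training suite (seed %d)",
        config$synthetic$rng_seed)
    suite <- generate_training_suite(config$synthetic)
    train <- suite[!vapply(suite, `[[`, logical(1), "held_out")]
    val <- suite[vapply(suite, `[[`, logical(1), "held_out")][[1L]]
    train_images <- lapply(train, `[[`, "image")
    train_masks <- lapply(train, `[[`, "mask")
    val_image <- val$image
    val_mask <- val$mask
    truth_table <- val$truth_table
    scale <- config$synthetic$scale_um_per_px
  } else {
    say("[load] reading %d training image(s)", length(config$images))
    if (length(config$images) != length(config$masks) ||
        length(config$images) == 0L) {
      stage_abort("load", "`images` and `masks` must be non-empty and paired.")
    }
    for (p in c(config$images, config$masks,
                config$validation_image, config$validation_mask)) {
      if (!file.exists(p)) stage_abort("load", sprintf("missing file: %s", p))
    }
    train_images <- lapply(config$images, function(p)
      normalize_magnification(load_image(p, config$magnification)))
    train_masks <- lapply(config$masks, load_mask)
    val_image <- normalize_magnification(
      load_image(config$validation_image, config$magnification))
    val_mask <- load_mask(config$validation_mask)
    truth_table <- extract_rod_objects(val_mask, config$morphometry,
                                       source = "validation-truth")
    scale <- config$morphometry$scale_um_per_px
  }

  # ---- augment --------------------------------------------------------
  say("[augment] flip augmentation: %d -> %d pairs",
      length(train_images), 3L * length(train_images))
  pairs <- augment_flips(train_images, train_masks)

  # ---- expand ---------------------------------------------------------
  selection <- layer_selection(config$layers)
  extractor <- build_extractor(selection, backend = config$feature_backend,
                               seed = config$seed,
                               weights = config$vgg16_weights)
  say("[expand] %s, layers {%s}: %d features/px", extractor$backend_id,
      paste(config$layers, collapse = ", "), n_features(selection))
  prep <- function(px) {
    if (config$normalize_intensity) {
      px <- (px - mean(px)) / max(sd(px), 1e-12)
    }
    px
  }

  # ---- train ----------------------------------------------------------
  say("[train] %d trees on %.0f%% of pixels (seed %d)",
      config$n_trees, 100 * config$subsample_fraction, config$seed)
  ts <- expand_and_assemble(pairs, extractor,
                            subsample_fraction = config$subsample_fraction,
                            seed = config$seed, prep = prep)
  clf <- train_classifier(ts, n_trees = config$n_trees, seed = config$seed)

  # ---- predict --------------------------------------------------------
  say("[segment] predicting held-out image")
  vstack <- expand_features(prep(val_image), extractor)
  pred <- predict_mask(clf, vstack)
  rm(vstack)

  # ---- morphometrics --------------------------------------------------
  mor <- config$morphometry
  mor$scale_um_per_px <- scale
  say("[analyze] despeckle + rod morphometrics")
  rod_table <- extract_rod_objects(pred$mask, mor, source = "predicted")
  profile <- tryCatch(crossband_profile(rod_table, "auto"),
                      error = function(e) NULL)

  # ---- validate -------------------------------------------------------
  say("[validate] registration at +/-%g px", config$registration_tolerance_px)
  report <- evaluate_segmentation(pred, val_mask, rod_table, truth_table,
                                  tolerance_px = config$registration_tolerance_px)

  result <- list(classifier = clf, prediction = pred, rod_table = rod_table,
                 profile = profile, report = report,
                 truth_table = truth_table, config = config,
                 config_hash = hash)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_pipeline_config(config, file.path(output_dir, "config.yaml"))
    write_image(val_image, file.path(output_dir, "validation_image.tif"))
    write_mask(val_mask, file.path(output_dir, "validation_truth_mask.png"))
    write_mask(pred$mask, file.path(output_dir, "predicted_mask.png"))
    save_classifier(clf, file.path(output_dir, "classifier.rds"))
    write_rod_csv(rod_table, file.path(output_dir, "rod_table.csv"), hash)
    if (!is.null(profile)) {
      write_rod_csv(profile, file.path(output_dir, "crossband_profile.csv"), hash)
    }
    write_rod_csv(report$registration$pairs,
                  file.path(output_dir, "registered_pairs.csv"), hash)
    yaml::write_yaml(
      list(config_hash = hash,
           seed = config$seed,
           package_version = as.character(utils::packageVersion("rodseg")),
           elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
           pixel_accuracy_percent = report$accuracy$pixel_accuracy_percent,
           iou = report$accuracy$iou,
           n_truth = report$registration$n_truth,
           n_matched = report$registration$n_matched,
           match_fraction = report$registration$match_fraction,
           r_squared_identity = report$registration$r_squared,
           r_squared_fit = report$registration$r_squared_fit,
           pass_similarity = report$pass_similarity),
      file.path(output_dir, "validation_report.yaml"))
  }
  say("[done] accuracy %.2f%%, %d/%d rods registered, identity R^2 = %s",
      report$accuracy$pixel_accuracy_percent, report$registration$n_matched,
      report$registration$n_truth,
      format(report$registration$r_squared, digits = 3))
  invisible(result)
}
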