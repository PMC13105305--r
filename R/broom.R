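#' Tidiers for rodseg result objects
#'
#' broom-style `tidy()` and `glance()` methods: `tidy()` returns the
#' per-unit records of a result (registered pairs, per-fold accuracies,
#' per-selection scores), `glance()` a one-row summary.
#'
#' @param x A rodseg result object.
#' @param ... Unused.
#' @return A tibble.
#' @name rodseg-tidiers
NULL

#' @rdname rodseg-tidiers
#' @method tidy registration_result
#' @export
tidy.registration_result <- function(x, ...) {
  x$pairs
}

#' @rdname rodseg-tidiers
#' @method glance registration_result
#' @export
glance.registration_result <- function(x, ...) {
  tibble(n_truth = x$n_truth, n_predicted = x$n_predicted,
         n_matched = x$n_matched, match_fraction = x$match_fraction,
         r_squared = x$r_squared, r_squared_fit = x$r_squared_fit,
         tolerance_px = x$tolerance_px)
}

#' @rdname rodseg-tidiers
#' @method tidy crossval_result
#' @export
tidy.crossval_result <- function(x, ...) {
  x$folds
}

#' @rdname rodseg-tidiers
#' @method glance crossval_result
#' @export
glance.crossval_result <- function(x, ...) {
  tibble(k = x$k, n_trees = x$n_trees,
         mean_accuracy_percent = x$mean_accuracy_percent,
         sd_accuracy_percent = sd(x$folds$accuracy_percent))
}

#' @rdname rodseg-tidiers
#' @method glance pixel_classifier
#' @export
glance.pixel_classifier <- function(x, ...) {
  tibble(n_trees = x$n_trees, n_features = x$n_features,
         mtry = x$forest$mtry, min_node_size = x$forest$min.node.size,
         oob_brier = x$forest$prediction.error, seed = x$seed,
         layers = if (is.null(x$selection)) NA_character_ else format(x$selection))
}

#' @rdname rodseg-tidiers
#' @method glance segmentation_report
#' @export
glance.segmentation_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble(pixel_accuracy_percent = x$accuracy$pixel_accuracy_percent,
           iou = x$accuracy$iou),
    glance(x$registration)[c("n_truth", "n_matched", "match_fraction",
                             "r_squared", "r_squared_fit")],
    tibble(r2_criterion = x$r2_criterion, pass_similarity = x$pass_similarity)
  )
}

#' @rdname rodseg-tidiers
#' @method tidy accuracy_report
#' @export
tidy.accuracy_report <- function(x, ...) {
  tibble(metric = c("pixel_accuracy_percent", "iou", "tp", "tn", "fp", "fn"),
         value = c(x$pixel_accuracy_percent, x$iou, x$tp, x$tn, x$fp, x$fn))
}
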