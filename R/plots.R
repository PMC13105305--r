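#' Plot methods for rodseg result objects
#'
#' `autoplot()` methods returning ggplot objects: a rod map coloured by
#' classification for `rod_table`, pitch versus projected position for
#' `crossband_profile`, predicted-versus-truth pitch with the identity
#' line for `registration_result`, and accuracy versus layer count for
#' `layer_search_result`.
#'
#' @param object A rodseg result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name rodseg-autoplot
NULL

#' @rdname rodseg-autoplot
#' @method autoplot rod_table
#' @export
autoplot.rod_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$centroid_col, y = .data$centroid_row,
                               colour = .data$classification,
                               size = .data$area_um2)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "column (px)", y = "row (px)",
                  colour = "class", size = expression(area ~ (mu * m^2)),
                  title = "Rod map") +
    ggplot2::theme_minimal()
}

#' @rdname rodseg-autoplot
#' @method autoplot crossband_profile
#' @export
autoplot.crossband_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$position_um, y = .data$pitch_deg,
                               colour = .data$classification)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = expression(position ~ along ~ analysis ~ axis ~ (mu * m)),
                  y = "pitch (deg)", colour = "class",
                  title = sprintf("Cross-band pitch profile (axis %.1f deg)",
                                  attr(object, "axis_angle_deg"))) +
    ggplot2::theme_minimal()
}

#' @rdname rodseg-autoplot
#' @method autoplot registration_result
#' @export
autoplot.registration_result <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$truth_pitch, y = .data$pred_pitch)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_fixed(xlim = c(0, 90), ylim = c(0, 90)) +
    ggplot2::labs(x = "ground-truth pitch (deg)", y = "predicted pitch (deg)",
                  title = sprintf("Registered rods: %d/%d, identity R^2 = %.3f",
                                  object$n_matched, object$n_truth,
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @rdname rodseg-autoplot
#' @method autoplot layer_search_result
#' @export
autoplot.layer_search_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n_layers, y = .data$accuracy_percent)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::stat_summary(fun = max, geom = "line", colour = "steelblue") +
    ggplot2::labs(x = "number of layers", y = "validation accuracy (%)",
                  title = "Layer-combination search") +
    ggplot2::theme_minimal()
}

#' Overlay a mask boundary on an image for quick inspection
#'
#' @param image An [sem_image()] or matrix.
#' @param mask A \{0, 1\} matrix (or [predict_mask()] result).
#' @return A ggplot object (raster image with the mask tinted).
#' @export
plot_mask_overlay <- function(image, mask) {
  px <- if (inherits(image, "sem_image")) image$pixels else image
  mask <- as_mask(mask)
  df <- tibble(
    row = rep(seq_len(nrow(px)), times = ncol(px)),
    col = rep(seq_len(ncol(px)), each = nrow(px)),
    intensity = as.numeric(px),
    rod = as.numeric(mask)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_raster(data = df[df$rod > 0, ],
                         fill = "tomato", alpha = 0.35) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
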