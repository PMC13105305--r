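#' Register rods between a ground-truth and a predicted table
#'
#' Candidate pairs are rods whose centroids agree within `tolerance_px` in
#' each coordinate (a per-coordinate box, the +/- 5 pixel convention);
#' candidates are matched greedily by ascending Euclidean centroid
#' distance under a one-to-one constraint. Paired pitch values are scored
#' with the identity-line coefficient of determination (see
#' [registration_r_squared()]); the ordinary least-squares R-squared is
#' also reported for transparency.
#'
#' @param truth,predicted `rod_table` tibbles (or any tables with
#'   `rod_id`, `centroid_row`, `centroid_col`, `pitch_deg`) from the same
#'   image frame.
#' @param tolerance_px Per-coordinate centroid tolerance (default 5).
#' @return A `registration_result`: list with `pairs` (tibble: truth_id,
#'   pred_id, truth_pitch, pred_pitch, centroid_distance_px), `n_truth`,
#'   `n_predicted`, `n_matched`, `match_fraction`, `r_squared`
#'   (identity-line), `r_squared_fit` (free line), `tolerance_px`.
#' @export
register_rod_tables <- function(truth, predicted, tolerance_px = 5) {
  fd_t <- attr(truth, "frame_dim"); fd_p <- attr(predicted, "frame_dim")
  if (!is.null(fd_t) && !is.null(fd_p) && !identical(fd_t, fd_p)) {
    abort("Tables come from different image frames.",
          class = "rodseg_validation_error")
  }
  nt <- nrow(truth); np <- nrow(predicted)
  pairs <- tibble(truth_id = integer(0), pred_id = integer(0),
                  truth_pitch = numeric(0), pred_pitch = numeric(0),
                  centroid_distance_px = numeric(0))
  if (nt > 0L && np > 0L) {
    dr <- outer(truth$centroid_row, predicted$centroid_row, "-")
    dc <- outer(truth$centroid_col, predicted$centroid_col, "-")
    inbox <- abs(dr) <= tolerance_px & abs(dc) <= tolerance_px
    cand <- which(inbox, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      d <- sqrt(dr[cand]^2 + dc[cand]^2)
      ord <- order(d, cand[, 1L], cand[, 2L])
      used_t <- logical(nt); used_p <- logical(np)
      keep <- integer(0)
      for (i in ord) {
        ti <- cand[i, 1L]; pj <- cand[i, 2L]
        if (!used_t[ti] && !used_p[pj]) {
          used_t[ti] <- TRUE; used_p[pj] <- TRUE
          keep <- c(keep, i)
        }
      }
      pairs <- tibble(
        truth_id = truth$rod_id[cand[keep, 1L]],
        pred_id = predicted$rod_id[cand[keep, 2L]],
        truth_pitch = truth$pitch_deg[cand[keep, 1L]],
        pred_pitch = predicted$pitch_deg[cand[keep, 2L]],
        centroid_distance_px = d[keep]
      )
    }
  }
  r2 <- registration_r_squared(pairs$truth_pitch, pairs$pred_pitch)
  r2_fit <- if (nrow(pairs) >= 2L && sd(pairs$truth_pitch) > 0 &&
                sd(pairs$pred_pitch) > 0) {
    cor(pairs$truth_pitch, pairs$pred_pitch)^2
  } else NA_real_
  structure(
    list(pairs = pairs, n_truth = nt, n_predicted = np,
         n_matched = nrow(pairs),
         match_fraction = if (nt > 0L) nrow(pairs) / nt else NA_real_,
         r_squared = r2, r_squared_fit = r2_fit,
         tolerance_px = tolerance_px),
    class = "registration_result"
  )
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(paste0("<registration_result> %d/%d truth rods matched ",
                     "(%.1f%%) at +/-%g px; identity-line R^2 = %s\n"),
              x$n_matched, x$n_truth, 100 * x$match_fraction, x$tolerance_px,
              format(x$r_squared, digits = 4)))
  invisible(x)
}

#' Identity-line coefficient of determination for paired pitch values
#'
#' For a perfectly accurate segmentation the predicted pitch of every
#' registered rod equals its ground-truth pitch, so the pairs lie on the
#' line of equality. This R-squared measures agreement with that line:
#' `1 - sum((pred - truth)^2) / sum((truth - mean(truth))^2)`. It equals 1
#' iff prediction matches truth exactly and can be negative for poor
#' agreement.
#'
#' @param truth,predicted Paired pitch vectors (degrees). Alternatively
#'   `truth` may be a two-column data frame of pairs.
#' @return The R-squared, or `NA` (with a warning) for fewer than two
#'   pairs or zero truth variance.
#' @export
registration_r_squared <- function(truth, predicted = NULL) {
  if (is.null(predicted)) {
    stopifnot(ncol(truth) >= 2L)
    predicted <- truth[[2L]]
    truth <- truth[[1L]]
  }
  if (length(truth) != length(predicted)) {
    abort("Pitch vectors must have equal length.",
          class = "rodseg_validation_error")
  }
  if (length(truth) < 2L) {
    warn("Fewer than two registered pairs; R^2 is undefined.")
    return(NA_real_)
  }
  sstot <- sum((truth - mean(truth))^2)
  if (sstot == 0) {
    warn("Zero variance in truth pitch; R^2 is undefined.")
    return(NA_real_)
  }
  1 - sum((predicted - truth)^2) / sstot
}

#' Combined segmentation quality report
#'
#' Bundles pixel-level accuracy (accuracy and IoU), rod-level centroid
#' registration, and the similarity criterion: an identity-line R-squared
#' greater than 0.90 on the paired pitch values is considered
#' significantly similar.
#'
#' @param predicted_mask,truth_mask \{0, 1\} matrices of equal shape (a
#'   [predict_mask()] result is accepted).
#' @param predicted_table,truth_table Corresponding rod tables.
#' @param tolerance_px Registration tolerance (default 5).
#' @param r2_criterion Similarity threshold on the identity-line
#'   R-squared (default 0.90).
#' @return A `segmentation_report`: list with `accuracy`
#'   (an `accuracy_report`), `registration` (a `registration_result`),
#'   `r2_criterion` and `pass_similarity`.
#' @export
evaluate_segmentation <- function(predicted_mask, truth_mask,
                                  predicted_table, truth_table,
                                  tolerance_px = 5, r2_criterion = 0.90) {
  acc <- pixel_accuracy(predicted_mask, truth_mask)
  reg <- register_rod_tables(truth_table, predicted_table,
                             tolerance_px = tolerance_px)
  structure(
    list(accuracy = acc, registration = reg,
         r2_criterion = r2_criterion,
         pass_similarity = !is.na(reg$r_squared) && reg$r_squared > r2_criterion),
    class = "segmentation_report"
  )
}

#' @export
print.segmentation_report <- function(x, ...) {
  cat(sprintf(paste0("<segmentation_report> accuracy %.2f%%, IoU %.3f; ",
                     "%d/%d rods registered; identity R^2 = %s (%s %0.2f: %s)\n"),
              x$accuracy$pixel_accuracy_percent, x$accuracy$iou,
              x$registration$n_matched, x$registration$n_truth,
              format(x$registration$r_squared, digits = 4), ">",
              x$r2_criterion,
              if (x$pass_similarity) "pass" else "fail"))
  invisible(x)
}
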