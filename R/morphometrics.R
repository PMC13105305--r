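#' Morphometry configuration
#'
#' Thresholds of the rod-level analysis. Physical thresholds are stored in
#' micrometres and converted to pixels per image via the scale, so images
#' normalised from other magnifications are filtered identically.
#'
#' @param despeckle_min_area_px Components smaller than this many pixels
#'   are removed before analysis (default 20).
#' @param diazone_pitch_threshold_deg Rods with pitch strictly greater than
#'   this are diazone (default 25).
#' @param max_minor_axis_um Rods with fit-ellipse minor axis `b` at or
#'   above this are rejected as merged (default 5.5; single rods are about
#'   5 um in diameter).
#' @param max_area_um2 Rods with area strictly greater than this are
#'   rejected as multiple merged rods (default 70).
#' @param scale_um_per_px Pixel size used to convert to physical units.
#' @return A `morphometry_config` list.
#' @export
morphometry_config <- function(despeckle_min_area_px = 20L,
                               diazone_pitch_threshold_deg = 25,
                               max_minor_axis_um = 5.5,
                               max_area_um2 = 70,
                               scale_um_per_px = canonical_frame$um_per_px_at_reference) {
  vals <- list(despeckle_min_area_px = despeckle_min_area_px,
               diazone_pitch_threshold_deg = diazone_pitch_threshold_deg,
               max_minor_axis_um = max_minor_axis_um,
               max_area_um2 = max_area_um2,
               scale_um_per_px = scale_um_per_px)
  for (f in names(vals)) {
    if (!is.numeric(vals[[f]]) || length(vals[[f]]) != 1L || vals[[f]] <= 0) {
      abort(sprintf("`%s` must be a single positive number.", f),
            class = "rodseg_validation_error")
    }
  }
  structure(vals, class = "morphometry_config")
}

#' Remove small speckle components from a mask
#'
#' Connected components (8-connectivity) with area strictly below
#' `min_area_px` are set to background; everything else is unchanged. The
#' operation is idempotent.
#'
#' @param mask \{0, 1\} matrix.
#' @param min_area_px Minimum surviving component area (default 20).
#' @return The despeckled \{0, 1\} matrix.
#' @export
despeckle <- function(mask, min_area_px = 20L) {
  mask <- as_mask(mask)
  lab <- label_components8(mask)
  if (max(lab) == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L])
  drop <- which(areas < min_area_px)
  if (length(drop) > 0L) {
    mask[lab %in% drop] <- 0L
  }
  mask
}

#' Rod pitch from fit-ellipse axes
#'
#' The out-of-plane tilt of a quasi-cylindrical rod relative to the image
#' plane follows from its elliptical cross-section: `pitch = asin(b / a)`
#' in degrees, where `a` and `b` are the major and minor axes of the fit
#' ellipse. 90 degrees means the rod is perpendicular to the section.
#'
#' @param a,b Major and minor axis lengths (same units, both positive).
#'   Vectorised. `b` exceeding `a` beyond a 1e-9 relative tolerance is an
#'   error: swapped axes upstream are a bug, not data.
#' @return Pitch in degrees, in (0, 90\].
#' @examples
#' compute_pitch(10, 5)  # 30
#' compute_pitch(10, 10) # 90
#' @export
compute_pitch <- function(a, b) {
  if (any(a <= 0) || any(b < 0)) {
    abort("Axis lengths must be positive.", class = "rodseg_validation_error")
  }
  if (any(b > a * (1 + 1e-9))) {
    abort("Minor axis `b` exceeds major axis `a`: axes are swapped upstream.",
          class = "rodseg_validation_error")
  }
  asin(pmin(b / a, 1)) * 180 / pi
}

#' Fold an orientation to yaw in (-90, 90]
#'
#' Yaw is the angle between a rod's fit-ellipse major axis and the image's
#' vertical axis, positive clockwise as displayed. Being an axial quantity
#' (orientation without direction) it is folded to (-90, 90\], with -90
#' reported as +90.
#'
#' @param orientation_deg Angle(s) from the vertical axis, degrees, any
#'   real value.
#' @return Yaw in degrees in (-90, 90\].
#' @export
compute_yaw <- function(orientation_deg) {
  y <- ((orientation_deg + 90) %% 180) - 90
  ifelse(y == -90, 90, y)
}

# Axial circular mean of orientations in degrees (double-angle method);
# robust near +/-90 where the arithmetic mean misbehaves.
axial_mean_deg <- function(deg) {
  th <- deg * pi / 90  # doubled angle in radians
  compute_yaw(atan2(mean(sin(th)), mean(cos(th))) * 90 / pi)
}

#' Extract per-rod morphometrics from a binary mask
#'
#' Despeckles, labels 8-connected components, and fits each with the
#' normalised-second-central-moment ellipse (full axis lengths
#' `a = 4 sqrt(lambda1)`, `b = 4 sqrt(lambda2)` in pixels, converted to um;
#' under this convention a disk of diameter d yields `a = b = d`). Pitch,
#' yaw, solidity, equivalent diameter and the parazone/diazone/rejected
#' classification are attached per rod. Border-touching components are
#' retained and flagged.
#'
#' @param mask \{0, 1\} matrix (a [predict_mask()] result is accepted).
#' @param config A [morphometry_config()].
#' @param source Optional identifier recorded on the table.
#' @return A `rod_table` tibble, one row per rod: `rod_id`,
#'   `centroid_row`, `centroid_col`, `area_px`, `area_um2`, `a_um`, `b_um`,
#'   `orientation_deg`, `yaw_deg`, `pitch_deg`, `solidity`,
#'   `equiv_diameter_um`, `touches_border`, `classification`.
#' @export
extract_rod_objects <- function(mask, config = morphometry_config(),
                                source = NULL) {
  mask <- as_mask(mask)
  stopifnot(inherits(config, "morphometry_config"))
  s <- config$scale_um_per_px
  mask <- despeckle(mask, config$despeckle_min_area_px)
  lab <- label_components8(mask)
  ncomp <- max(lab)
  H <- nrow(mask); W <- ncol(mask)
  empty <- tibble(
    rod_id = integer(0), centroid_row = numeric(0), centroid_col = numeric(0),
    area_px = integer(0), area_um2 = numeric(0), a_um = numeric(0),
    b_um = numeric(0), orientation_deg = numeric(0), yaw_deg = numeric(0),
    pitch_deg = numeric(0), solidity = numeric(0),
    equiv_diameter_um = numeric(0), touches_border = logical(0),
    classification = character(0)
  )
  if (ncomp == 0L) {
    return(new_rod_table(empty, config, source, c(H, W)))
  }
  idx <- which(lab > 0L)
  id <- lab[idx]
  r <- (idx - 1L) %% H + 1L
  c_ <- (idx - 1L) %/% H + 1L
  area <- tabulate(id, ncomp)
  mr <- tapply(r, id, mean)
  mc <- tapply(c_, id, mean)
  dx <- c_ - mc[id]   # x = column
  dy <- r - mr[id]    # y = row (down)
  mu20 <- tapply(dx * dx, id, sum) / area
  mu02 <- tapply(dy * dy, id, sum) / area
  mu11 <- tapply(dx * dy, id, sum) / area
  common <- sqrt(pmax((mu20 - mu02)^2 + 4 * mu11^2, 0))
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  a_px <- 4 * sqrt(pmax(l1, 0))
  b_px <- 4 * sqrt(pmax(l2, 0))
  # orientation of the major axis: angle phi from the x (column) axis with
  # y down, converted to the from-vertical yaw convention
  phi <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  orientation <- compute_yaw(phi - 90)
  sol <- component_solidity(r, c_, id, area)
  touches <- tapply(r == 1L | r == H | c_ == 1L | c_ == W, id, any)
  pitch <- compute_pitch(pmax(a_px, 1e-9) * s, pmin(b_px, a_px) * s)

  tab <- tibble(
    rod_id = seq_len(ncomp),
    centroid_row = as.numeric(mr),
    centroid_col = as.numeric(mc),
    area_px = as.integer(area),
    area_um2 = as.numeric(area) * s^2,
    a_um = as.numeric(a_px) * s,
    b_um = as.numeric(b_px) * s,
    orientation_deg = as.numeric(orientation),
    yaw_deg = as.numeric(orientation),
    pitch_deg = as.numeric(pitch),
    solidity = as.numeric(sol),
    equiv_diameter_um = 2 * sqrt(area / pi) * s,
    touches_border = as.logical(touches)
  )
  tab$classification <- classify_rods(tab, config)
  new_rod_table(tab, config, source, c(H, W))
}

new_rod_table <- function(tab, config, source, frame_dim) {
  class(tab) <- c("rod_table", class(tab))
  attr(tab, "config") <- config
  attr(tab, "scale_um_per_px") <- config$scale_um_per_px
  attr(tab, "source") <- source
  attr(tab, "frame_dim") <- frame_dim
  tab
}

# Solidity = area / convex hull area. Hull area from pixel centres via the
# shoelace formula, corrected by half the boundary (Pick-style) so a filled
# convex shape scores ~1; capped to (0, 1].
component_solidity <- function(r, c_, id, area) {
  vapply(seq_along(area), function(i) {
    sel <- id == i
    xs <- c_[sel]; ys <- r[sel]
    pts <- unique(cbind(xs, ys))
    if (nrow(pts) < 3L) return(1)
    h <- grDevices::chull(pts)
    hx <- pts[h, 1L]; hy <- pts[h, 2L]
    n <- length(h)
    j <- c(2:n, 1L)
    poly <- abs(sum(hx * hy[j] - hx[j] * hy)) / 2
    per <- sum(sqrt((hx - hx[j])^2 + (hy - hy[j])^2))
    hull_px <- poly + per / 2 + 1
    min(1, area[i] / max(hull_px, area[i]))
  }, numeric(1))
}

#' Classify rods into parazone, diazone, or rejected
#'
#' Applies the merged-rod filters and the pitch rule with fixed precedence:
#' components below the despeckle area are speckle; a minor axis `b` at or
#' above `max_minor_axis_um` marks a rod merged with a neighbour; an area
#' strictly above `max_area_um2` marks multiple merged in-plane rods; of
#' the remaining rods, pitch strictly greater than
#' `diazone_pitch_threshold_deg` is diazone, otherwise parazone. A rod
#' failing a merged-rod filter is never classified parazone or diazone.
#'
#' @param rods Data frame with columns `pitch_deg`, `b_um`, `area_um2`
#'   (and optionally `area_px`).
#' @param config A [morphometry_config()].
#' @return Character vector of classifications.
#' @export
classify_rods <- function(rods, config = morphometry_config()) {
  need <- c("pitch_deg", "b_um", "area_um2")
  if (!all(need %in% names(rods)) ||
      any(vapply(rods[need], function(x) any(is.na(x)), logical(1)))) {
    abort("`rods` must have complete pitch_deg, b_um and area_um2 columns.",
          class = "rodseg_validation_error")
  }
  out <- ifelse(rods$pitch_deg > config$diazone_pitch_threshold_deg,
                "diazone", "parazone")
  out[rods$area_um2 > config$max_area_um2] <- "rejected_merged_area"
  out[rods$b_um >= config$max_minor_axis_um] <- "rejected_merged_minor_axis"
  if ("area_px" %in% names(rods)) {
    out[rods$area_px < config$despeckle_min_area_px] <- "rejected_speckle"
  }
  out
}

#' Cross-band pitch profile
#'
#' Projects each retained (parazone or diazone) rod centroid onto an
#' analysis axis running across the decussation bands and pairs the
#' projected position with the rod's pitch. In `"auto"` mode the axis is
#' perpendicular to the average parazone yaw (axial circular mean + 90
#' degrees), mirroring the convention of running the analysis parallel to
#' the dentin-enamel junction; `"explicit"` mode uses a supplied axis
#' angle (degrees from the image vertical, clockwise).
#'
#' @param table A [extract_rod_objects()] result (or truth table with
#'   `centroid_row`, `centroid_col`, `pitch_deg`, and either
#'   `classification` or `band`).
#' @param axis_mode `"auto"` or `"explicit"`.
#' @param axis_angle_deg Axis angle for `"explicit"` mode.
#' @param scale_um_per_px Pixel size; defaults to the table's attribute.
#' @return A `crossband_profile` tibble (`rod_id`, `position_um`,
#'   `pitch_deg`, `classification`) with an `axis_angle_deg` attribute,
#'   sorted by position.
#' @export
crossband_profile <- function(table, axis_mode = c("auto", "explicit"),
                              axis_angle_deg = NULL,
                              scale_um_per_px = attr(table, "scale_um_per_px")) {
  axis_mode <- match.arg(axis_mode)
  cls <- if ("classification" %in% names(table)) table$classification
         else if ("band" %in% names(table)) table$band
         else abort("`table` needs a classification or band column.",
                    class = "rodseg_validation_error")
  keep <- cls %in% c("parazone", "diazone")
  if (!any(keep)) {
    abort("No retained (parazone/diazone) rods in the table.",
          class = "rodseg_validation_error")
  }
  scale_um_per_px <- scale_um_per_px %||% canonical_frame$um_per_px_at_reference
  if (axis_mode == "auto") {
    yaw_col <- if ("yaw_deg" %in% names(table)) table$yaw_deg else
      abort("Auto mode needs a yaw_deg column.", class = "rodseg_validation_error")
    para <- keep & cls == "parazone"
    if (!any(para)) {
      abort(paste0("Auto mode requires at least one parazone rod; supply ",
                   "axis_mode = \"explicit\" with an operator-chosen angle."),
            class = "rodseg_validation_error")
    }
    axis_angle_deg <- compute_yaw(axial_mean_deg(yaw_col[para]) + 90)
  } else if (is.null(axis_angle_deg)) {
    abort("Explicit mode requires `axis_angle_deg`.",
          class = "rodseg_validation_error")
  }
  th <- axis_angle_deg * pi / 180
  # axis unit vector in (x, y-down) coords for an angle from the vertical
  ux <- sin(th); uy <- -cos(th)
  pos <- (table$centroid_col[keep] * ux + table$centroid_row[keep] * uy) *
    scale_um_per_px
  out <- tibble(
    rod_id = table$rod_id[keep],
    position_um = pos,
    pitch_deg = table$pitch_deg[keep],
    classification = cls[keep]
  )
  out <- out[order(out$position_um), ]
  class(out) <- c("crossband_profile", class(out))
  attr(out, "axis_angle_deg") <- axis_angle_deg
  out
}

#' Write a rod table or profile to CSV
#'
#' @param x A `rod_table` or `crossband_profile`.
#' @param path Output CSV path.
#' @param config_hash Optional provenance hash written as a leading
#'   comment line.
#' @return `path`, invisibly.
#' @export
write_rod_csv <- function(x, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash)) {
    writeLines(sprintf("# rodseg config %s", config_hash), con)
  }
  df <- as.data.frame(lapply(as.list(x), function(col) {
    if (is.list(col)) vapply(col, paste, character(1), collapse = "+") else col
  }))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
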