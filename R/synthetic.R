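#' Specification for a synthetic enamel micrograph
#'
#' Describes an idealised decussated enamel surface as imaged by SEM at the
#' canonical 500x frame: alternating parazone/diazone bands of quasi-
#' cylindrical rods about 5 um in diameter separated by roughly 0.5 um of
#' interrod enamel. Each rod is rendered as the elliptical cross-section of
#' a tilted cylinder: the minor axis `b` equals the rod diameter and the
#' major axis follows `a = b / sin(pitch)`, so the drawn ellipse encodes the
#' rod's out-of-plane pitch exactly via `pitch = asin(b / a)`. Bands run
#' perpendicular to the image x-axis; parazone rods are low-pitch
#' (elongated), diazone rods high-pitch (nearly circular).
#'
#' @param canvas_width_px,canvas_height_px Canvas size in pixels
#'   (default the canonical 640 x 520 frame).
#' @param scale_um_per_px Pixel size; default the canonical 0.38125 um/px.
#' @param band_period_um Spatial period of one parazone + diazone pair.
#' @param band_fraction_diazone Fraction of the period occupied by diazone,
#'   in (0, 1).
#' @param rod_diameter_um True rod diameter (the drawn minor axis).
#' @param interrod_gap_um Nominal interrod spacing between rod envelopes.
#' @param pitch_parazone_deg,pitch_diazone_deg Two-element ranges (degrees,
#'   in (0, 90\]) from which per-rod pitch is drawn uniformly. The parazone
#'   default (18-25 deg) keeps a single in-plane rod's cross-section below
#'   the 70 um^2 merged-object bound used downstream.
#' @param yaw_mean_deg,yaw_jitter_deg In-plane rod orientation: mean angle
#'   from the image vertical and the s.d. of per-rod Gaussian jitter
#'   (truncated at 2.5 s.d. so lattice spacing stays collision-free).
#' @param texture_noise_sd S.d. of additive Gaussian etch-texture noise on
#'   the \[0, 1\] intensity scale.
#' @param background_level,rod_level Mean interrod and rod intensities.
#' @param rod_level_jitter S.d. of per-rod brightness jitter.
#' @param shading_amplitude Amplitude of a mild left-right linear intensity
#'   gradient.
#' @param fill_fraction Probability that a lattice site carries a rod;
#'   with the defaults this yields roughly 300-600 rods per image, matching
#'   the density of a manually annotated micrograph.
#' @param position_jitter_um Uniform per-rod centre jitter (each axis).
#' @param merge_probability Probability that a rod is bridged to its
#'   right-hand lattice neighbour, emulating merged rods in poor
#'   segmentations; 0 disables merging and makes rods non-overlapping by
#'   construction.
#' @param rng_seed Integer seed; a fixed seed makes the specimen
#'   bit-reproducible.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(canvas_width_px = 640L,
                           canvas_height_px = 520L,
                           scale_um_per_px = canonical_frame$um_per_px_at_reference,
                           band_period_um = 60,
                           band_fraction_diazone = 0.5,
                           rod_diameter_um = 5,
                           interrod_gap_um = 0.5,
                           pitch_parazone_deg = c(18, 25),
                           pitch_diazone_deg = c(35, 65),
                           yaw_mean_deg = 0,
                           yaw_jitter_deg = 4,
                           texture_noise_sd = 0.12,
                           background_level = 0.35,
                           rod_level = 0.62,
                           rod_level_jitter = 0.05,
                           shading_amplitude = 0.05,
                           fill_fraction = 0.62,
                           position_jitter_um = 0.1,
                           merge_probability = 0,
                           rng_seed = 1L) {
  spec <- list(
    canvas_width_px = as.integer(canvas_width_px),
    canvas_height_px = as.integer(canvas_height_px),
    scale_um_per_px = scale_um_per_px,
    band_period_um = band_period_um,
    band_fraction_diazone = band_fraction_diazone,
    rod_diameter_um = rod_diameter_um,
    interrod_gap_um = interrod_gap_um,
    pitch_parazone_deg = as.numeric(pitch_parazone_deg),
    pitch_diazone_deg = as.numeric(pitch_diazone_deg),
    yaw_mean_deg = yaw_mean_deg,
    yaw_jitter_deg = yaw_jitter_deg,
    texture_noise_sd = texture_noise_sd,
    background_level = background_level,
    rod_level = rod_level,
    rod_level_jitter = rod_level_jitter,
    shading_amplitude = shading_amplitude,
    fill_fraction = fill_fraction,
    position_jitter_um = position_jitter_um,
    merge_probability = merge_probability,
    rng_seed = as.integer(rng_seed)
  )
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(spec) {
  pos <- c("canvas_width_px", "canvas_height_px", "scale_um_per_px",
           "band_period_um", "rod_diameter_um", "interrod_gap_um")
  for (f in pos) {
    if (!is.numeric(spec[[f]]) || length(spec[[f]]) != 1L ||
        !is.finite(spec[[f]]) || spec[[f]] <= 0) {
      abort(sprintf("`%s` must be a single positive number.", f),
            class = "rodseg_validation_error")
    }
  }
  if (spec$band_fraction_diazone <= 0 || spec$band_fraction_diazone >= 1) {
    abort("`band_fraction_diazone` must lie in (0, 1).",
          class = "rodseg_validation_error")
  }
  for (f in c("pitch_parazone_deg", "pitch_diazone_deg")) {
    r <- spec[[f]]
    if (length(r) != 2L || any(r <= 0) || any(r > 90) || r[1L] > r[2L]) {
      abort(sprintf("`%s` must be an increasing range within (0, 90].", f),
            class = "rodseg_validation_error")
    }
  }
  if (spec$fill_fraction <= 0 || spec$fill_fraction > 1) {
    abort("`fill_fraction` must lie in (0, 1].", class = "rodseg_validation_error")
  }
  if (spec$merge_probability < 0 || spec$merge_probability > 1) {
    abort("`merge_probability` must lie in [0, 1].", class = "rodseg_validation_error")
  }
  if (spec$rod_diameter_um / spec$scale_um_per_px <= 2) {
    abort("Rod diameter is 2 px or less at this scale: unresolvable geometry.",
          class = "rodseg_validation_error")
  }
  invisible(spec)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_spec> %d x %d px @ %.5f um/px, band period ",
                     "%g um, rods %g um / gap %g um, seed %d\n"),
              x$canvas_width_px, x$canvas_height_px, x$scale_um_per_px,
              x$band_period_um, x$rod_diameter_um, x$interrod_gap_um, x$rng_seed))
  invisible(x)
}

# Pixel set of a filled rotated ellipse. Centre (row, col) in pixel units,
# full axes a_px >= b_px, yaw in degrees from the image vertical (clockwise
# as displayed). Returns an integer matrix with columns row, col.
ellipse_pixels <- function(center_row, center_col, a_px, b_px, yaw_deg, H, W) {
  th <- yaw_deg * pi / 180
  dmaj <- c(sin(th), -cos(th))  # (x, y-down) direction of the major axis
  dmin <- c(cos(th), sin(th))
  ex <- sqrt((a_px / 2 * dmaj[1L])^2 + (b_px / 2 * dmin[1L])^2)
  ey <- sqrt((a_px / 2 * dmaj[2L])^2 + (b_px / 2 * dmin[2L])^2)
  cols <- max(1L, floor(center_col - ex)):min(W, ceiling(center_col + ex))
  rows <- max(1L, floor(center_row - ey)):min(H, ceiling(center_row + ey))
  dx <- rep(cols, each = length(rows)) - center_col
  dy <- rep(rows, times = length(cols)) - center_row
  u <- (dx * dmaj[1L] + dy * dmaj[2L]) / (a_px / 2)
  v <- (dx * dmin[1L] + dy * dmin[2L]) / (b_px / 2)
  keep <- u * u + v * v <= 1
  cbind(row = rep(rows, times = length(cols))[keep],
        col = rep(cols, each = length(rows))[keep])
}

#' Generate one synthetic enamel specimen
#'
#' Places rods on a jittered per-band lattice, draws each as a filled
#' ellipse encoding its sampled pitch, renders an SEM-like intensity image
#' (bright rods over a darker interrod background, per-rod brightness
#' jitter, a mild shading gradient, and Gaussian etch-texture noise), and
#' returns the image together with a pixel-exact ground-truth mask, a
#' per-rod truth table, and a per-pixel band map. With
#' `merge_probability = 0` rods are non-overlapping by construction and
#' truth rows correspond 1:1 to mask components.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `synthetic_specimen`: a list with elements
#'   `image` ([sem_image()]), `mask` (\{0, 1\} integer matrix),
#'   `truth_table` (tibble: rod_id, centroid_row, centroid_col, area_px,
#'   a_um, b_um, yaw_deg, pitch_deg, band, merged), `band_map` (integer
#'   matrix, 1 = parazone, 2 = diazone), `spec`, and `held_out`.
#' @export
generate_specimen <- function(spec) {
  validate_synthetic_spec(spec)
  withr_seed <- spec$rng_seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(withr_seed)

  s <- spec$scale_um_per_px
  H <- spec$canvas_height_px; W <- spec$canvas_width_px
  b_px <- spec$rod_diameter_um / s
  gap_px <- spec$interrod_gap_um / s
  period_px <- spec$band_period_um / s
  wp_px <- period_px * (1 - spec$band_fraction_diazone)
  jit_px <- spec$position_jitter_um / s
  yaw_cap <- 2.5 * spec$yaw_jitter_deg

  band_of_x <- function(x) {
    phase <- ((x - 1) %% period_px) / period_px
    ifelse(phase < (1 - spec$band_fraction_diazone), 1L, 2L)
  }
  band_map <- matrix(band_of_x(rep(seq_len(W), each = H)), H, W)

  # lattice sites per band instance
  sites <- list()
  k <- 0L
  x_start <- 1
  repeat {
    x0 <- k * period_px + 1
    if (x0 > W) break
    for (part in 1:2) {
      xa <- x0 + if (part == 2L) wp_px else 0
      xb <- x0 + if (part == 2L) period_px else wp_px
      if (xa > W || xb < 1) next
      range_deg <- if (part == 1L) spec$pitch_parazone_deg else spec$pitch_diazone_deg
      a_max_px <- b_px / sin(range_deg[1L] * pi / 180)
      th_max <- min(abs(spec$yaw_mean_deg) + yaw_cap, 89) * pi / 180
      ext_x <- sqrt((a_max_px * sin(th_max))^2 + (b_px * cos(th_max))^2)
      ext_y <- sqrt((a_max_px * cos(th_max))^2 + (b_px * sin(th_max))^2)
      sx <- ext_x + gap_px
      sy <- ext_y + gap_px
      xs <- seq(xa + ext_x / 2 + 1, xb - ext_x / 2 - 1, by = sx)
      xs <- xs[xs >= ext_x / 2 + 1 & xs <= W - ext_x / 2]
      ys <- seq(ext_y / 2 + 2, H - ext_y / 2 - 1, by = sy)
      if (length(xs) == 0L || length(ys) == 0L) next
      g <- expand.grid(y = ys, x = xs)
      sites[[length(sites) + 1L]] <- data.frame(
        x = g$x, y = g$y, band = part,
        col_index = rep(seq_along(xs), each = length(ys)),
        row_index = rep(seq_along(ys), times = length(xs)),
        band_instance = k * 2L + part
      )
    }
    k <- k + 1L
  }
  sites <- do.call(rbind, sites)
  keep <- runif(nrow(sites)) < spec$fill_fraction
  sites <- sites[keep, , drop = FALSE]
  n <- nrow(sites)
  if (n == 0L) {
    abort("Spec yields no rods; enlarge the canvas or the fill fraction.",
          class = "rodseg_validation_error")
  }

  range_mat <- rbind(spec$pitch_parazone_deg, spec$pitch_diazone_deg)
  pitch <- runif(n, range_mat[sites$band, 1L], range_mat[sites$band, 2L])
  yaw_off <- pmin(pmax(rnorm(n, 0, spec$yaw_jitter_deg), -yaw_cap), yaw_cap)
  yaw <- spec$yaw_mean_deg + yaw_off
  a_um <- spec$rod_diameter_um / sin(pitch * pi / 180)
  cx <- sites$x + runif(n, -jit_px, jit_px)
  cy <- sites$y + runif(n, -jit_px, jit_px)

  lab <- matrix(0L, H, W)
  for (i in seq_len(n)) {
    px <- ellipse_pixels(cy[i], cx[i], a_um[i] / s, b_px, yaw[i], H, W)
    if (nrow(px) == 0L) next
    # drop pixels 8-adjacent to an already drawn rod so sub-pixel lattice
    # jitter can never fuse two rods in the rasterised mask
    idx <- (px[, "col"] - 1L) * H + px[, "row"]
    nbr_clear <- rep(TRUE, nrow(px))
    for (dj in -1:1) for (di in -1:1) {
      rr <- px[, "row"] + di; cc <- px[, "col"] + dj
      ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
      hit <- logical(nrow(px))
      hit[ok] <- lab[(cc[ok] - 1L) * H + rr[ok]] > 0L
      nbr_clear <- nbr_clear & !hit
    }
    lab[idx[nbr_clear]] <- i
  }

  # optional merged-rod emulation: bridge a rod to its right-hand neighbour
  merged_with <- integer(0)
  if (spec$merge_probability > 0) {
    for (i in seq_len(n)) {
      j <- which(sites$band_instance == sites$band_instance[i] &
                 sites$row_index == sites$row_index[i] &
                 sites$col_index == sites$col_index[i] + 1L)
      if (length(j) == 1L && runif(1) < spec$merge_probability) {
        bp <- bridge_pixels(cy[i], cx[i], cy[j], cx[j], width_px = 3, H, W)
        lab[(bp[, "col"] - 1L) * H + bp[, "row"]] <- i
        merged_with <- c(merged_with, i, j)
      }
    }
  }

  mask <- matrix(as.integer(lab > 0L), H, W)

  # truth table from the drawn parameters; centroids from the rasterised
  # pixels so they coincide exactly with mask-component centroids
  idx_by_rod <- split(which(lab > 0L), lab[lab > 0L])
  present <- as.integer(names(idx_by_rod))
  cent_row <- vapply(idx_by_rod, function(ix) mean((ix - 1L) %% H + 1L), numeric(1))
  cent_col <- vapply(idx_by_rod, function(ix) mean((ix - 1L) %/% H + 1L), numeric(1))
  truth <- tibble(
    rod_id = seq_along(present),
    centroid_row = cent_row,
    centroid_col = cent_col,
    area_px = vapply(idx_by_rod, length, integer(1)),
    a_um = a_um[present],
    b_um = spec$rod_diameter_um,
    yaw_deg = compute_yaw(yaw[present]),
    pitch_deg = pitch[present],
    band = c("parazone", "diazone")[sites$band[present]],
    merged = present %in% merged_with
  )

  # collapse bridged rods into their mask component
  if (length(merged_with) > 0L) {
    comp <- label_components8(mask)
    comp_of <- vapply(idx_by_rod, function(ix) comp[ix[1L]], integer(1))
    truth$component <- comp_of
    truth <- truth |>
      dplyr::group_by(.data$component) |>
      dplyr::summarise(
        rod_id = dplyr::first(.data$rod_id),
        centroid_row = sum(.data$centroid_row * .data$area_px) / sum(.data$area_px),
        centroid_col = sum(.data$centroid_col * .data$area_px) / sum(.data$area_px),
        area_px = sum(.data$area_px),
        a_um = max(.data$a_um),
        b_um = dplyr::first(.data$b_um),
        yaw_deg = dplyr::first(.data$yaw_deg),
        pitch_deg = mean(.data$pitch_deg),
        band = dplyr::first(.data$band),
        merged = any(.data$merged) | dplyr::n() > 1L,
        .groups = "drop"
      ) |>
      dplyr::select(-"component") |>
      dplyr::mutate(rod_id = dplyr::row_number())
  }

  # render intensity image
  shade <- matrix(rep(spec$shading_amplitude *
                        (2 * (seq_len(W) - 1) / (W - 1) - 1), each = H), H, W)
  img <- spec$background_level + shade
  if (nrow(truth) > 0L && length(present) > 0L) {
    lev <- spec$rod_level + rnorm(n, 0, spec$rod_level_jitter)
    img[lab > 0L] <- img[lab > 0L] + (lev[lab[lab > 0L]] - spec$background_level)
  }
  img <- img + matrix(rnorm(H * W, 0, spec$texture_noise_sd), H, W)
  img <- pmin(pmax(img, 0), 1)

  structure(
    list(
      image = sem_image(img, canonical_frame$reference_magnification,
                        scale_um_per_px = s,
                        metadata = list(synthetic = TRUE, rng_seed = spec$rng_seed)),
      mask = mask,
      truth_table = truth,
      band_map = band_map,
      spec = spec,
      held_out = FALSE
    ),
    class = "synthetic_specimen"
  )
}

bridge_pixels <- function(r1, c1, r2, c2, width_px, H, W) {
  npts <- ceiling(max(abs(r2 - r1), abs(c2 - c1))) * 2L + 2L
  t <- seq(0, 1, length.out = npts)
  rs <- r1 + t * (r2 - r1); cs <- c1 + t * (c2 - c1)
  half <- floor(width_px / 2)
  off <- expand.grid(dr = -half:half, dc = -half:half)
  rr <- round(rep(rs, each = nrow(off)) + off$dr)
  cc <- round(rep(cs, each = nrow(off)) + off$dc)
  ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
  unique(cbind(row = as.integer(rr[ok]), col = as.integer(cc[ok])))
}

#' @export
print.synthetic_specimen <- function(x, ...) {
  cat(sprintf("<synthetic_specimen> %d x %d px, %d rods (%s), seed %d%s\n",
              nrow(x$mask), ncol(x$mask), nrow(x$truth_table),
              paste(table(x$truth_table$band), collapse = "/"),
              x$spec$rng_seed, if (x$held_out) ", held out" else ""))
  invisible(x)
}

#' Generate a seeded training/validation suite
#'
#' Emulates the annotation effort of a segmentation study: several
#' specimens for training and at least one held out for validation, each
#' generated from a seed derived deterministically from the master seed in
#' `spec`.
#'
#' @param spec A [synthetic_spec()]; its `rng_seed` is the master seed.
#' @param n_train,n_validation Number of training / held-out specimens
#'   (defaults 3 and 1).
#' @return A list of `synthetic_specimen` objects, validation specimens
#'   last with `held_out = TRUE`.
#' @export
generate_training_suite <- function(spec, n_train = 3L, n_validation = 1L) {
  if (n_train < 1L || n_validation < 1L) {
    abort("`n_train` and `n_validation` must each be at least 1.",
          class = "rodseg_validation_error")
  }
  n <- n_train + n_validation
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$rng_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spec
    sp$rng_seed <- seeds[i]
    out[[i]] <- generate_specimen(sp)
    out[[i]]$held_out <- i > n_train
  }
  names(out) <- c(paste0("train", seq_len(n_train)),
                  paste0("validation", seq_len(n_validation)))
  out
}
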