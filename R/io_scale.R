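#' Canonical imaging frame
#'
#' All classifier inputs are normalised to the frame of the reference
#' acquisition: 640 x 520 pixels at 500x nominal magnification, which images
#' a field of view of about 244 um across. Calibrating the pixel size from
#' the 244 um width gives 0.38125 um per pixel; pixels are treated as square
#' (see the methods vignette for the height-calibration caveat).
#'
#' @format A list with elements `width_px`, `height_px`,
#'   `reference_magnification` and `um_per_px_at_reference`.
#' @export
canonical_frame <- list(
  width_px = 640L,
  height_px = 520L,
  reference_magnification = 500,
  um_per_px_at_reference = 244 / 640
)

#' Construct an SEM image object
#'
#' An `sem_image` couples a grayscale pixel grid with the nominal
#' magnification it was acquired at and the physical pixel size derived from
#' it. Intensities are stored as doubles in \[0, 1\] regardless of the bit
#' depth on disk.
#'
#' @param pixels Numeric matrix (rows x cols) of finite, non-negative
#'   intensities.
#' @param magnification Positive nominal magnification (e.g. 500).
#' @param scale_um_per_px Micrometres per pixel. Defaults to the value
#'   implied by `magnification` via [pixel_scale_for_magnification()].
#' @param metadata Free-form named list (species, tooth, section plane, ...).
#' @return An object of class `sem_image`.
#' @export
sem_image <- function(pixels, magnification,
                      scale_um_per_px = pixel_scale_for_magnification(magnification),
                      metadata = list()) {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L) {
    abort("`pixels` must be a matrix with at least one row and one column.",
          class = "rodseg_validation_error")
  }
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    abort("`pixels` must be finite and non-negative.",
          class = "rodseg_validation_error")
  }
  if (!is.numeric(magnification) || length(magnification) != 1L || magnification <= 0) {
    abort("`magnification` must be a single positive number.",
          class = "rodseg_validation_error")
  }
  if (scale_um_per_px <= 0) {
    abort("`scale_um_per_px` must be positive.", class = "rodseg_validation_error")
  }
  structure(
    list(pixels = pixels, magnification = magnification,
         scale_um_per_px = scale_um_per_px, metadata = metadata),
    class = "sem_image"
  )
}

#' @export
print.sem_image <- function(x, ...) {
  cat(sprintf("<sem_image> %d x %d px, mag %gx, %.5f um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$magnification, x$scale_um_per_px))
  invisible(x)
}

#' @export
dim.sem_image <- function(x) dim(x$pixels)

#' Physical pixel size for a nominal magnification
#'
#' The calibration constant is fixed so that a 500x micrograph spans 244 um
#' over 640 pixels; pixel size is inversely proportional to magnification.
#'
#' @param magnification Positive magnification(s).
#' @return Micrometres per pixel, same length as `magnification`.
#' @examples
#' pixel_scale_for_magnification(500)   # 0.38125
#' pixel_scale_for_magnification(1000)  # half of that
#' @export
pixel_scale_for_magnification <- function(magnification) {
  if (!is.numeric(magnification) || any(!is.finite(magnification)) ||
      any(magnification <= 0)) {
    abort("`magnification` must be positive and finite.",
          class = "rodseg_validation_error")
  }
  k <- canonical_frame$reference_magnification * canonical_frame$um_per_px_at_reference
  k / magnification
}

#' Load a grayscale SEM micrograph
#'
#' Reads an 8- or 16-bit TIFF or PNG, collapsing RGB to luminance
#' (0.299 R + 0.587 G + 0.114 B) and any alpha channel is dropped.
#' Intensities are rescaled to \[0, 1\].
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param magnification Positive nominal magnification of the acquisition.
#' @param metadata Optional named list carried on the result.
#' @return An [sem_image()].
#' @export
load_image <- function(path, magnification, metadata = list()) {
  arr <- read_raster(path)
  px <- collapse_gray(arr)
  sem_image(px, magnification, metadata = metadata)
}

read_raster <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Image file not found: %s", path), class = "rodseg_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      tif = ,
      tiff = tiff::readTIFF(path),
      png = png::readPNG(path),
      abort(sprintf("Unsupported image format '.%s' (use TIFF or PNG): %s",
                    ext, path), class = "rodseg_io_error")
    ),
    error = function(e) {
      if (inherits(e, "rodseg_io_error")) stop(e)
      abort(sprintf("Failed to decode image %s: %s", path, conditionMessage(e)),
            class = "rodseg_io_error")
    }
  )
  arr
}

collapse_gray <- function(arr) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3L]
    if (nch >= 3L) {
      return(0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L])
    }
    return(arr[, , 1L])
  }
  abort("Image must be a 2-D grayscale or RGB raster.", class = "rodseg_io_error")
}

#' Load a binary rod mask
#'
#' Masks are PNG images with background 0 and rods at full intensity; any
#' value above `threshold` maps to 1.
#'
#' @param path Path to a PNG (or TIFF) mask.
#' @param threshold Intensity (on the \[0, 1\] scale) above which a pixel is a
#'   rod. Default 0.5.
#' @return Integer matrix over \{0, 1\}.
#' @export
load_mask <- function(path, threshold = 0.5) {
  px <- collapse_gray(read_raster(path))
  m <- matrix(as.integer(px > threshold), nrow(px), ncol(px))
  m
}

#' Write an image or mask to disk
#'
#' `write_image` writes the pixel grid of an [sem_image()] (or a plain
#' matrix in \[0, 1\]) as TIFF or PNG by extension; `write_mask` writes a
#' \{0, 1\} matrix as a \{0, 255\} 8-bit PNG.
#'
#' @param image An `sem_image` or numeric matrix in \[0, 1\].
#' @param path Output path (`.tif`/`.tiff`/`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "sem_image")) image$pixels else image
  px <- pmin(pmax(px, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 16L),
    png = png::writePNG(px, path),
    abort(sprintf("Unsupported output format '.%s'", ext), class = "rodseg_io_error")
  )
  invisible(path)
}

#' @rdname write_image
#' @param mask Integer/logical matrix over \{0, 1\}.
#' @export
write_mask <- function(mask, path) {
  assert_binary_mask(mask)
  png::writePNG(matrix(as.numeric(mask != 0L), nrow(mask), ncol(mask)), path)
  invisible(path)
}

assert_binary_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !all(mask %in% c(0L, 1L))) {
    abort(sprintf("`%s` must be a matrix with values in {0, 1}.", arg),
          class = "rodseg_validation_error")
  }
  invisible(mask)
}

# Dimensions of the magnification-proportional intermediate frame: the size
# the canonical 640 x 520 grid takes when scaled by mag / 500.
mag_frame_dims <- function(magnification) {
  f <- magnification / canonical_frame$reference_magnification
  d <- c(round(canonical_frame$height_px * f), round(canonical_frame$width_px * f))
  pmax(d, 1L)
}

#' Normalise a micrograph to the canonical 500x frame
#'
#' Images acquired at magnifications other than 500x are first brought to a
#' scale proportionate to a 500x acquisition -- padded symmetrically with
#' black (zero) pixels when the magnification is above 500x, centre-cropped
#' when below -- and then resampled bilinearly to exactly 640 x 520 pixels.
#' After normalisation rods have the same pixel dimensions as in a native
#' 500x image. A 500x, 640 x 520 input is returned unchanged.
#'
#' @param image An [sem_image()].
#' @return An `sem_image` in the canonical frame, with magnification
#'   recorded as 500-equivalent.
#' @export
normalize_magnification <- function(image) {
  stopifnot(inherits(image, "sem_image"))
  mag <- image$magnification
  if (mag < 400 || mag > 600) {
    warn(sprintf(paste0("Magnification %gx is outside the supported 400-600x ",
                        "range; normalising anyway."), mag))
  }
  H <- canonical_frame$height_px
  W <- canonical_frame$width_px
  ref <- canonical_frame$reference_magnification
  px <- image$pixels
  if (mag == ref && nrow(px) == H && ncol(px) == W) {
    out <- image
    out$scale_um_per_px <- canonical_frame$um_per_px_at_reference
    return(out)
  }
  target <- mag_frame_dims(mag)
  px <- crop_or_pad(px, target[1L], target[2L])
  px <- resize_bilinear(px, H, W)
  sem_image(pmin(pmax(px, 0), Inf), ref,
            scale_um_per_px = canonical_frame$um_per_px_at_reference,
            metadata = c(image$metadata, list(normalized_from_magnification = mag)))
}

# Centre-crop or symmetrically zero-pad a matrix to (Hout, Wout); when the
# split is uneven the extra pixel goes to the bottom/right.
crop_or_pad <- function(px, Hout, Wout) {
  if (Hout < 1L || Wout < 1L) {
    abort("Crop target smaller than 1 px.", class = "rodseg_validation_error")
  }
  H <- nrow(px); W <- ncol(px)
  adj_rows <- function(m) {
    h <- nrow(m)
    if (h == Hout) return(m)
    if (h > Hout) {
      off <- (h - Hout) %/% 2L
      return(m[(off + 1L):(off + Hout), , drop = FALSE])
    }
    top <- (Hout - h) %/% 2L
    rbind(matrix(0, top, ncol(m)), m, matrix(0, Hout - h - top, ncol(m)))
  }
  adj_cols <- function(m) {
    w <- ncol(m)
    if (w == Wout) return(m)
    if (w > Wout) {
      off <- (w - Wout) %/% 2L
      return(m[, (off + 1L):(off + Wout), drop = FALSE])
    }
    left <- (Wout - w) %/% 2L
    cbind(matrix(0, nrow(m), left), m, matrix(0, nrow(m), Wout - w - left))
  }
  adj_cols(adj_rows(px))
}
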