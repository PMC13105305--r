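# Independent rasterizer used as an oracle for the moment-fit ellipse code:
# draws by rotating the full coordinate grid, a different route from the
# bounding-box renderer inside the package.
raster_ellipse <- function(H, W, center_row, center_col, semi_major,
                           semi_minor, angle_from_vertical_deg) {
  th <- angle_from_vertical_deg * pi / 180
  r <- matrix(rep(seq_len(H), W), H, W)
  c_ <- matrix(rep(seq_len(W), each = H), H, W)
  x <- c_ - center_col
  y <- r - center_row
  u <- x * sin(th) - y * cos(th)  # along the major axis
  v <- x * cos(th) + y * sin(th)
  matrix(as.integer((u / semi_major)^2 + (v / semi_minor)^2 <= 1), H, W)
}

raster_disk <- function(H, W, center_row, center_col, radius) {
  raster_ellipse(H, W, center_row, center_col, radius, radius, 0)
}

# Direct "textbook" 2-D convolution with zero padding, the oracle for the
# Rcpp convolution chain.
conv2d_oracle <- function(img, kernel) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (c_ in seq_len(W)) {
      acc <- 0
      for (i in -1:1) for (j in -1:1) {
        rr <- r + i; cc <- c_ + j
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) {
          acc <- acc + kernel[i + 2, j + 2] * img[rr, cc]
        }
      }
      out[r, c_] <- acc
    }
  }
  out
}

# Quarter-size synthetic spec for tests that only need plumbing, not the
# full canonical canvas.
small_spec <- function(seed = 1, ...) {
  synthetic_spec(canvas_width_px = 240L, canvas_height_px = 200L,
                 rng_seed = seed, ...)
}

# A trivially separable two-blob training set.
toy_training_set <- function(n_per_class = 100, seed = 1, sep = 6) {
  set.seed(seed)
  f <- rbind(matrix(rnorm(2 * n_per_class), ncol = 2),
             matrix(rnorm(2 * n_per_class, mean = sep), ncol = 2))
  colnames(f) <- c("f0001", "f0002")
  structure(
    list(features = f,
         labels = rep(c(0L, 1L), each = n_per_class),
         provenance = tibble::tibble(image = 1L,
                                     row = seq_len(2 * n_per_class),
                                     col = 1L),
         selection = NULL, subsample_fraction = 1, seed = as.integer(seed)),
    class = "training_set"
  )
}

# Hand-built feature stack for assembly tests.
fake_stack <- function(H, W, n_feat, seed = 1) {
  set.seed(seed)
  structure(list(features = array(rnorm(H * W * n_feat), c(H, W, n_feat)),
                 selection = NULL, backend_id = "test"),
            class = "feature_stack")
}

# Minimal rod table for registration tests.
toy_rod_table <- function(rows, cols, pitch) {
  tibble::tibble(rod_id = seq_along(rows), centroid_row = rows,
                 centroid_col = cols, pitch_deg = pitch)
}
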