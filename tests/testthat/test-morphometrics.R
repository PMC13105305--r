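test_that("despeckle removes components strictly below the area threshold and is idempotent", {
  m <- matrix(0L, 60, 80)
  m[2:20, 2:27] <- raster_disk(19, 26, 10, 13, 6)[1:19, 1:26]   # large blob
  m[40, 10:28] <- 1L                                            # 19 px line
  m[50, 10:29] <- 1L                                            # 20 px line
  areas <- function(x) {
    lab <- rodseg:::label_components8(x)
    sort(tabulate(lab[lab > 0]))
  }
  expect_equal(length(areas(m)), 3L)
  d <- despeckle(m, 20)
  expect_equal(length(areas(d)), 2L)
  expect_true(all(areas(d) >= 20))
  expect_identical(despeckle(d, 20), d)
  empty <- matrix(0L, 10, 10)
  expect_identical(despeckle(empty), empty)
})

test_that("pitch follows asin(b/a) with swapped axes rejected", {
  expect_equal(compute_pitch(10, 10), 90)
  expect_equal(compute_pitch(10, 5), 30)
  expect_equal(compute_pitch(10, 7.0710678), 45, tolerance = 1e-6)
  b <- seq(0.5, 10, by = 0.5)
  p <- compute_pitch(10, b)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p <= 90))
  # tiny numerical overshoot is tolerated, real swaps are not
  expect_equal(compute_pitch(10, 10 * (1 + 1e-12)), 90)
  expect_error(compute_pitch(10, 10.1), class = "rodseg_validation_error")
  expect_error(compute_pitch(0, 1), class = "rodseg_validation_error")
})

test_that("yaw folds orientations into (-90, 90] with -90 reported as +90", {
  expect_equal(compute_yaw(0), 0)
  expect_equal(compute_yaw(30), 30)
  expect_equal(compute_yaw(90), 90)
  expect_equal(compute_yaw(-90), 90)
  expect_equal(compute_yaw(150), -30)
  expect_equal(compute_yaw(-150), 30)
  expect_equal(compute_yaw(210), 30)
})

test_that("moment-fit morphometrics match analytic ellipse parameters", {
  cfg <- morphometry_config(scale_um_per_px = 1)
  # rasterised disk, diameter 13 px
  disk <- raster_disk(40, 40, 20, 20, 6.5)
  rt <- extract_rod_objects(disk, cfg)
  expect_equal(nrow(rt), 1L)
  expect_equal(rt$a_um / rt$b_um, 1, tolerance = 0.02)
  expect_gte(rt$pitch_deg, 85)
  expect_lte(rt$pitch_deg, 90)
  expect_equal(rt$equiv_diameter_um, 13, tolerance = 0.05)
  expect_gt(rt$solidity, 0.9)
  # axis-aligned ellipse, semi-axes 20 and 10 px
  ell <- raster_ellipse(60, 60, 30, 30, 20, 10, 0)
  rt <- extract_rod_objects(ell, cfg)
  expect_equal(rt$a_um / rt$b_um, 2, tolerance = 0.05)
  expect_equal(rt$pitch_deg, 30, tolerance = 1)
  expect_equal(rt$yaw_deg, 0, tolerance = 1)
  # tilted ellipse: yaw matches the drawing angle
  tilt <- raster_ellipse(80, 80, 40, 40, 20, 10, 30)
  rt <- extract_rod_objects(tilt, cfg)
  expect_equal(rt$yaw_deg, 30, tolerance = 1.5)
  # three disjoint blobs -> three rows
  multi <- matrix(0L, 60, 60)
  multi <- multi | raster_disk(60, 60, 12, 12, 5) |
    raster_disk(60, 60, 12, 45, 5) | raster_disk(60, 60, 45, 30, 5)
  rt <- extract_rod_objects(matrix(as.integer(multi), 60, 60), cfg)
  expect_equal(nrow(rt), 3L)
  expect_error(extract_rod_objects(matrix(2L, 5, 5), cfg),
               class = "rodseg_validation_error")
})

test_that("pitch from the moment fit is invariant under rotation of the drawn ellipse", {
  cfg <- morphometry_config(scale_um_per_px = 1)
  pitches <- vapply(c(0, 30, 45, 90), function(ang) {
    m <- raster_ellipse(120, 120, 60, 60, 30, 15, ang)
    extract_rod_objects(m, cfg)$pitch_deg
  }, numeric(1))
  expect_lt(diff(range(pitches)), 1)
  expect_true(all(abs(pitches - 30) < 1))
})

test_that("classification precedence: merged-rod filters outrank the pitch rule", {
  cfg <- morphometry_config()
  grid <- expand.grid(pitch_deg = c(10, 25, 26, 60),
                      b_um = c(4, 5.5, 5.6),
                      area_um2 = c(20, 70, 80))
  cls <- classify_rods(grid, cfg)
  for (i in seq_len(nrow(grid))) {
    expected <- if (grid$b_um[i] >= 5.5) "rejected_merged_minor_axis"
      else if (grid$area_um2[i] > 70) "rejected_merged_area"
      else if (grid$pitch_deg[i] > 25) "diazone"
      else "parazone"
    expect_identical(cls[i], expected)
  }
  # no rod failing a merged filter is ever parazone/diazone
  bad <- grid$b_um >= 5.5 | grid$area_um2 > 70
  expect_false(any(cls[bad] %in% c("parazone", "diazone")))
  # boundary semantics: pitch 25 is parazone, 70 um^2 passes, b = 5.5 fails
  expect_identical(classify_rods(data.frame(pitch_deg = 25, b_um = 4,
                                            area_um2 = 20), cfg), "parazone")
  expect_identical(classify_rods(data.frame(pitch_deg = 26, b_um = 4,
                                            area_um2 = 20), cfg), "diazone")
  expect_error(classify_rods(data.frame(pitch_deg = NA, b_um = 4,
                                        area_um2 = 20), cfg),
               class = "rodseg_validation_error")
})

test_that("cross-band profiles project centroids onto the analysis axis", {
  tab <- tibble::tibble(
    rod_id = 1:4,
    centroid_row = c(10, 20, 30, 40),
    centroid_col = c(5, 15, 25, 35),
    pitch_deg = c(20, 50, 21, 52),
    yaw_deg = c(0, 3, -2, 1),
    classification = c("parazone", "diazone", "parazone", "diazone")
  )
  # explicit horizontal axis: position is column * scale
  pr <- crossband_profile(tab, "explicit", axis_angle_deg = 90,
                          scale_um_per_px = 0.5)
  expect_equal(sort(pr$position_um), sort(tab$centroid_col * 0.5))
  expect_equal(pr$pitch_deg[order(pr$rod_id)], tab$pitch_deg)
  # auto mode: near-vertical parazone rods give a near-horizontal axis
  pr2 <- crossband_profile(tab, "auto", scale_um_per_px = 0.5)
  expect_lt(abs(abs(attr(pr2, "axis_angle_deg")) - 90), 3)
  # vertical axis projects rows
  pr3 <- crossband_profile(tab, "explicit", axis_angle_deg = 0,
                           scale_um_per_px = 1)
  expect_equal(sort(abs(pr3$position_um)), sort(tab$centroid_row))
  # auto mode without parazone rods instructs explicit mode
  dia <- tab[tab$classification == "diazone", ]
  expect_error(crossband_profile(dia, "auto"), regexp = "explicit",
               class = "rodseg_validation_error")
  # rejected rods contribute no points
  tab$classification[2] <- "rejected_merged_area"
  pr4 <- crossband_profile(tab, "explicit", axis_angle_deg = 90)
  expect_equal(nrow(pr4), 3L)
})

test_that("axial yaw averaging behaves near +/-90 where arithmetic means fail", {
  expect_equal(abs(rodseg:::axial_mean_deg(c(89, -89))), 90, tolerance = 1e-6)
  expect_equal(rodseg:::axial_mean_deg(c(10, 20)), 15, tolerance = 1e-6)
})
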