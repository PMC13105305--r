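test_that("specimens are bit-reproducible for a fixed seed", {
  sp <- small_spec(seed = 5)
  a <- generate_specimen(sp)
  b <- generate_specimen(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$mask, b$mask)
  expect_identical(a$truth_table, b$truth_table)
})

test_that("the default spec yields 300-600 rods at roughly one-third rod cover", {
  sp <- generate_specimen(synthetic_spec(rng_seed = 2))
  expect_gte(nrow(sp$truth_table), 300)
  expect_lte(nrow(sp$truth_table), 600)
  frac <- mean(sp$mask)
  expect_gt(frac, 0.15)
  expect_lt(frac, 0.5)
  expect_setequal(unique(sp$truth_table$band), c("parazone", "diazone"))
})

test_that("truth rows correspond 1:1 with mask components and pitch encodes the drawn axes", {
  sp <- generate_specimen(small_spec(seed = 9))
  lab <- rodseg:::label_components8(sp$mask)
  expect_equal(max(lab), nrow(sp$truth_table))
  expect_equal(sp$truth_table$pitch_deg,
               asin(sp$truth_table$b_um / sp$truth_table$a_um) * 180 / pi)
  expect_true(all(sp$truth_table$area_px >= 20))
})

test_that("noise-free 90-degree rods are circular (a equals b)", {
  sp <- small_spec(seed = 3,
                   pitch_parazone_deg = c(90, 90), pitch_diazone_deg = c(90, 90),
                   texture_noise_sd = 1e-6, rod_level_jitter = 0,
                   shading_amplitude = 0)
  s <- generate_specimen(sp)
  expect_equal(s$truth_table$a_um, rep(sp$rod_diameter_um, nrow(s$truth_table)))
  expect_equal(s$truth_table$b_um, rep(sp$rod_diameter_um, nrow(s$truth_table)))
  expect_equal(s$truth_table$pitch_deg, rep(90, nrow(s$truth_table)))
})

test_that("rod cover increases as the interrod gap narrows", {
  fracs <- vapply(c(2.0, 1.0, 0.4), function(g) {
    mean(generate_specimen(synthetic_spec(rng_seed = 4, interrod_gap_um = g))$mask)
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})

test_that("unresolvable rod geometry is rejected", {
  expect_error(synthetic_spec(rod_diameter_um = 0.5),
               class = "rodseg_validation_error")
  expect_error(synthetic_spec(pitch_parazone_deg = c(0, 20)),
               class = "rodseg_validation_error")
  expect_error(synthetic_spec(band_fraction_diazone = 1),
               class = "rodseg_validation_error")
})

test_that("morphometrics on the ground-truth mask recovers true pitch to within 3 degrees", {
  sp <- generate_specimen(synthetic_spec(rng_seed = 11))
  cfg <- morphometry_config(scale_um_per_px = sp$spec$scale_um_per_px)
  rt <- extract_rod_objects(sp$mask, cfg)
  reg <- register_rod_tables(sp$truth_table, rt)
  pairs <- tidy(reg)
  truth_low <- pairs$truth_pitch <= 60
  expect_gt(sum(truth_low), 100)
  mae <- mean(abs(pairs$pred_pitch[truth_low] - pairs$truth_pitch[truth_low]))
  expect_lte(mae, 3)
})

test_that("the band period is recoverable from the truth-table cross-band profile", {
  sp <- generate_specimen(synthetic_spec(rng_seed = 11))
  pr <- crossband_profile(sp$truth_table, "explicit", axis_angle_deg = 90)
  bins <- seq(0, max(pr$position_um) + 2, by = 2)
  bp <- tapply(pr$pitch_deg, cut(pr$position_um, bins), mean)
  x <- as.numeric(bp)
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  ac <- stats::acf(x, lag.max = 60, plot = FALSE)$acf[-1]
  lags <- 10:60  # periods of 20-120 um, beyond the rod lattice spacing
  period <- lags[which.max(ac[lags])] * 2
  lattice_um <- sp$spec$rod_diameter_um + sp$spec$interrod_gap_um + 1
  expect_lte(abs(period - sp$spec$band_period_um), lattice_um)
})

test_that("merged-rod emulation fuses neighbours that the filters then reject", {
  sp <- synthetic_spec(merge_probability = 0.4, rng_seed = 3)
  s <- generate_specimen(sp)
  expect_gt(sum(s$truth_table$merged), 10)
  lab <- rodseg:::label_components8(s$mask)
  expect_equal(max(lab), nrow(s$truth_table))
  rt <- extract_rod_objects(s$mask, morphometry_config())
  expect_gt(sum(startsWith(rt$classification, "rejected_")), 10)
})

test_that("the training suite derives distinct seeds and flags the held-out specimen", {
  suite <- generate_training_suite(small_spec(seed = 21))
  expect_length(suite, 4L)
  expect_identical(unname(vapply(suite, `[[`, logical(1), "held_out")),
                   c(FALSE, FALSE, FALSE, TRUE))
  expect_false(identical(suite[[1]]$mask, suite[[2]]$mask))
  suite2 <- generate_training_suite(small_spec(seed = 21))
  expect_identical(suite[[1]]$image$pixels, suite2[[1]]$image$pixels)
  expect_identical(suite[[4]]$mask, suite2[[4]]$mask)
  two <- generate_training_suite(small_spec(seed = 8), n_train = 1, n_validation = 1)
  expect_length(two, 2L)
  expect_false(identical(two[[1]]$mask, two[[2]]$mask))
  expect_error(generate_training_suite(small_spec(), n_train = 0),
               class = "rodseg_validation_error")
})
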