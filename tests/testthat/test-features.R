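test_that("feature counts follow the layer filter sizes and are additive", {
  expect_equal(n_features(layer_selection(1)), 64)
  expect_equal(n_features(layer_selection(1:13)), 4224)
  expect_equal(sum(vgg16_filter_counts), 4224)
  expect_equal(n_features(layer_selection(c(1, 5))),
               n_features(layer_selection(1)) + n_features(layer_selection(5)))
  expect_equal(n_features(layer_selection(c(3, 8, 13))), 128 + 512 + 512)
  expect_error(layer_selection(integer(0)), class = "rodseg_validation_error")
  expect_error(layer_selection(14), class = "rodseg_validation_error")
})

test_that("filter-bank extractors are seed-deterministic and share layer kernels across selections", {
  e1 <- build_extractor(layer_selection(c(1, 2)), seed = 3)
  e2 <- build_extractor(layer_selection(c(1, 2)), seed = 3)
  expect_identical(e1$layers, e2$layers)
  e3 <- build_extractor(layer_selection(2), seed = 3)
  expect_identical(e1$layers[[1]]$kernels, e3$layers[[1]]$kernels)
  expect_identical(e1$layers[[2]]$kernels, e3$layers[[2]]$kernels)
  e4 <- build_extractor(layer_selection(1), seed = 4)
  expect_false(identical(e1$layers[[1]]$kernels, e4$layers[[1]]$kernels))
})

test_that("the pretrained backend demands local weights with the right shapes", {
  expect_error(build_extractor(layer_selection(1), backend = "vgg16"),
               class = "rodseg_weights_error")
  expect_error(build_extractor(layer_selection(1), backend = "vgg16",
                               weights = "/no/such/weights.rds"),
               regexp = "filterbank", class = "rodseg_weights_error")
  bad <- list(list(kernels = array(0, c(3, 3, 2, 64)), bias = numeric(64)))
  expect_error(build_extractor(layer_selection(1), backend = "vgg16",
                               weights = bad),
               class = "rodseg_weights_error")
  ok <- list(list(kernels = array(rnorm(9 * 64), c(3, 3, 1, 64)),
                  bias = numeric(64)))
  ex <- build_extractor(layer_selection(1), backend = "vgg16", weights = ok)
  expect_equal(ex$backend_id, "vgg16-pretrained")
})

test_that("expansion preserves spatial shape and honours the feature count", {
  set.seed(1)
  img <- matrix(runif(16 * 16), 16, 16)
  ex <- build_extractor(layer_selection(c(1, 3)), seed = 1)
  st <- expand_features(img, ex)
  expect_equal(dim(st$features), c(16L, 16L, 64L + 128L))
  st1 <- expand_features(img, build_extractor(layer_selection(1), seed = 1))
  expect_equal(dim(st1$features), c(16L, 16L, 64L))
  expect_error(expand_features(matrix(c(1, NA, 1, 1), 2, 2), ex),
               class = "rodseg_validation_error")
})

test_that("with activations and pooling omitted the expansion is linear and zero maps to zero", {
  ex <- build_extractor(layer_selection(c(1, 2)), seed = 2)
  zero <- expand_features(matrix(0, 12, 12), ex)
  expect_true(all(zero$features == 0))
  set.seed(3)
  img <- matrix(rnorm(12 * 12), 12, 12)
  one <- expand_features(img, ex)
  two <- expand_features(2 * img, ex)
  expect_equal(two$features, 2 * one$features, tolerance = 1e-12)
})

test_that("a constant image yields spatially constant interior features", {
  ex <- build_extractor(layer_selection(2), seed = 5)
  st <- expand_features(matrix(1, 20, 20), ex)
  interior <- st$features[5:16, 5:16, ]
  rng <- apply(interior, 3, function(m) diff(range(m)))
  expect_lt(max(rng), 1e-10)
})

test_that("the convolution chain matches a direct convolution oracle", {
  set.seed(8)
  img <- matrix(rnorm(12 * 12), 12, 12)
  ex <- build_extractor(layer_selection(1), seed = 8)
  st <- expand_features(img, ex)
  for (k in c(1, 17, 64)) {
    expect_equal(st$features[, , k],
                 conv2d_oracle(img, ex$layers[[1]]$kernels[, , 1, k]),
                 tolerance = 1e-12)
  }
})

test_that("layer-selection enumeration counts subsets and samples reproducibly", {
  expect_length(enumerate_layer_selections(2, pool = 1:3), 6L)
  expect_length(enumerate_layer_selections(3, pool = 1:3), 7L)
  s100 <- enumerate_layer_selections(13, sample_n = 100, seed = 9)
  expect_length(s100, 100L)
  expect_equal(length(unique(vapply(s100, format, character(1)))), 100L)
  s100b <- enumerate_layer_selections(13, sample_n = 100, seed = 9)
  expect_identical(s100, s100b)
  expect_warning(all6 <- enumerate_layer_selections(2, sample_n = 50, pool = 1:3),
                 "population")
  expect_length(all6, 6L)
})
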