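test_that("flip augmentation triples pairs, transforms masks identically, and flips are involutions", {
  set.seed(1)
  imgs <- lapply(1:3, function(i) matrix(runif(20 * 16), 20, 16))
  msks <- lapply(1:3, function(i) raster_disk(20, 16, 10, 8, 4))
  out <- augment_flips(imgs, msks)
  expect_length(out, 9L)
  expect_equal(vapply(out, `[[`, character(1), "augmentation"),
               rep(c("original", "fliplr", "flipud"), 3))
  one <- augment_flips(imgs[1], msks[1])
  expect_length(one, 3L)
  # masks transformed identically to images
  expect_identical(out[[2]]$image, imgs[[1]][, 16:1])
  expect_identical(out[[2]]$mask, msks[[1]][, 16:1])
  expect_identical(out[[3]]$mask, msks[[1]][20:1, ])
  # flipping twice restores the original
  expect_identical(out[[2]]$image[, 16:1], imgs[[1]])
  expect_identical(out[[3]]$image[20:1, ], imgs[[1]])
  expect_error(augment_flips(imgs, msks[1:2]), class = "rodseg_validation_error")
  expect_error(augment_flips(imgs[1], list(raster_disk(5, 5, 3, 3, 1))),
               class = "rodseg_validation_error")
})

test_that("training-set assembly pools pixel rows with seeded subsampling", {
  s1 <- fake_stack(10, 10, 3, seed = 1)
  s2 <- fake_stack(10, 10, 3, seed = 2)
  m <- matrix(rep(c(0L, 1L), 50), 10, 10)
  ts <- assemble_training_set(list(s1, s2), list(m, m), subsample_fraction = 1)
  expect_equal(nrow(ts$features), 200L)
  expect_equal(ts$labels, c(as.integer(m), as.integer(m)))
  half1 <- assemble_training_set(list(s1), list(m), 0.5, seed = 4)
  half2 <- assemble_training_set(list(s1), list(m), 0.5, seed = 4)
  expect_identical(half1$features, half2$features)
  expect_equal(nrow(half1$features), 50L)
  expect_error(assemble_training_set(list(s1, fake_stack(10, 10, 4)), list(m, m)),
               class = "rodseg_validation_error")
})

test_that("streaming expansion-plus-assembly matches the two-step route row for row", {
  sp <- generate_specimen(small_spec(seed = 31))
  sp2 <- generate_specimen(small_spec(seed = 32))
  pairs <- list(list(image = sp$image$pixels, mask = sp$mask),
                list(image = sp2$image$pixels, mask = sp2$mask))
  ex <- build_extractor(layer_selection(1), seed = 2)
  ts1 <- expand_and_assemble(pairs, ex, subsample_fraction = 0.1, seed = 5)
  stacks <- lapply(pairs, function(p) expand_features(p$image, ex))
  ts2 <- assemble_training_set(stacks, lapply(pairs, `[[`, "mask"),
                               subsample_fraction = 0.1, seed = 5)
  expect_identical(ts1$features, ts2$features)
  expect_identical(ts1$labels, ts2$labels)
  expect_identical(ts1$provenance, ts2$provenance)
})

test_that("nine full-frame stacks at full sampling pool 9 * 640 * 520 rows", {
  stacks <- lapply(1:9, function(i)
    structure(list(features = array(0, c(520, 640, 1)), selection = NULL,
                   backend_id = "test"), class = "feature_stack"))
  masks <- lapply(1:9, function(i) matrix(0L, 520, 640))
  for (m in seq_along(masks)) masks[[m]][1, 1] <- 1L
  ts <- assemble_training_set(stacks, masks, subsample_fraction = 1)
  expect_equal(nrow(ts$features), 9L * 640L * 520L)
})

test_that("the forest separates separable blobs, is seed-deterministic, and defaults to 150 trees", {
  ts <- toy_training_set(150, seed = 2)
  clf <- train_classifier(ts, n_trees = 50, seed = 1)
  pr <- predict(clf$forest, data = ts$features, num.threads = 1)$predictions
  expect_equal(as.integer(pr[, "rod"] >= 0.5), ts$labels)

  probe <- ts$features[c(1, 100, 200, 250), , drop = FALSE]
  clf2 <- train_classifier(ts, n_trees = 50, seed = 1)
  p1 <- predict(clf$forest, data = probe, num.threads = 1)$predictions
  p2 <- predict(clf2$forest, data = probe, num.threads = 1)$predictions
  expect_identical(p1, p2)

  dflt <- train_classifier(toy_training_set(30), seed = 1)
  expect_equal(dflt$n_trees, 150L)

  bad <- toy_training_set(30)
  bad$labels <- rep(1L, length(bad$labels))
  expect_error(train_classifier(bad), class = "rodseg_validation_error")
})

test_that("mask prediction enforces the feature contract and yields probabilities in [0,1]", {
  ts <- toy_training_set(100, seed = 3)
  clf <- train_classifier(ts, n_trees = 30, seed = 1)
  H <- 8; W <- 6
  set.seed(5)
  feats <- array(rnorm(H * W * 2, mean = 3), c(H, W, 2))
  st <- structure(list(features = feats, selection = NULL, backend_id = "test"),
                  class = "feature_stack")
  pm <- predict_mask(clf, st)
  expect_equal(dim(pm$mask), c(H, W))
  expect_true(all(pm$probability >= 0 & pm$probability <= 1))
  expect_true(all(pm$mask %in% c(0L, 1L)))
  expect_identical(pm$mask, matrix(as.integer(pm$probability >= 0.5), H, W))
  wrong <- structure(list(features = array(0, c(H, W, 5)), selection = NULL,
                          backend_id = "test"), class = "feature_stack")
  expect_error(predict_mask(clf, wrong), class = "rodseg_validation_error")
})

test_that("pixel accuracy counts agree with identity, complement and single-pixel cases and are symmetric", {
  m <- raster_disk(20, 20, 10, 10, 5)
  perfect <- pixel_accuracy(m, m)
  expect_equal(perfect$pixel_accuracy_percent, 100)
  expect_equal(perfect$iou, 1)
  comp <- pixel_accuracy(1L - m, m)
  expect_equal(comp$pixel_accuracy_percent, 0)
  expect_equal(comp$iou, 0)
  a <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  b <- matrix(c(1L, 0L, 1L, 1L), 2, 2)
  expect_equal(pixel_accuracy(a, b)$pixel_accuracy_percent, 75)
  set.seed(9)
  r1 <- matrix(rbinom(100, 1, 0.3), 10, 10)
  r2 <- matrix(rbinom(100, 1, 0.3), 10, 10)
  expect_equal(pixel_accuracy(r1, r2)$pixel_accuracy_percent,
               pixel_accuracy(r2, r1)$pixel_accuracy_percent)
  expect_equal(sum(pixel_accuracy(r1, r2)[, c("tp", "tn", "fp", "fn")]), 100)
  expect_error(pixel_accuracy(a, matrix(0L, 3, 3)),
               class = "rodseg_validation_error")
})

test_that("cross-validation partitions rows, warns on pixel-level fallback, and is seeded", {
  ts <- toy_training_set(500, seed = 6)  # 1000 rows, one source image
  expect_warning(cv <- kfold_crossvalidate(ts, k = 5, n_trees = 20, seed = 2),
                 "pixel-level")
  expect_equal(nrow(cv$folds), 5L)
  expect_equal(sort(cv$folds$n_test), rep(200L, 5))
  expect_true(all(cv$folds$accuracy_percent >= 0 & cv$folds$accuracy_percent <= 100))
  expect_equal(cv$mean_accuracy_percent, mean(cv$folds$accuracy_percent))
  suppressWarnings({
    cv2 <- kfold_crossvalidate(ts, k = 5, n_trees = 20, seed = 2)
  })
  expect_identical(cv$folds, cv2$folds)
  # grouped folds when enough source images exist
  ts$provenance$image <- rep(1:5, each = 200)
  expect_no_warning(cvg <- kfold_crossvalidate(ts, k = 5, n_trees = 10, seed = 1))
  expect_equal(nrow(cvg$folds), 5L)
  expect_error(kfold_crossvalidate(ts, k = 1), class = "rodseg_validation_error")
})

test_that("a singleton layer search equals a direct train-and-score", {
  sp <- generate_specimen(small_spec(seed = 13))
  sp2 <- generate_specimen(small_spec(seed = 14))
  train <- list(list(image = sp$image$pixels, mask = sp$mask))
  val <- list(image = sp2$image$pixels, mask = sp2$mask)
  res <- layer_search(train, val, list(1), n_trees = 25,
                      subsample_fraction = 0.05, seed = 3)
  expect_equal(nrow(res), 1L)

  ex <- build_extractor(layer_selection(1), seed = 3)
  st <- expand_features(train[[1]]$image, ex)
  ts <- assemble_training_set(list(st), list(train[[1]]$mask), 0.05, seed = 3)
  clf <- train_classifier(ts, n_trees = 25, seed = 3)
  pm <- predict_mask(clf, expand_features(val$image, ex))
  direct <- pixel_accuracy(pm, val$mask)
  expect_equal(res$accuracy_percent, direct$pixel_accuracy_percent)
  expect_error(layer_search(train, val, list()), class = "rodseg_validation_error")
})

test_that("classifier artifacts round-trip through disk with their contract", {
  ts <- toy_training_set(50, seed = 4)
  clf <- train_classifier(ts, n_trees = 20, seed = 1)
  f <- withr::local_tempfile(fileext = ".rds")
  save_classifier(clf, f)
  back <- load_classifier(f)
  expect_equal(back$n_trees, 20L)
  pr1 <- predict(clf$forest, data = ts$features[1:5, ], num.threads = 1)$predictions
  pr2 <- predict(back$forest, data = ts$features[1:5, ], num.threads = 1)$predictions
  expect_identical(pr1, pr2)
  g <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), g)
  expect_error(load_classifier(g), class = "rodseg_io_error")
})
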