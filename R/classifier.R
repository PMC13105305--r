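#' Flip augmentation for image/mask pairs
#'
#' Expands each training pair into three: the original, a left-right flip,
#' and a top-bottom flip, with the mask transformed identically. These are
#' the only augmentations applied; harsher distortions are avoided because
#' they degrade per-pixel correspondence between image and mask.
#'
#' @param images List of [sem_image()] objects or numeric matrices.
#' @param masks List of \{0, 1\} matrices, shape-matched 1:1 with `images`.
#' @return A list of length `3 * length(images)`; each element has fields
#'   `image`, `mask`, `source` (input index) and `augmentation`
#'   (`"original"`, `"fliplr"`, `"flipud"`).
#' @export
augment_flips <- function(images, masks) {
  if (length(images) != length(masks)) {
    abort("`images` and `masks` must have the same length.",
          class = "rodseg_validation_error")
  }
  flip_lr <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  flip_ud <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  out <- list()
  for (i in seq_along(images)) {
    px <- if (inherits(images[[i]], "sem_image")) images[[i]]$pixels else images[[i]]
    mk <- masks[[i]]
    assert_binary_mask(mk, sprintf("masks[[%d]]", i))
    if (!identical(dim(px), dim(mk))) {
      abort(sprintf("Image %d and its mask differ in shape.", i),
            class = "rodseg_validation_error")
    }
    out <- c(out, list(
      list(image = px, mask = mk, source = i, augmentation = "original"),
      list(image = flip_lr(px), mask = flip_lr(mk), source = i, augmentation = "fliplr"),
      list(image = flip_ud(px), mask = flip_ud(mk), source = i, augmentation = "flipud")
    ))
  }
  out
}

#' Pool per-pixel feature rows into a training set
#'
#' Flattens each feature stack to one row per pixel, pairs rows with the
#' mask labels, and pools across images. A seeded uniform pixel subsample
#' can be taken per image; `subsample_fraction = 1` reproduces exact
#' pooling of every pixel. The default fraction of 0.02 is chosen so a
#' full training run completes in minutes on a single core; random-forest
#' accuracy on this task saturates well below that sampling rate (see the
#' methods vignette).
#'
#' @param stacks List of [expand_features()] results with identical
#'   feature dimension.
#' @param masks List of \{0, 1\} matrices, spatially matched to `stacks`.
#' @param subsample_fraction Fraction of pixels kept per image, in (0, 1].
#' @param seed Seed for the pixel subsample.
#' @return A `training_set`: list with `features` (rows x n_features
#'   matrix), `labels` (integer 0/1), `provenance` (tibble: image, row,
#'   col), and `selection`.
#' @export
assemble_training_set <- function(stacks, masks, subsample_fraction = 0.02,
                                  seed = 1L) {
  if (length(stacks) != length(masks) || length(stacks) == 0L) {
    abort("`stacks` and `masks` must be non-empty and of equal length.",
          class = "rodseg_validation_error")
  }
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    abort("`subsample_fraction` must lie in (0, 1].",
          class = "rodseg_validation_error")
  }
  nf <- vapply(stacks, function(s) dim(s$features)[3L], integer(1))
  if (length(unique(nf)) != 1L) {
    abort("All stacks must share one feature dimension.",
          class = "rodseg_validation_error")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  feats <- vector("list", length(stacks))
  labs <- vector("list", length(stacks))
  prov <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    f <- stacks[[i]]$features
    H <- dim(f)[1L]; W <- dim(f)[2L]
    mk <- masks[[i]]
    assert_binary_mask(mk, sprintf("masks[[%d]]", i))
    if (!identical(dim(mk), c(H, W))) {
      abort(sprintf("Stack %d and its mask differ in spatial shape.", i),
            class = "rodseg_validation_error")
    }
    npx <- H * W
    idx <- if (subsample_fraction < 1) {
      sort(sample.int(npx, ceiling(subsample_fraction * npx)))
    } else seq_len(npx)
    fm <- matrix(f, npx, dim(f)[3L])
    feats[[i]] <- fm[idx, , drop = FALSE]
    labs[[i]] <- as.integer(mk)[idx]
    prov[[i]] <- tibble(image = i,
                        row = (idx - 1L) %% H + 1L,
                        col = (idx - 1L) %/% H + 1L)
  }
  features <- do.call(rbind, feats)
  colnames(features) <- sprintf("f%04d", seq_len(ncol(features)))
  structure(
    list(features = features,
         labels = unlist(labs),
         provenance = dplyr::bind_rows(prov),
         selection = stacks[[1L]]$selection,
         subsample_fraction = subsample_fraction,
         seed = as.integer(seed)),
    class = "training_set"
  )
}

#' Expand images and pool a training set in one streaming pass
#'
#' Equivalent to [expand_features()] on every pair followed by
#' [assemble_training_set()] (identical row sampling for the same seed),
#' but expands one image at a time and keeps only the sampled rows, so
#' peak memory stays near a single feature stack.
#'
#' @param pairs List of `list(image =, mask =)` pairs (e.g. from
#'   [augment_flips()]).
#' @param extractor A [build_extractor()] result.
#' @param subsample_fraction,seed As in [assemble_training_set()].
#' @param prep Optional function applied to each image matrix before
#'   expansion (e.g. intensity standardisation).
#' @return A `training_set`.
#' @export
expand_and_assemble <- function(pairs, extractor, subsample_fraction = 0.02,
                                seed = 1L, prep = identity) {
  if (length(pairs) == 0L) {
    abort("`pairs` must be non-empty.", class = "rodseg_validation_error")
  }
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    abort("`subsample_fraction` must lie in (0, 1].",
          class = "rodseg_validation_error")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  feats <- vector("list", length(pairs))
  labs <- vector("list", length(pairs))
  prov <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    px <- pairs[[i]]$image
    if (inherits(px, "sem_image")) px <- px$pixels
    mk <- pairs[[i]]$mask
    assert_binary_mask(mk, sprintf("pairs[[%d]]$mask", i))
    st <- expand_features(prep(px), extractor)
    d <- dim(st$features)
    if (!identical(dim(mk), d[1:2])) {
      abort(sprintf("Pair %d: image and mask differ in shape.", i),
            class = "rodseg_validation_error")
    }
    npx <- d[1L] * d[2L]
    idx <- if (subsample_fraction < 1) {
      sort(sample.int(npx, ceiling(subsample_fraction * npx)))
    } else seq_len(npx)
    feats[[i]] <- matrix(st$features, npx, d[3L])[idx, , drop = FALSE]
    labs[[i]] <- as.integer(mk)[idx]
    prov[[i]] <- tibble(image = i,
                        row = (idx - 1L) %% d[1L] + 1L,
                        col = (idx - 1L) %/% d[1L] + 1L)
    rm(st)
  }
  features <- do.call(rbind, feats)
  colnames(features) <- sprintf("f%04d", seq_len(ncol(features)))
  structure(
    list(features = features,
         labels = unlist(labs),
         provenance = dplyr::bind_rows(prov),
         selection = extractor$selection,
         subsample_fraction = subsample_fraction,
         seed = as.integer(seed)),
    class = "training_set"
  )
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d rows x %d features from %d image(s), %.1f%% rod\n",
              nrow(x$features), ncol(x$features),
              length(unique(x$provenance$image)), 100 * mean(x$labels)))
  invisible(x)
}

#' Train the random-forest pixel classifier
#'
#' Fits a random forest with standard hyperparameters -- unlimited depth,
#' sqrt(n_features) candidate variables per split, Gini impurity, bootstrap
#' sampling -- varying only the number of trees (default 150). The forest
#' is a probability forest so each pixel also receives a vote-fraction rod
#' probability.
#'
#' @param ts A [assemble_training_set()] result.
#' @param n_trees Number of trees (default 150).
#' @param seed Seed for tree growing; fixed seed gives identical
#'   predictions across runs.
#' @param class_weights Optional length-2 weights (background, rod) to
#'   counter class imbalance; `NULL` (default) leaves classes unweighted.
#' @param num_threads Threads for ranger (default 1; results are
#'   independent of thread count for a fixed seed).
#' @return A `pixel_classifier`.
#' @export
train_classifier <- function(ts, n_trees = 150L, seed = 1L,
                             class_weights = NULL, num_threads = 1L) {
  stopifnot(inherits(ts, "training_set"))
  if (length(unique(ts$labels)) < 2L) {
    abort("Training set contains a single class; both rod and background pixels are required.",
          class = "rodseg_validation_error")
  }
  y <- factor(ts$labels, levels = c(0L, 1L), labels = c("background", "rod"))
  fit <- ranger::ranger(
    x = ts$features, y = y,
    num.trees = n_trees,
    probability = TRUE,
    seed = seed,
    num.threads = num_threads,
    class.weights = class_weights,
    verbose = FALSE
  )
  structure(
    list(forest = fit,
         n_trees = as.integer(n_trees),
         seed = as.integer(seed),
         selection = ts$selection,
         n_features = ncol(ts$features),
         feature_names = colnames(ts$features),
         threshold = 0.5),
    class = "pixel_classifier"
  )
}

#' @export
print.pixel_classifier <- function(x, ...) {
  sel <- if (is.null(x$selection)) "unspecified" else
    paste(unclass(x$selection), collapse = ", ")
  cat(sprintf("<pixel_classifier> %d trees on %d features (layers {%s}), OOB Brier %.4f\n",
              x$n_trees, x$n_features, sel, x$forest$prediction.error))
  invisible(x)
}

#' Predict a rod mask from a feature stack
#'
#' Applies the forest per pixel and thresholds the vote-fraction rod
#' probability at `threshold` (default 0.5, i.e. majority vote; ties go to
#' rod).
#'
#' @param clf A [train_classifier()] result.
#' @param stack A [expand_features()] result whose feature dimension
#'   matches the classifier's training contract.
#' @param threshold Probability threshold for the rod class.
#' @param num_threads Threads for prediction.
#' @return A `mask_prediction`: list with `mask` (\{0, 1\} matrix) and
#'   `probability` (matrix in \[0, 1\]).
#' @export
predict_mask <- function(clf, stack, threshold = clf$threshold, num_threads = 1L) {
  stopifnot(inherits(clf, "pixel_classifier"), inherits(stack, "feature_stack"))
  d <- dim(stack$features)
  if (d[3L] != clf$n_features) {
    abort(sprintf(paste0("Feature contract mismatch: classifier expects %d ",
                         "features per pixel, stack provides %d."),
                  clf$n_features, d[3L]),
          class = "rodseg_validation_error")
  }
  fm <- matrix(stack$features, d[1L] * d[2L], d[3L])
  colnames(fm) <- clf$feature_names
  pr <- stats::predict(clf$forest, data = fm, num.threads = num_threads,
                       verbose = FALSE)$predictions
  prob <- matrix(pr[, "rod"], d[1L], d[2L])
  structure(
    list(mask = matrix(as.integer(prob >= threshold), d[1L], d[2L]),
         probability = prob,
         threshold = threshold),
    class = "mask_prediction"
  )
}

#' @export
print.mask_prediction <- function(x, ...) {
  cat(sprintf("<mask_prediction> %d x %d px, %.1f%% rod at threshold %.2f\n",
              nrow(x$mask), ncol(x$mask), 100 * mean(x$mask), x$threshold))
  invisible(x)
}

as_mask <- function(x, arg = "mask") {
  if (inherits(x, "mask_prediction")) x <- x$mask
  if (is.logical(x)) x <- matrix(as.integer(x), nrow(x), ncol(x))
  assert_binary_mask(x, arg)
  x
}

#' Pixel accuracy and overlap of a predicted mask
#'
#' Accuracy is the percentage of pixels (rod or background) classified
#' identically in both masks; IoU is the rod-class intersection over union
#' TP / (TP + FP + FN).
#'
#' @param pred,truth \{0, 1\} matrices of equal shape (a
#'   [predict_mask()] result is accepted for `pred`).
#' @return An `accuracy_report`: one-row tibble with
#'   `pixel_accuracy_percent`, `iou`, `tp`, `tn`, `fp`, `fn`.
#' @export
pixel_accuracy <- function(pred, truth) {
  pred <- as_mask(pred, "pred")
  truth <- as_mask(truth, "truth")
  if (!identical(dim(pred), dim(truth))) {
    abort("`pred` and `truth` must have the same shape.",
          class = "rodseg_validation_error")
  }
  tp <- sum(pred == 1L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  total <- tp + tn + fp + fn
  denom <- tp + fp + fn
  out <- tibble(
    pixel_accuracy_percent = 100 * (tp + tn) / total,
    iou = if (denom == 0L) 1 else tp / denom,
    tp = tp, tn = tn, fp = fp, fn = fn
  )
  class(out) <- c("accuracy_report", class(out))
  out
}

#' Brute-force search over layer combinations
#'
#' Scores each candidate layer selection by building the extractor,
#' expanding the training and validation images, training a forest (50
#' trees by default, as in the screening stage of the optimisation) and
#' measuring pixel accuracy on the held-out validation image. Internally
#' the convolutional chain is evaluated once per image over the union of
#' all candidate layers and sliced per selection, so the search cost is
#' dominated by a single expansion per image.
#'
#' @param train_pairs List of `list(image =, mask =)` training pairs
#'   (e.g. from [augment_flips()]).
#' @param validation_pair One held-out `list(image =, mask =)` pair.
#' @param selections List of [layer_selection()] objects (or id vectors).
#' @param n_trees Trees per candidate model (default 50).
#' @param subsample_fraction,seed Passed to [assemble_training_set()] and
#'   [train_classifier()]; one fixed seed is used for every candidate.
#' @param backend,weights Passed to [build_extractor()].
#' @param num_threads Threads for training/prediction.
#' @return A `layer_search_result` tibble, sorted by decreasing accuracy
#'   (ties: fewer features, then lexicographic layer ids), with columns
#'   `rank`, `layers`, `layer_ids` (list), `n_layers`, `n_features`,
#'   `accuracy_percent`, `iou`.
#' @export
layer_search <- function(train_pairs, validation_pair, selections,
                         n_trees = 50L, subsample_fraction = 0.02, seed = 1L,
                         backend = "filterbank", weights = NULL,
                         num_threads = 1L) {
  if (length(selections) == 0L) {
    abort("`selections` must contain at least one layer selection.",
          class = "rodseg_validation_error")
  }
  selections <- lapply(selections, function(s)
    if (inherits(s, "layer_selection")) s else layer_selection(s))
  union_sel <- layer_selection(sort(unique(unlist(lapply(selections, unclass)))))
  extractor <- build_extractor(union_sel, backend = backend, seed = seed,
                               weights = weights)
  # channel offsets of each layer inside the union stack
  ids <- unclass(union_sel)
  ends <- cumsum(vgg16_filter_counts[ids])
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  cols_for <- function(sel) {
    unlist(lapply(unclass(sel), function(l) {
      j <- match(l, ids)
      starts[j]:ends[j]
    }))
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  train_feats <- vector("list", length(train_pairs))
  train_labs <- vector("list", length(train_pairs))
  for (i in seq_along(train_pairs)) {
    st <- expand_features(train_pairs[[i]]$image, extractor)
    d <- dim(st$features)
    npx <- d[1L] * d[2L]
    idx <- if (subsample_fraction < 1) {
      sort(sample.int(npx, ceiling(subsample_fraction * npx)))
    } else seq_len(npx)
    train_feats[[i]] <- matrix(st$features, npx, d[3L])[idx, , drop = FALSE]
    train_labs[[i]] <- as.integer(validation_pair_mask(train_pairs[[i]]))[idx]
    rm(st)
  }
  vst <- expand_features(validation_pair$image, extractor)
  vd <- dim(vst$features)
  vmat <- matrix(vst$features, vd[1L] * vd[2L], vd[3L])
  vtruth <- as_mask(validation_pair$mask, "validation mask")
  rm(vst)

  xs <- do.call(rbind, train_feats)
  ys <- unlist(train_labs)
  rows <- vector("list", length(selections))
  for (si in seq_along(selections)) {
    sel <- selections[[si]]
    cc <- cols_for(sel)
    xsub <- xs[, cc, drop = FALSE]
    colnames(xsub) <- sprintf("f%04d", seq_along(cc))
    ts <- structure(list(features = xsub, labels = ys,
                         provenance = tibble(image = integer(0)),
                         selection = sel,
                         subsample_fraction = subsample_fraction,
                         seed = as.integer(seed)),
                    class = "training_set")
    clf <- train_classifier(ts, n_trees = n_trees, seed = seed,
                            num_threads = num_threads)
    vm <- vmat[, cc, drop = FALSE]
    colnames(vm) <- clf$feature_names
    pr <- stats::predict(clf$forest, data = vm, num.threads = num_threads,
                         verbose = FALSE)$predictions
    pmask <- matrix(as.integer(pr[, "rod"] >= 0.5), vd[1L], vd[2L])
    acc <- pixel_accuracy(pmask, vtruth)
    rows[[si]] <- tibble(
      layers = format(sel),
      layer_ids = list(unclass(sel)),
      n_layers = length(unclass(sel)),
      n_features = n_features(sel),
      accuracy_percent = acc$pixel_accuracy_percent,
      iou = acc$iou
    )
  }
  out <- dplyr::bind_rows(rows)
  lex <- vapply(out$layer_ids, function(v) paste(sprintf("%02d", v), collapse = ""),
                character(1))
  out <- out[order(-out$accuracy_percent, out$n_features, lex), ]
  out$rank <- seq_len(nrow(out))
  out <- out[, c("rank", "layers", "layer_ids", "n_layers", "n_features",
                 "accuracy_percent", "iou")]
  class(out) <- c("layer_search_result", class(out))
  attr(out, "n_trees") <- n_trees
  attr(out, "seed") <- seed
  out
}

validation_pair_mask <- function(pair) {
  assert_binary_mask(pair$mask, "mask")
}

#' k-fold cross-validation of the pixel classifier
#'
#' Partitions the training rows into `k` folds -- grouped by source image
#' when the training set spans at least `k` images, so no image leaks
#' between training and validation folds; otherwise pixel-level folds are
#' used with a warning -- and reports per-fold validation accuracy and the
#' mean.
#'
#' @param ts A [assemble_training_set()] result.
#' @param k Number of folds (default 5).
#' @param n_trees,seed,num_threads Passed to [train_classifier()].
#' @return A `crossval_result`: list with `folds` (tibble: fold, n_test,
#'   accuracy_percent) and `mean_accuracy_percent`.
#' @export
kfold_crossvalidate <- function(ts, k = 5L, n_trees = 150L, seed = 1L,
                                num_threads = 1L) {
  stopifnot(inherits(ts, "training_set"))
  if (k < 2L) {
    abort("`k` must be at least 2.", class = "rodseg_validation_error")
  }
  n <- nrow(ts$features)
  if (n < k) {
    abort("Training set too small for the requested number of folds.",
          class = "rodseg_validation_error")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  groups <- unique(ts$provenance$image)
  if (length(groups) >= k) {
    ga <- sample(rep_len(seq_len(k), length(groups)))
    fold <- ga[match(ts$provenance$image, groups)]
  } else {
    warn(sprintf(paste0("Only %d source image(s) for %d folds; falling back ",
                        "to pixel-level folds."), length(groups), k))
    fold <- sample(rep_len(seq_len(k), n))
  }
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold == f
    sub <- structure(list(features = ts$features[!test, , drop = FALSE],
                          labels = ts$labels[!test],
                          provenance = ts$provenance[!test, ],
                          selection = ts$selection,
                          subsample_fraction = ts$subsample_fraction,
                          seed = ts$seed),
                     class = "training_set")
    clf <- train_classifier(sub, n_trees = n_trees, seed = seed,
                            num_threads = num_threads)
    pr <- stats::predict(clf$forest, data = ts$features[test, , drop = FALSE],
                         num.threads = num_threads, verbose = FALSE)$predictions
    pred <- as.integer(pr[, "rod"] >= 0.5)
    rows[[f]] <- tibble(fold = f, n_test = sum(test),
                        accuracy_percent = 100 * mean(pred == ts$labels[test]))
  }
  folds <- dplyr::bind_rows(rows)
  structure(list(folds = folds,
                 mean_accuracy_percent = mean(folds$accuracy_percent),
                 k = as.integer(k), n_trees = as.integer(n_trees),
                 seed = as.integer(seed)),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("<crossval_result> %d-fold, mean accuracy %.2f%%\n",
              x$k, x$mean_accuracy_percent))
  print(x$folds)
  invisible(x)
}

#' Save or load a trained pixel classifier
#'
#' The artifact embeds the layer selection, seed, tree count and package
#' version; [predict_mask()] refuses stacks whose feature dimension does
#' not match the embedded contract.
#'
#' @param clf A [train_classifier()] result.
#' @param path Destination / source `.rds` path.
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   the restored `pixel_classifier`.
#' @export
save_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "pixel_classifier"))
  clf$package_version <- as.character(utils::packageVersion("rodseg"))
  saveRDS(clf, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  clf <- readRDS(path)
  if (!inherits(clf, "pixel_classifier") || is.null(clf$forest)) {
    abort("File does not contain a rodseg pixel classifier.",
          class = "rodseg_io_error")
  }
  clf
}
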