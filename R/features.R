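#' Filter counts of the VGG16 convolutional layers
#'
#' The 13 convolutional layers of the VGG16 architecture carry
#' 64, 64, 128, 128, 256, 256, 256, 512, 512, 512, 512, 512, 512 filters.
#' Only these layers can produce per-pixel feature maps once pooling and
#' activation layers are omitted, so they are the selectable pool; a
#' selection of all 13 yields 4224 features per pixel and the shallowest
#' single layer yields 64.
#'
#' @format Integer vector of length 13.
#' @export
vgg16_filter_counts <- c(64L, 64L, 128L, 128L, 256L, 256L, 256L,
                         512L, 512L, 512L, 512L, 512L, 512L)

#' Select convolutional layers for feature expansion
#'
#' @param layer_ids Integer subset of 1..13, the convolutional layers whose
#'   outputs become per-pixel features.
#' @return A `layer_selection`: sorted unique layer ids with an
#'   `n_features` attribute (sum of the selected layers' filter counts).
#' @examples
#' n_features(layer_selection(1))     # 64
#' n_features(layer_selection(1:13))  # 4224
#' @export
layer_selection <- function(layer_ids) {
  ids <- sort(unique(as.integer(layer_ids)))
  if (length(ids) == 0L || any(is.na(ids)) || any(ids < 1L) || any(ids > 13L)) {
    abort("`layer_ids` must be a non-empty subset of 1..13.",
          class = "rodseg_validation_error")
  }
  structure(ids, n_features = sum(vgg16_filter_counts[ids]),
            class = "layer_selection")
}

#' @rdname layer_selection
#' @param x A `layer_selection` (or coercible vector).
#' @export
n_features <- function(x) {
  if (!inherits(x, "layer_selection")) x <- layer_selection(x)
  attr(x, "n_features")
}

#' @export
print.layer_selection <- function(x, ...) {
  cat(sprintf("<layer_selection> layers {%s}: %d features/px\n",
              paste(unclass(x), collapse = ", "), attr(x, "n_features")))
  invisible(x)
}

#' @export
format.layer_selection <- function(x, ...) {
  paste(unclass(x), collapse = "+")
}

#' Build a frozen feature extractor
#'
#' Constructs the convolutional chain of the VGG16 architecture up to the
#' deepest selected layer, with all pooling and activation layers omitted
#' so every layer keeps full image resolution. The `"vgg16"` backend uses
#' pretrained kernel weights (and biases) supplied as an RDS file or list;
#' the `"filterbank"` backend substitutes fixed-seed Gaussian kernels of
#' identical shapes with zero biases, scaled to preserve variance through
#' the linear chain. The filter bank honours the same feature-count
#' contract but is not equivalent to the pretrained weights; it exists so
#' the pipeline runs and is testable with no weight download.
#'
#' @param selection A [layer_selection()] (or vector of layer ids).
#' @param backend `"filterbank"` (default) or `"vgg16"`.
#' @param seed Integer seed for the filter-bank kernels. Layer kernels are
#'   derived per layer from this seed, so two extractors with the same seed
#'   agree on every shared layer regardless of selection.
#' @param weights For `backend = "vgg16"`: path to an RDS file, or a list,
#'   holding one element per convolutional layer with fields `kernels`
#'   (3 x 3 x in x out array) and `bias` (length out).
#' @return A `feature_extractor`.
#' @export
build_extractor <- function(selection, backend = c("filterbank", "vgg16"),
                            seed = 1L, weights = NULL) {
  backend <- match.arg(backend)
  selection <- if (inherits(selection, "layer_selection")) selection else layer_selection(selection)
  max_layer <- max(unclass(selection))
  in_ch <- c(1L, vgg16_filter_counts)
  layers <- vector("list", max_layer)
  if (backend == "filterbank") {
    for (l in seq_len(max_layer)) {
      # per-layer derived seed: identical kernels across selections
      set.seed(seed * 101L + l)
      cin <- in_ch[l]; cout <- vgg16_filter_counts[l]
      layers[[l]] <- list(
        kernels = array(rnorm(9 * cin * cout, sd = 1 / sqrt(9 * cin)),
                        dim = c(3L, 3L, cin, cout)),
        bias = numeric(cout)
      )
    }
    backend_id <- sprintf("filterbank-seed%d", seed)
  } else {
    if (is.character(weights) && length(weights) == 1L) {
      if (!file.exists(weights)) {
        abort(paste0("Pretrained VGG16 weights unavailable at '", weights,
                     "'. Supply a weights file or use backend = \"filterbank\"."),
              class = "rodseg_weights_error")
      }
      weights <- readRDS(weights)
    }
    if (!is.list(weights) || length(weights) < max_layer) {
      abort(paste0("Pretrained VGG16 weights unavailable: supply `weights` ",
                   "covering the selected layers, or use backend = \"filterbank\"."),
            class = "rodseg_weights_error")
    }
    for (l in seq_len(max_layer)) {
      wl <- weights[[l]]
      kd <- dim(wl$kernels)
      if (is.null(kd) || length(kd) != 4L ||
          !all(kd == c(3L, 3L, in_ch[l], vgg16_filter_counts[l])) ||
          length(wl$bias) != vgg16_filter_counts[l]) {
        abort(sprintf("Weights for layer %d have the wrong shape.", l),
              class = "rodseg_weights_error")
      }
      layers[[l]] <- list(kernels = wl$kernels, bias = as.numeric(wl$bias))
    }
    backend_id <- "vgg16-pretrained"
  }
  structure(list(selection = selection, backend_id = backend_id,
                 layers = layers, max_layer = max_layer),
            class = "feature_extractor")
}

#' @export
print.feature_extractor <- function(x, ...) {
  cat(sprintf("<feature_extractor> %s, layers {%s}, %d features/px\n",
              x$backend_id, paste(unclass(x$selection), collapse = ", "),
              n_features(x$selection)))
  invisible(x)
}

#' Expand an image into per-pixel features
#'
#' Runs the image through the extractor's convolutional chain and stacks
#' the outputs of the selected layers into an H x W x n_features array.
#' With pooling and activations omitted, the spatial shape is preserved at
#' every layer and the map is linear in the input for zero-bias kernels.
#'
#' @param image An [sem_image()] or a numeric matrix.
#' @param extractor A [build_extractor()] result.
#' @return A `feature_stack`: list with `features` (H x W x n_features
#'   array), `selection`, and `backend_id`.
#' @export
expand_features <- function(image, extractor) {
  stopifnot(inherits(extractor, "feature_extractor"))
  px <- if (inherits(image, "sem_image")) image$pixels else image
  if (!is.matrix(px) || !all(is.finite(px))) {
    abort("Image pixels must be a finite numeric matrix.",
          class = "rodseg_validation_error")
  }
  H <- nrow(px); W <- ncol(px)
  sel <- unclass(extractor$selection)
  cur <- array(px, dim = c(H, W, 1L))
  outputs <- vector("list", length(sel))
  for (l in seq_len(extractor$max_layer)) {
    ly <- extractor$layers[[l]]
    cin <- dim(ly$kernels)[3L]; cout <- dim(ly$kernels)[4L]
    cur <- conv3x3_same(cur, ly$kernels, ly$bias, H, W, cin, cout)
    pos <- match(l, sel)
    if (!is.na(pos)) outputs[[pos]] <- cur
  }
  feats <- if (length(outputs) == 1L) outputs[[1L]] else {
    array(do.call(c, lapply(outputs, as.numeric)),
          dim = c(H, W, n_features(extractor$selection)))
  }
  structure(list(features = feats, selection = extractor$selection,
                 backend_id = extractor$backend_id),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  d <- dim(x$features)
  cat(sprintf("<feature_stack> %d x %d px, %d features (%s)\n",
              d[1L], d[2L], d[3L], x$backend_id))
  invisible(x)
}

#' @export
dim.feature_stack <- function(x) dim(x$features)

#' Enumerate layer selections for the brute-force search
#'
#' Lists all subsets of the layer pool of size up to `max_layers`, or a
#' seeded uniform sample of them, as used by the layer-combination search.
#'
#' @param max_layers Largest subset size, 1..length(pool).
#' @param sample_n If not `NULL`, return this many distinct selections
#'   sampled uniformly without replacement; if it exceeds the population,
#'   the full population is returned with a warning.
#' @param seed Seed for sampling.
#' @param pool Layer ids to draw from (default all 13).
#' @return A list of [layer_selection()] objects.
#' @export
enumerate_layer_selections <- function(max_layers, sample_n = NULL, seed = 1L,
                                       pool = 1:13) {
  pool <- sort(unique(as.integer(pool)))
  if (max_layers < 1L || max_layers > length(pool)) {
    abort("`max_layers` must be between 1 and the pool size.",
          class = "rodseg_validation_error")
  }
  all_sets <- unlist(
    lapply(seq_len(max_layers), function(k) {
      m <- utils::combn(pool, k)
      lapply(seq_len(ncol(m)), function(j) m[, j])
    }),
    recursive = FALSE
  )
  if (!is.null(sample_n)) {
    if (sample_n > length(all_sets)) {
      warn(sprintf(paste0("Requested %d selections but only %d exist; ",
                          "returning the full population."),
                   sample_n, length(all_sets)))
    } else {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
      all_sets <- all_sets[sample.int(length(all_sets), sample_n)]
    }
  }
  lapply(all_sets, layer_selection)
}
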