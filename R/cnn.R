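#' Slice-classifier model specification
#'
#' Two backbones share one interface. `"vgg16_imagenet"` is the
#' transfer-learning configuration: a frozen ImageNet-pretrained VGG-16
#' convolutional stack whose pooled 512-dimensional features feed a
#' retrained head (fully connected layer of 256 units plus a two-way
#' softmax). `"compact_scratch"` is a small three-block convolutional
#' network (3x3 convs of 8, 16 and 32 channels, each followed by ReLU and
#' 2x2 max pooling, then global average pooling) trained end to end; it
#' needs no pretrained weights and trains on a CPU in minutes.
#'
#' @param backbone `"compact_scratch"` or `"vgg16_imagenet"`.
#' @param input_size `c(height, width)` the slice is resized to;
#'   defaults: 48 for the compact net (fine enough that slice-periodic
#'   banding of period 3-5 survives resampling), 224 for VGG-16.
#' @param channels input channels (the single MR channel is replicated).
#' @param hidden width of the fully connected head (default 256).
#' @param conv_channels channel widths of the compact backbone's blocks.
#' @param weights_path optional path to pretrained VGG-16 weights.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(backbone = c("compact_scratch", "vgg16_imagenet"),
                       input_size = NULL, channels = NULL, hidden = 256L,
                       conv_channels = c(8L, 16L, 32L),
                       weights_path = NULL) {
  backbone <- match.arg(backbone)
  if (is.null(input_size))
    input_size <- if (backbone == "vgg16_imagenet") c(224L, 224L)
                  else c(48L, 48L)
  if (is.null(channels))
    channels <- if (backbone == "vgg16_imagenet") 3L else 1L
  pooled_dim <- if (backbone == "vgg16_imagenet") 512L
                else conv_channels[length(conv_channels)]
  structure(list(backbone = backbone,
                 input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 hidden = as.integer(hidden),
                 conv_channels = as.integer(conv_channels),
                 pooled_dim = as.integer(pooled_dim),
                 weights_path = weights_path),
            class = "model_spec")
}

#' Trainable-parameter count of the classification head
#'
#' `pooled_dim * hidden + hidden` weights and biases for the fully
#' connected layer plus `hidden * 2 + 2` for the softmax layer. For the
#' frozen-backbone configuration this is the model's entire trainable
#' parameter count.
#'
#' @param spec a [model_spec()].
#' @return integer parameter count.
#' @export
head_parameter_count <- function(spec) {
  spec$pooled_dim * spec$hidden + spec$hidden + spec$hidden * 2L + 2L
}

#' Training configuration
#'
#' Defaults follow the transfer-learning recipe: 20 epochs of RMSprop at
#' learning rate 2e-4 with a cross-entropy loss. Class imbalance is
#' handled with inverse-frequency class weights in the loss by default.
#'
#' @param epochs number of epochs (>= 1).
#' @param learning_rate RMSprop learning rate (> 0).
#' @param batch_size minibatch size.
#' @param class_weighting `"inverse"` (inverse-frequency weights) or
#'   `"none"`.
#' @param rho,epsilon RMSprop decay and stabiliser.
#' @param seed integer seed controlling initialisation order, shuffling
#'   and dropout; fixed seed means bit-identical training runs.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 20L, learning_rate = 2e-4,
                         batch_size = 32L,
                         class_weighting = c("inverse", "none"),
                         rho = 0.9, epsilon = 1e-7, seed = 1L) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning rate must be > 0")
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 class_weighting = match.arg(class_weighting),
                 rho = rho, epsilon = epsilon, seed = as.integer(seed)),
            class = "train_config")
}

compact_layers <- function(spec) {
  cc <- spec$conv_channels
  layers <- list()
  c_in <- spec$channels
  for (c_out in cc) {
    layers <- c(layers, list(nn_conv3(c_in, c_out), nn_relu(),
                             nn_maxpool2()))
    c_in <- c_out
  }
  c(layers, list(nn_gap(), nn_dense(spec$pooled_dim, spec$hidden),
                 nn_relu(), nn_dense(spec$hidden, 2L)))
}

#' Build an untrained detector model
#'
#' For the compact backbone, all layers are initialised (He scheme) from
#' `seed` and trainable. For `vgg16_imagenet`, pretrained ImageNet weights
#' must be locatable via `spec$weights_path`; without them an error directs
#' to the compact backbone, which trains from scratch with no downloads.
#'
#' @param spec a [model_spec()].
#' @param view `"axial"` or `"sagittal"`: which detector this model is.
#' @param seed integer initialisation seed.
#' @return object of class `detector_model`.
#' @export
build_model <- function(spec, view = c("axial", "sagittal"), seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  view <- match.arg(view)
  if (spec$backbone == "vgg16_imagenet") {
    if (is.null(spec$weights_path) || !file.exists(spec$weights_path))
      stop("pretrained ImageNet weights for the VGG-16 backbone were not ",
           "found (set `weights_path` in model_spec()). For a network ",
           "that trains from scratch without pretrained weights, use ",
           "model_spec(backbone = 'compact_scratch').")
    stop("loading external VGG-16 weight files is not implemented in ",
         "this build; use model_spec(backbone = 'compact_scratch')")
  }
  layers <- with_seed(seed, compact_layers(spec))
  structure(list(view = view, spec = spec, layers = layers,
                 trained = FALSE, loss_trace = NULL, manifest = NULL),
            class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat("<detector_model> ", x$view, " view, backbone ", x$spec$backbone,
      if (x$trained) " (trained)" else " (untrained)", "\n", sep = "")
  invisible(x)
}

#' Prepare a slice for the model
#'
#' The (normalized) slice is padded to a square with zeros (the mean value
#' after normalization), resized to the spec's input size with bilinear
#' interpolation — padding first preserves the aspect ratio, so artifact
#' patterns are not anisotropically distorted — and the single MR channel
#' is replicated across the channel dimension.
#'
#' @param s a [slice_sample()] (normalize with [normalize_slice()] first).
#' @param spec a [model_spec()].
#' @return array `[H, W, channels]`.
#' @export
preprocess_for_model <- function(s, spec) {
  img <- s$image
  h <- nrow(img); w <- ncol(img)
  n <- max(h, w)
  if (h != w) {
    sq <- matrix(0, n, n)
    x0 <- (n - h) %/% 2; y0 <- (n - w) %/% 2
    sq[x0 + seq_len(h), y0 + seq_len(w)] <- img
    img <- sq
  }
  img <- bilinear_resize(img, spec$input_size[1], spec$input_size[2])
  array(rep(img, spec$channels),
        c(spec$input_size[1], spec$input_size[2], spec$channels))
}

stack_inputs <- function(slices, spec) {
  n <- length(slices)
  x <- array(0, c(n, spec$input_size[1], spec$input_size[2],
                  spec$channels))
  for (i in seq_len(n))
    x[i, , , ] <- preprocess_for_model(slices[[i]], spec)
  x
}

slice_classes <- function(slices) {
  labs <- vapply(slices, function(s) {
    if (is.null(s$label)) stop("all training slices must carry a label")
    s$label
  }, "")
  # class 1 = artifact_free, class 2 = artifactual
  ifelse(labs == "artifactual", 2L, 1L)
}

#' Train a slice detector
#'
#' Trains the model on labeled slices of its view with RMSprop and a
#' (class-weighted) cross-entropy loss. Slices are normalized and resized
#' internally; optional augmentation expands the training set before
#' preprocessing. Training is deterministic given `cfg$seed`.
#'
#' @param model an untrained or trained [build_model()] result.
#' @param samples list of labeled [slice_sample()], all of `model$view`.
#' @param cfg a [train_config()].
#' @param augment optional [augment_config()]; when given, the set is
#'   expanded with [build_augmented_set()] (`multiplier` below).
#' @param multiplier augmentation multiplier when `augment` is given.
#' @return the trained `detector_model`, with `loss_trace` filled.
#' @export
train_detector <- function(model, samples, cfg = train_config(),
                           augment = NULL, multiplier = 2L) {
  stopifnot(inherits(model, "detector_model"),
            inherits(cfg, "train_config"))
  views <- unique(vapply(samples, `[[`, "", "view"))
  if (length(views) != 1 || views != model$view)
    stop("training samples must all be of the model's view (",
         model$view, ")")
  y <- slice_classes(samples)
  if (length(unique(y)) < 2)
    stop("training data must contain both classes")
  if (!is.null(augment))
    samples <- build_augmented_set(samples, augment, multiplier,
                                   seed = cfg$seed)
  samples <- lapply(samples, normalize_slice)
  y <- slice_classes(samples)
  x <- stack_inputs(samples, model$spec)
  cw <- if (cfg$class_weighting == "inverse") {
    tab <- tabulate(y, 2L)
    length(y) / (2 * pmax(tab, 1L))
  } else c(1, 1)
  fit <- nn_train(model$layers, x, y, epochs = cfg$epochs,
                  lr = cfg$learning_rate, batch_size = cfg$batch_size,
                  class_weights = cw, seed = cfg$seed, rho = cfg$rho,
                  eps = cfg$epsilon)
  model$layers <- fit$layers
  model$loss_trace <- fit$loss_trace
  model$trained <- TRUE
  model$manifest <- list(n_samples = length(samples),
                         class_counts = tabulate(y, 2L),
                         config = unclass(cfg))
  model
}

#' Predict artifact probabilities for slices
#'
#' Returns, per slice and in input order, the probability of the
#' artifactual class and the binary label at threshold 0.5. A probability
#' of exactly 0.5 is labeled artifactual: in QC a false positive (an extra
#' slice for the analyst to glance at) is preferable to a missed artifact.
#'
#' @param model a trained [detector_model].
#' @param slices list of [slice_sample()] of the model's view.
#' @return data.frame with columns `volume_id, view, gradient_index,
#'   slice_index, probability, label`.
#' @export
predict_slices <- function(model, slices) {
  stopifnot(inherits(model, "detector_model"))
  views <- unique(vapply(slices, `[[`, "", "view"))
  if (length(views) != 1 || views != model$view)
    stop("slices must all be of the model's view (", model$view, ")")
  slices <- lapply(slices, normalize_slice)
  x <- stack_inputs(slices, model$spec)
  p <- nn_predict_probs(model$layers, x)[, 2]
  data.frame(
    volume_id = vapply(slices, `[[`, "", "volume_id"),
    view = model$view,
    gradient_index = vapply(slices, `[[`, 1L, "gradient_index"),
    slice_index = vapply(slices, `[[`, 1L, "slice_index"),
    probability = p,
    label = ifelse(p >= 0.5, "artifactual", "artifact_free"),
    stringsAsFactors = FALSE
  )
}

#' Extract pooled convolutional features
#'
#' Runs slices through the convolutional backbone up to and including
#' global average pooling and returns the pooled feature vectors (the
#' input to the classification head). These are the features consumed by
#' the PCA + SVM comparison pipeline.
#'
#' @param model a [detector_model].
#' @param slices list of [slice_sample()].
#' @return numeric matrix `[n_slices, pooled_dim]`.
#' @export
extract_features <- function(model, slices) {
  stopifnot(inherits(model, "detector_model"))
  slices <- lapply(slices, normalize_slice)
  x <- stack_inputs(slices, model$spec)
  gap_at <- which(vapply(model$layers, `[[`, "", "type") == "gap")
  for (i in seq_len(gap_at))
    x <- layer_forward(model$layers[[i]], x, training = FALSE)$y
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}

#' k-fold cross-validation of a slice detector
#'
#' Samples are shuffled and partitioned into `k` folds whose sizes differ
#' by at most one; each fold serves once as the test set while a fresh
#' model is trained on the rest. Augmentation, when configured, is applied
#' to training folds only. By default folds are drawn at the slice level
#' (slices of one volume can land in train and test folds — reports flag
#' this as permitting subject leakage); `by_volume = TRUE` partitions
#' volumes instead.
#'
#' @param samples labeled slices of one view.
#' @param k number of folds (>= 2).
#' @param spec a [model_spec()].
#' @param cfg a [train_config()].
#' @param augment optional [augment_config()] for training folds.
#' @param multiplier augmentation multiplier.
#' @param seed seed for the fold shuffle.
#' @param by_volume partition volumes rather than slices.
#' @return list with `fold_confusions` (list of [confusion_counts()]),
#'   `fold_metrics`, `pooled_confusion`, `pooled_metrics`, `assignments`
#'   (fold id per sample), and `leakage_note`.
#' @export
cross_validate <- function(samples, k = 5L, spec = model_spec(),
                           cfg = train_config(), augment = NULL,
                           multiplier = 2L, seed = 1L,
                           by_volume = FALSE) {
  n <- length(samples)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("fewer samples than folds")
  view <- samples[[1]]$view
  assignments <- integer(n)
  if (by_volume) {
    vols <- vapply(samples, `[[`, "", "volume_id")
    uv <- unique(vols)
    if (length(uv) < k) stop("fewer volumes than folds")
    vfold <- with_seed(seed, fold_sizes_assign(length(uv), k))
    assignments <- vfold[match(vols, uv)]
  } else {
    assignments <- with_seed(seed, fold_sizes_assign(n, k))
  }
  fold_conf <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(assignments == f)
    train_idx <- setdiff(seq_len(n), test_idx)
    model <- build_model(spec, view = view, seed = seed + f)
    cfg_f <- cfg; cfg_f$seed <- cfg$seed + f
    model <- train_detector(model, samples[train_idx], cfg_f,
                            augment = augment, multiplier = multiplier)
    pred <- predict_slices(model, samples[test_idx])
    truth <- vapply(samples[test_idx], `[[`, "", "label")
    fold_conf[[f]] <- confusion_from_labels(truth, pred$label)
  }
  pooled <- Reduce(add_confusion, fold_conf)
  list(
    fold_confusions = fold_conf,
    fold_metrics = lapply(fold_conf, compute_metrics),
    pooled_confusion = pooled,
    pooled_metrics = compute_metrics(pooled),
    assignments = assignments,
    leakage_note = if (by_volume) "volume-level folds"
      else paste("slice-level folds: slices of one volume may appear in",
                 "both train and test folds (subject leakage possible)")
  )
}

# shuffled fold ids with sizes differing by <= 1
fold_sizes_assign <- function(n, k) {
  base <- n %/% k; extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  sample(rep(seq_len(k), times = sizes))
}

#' Save / load a trained detector
#'
#' The serialized object embeds the model spec, training config and loss
#' trace alongside the parameters, so a checkpoint is self-describing.
#'
#' @param model a `detector_model`.
#' @param path file path (`.rds`).
#' @return `path` (save) or the `detector_model` (load).
#' @export
save_detector <- function(model, path) {
  stopifnot(inherits(model, "detector_model"))
  saveRDS(list(format = "dmriqc_detector_v1", model = model), path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "dmriqc_detector_v1"))
    stop("'", path, "' is not a dmriqc detector checkpoint")
  obj$model
}
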