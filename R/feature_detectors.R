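# Comparison detectors over texture/CNN features. All detectors share one
# predict contract — predict(detector, features) returns a data.frame with
# `probability` (of the artifactual class) and `label` at threshold 0.5 —
# so the reporting module can consume any of them interchangeably.

as_label_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("artifactual", "artifact_free"))
  if (length(bad))
    stop("unknown labels: ", paste(bad, collapse = ", "))
  factor(labels, levels = c("artifact_free", "artifactual"))
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2)
    stop("training data must contain both classes")
}

#' Train a feature-based artifact detector
#'
#' Fits a random forest (100 trees) or an RBF-kernel SVM on a feature
#' matrix with binary QC labels. Deterministic given `seed`.
#'
#' @param features numeric matrix, one row per slice.
#' @param labels character vector of `"artifactual"` / `"artifact_free"`.
#' @param kind `"random_forest"` (default) or `"svm"`.
#' @param seed integer seed.
#' @param ntree number of random-forest trees.
#' @return object of class `feature_detector`.
#' @export
train_feature_detector <- function(features, labels,
                                   kind = c("random_forest", "svm"),
                                   seed = 1L, ntree = 100L) {
  kind <- match.arg(kind)
  features <- as.matrix(features)
  y <- as_label_factor(labels)
  check_two_classes(y)
  fit <- with_seed(seed, switch(kind,
    random_forest = randomForest::randomForest(features, y,
                                               ntree = ntree),
    svm = e1071::svm(features, y, kernel = "radial",
                     probability = TRUE)
  ))
  structure(list(kind = kind, fit = fit, seed = seed,
                 n_features = ncol(features)),
            class = "feature_detector")
}

#' @export
predict.feature_detector <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  p <- switch(object$kind,
    random_forest =
      predict(object$fit, newdata, type = "prob")[, "artifactual"],
    svm = {
      pr <- predict(object$fit, newdata, probability = TRUE)
      attr(pr, "probabilities")[, "artifactual"]
    }
  )
  data.frame(probability = unname(p),
             label = ifelse(p >= 0.5, "artifactual", "artifact_free"),
             stringsAsFactors = FALSE)
}

#' Gabor features into a fully connected network
#'
#' Feeds feature vectors into a single 256-unit fully connected layer with
#' ReLU, dropout, and a two-way softmax, trained with the same RMSprop /
#' cross-entropy recipe as the slice classifiers. Features are
#' standardised with training-set statistics.
#'
#' @param features numeric matrix (typically Gabor features).
#' @param labels binary QC labels.
#' @param hidden hidden-layer width (default 256).
#' @param dropout dropout rate on the hidden layer (default 0.5).
#' @param cfg a [train_config()]; the default from-scratch rate 1e-3 is
#'   used unless overridden.
#' @param seed integer seed (overrides `cfg$seed`).
#' @return object of class `fc_detector`.
#' @export
gabor_fc_detector <- function(features, labels, hidden = 256L,
                              dropout = 0.5,
                              cfg = train_config(learning_rate = 1e-3),
                              seed = 1L) {
  features <- as.matrix(features)
  y <- as_label_factor(labels)
  check_two_classes(y)
  yi <- as.integer(y)
  mu <- colMeans(features)
  sdv <- apply(features, 2, sd_pop)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(features, 2, mu), 2, sdv, `/`)
  layers <- with_seed(seed, list(
    nn_dense(ncol(features), hidden), nn_relu(), nn_dropout(dropout),
    nn_dense(hidden, 2L)
  ))
  cw <- {
    tab <- tabulate(yi, 2L)
    length(yi) / (2 * pmax(tab, 1L))
  }
  fit <- nn_train(layers, xs, yi, epochs = cfg$epochs,
                  lr = cfg$learning_rate, batch_size = cfg$batch_size,
                  class_weights = cw, seed = seed, rho = cfg$rho,
                  eps = cfg$epsilon)
  structure(list(layers = fit$layers, mu = mu, sd = sdv,
                 loss_trace = fit$loss_trace, hidden = hidden,
                 dropout = dropout, seed = seed),
            class = "fc_detector")
}

#' @export
predict.fc_detector <- function(object, newdata, ...) {
  xs <- sweep(sweep(as.matrix(newdata), 2, object$mu), 2, object$sd, `/`)
  p <- nn_predict_probs(object$layers, xs)[, 2]
  data.frame(probability = unname(p),
             label = ifelse(p >= 0.5, "artifactual", "artifact_free"),
             stringsAsFactors = FALSE)
}

#' CNN features into PCA and an SVM
#'
#' Principal components are fitted on the training features only, keeping
#' the smallest number of components whose cumulative explained variance
#' reaches `variance` (default 0.98); an RBF SVM is fitted on the
#' projected features. Prediction projects new data with the training
#' means and axes — the PCA is never refitted.
#'
#' @param features numeric matrix of pooled CNN features (see
#'   [extract_features()]).
#' @param labels binary QC labels.
#' @param variance retained-variance fraction in (0, 1].
#' @param seed integer seed.
#' @return object of class `pca_svm_detector` with `k` retained
#'   components and `explained` cumulative variance.
#' @export
cnn_pca_svm <- function(features, labels, variance = 0.98, seed = 1L) {
  if (variance <= 0 || variance > 1)
    stop("retained-variance fraction must lie in (0, 1]")
  features <- as.matrix(features)
  y <- as_label_factor(labels)
  check_two_classes(y)
  pc <- prcomp(features, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cum >= variance)[1]
  proj <- pc$x[, seq_len(k), drop = FALSE]
  fit <- with_seed(seed, e1071::svm(proj, y, kernel = "radial",
                                    probability = TRUE))
  structure(list(fit = fit, center = pc$center,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 k = k, explained = cum[k], seed = seed),
            class = "pca_svm_detector")
}

#' Project features with a fitted PCA + SVM detector
#' @param object a `pca_svm_detector`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return data.frame with `probability` and `label`.
#' @export
predict.pca_svm_detector <- function(object, newdata, ...) {
  proj <- sweep(as.matrix(newdata), 2, object$center) %*% object$rotation
  pr <- predict(object$fit, proj, probability = TRUE)
  p <- attr(pr, "probabilities")[, "artifactual"]
  data.frame(probability = unname(p),
             label = ifelse(p >= 0.5, "artifactual", "artifact_free"),
             stringsAsFactors = FALSE)
}

#' k-fold cross-validation of a feature detector
#'
#' Same fold construction as [cross_validate()] (shuffled folds whose
#' sizes differ by at most one) applied to a feature matrix.
#'
#' @param features numeric matrix.
#' @param labels binary QC labels.
#' @param kind classifier kind passed to [train_feature_detector()].
#' @param k number of folds.
#' @param seed fold-shuffle and training seed.
#' @return list with `pooled_confusion`, `pooled_metrics`,
#'   `fold_confusions`.
#' @export
cv_feature_detector <- function(features, labels, kind = "random_forest",
                                k = 5L, seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < k) stop("fewer samples than folds")
  assignments <- with_seed(seed, fold_sizes_assign(n, k))
  fold_conf <- vector("list", k)
  for (f in seq_len(k)) {
    te <- assignments == f
    det <- train_feature_detector(features[!te, , drop = FALSE],
                                  labels[!te], kind = kind,
                                  seed = seed + f)
    pred <- predict(det, features[te, , drop = FALSE])
    fold_conf[[f]] <- confusion_from_labels(labels[te], pred$label)
  }
  pooled <- Reduce(add_confusion, fold_conf)
  list(fold_confusions = fold_conf, pooled_confusion = pooled,
       pooled_metrics = compute_metrics(pooled))
}
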