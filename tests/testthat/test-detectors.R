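make_separable <- function(n = 60, seed = 1) {
  set.seed(seed)
  f <- rbind(matrix(rnorm(2 * n), n, 2), matrix(rnorm(2 * n) + 5, n, 2))
  colnames(f) <- c("f1", "f2")
  list(features = f,
       labels = rep(c("artifact_free", "artifactual"), each = n))
}

test_that("feature detectors separate separable clusters and are seeded", {
  d <- make_separable()
  for (kind in c("random_forest", "svm")) {
    det <- train_feature_detector(d$features, d$labels, kind, seed = 3)
    pred <- predict(det, d$features)
    expect_identical(mean(pred$label == d$labels), 1)
    det2 <- train_feature_detector(d$features, d$labels, kind, seed = 3)
    expect_identical(predict(det2, d$features)$probability,
                     pred$probability)
    expect_true(all(c("probability", "label") %in% names(pred)))
    expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  }
  expect_error(train_feature_detector(d$features,
                                      rep("artifactual", 120)),
               "both classes")
})

test_that("the Gabor fully connected detector trains and normalises", {
  d <- make_separable(80, seed = 2)
  det <- gabor_fc_detector(d$features, d$labels,
                           cfg = train_config(epochs = 30,
                                              learning_rate = 1e-2),
                           seed = 4)
  pred <- predict(det, d$features)
  expect_true(all(abs((pred$probability +
                         (1 - pred$probability)) - 1) < 1e-6))
  expect_gte(mean(pred$label == d$labels), 0.95)
  det2 <- gabor_fc_detector(d$features, d$labels,
                            cfg = train_config(epochs = 30,
                                               learning_rate = 1e-2),
                            seed = 4)
  expect_identical(det$layers, det2$layers)
  expect_lt(det$loss_trace[30], det$loss_trace[1])
})

test_that("softmax probabilities of the shared engine sum to one", {
  d <- make_separable(20, seed = 5)
  det <- gabor_fc_detector(d$features, d$labels,
                           cfg = train_config(epochs = 2,
                                              learning_rate = 1e-3),
                           seed = 1)
  xs <- sweep(sweep(d$features, 2, det$mu), 2, det$sd, `/`)
  p <- dmriqc:::nn_predict_probs(det$layers, xs)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
})

test_that("PCA retains the smallest component set reaching 98%", {
  set.seed(6)
  # constructed spectrum: two dominant directions carry >= 98% variance
  z <- cbind(rnorm(300, sd = 10), rnorm(300, sd = 6),
             matrix(rnorm(300 * 8, sd = 0.05), 300, 8))
  labels <- rep(c("artifact_free", "artifactual"), 150)
  det <- cnn_pca_svm(z, labels, variance = 0.98, seed = 2)
  expect_identical(det$k, 2L)
  expect_gte(det$explained, 0.98)
  # one fewer component falls short of the target (definition check)
  pc <- prcomp(z, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  expect_lt(cum[det$k - 1], 0.98)
})

test_that("PCA projection of new data reuses training axes", {
  d <- make_separable(50, seed = 7)
  f <- cbind(d$features, matrix(rnorm(100 * 6, sd = 0.01), 100, 6))
  det <- cnn_pca_svm(f, d$labels, seed = 3)
  newdata <- f + 10  # shifted test data must be centred by TRAIN means
  proj_manual <- sweep(newdata, 2, det$center) %*% det$rotation
  pr <- predict(det$fit, proj_manual, probability = TRUE)
  p_manual <- attr(pr, "probabilities")[, "artifactual"]
  expect_equal(predict(det, newdata)$probability, unname(p_manual))
})

test_that("feature-level cross-validation pools fold confusions", {
  d <- make_separable(52, seed = 8)  # 104 samples
  cv <- cv_feature_detector(d$features, d$labels, "random_forest",
                            k = 5, seed = 2)
  expect_length(cv$fold_confusions, 5L)
  total <- cv$pooled_confusion
  expect_identical(total$tp + total$fp + total$tn + total$fn, 104L)
  summed <- Reduce(dmriqc:::add_confusion, cv$fold_confusions)
  expect_identical(unclass(total), unclass(summed))
  expect_gte(cv$pooled_metrics$accuracy, 0.95)
})
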