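test_that("the transfer head has the declared parameter count", {
  spec <- model_spec("vgg16_imagenet")
  expect_identical(spec$pooled_dim, 512L)
  expect_identical(head_parameter_count(spec),
                   512L * 256L + 256L + 256L * 2L + 2L)
  expect_identical(head_parameter_count(spec), 131842L)
})

test_that("missing pretrained weights give an actionable error", {
  expect_error(build_model(model_spec("vgg16_imagenet"), "axial"),
               "compact_scratch")
  expect_error(
    build_model(model_spec("vgg16_imagenet",
                           weights_path = "/nonexistent/vgg16.rds"),
                "axial"),
    "compact_scratch")
})

test_that("model building is seed-reproducible with normalized outputs", {
  spec <- model_spec("compact_scratch")
  m1 <- build_model(spec, "axial", seed = 5)
  m2 <- build_model(spec, "axial", seed = 5)
  m3 <- build_model(spec, "axial", seed = 6)
  expect_identical(m1$layers, m2$layers)
  expect_false(identical(m1$layers, m3$layers))

  slices <- toy_ghost_slices(3, seed = 1, size = 40L)
  x <- dmriqc:::stack_inputs(lapply(slices, normalize_slice), spec)
  p <- dmriqc:::nn_predict_probs(m1$layers, x)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("preprocessing pads to square, resizes, replicates channels", {
  spec <- model_spec("compact_scratch", input_size = c(48L, 48L),
                     channels = 3L)
  s <- slice_sample(matrix(rnorm(64 * 80), 64, 80), "axial")
  x <- preprocess_for_model(s, spec)
  expect_identical(dim(x), c(48L, 48L, 3L))
  expect_identical(x[, , 1], x[, , 2])
  expect_identical(x[, , 1], x[, , 3])

  const <- preprocess_for_model(slice_sample(matrix(2, 60, 60), "axial"),
                                model_spec("compact_scratch"))
  expect_true(all(abs(const - 2) < 1e-12))

  # padding preserves aspect: the brain occupies the middle rows
  tall <- slice_sample(matrix(1, 20, 60), "axial")
  xt <- preprocess_for_model(tall, model_spec("compact_scratch"))
  expect_true(all(xt[1:8, , 1] == 0))    # padded band
  expect_true(any(xt[20:28, , 1] != 0))  # content band
})

test_that("training reduces the loss, is deterministic, validates input", {
  slices <- toy_ghost_slices(60, seed = 3, size = 40L)
  spec <- model_spec("compact_scratch")
  cfg <- train_config(epochs = 3, learning_rate = 1e-3, seed = 2)
  m <- train_detector(build_model(spec, "axial", seed = 1), slices, cfg)
  expect_lt(m$loss_trace[3], m$loss_trace[1])
  expect_true(m$trained)

  m2 <- train_detector(build_model(spec, "axial", seed = 1), slices, cfg)
  expect_identical(m$layers, m2$layers)

  expect_error(train_config(epochs = 0), ">= 1")
  mixed <- slices
  mixed[[1]]$view <- "sagittal"
  expect_error(train_detector(build_model(spec, "axial"), mixed, cfg),
               "view")
  one_class <- lapply(slices, function(s) { s$label <- "artifactual"; s })
  expect_error(train_detector(build_model(spec, "axial"), one_class, cfg),
               "both classes")
})

test_that("prediction keeps order, duplicates agree, ties are flagged", {
  slices <- toy_ghost_slices(40, seed = 4, size = 40L)
  spec <- model_spec("compact_scratch")
  m <- train_detector(build_model(spec, "axial", seed = 2), slices,
                      train_config(epochs = 3, learning_rate = 1e-3,
                                   seed = 3))
  test <- toy_ghost_slices(10, seed = 5, size = 40L)
  pred <- predict_slices(m, test)
  expect_identical(nrow(pred), 20L)
  expect_identical(pred$slice_index,
                   vapply(test, `[[`, 1L, "slice_index"))
  dup <- predict_slices(m, list(test[[1]], test[[1]]))
  expect_identical(dup$probability[1], dup$probability[2])
  expect_error(predict_slices(m, lapply(test, function(s) {
    s$view <- "sagittal"; s
  })), "view")

  # a 0.5 probability must flag: zero the head so logits tie exactly
  tied <- m
  last <- length(tied$layers)
  tied$layers[[last]]$W[] <- 0
  tied$layers[[last]]$b[] <- 0
  pt <- predict_slices(tied, test[1:2])
  expect_identical(pt$probability, c(0.5, 0.5))
  expect_identical(pt$label, c("artifactual", "artifactual"))
})

test_that("pooled features are deterministic and linearly separable", {
  slices <- toy_ghost_slices(50, seed = 6, size = 40L)
  spec <- model_spec("compact_scratch")
  m <- train_detector(build_model(spec, "axial", seed = 3), slices,
                      train_config(epochs = 4, learning_rate = 1e-3,
                                   seed = 4))
  f1 <- extract_features(m, slices)
  f2 <- extract_features(m, slices)
  expect_identical(f1, f2)
  expect_identical(ncol(f1), spec$pooled_dim)

  probe <- train_feature_detector(f1, vapply(slices, `[[`, "", "label"),
                                  "svm", seed = 1)
  acc <- mean(predict(probe, f1)$label ==
                vapply(slices, `[[`, "", "label"))
  expect_gte(acc, 0.95)
})

test_that("cross-validation partitions correctly and pools confusions", {
  slices <- toy_ghost_slices(52, seed = 7, size = 32L)[1:103]
  cv <- cross_validate(slices, k = 5,
                       spec = model_spec("compact_scratch",
                                         input_size = c(32L, 32L)),
                       cfg = train_config(epochs = 1,
                                          learning_rate = 1e-3),
                       seed = 11)
  sizes <- sort(as.integer(table(cv$assignments)), decreasing = TRUE)
  expect_identical(sizes, c(21L, 21L, 21L, 20L, 20L))
  expect_identical(sort(unique(cv$assignments)), 1:5)
  total <- cv$pooled_confusion
  expect_identical(total$tp + total$fp + total$tn + total$fn, 103L)
  expect_identical(unclass(total),
                   unclass(Reduce(dmriqc:::add_confusion,
                                  cv$fold_confusions)))
  expect_match(cv$leakage_note, "leakage")
  expect_error(cross_validate(slices[1:3], k = 5), "fewer samples")
})

test_that("detector checkpoints round-trip through disk", {
  slices <- toy_ghost_slices(20, seed = 8, size = 32L)
  m <- train_detector(
    build_model(model_spec("compact_scratch", input_size = c(32L, 32L)),
                "axial", seed = 1),
    slices, train_config(epochs = 1, learning_rate = 1e-3))
  f <- withr::local_tempfile(fileext = ".rds")
  save_detector(m, f)
  back <- load_detector(f)
  expect_identical(back$layers, m$layers)
  expect_identical(predict_slices(back, slices[1:3]),
                   predict_slices(m, slices[1:3]))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_detector(bad), "checkpoint")
})
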