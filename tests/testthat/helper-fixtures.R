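# Fixtures are generated in code: small phantoms, toy ghost/clean slice
# sets, and hand-built brain extents for rule checks.

tiny_phantom <- function(dims = c(48L, 48L, 32L), noise_sigma = 0.02,
                         gradients = c(1, 0.6), seed = 1L)
  phantom_spec(dims = dims, noise_sigma = noise_sigma,
               gradient_attenuation = gradients, seed = seed)

# slice set with a synthetic half-FOV ghost as the artifact class
toy_ghost_slices <- function(n_per_class, seed = 1L, view = "axial",
                             size = 48L, alpha = 0.35) {
  set.seed(seed)
  mk <- function(i, ghost) {
    img <- matrix(0, size, size)
    core <- (size %/% 4):(3 * size %/% 4)
    img[core, core] <- 1 + 0.05 * rnorm(1)
    img <- abs(img + matrix(rnorm(size^2, 0, 0.05), size, size))
    if (ghost) {
      half <- size %/% 2
      img <- img + alpha * img[, c((half + 1):size, 1:half)]
    }
    slice_sample(img, view, volume_id = sprintf("v%02d", (i - 1) %/% 10),
                 gradient_index = 1L, slice_index = i,
                 label = if (ghost) "artifactual" else "artifact_free")
  }
  c(lapply(seq_len(n_per_class), mk, ghost = FALSE),
    lapply(seq_len(n_per_class) + n_per_class, mk, ghost = TRUE))
}

make_extent <- function(lr, ap, is, dims = c(64L, 64L, 64L)) {
  structure(list(`L-R` = as.integer(lr), `A-P` = as.integer(ap),
                 `I-S` = as.integer(is)),
            dims = dims, axis_labels = c("L-R", "A-P", "I-S"),
            class = "brain_extent")
}

constant_volume <- function(dims = c(64L, 64L, 64L), value = 1,
                            n_grad = 1L)
  dwi_volume(array(value, c(dims, n_grad)), affine = diag(c(2, 2, 2, 1)))

# rotation about the image centre with the package's resampler; used as a
# transform generator for invariance checks
rotate_image <- function(img, degrees) {
  th <- degrees * pi / 180
  dmriqc:::affine_resample(
    img, matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2), c(0, 0))
}

smooth_test_image <- function(size = 64L) {
  g <- function(cx, cy, s)
    outer(exp(-((seq_len(size)) - cx)^2 / (2 * s^2)),
          exp(-((seq_len(size)) - cy)^2 / (2 * s^2)))
  2 * g(0.56 * size, 0.47 * size, size / 13) +
    g(0.44 * size, 0.59 * size, size / 16) +
    0.5 * g((size + 1) / 2, (size + 1) / 2, size / 8)
}

random_confusion_case <- function(n) {
  truth <- sample(c("artifactual", "artifact_free"), n, replace = TRUE)
  pred <- sample(c("artifactual", "artifact_free"), n, replace = TRUE)
  list(truth = truth, pred = pred)
}

# independent brute-force metric oracle: recount pairs one by one
brute_force_metrics <- function(truth, pred) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == "artifactual" && pred[i] == "artifactual") tp <- tp + 1L
    else if (truth[i] != "artifactual" && pred[i] == "artifactual") fp <- fp + 1L
    else if (truth[i] != "artifactual" && pred[i] != "artifactual") tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    accuracy = (tp + tn) / n_distinct_total(tp, fp, tn, fn)
  )
}
n_distinct_total <- function(tp, fp, tn, fn) tp + fp + tn + fn

random_slice_report <- function(n_vols = 12L, n_grad = 2L,
                                n_slices = 15L, seed = 1L) {
  set.seed(seed)
  df <- expand.grid(volume_id = sprintf("v%02d", seq_len(n_vols)),
                    view = "axial", gradient_index = seq_len(n_grad),
                    slice_index = seq_len(n_slices),
                    stringsAsFactors = FALSE)
  df$probability <- runif(nrow(df))
  df$label <- ifelse(df$probability >= 0.5, "artifactual",
                     "artifact_free")
  slice_report(df)
}
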