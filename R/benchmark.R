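# End-to-end synthetic benchmark: generate a labeled dataset, train the
# compact axial and sagittal detectors, and measure held-out performance
# plus severity monotonicity. Problem sizes are chosen so the whole run
# fits in minutes on one CPU while exercising every pipeline stage; they
# are the package's reference desk-scale conditions and are reused by the
# acceptance script.

benchmark_phantom <- function(seed) {
  phantom_spec(dims = c(64L, 64L, 32L),
               gradient_attenuation = c(1, 0.6),
               noise_sigma = 0.02, seed = seed)
}

# cap slices per volume, label-aware: artifactual slices are scarce
# (an axial artifact touches a handful of slices per volume), so they are
# kept in full and only the abundant clean slices are subsampled
subsample_per_volume <- function(slices, per_volume, seed,
                                 label_aware = FALSE) {
  vols <- vapply(slices, `[[`, "", "volume_id")
  labs <- vapply(slices, `[[`, "", "label")
  keep <- with_seed(seed, unlist(lapply(unique(vols), function(v) {
    idx <- which(vols == v)
    if (length(idx) <= per_volume) return(idx)
    if (!label_aware) return(sort(sample(idx, per_volume)))
    # artifactual slices are scarce (an axial artifact touches a handful
    # of slices per volume): keep them all, subsample the clean surplus
    pos <- idx[labs[idx] == "artifactual"]
    neg <- idx[labs[idx] != "artifactual"]
    room <- max(per_volume - length(pos), 0L)
    sort(c(pos, if (room > 0) sample(neg, min(room, length(neg)))))
  })))
  slices[keep]
}

#' Run the end-to-end synthetic benchmark
#'
#' Generates `n_volumes` phantom volumes (half with mixed-type artifacts),
#' trains one compact detector per view on a volume-level 70/30 split
#' (volumes never straddle train and test, so there is no subject
#' leakage), and reports held-out slice accuracy per view together with a
#' ghosting severity sweep: the mean predicted artifact probability of the
#' axial detector over five ghost intensities, and its Spearman rank
#' correlation with severity.
#'
#' Training slices are capped per volume and view and the minority class
#' is augmented to parity ([augment_to_balance()]), giving a training set
#' near two thousand slices per view; training runs `epochs` epochs of
#' RMSprop at the from-scratch learning rate 1e-3 with batch size 16.
#'
#' @param n_volumes number of 4D volumes (default 60).
#' @param seed master seed for generation, splits and training.
#' @param epochs training epochs (default 10).
#' @param out_dir scratch directory for the generated dataset.
#' @param per_volume training-slice cap per volume and view.
#' @return list with per-view held-out `accuracy`, `confusion`,
#'   `metrics`, training sizes, and `severity` (data.frame of ghost
#'   intensity vs mean predicted probability, plus `spearman`).
#' @export
synthetic_benchmark <- function(n_volumes = 60L, seed = 1L, epochs = 10L,
                                out_dir = tempfile("dmriqc_bench"),
                                per_volume = 25L) {
  ds <- generate_dataset(benchmark_phantom(seed), artifact_menu_default(),
                         n_volumes = n_volumes, artifact_fraction = 0.5,
                         seed = seed, out_dir = out_dir)
  vols <- unique(ds$manifest$volume_id)
  n_train <- round(0.7 * length(vols))
  train_vols <- with_seed(seed + 1L, sample(vols, n_train))
  out <- list(seed = seed, n_volumes = n_volumes)
  for (view in c("axial", "sagittal")) {
    slices <- load_dataset_slices(ds$dir, view)
    svol <- vapply(slices, `[[`, "", "volume_id")
    train <- subsample_per_volume(slices[svol %in% train_vols],
                                  per_volume, seed + 2L,
                                  label_aware = TRUE)
    train <- augment_to_balance(train, augment_config(), seed = seed + 4L)
    test <- subsample_per_volume(slices[!svol %in% train_vols],
                                 per_volume, seed + 3L)
    model <- build_model(model_spec("compact_scratch"), view = view,
                         seed = seed + 10L)
    model <- train_detector(model, train,
                            train_config(epochs = epochs,
                                         learning_rate = 1e-3,
                                         batch_size = 16L,
                                         seed = seed + 20L))
    pred <- predict_slices(model, test)
    truth <- vapply(test, `[[`, "", "label")
    conf <- confusion_from_labels(truth, pred$label)
    out[[view]] <- list(model = model, confusion = conf,
                        metrics = compute_metrics(conf),
                        accuracy = compute_metrics(conf)$accuracy,
                        n_train = length(train), n_test = length(test),
                        loss_trace = model$loss_trace)
  }
  out$severity <- ghost_severity_sweep(out$axial$model, seed = seed)
  unlink(out_dir, recursive = TRUE)
  out
}

#' Ghosting severity sweep for a trained axial detector
#'
#' Renders a clean phantom, injects Nyquist ghosting at each intensity in
#' `severities` on a fixed block of axial slices, and records the mean
#' predicted artifact probability over those slices. A detector that has
#' learned the artifact, rather than memorised examples, responds
#' monotonically: the Spearman rank correlation between severity and mean
#' probability approaches one.
#'
#' @param model a trained axial `detector_model`.
#' @param severities ghost intensities to probe.
#' @param seed phantom noise seed.
#' @return data.frame with `severity` and `mean_probability`, plus
#'   attribute `spearman`.
#' @export
ghost_severity_sweep <- function(model,
                                 severities = c(0.1, 0.2, 0.3, 0.4, 0.5),
                                 seed = 1L) {
  stopifnot(model$view == "axial")
  ph <- benchmark_phantom(seed + 500L)
  base <- make_phantom_volume(ph)
  extent <- compute_brain_extent(base)
  idx <- retained_slice_indices(extent, "axial", 5L)
  target <- idx[seq(ceiling(length(idx) / 3),
                    floor(2 * length(idx) / 3))]
  mean_prob <- vapply(severities, function(a) {
    vg <- inject_ghosting(base, a, "A-P", affected_slices = target,
                          affected_gradients = seq_len(n_gradients(base)))
    slices <- extract_axial_slices(vg, extent, 5L)
    keep <- vapply(slices, function(s) s$slice_index %in% target, TRUE)
    mean(predict_slices(model, slices[keep])$probability)
  }, 1)
  res <- data.frame(severity = severities, mean_probability = mean_prob)
  attr(res, "spearman") <- cor(severities, mean_prob, method = "spearman")
  res
}

#' Baseline texture-detector comparison on synthetic fixtures
#'
#' Builds a balanced set of artifactual (herringbone and ghosting, axial
#' view) versus clean phantom slices, computes Gabor, Zernike and LBP
#' features, and cross-validates a random forest on each scheme. The
#' quantity of interest is the recall ordering across feature families —
#' oriented-frequency features see stripe and ghost structure that
#' intensity-pattern features miss.
#'
#' @param n_per_class slices per class (default 400).
#' @param seed master seed.
#' @param k cross-validation folds.
#' @return list of per-scheme pooled metrics (`gabor`, `zernike`, `lbp`),
#'   each with `recall`, `precision`, `accuracy`.
#' @export
baseline_comparison <- function(n_per_class = 400L, seed = 1L, k = 5L) {
  ph <- benchmark_phantom(seed + 900L)
  ph$gradient_attenuation <- 1  # one gradient volume per phantom
  slices <- list(); labels <- character(0)
  n_vols <- ceiling(n_per_class / 5)
  with_seed(seed, {
    for (v in seq_len(n_vols)) {
      phv <- ph; phv$seed <- ph$seed + v
      vol <- make_phantom_volume(phv)
      extent <- compute_brain_extent(vol)
      idx <- retained_slice_indices(extent, "axial", 5L)
      picks <- sort(sample(idx, min(10, length(idx))))
      half <- length(picks) %/% 2
      corrupt <- picks[seq_len(half)]
      med_k <- stats::median(Mod(fft(vol$data[, , corrupt[1], 1])))
      vol_c <- if (v %% 2 == 0)
        inject_herringbone(vol, runif(1, 4, 8) * med_k,
                           c(sample(5:20, 1), sample(5:20, 1)),
                           corrupt, 1L)
      else
        inject_ghosting(vol, runif(1, 0.2, 0.5), "A-P", corrupt, 1L)
      all_sl <- extract_axial_slices(vol_c, extent, 5L)
      for (s in all_sl) {
        if (!(s$slice_index %in% picks)) next
        slices[[length(slices) + 1L]] <- s
        labels <- c(labels, if (s$slice_index %in% corrupt) "artifactual"
                            else "artifact_free")
      }
    }
  })
  keep <- seq_len(min(length(labels), 2L * n_per_class))
  slices <- slices[keep]; labels <- labels[keep]
  out <- list()
  for (scheme in c("gabor", "zernike", "lbp")) {
    feats <- feature_matrix(slices, scheme)
    cv <- cv_feature_detector(feats, labels, "random_forest", k = k,
                              seed = seed + 5L)
    out[[scheme]] <- cv$pooled_metrics
  }
  out
}
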