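# Slice-wise and volume-wise QC reports, evaluation metrics, slice-count
# threshold sweeps, and the inspection-workload reduction estimator.

#' Confusion counts
#'
#' TP = correctly recognized artifactual, FP = incorrectly recognized
#' artifactual, TN = correctly recognized artifact-free, FN = incorrectly
#' recognized artifact-free.
#'
#' @param tp,fp,tn,fn nonnegative integer counts.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || any(v != round(v)))
    stop("confusion counts must be nonnegative integers")
  structure(as.list(stats::setNames(as.integer(round(v)), names(v))),
            class = "confusion_counts")
}

#' Count a confusion matrix from label vectors
#'
#' @param truth,predicted character vectors of
#'   `"artifactual"` / `"artifact_free"`, equal length.
#' @return a [confusion_counts()].
#' @export
confusion_from_labels <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  t_pos <- truth == "artifactual"
  p_pos <- predicted == "artifactual"
  confusion_counts(sum(t_pos & p_pos), sum(!t_pos & p_pos),
                   sum(!t_pos & !p_pos), sum(t_pos & !p_pos))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP=", x$tp, " FP=", x$fp, " TN=", x$tn,
      " FN=", x$fn, "\n", sep = "")
  invisible(x)
}

add_confusion <- function(a, b)
  confusion_counts(a$tp + b$tp, a$fp + b$fp, a$tn + b$tn, a$fn + b$fn)

#' Precision, recall and accuracy from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`. A zero denominator yields `NA`
#' (an explicit undefined marker), never an error and never a silent 0
#' or 1.
#'
#' @param c a [confusion_counts()].
#' @return list with `precision`, `recall`, `accuracy`.
#' @export
compute_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$tp + c$fp + c$tn + c$fn
  if (total < 1) stop("metrics need at least one counted case")
  list(
    precision = if (c$tp + c$fp == 0) NA_real_ else c$tp / (c$tp + c$fp),
    recall    = if (c$tp + c$fn == 0) NA_real_ else c$tp / (c$tp + c$fn),
    accuracy  = (c$tp + c$tn) / total
  )
}

#' Assemble a slice-wise report
#'
#' One row per evaluated slice with its predicted probability and label,
#' ordered by volume, view, gradient, then slice index, so reruns are
#' byte-stable. Duplicate (volume, view, gradient, slice) keys are an
#' error.
#'
#' @param predictions data.frame with columns `volume_id, view,
#'   gradient_index, slice_index, probability, label` (the format
#'   [predict_slices()] emits; several views may be row-bound).
#' @return the report data.frame.
#' @export
slice_report <- function(predictions) {
  need <- c("volume_id", "view", "gradient_index", "slice_index",
            "probability", "label")
  missing <- setdiff(need, names(predictions))
  if (length(missing))
    stop("predictions lack column(s): ", paste(missing, collapse = ", "))
  key <- paste(predictions$volume_id, predictions$view,
               predictions$gradient_index, predictions$slice_index)
  if (anyDuplicated(key))
    stop("duplicate (volume, view, gradient, slice) keys in predictions")
  ord <- order(predictions$volume_id, predictions$view,
               predictions$gradient_index, predictions$slice_index)
  out <- predictions[ord, need, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag volumes by artifactual-slice count
#'
#' A volume here is one 3D gradient image (identified by `volume_id` plus
#' `gradient_index`). It is flagged in a view when its number of
#' artifactual slices in that view is at least the slice-count threshold
#' `T`.
#'
#' @param report a [slice_report()] data.frame.
#' @param threshold slice-count threshold `T >= 1`.
#' @param view `"axial"` or `"sagittal"`.
#' @return data.frame with one row per (volume_id, gradient_index):
#'   `n_artifactual`, `flagged`, and the contributing slice indices as a
#'   comma-separated string.
#' @export
volume_flags <- function(report, threshold, view = c("axial", "sagittal")) {
  if (threshold < 1) stop("slice-count threshold must be >= 1")
  view <- match.arg(view)
  r <- report[report$view == view, , drop = FALSE]
  keys <- unique(r[, c("volume_id", "gradient_index")])
  keys <- keys[order(keys$volume_id, keys$gradient_index), , drop = FALSE]
  rownames(keys) <- NULL
  art <- r$label == "artifactual"
  keys$n_artifactual <- mapply(function(v, g)
    sum(art & r$volume_id == v & r$gradient_index == g),
    keys$volume_id, keys$gradient_index)
  keys$flagged <- keys$n_artifactual >= threshold
  keys$artifactual_slices <- mapply(function(v, g)
    paste(sort(r$slice_index[art & r$volume_id == v &
                               r$gradient_index == g]), collapse = ","),
    keys$volume_id, keys$gradient_index)
  keys$view <- view
  keys$threshold <- threshold
  keys
}

#' Volume-level truth from a manifest
#'
#' A gradient volume is truly artifactual in a view iff the manifest marks
#' at least one of its slices artifactual in that view.
#'
#' @param manifest data.frame as written by [generate_dataset()].
#' @param view `"axial"` or `"sagittal"`.
#' @return data.frame `volume_id, gradient_index, truth`.
#' @export
volume_truth <- function(manifest, view = c("axial", "sagittal")) {
  view <- match.arg(view)
  m <- manifest[manifest$view == view, , drop = FALSE]
  agg <- stats::aggregate(m$label == "artifactual",
                          by = list(volume_id = m$volume_id,
                                    gradient_index = m$gradient_index),
                          FUN = any)
  agg <- agg[order(agg$volume_id, agg$gradient_index), , drop = FALSE]
  data.frame(volume_id = agg$volume_id,
             gradient_index = agg$gradient_index,
             truth = ifelse(agg$x, "artifactual", "artifact_free"),
             stringsAsFactors = FALSE)
}

#' Sweep slice-count thresholds
#'
#' Volume-level precision/recall/accuracy at each threshold. Because the
#' flagged set can only shrink as `T` grows, recall is non-increasing in
#' `T`.
#'
#' @param report a [slice_report()].
#' @param truth data.frame `volume_id, gradient_index, truth` (see
#'   [volume_truth()]).
#' @param thresholds integer thresholds; default `c(1, 3, 5, 7, 10)`.
#' @param view `"axial"` or `"sagittal"`.
#' @return data.frame with columns `threshold, accuracy, precision,
#'   recall` (one row per threshold).
#' @export
sweep_thresholds <- function(report, truth,
                             thresholds = c(1L, 3L, 5L, 7L, 10L),
                             view = c("axial", "sagittal")) {
  view <- match.arg(view)
  rows <- lapply(thresholds, function(T) {
    vf <- volume_flags(report, T, view)
    key_f <- paste(vf$volume_id, vf$gradient_index)
    key_t <- paste(truth$volume_id, truth$gradient_index)
    m <- match(key_f, key_t)
    if (anyNA(m)) stop("truth lacks some volumes present in the report")
    conf <- confusion_from_labels(
      truth$truth[m],
      ifelse(vf$flagged, "artifactual", "artifact_free"))
    met <- compute_metrics(conf)
    data.frame(threshold = T, accuracy = met$accuracy,
               precision = met$precision, recall = met$recall)
  })
  do.call(rbind, rows)
}

#' Estimate the reduction in volumes to inspect
#'
#' If a detector with the given volume-level precision and recall flags
#' volumes for manual review, the expected number of flagged volumes is
#' `recall * n_artifactual / precision` (the recalled true positives plus
#' the implied false positives), and the analyst inspects only those
#' instead of all `n_total` volumes.
#'
#' @param n_total total number of gradient volumes.
#' @param n_artifactual number of truly artifactual volumes.
#' @param precision volume-level precision in (0, 1].
#' @param recall volume-level recall in \[0, 1\].
#' @return list with `n_total`, `n_artifactual`, `precision`, `recall`,
#'   `expected_flagged`, `reduction_percent` (0-100, rounded to 2 decimals
#'   for display in `reduction_percent_display`).
#' @export
estimate_inspection_reduction <- function(n_total, n_artifactual,
                                          precision, recall) {
  if (precision <= 0 || precision > 1)
    stop("precision must lie in (0, 1]")
  if (recall < 0 || recall > 1) stop("recall must lie in [0, 1]")
  if (n_artifactual > n_total)
    stop("n_artifactual cannot exceed n_total")
  flagged <- recall * n_artifactual / precision
  reduction <- 100 * (1 - flagged / n_total)
  list(n_total = n_total, n_artifactual = n_artifactual,
       precision = precision, recall = recall,
       expected_flagged = flagged,
       reduction_percent = reduction,
       reduction_percent_display = round(reduction, 2))
}

#' Write a volume report as CSV plus a JSON summary
#'
#' @param flags a [volume_flags()] data.frame.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return `flags`, invisibly.
#' @export
write_volume_report <- function(flags, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    write.csv(flags, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(view = flags$view[1], threshold = flags$threshold[1],
           n_volumes = nrow(flags), n_flagged = sum(flags$flagged)),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(flags)
}
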