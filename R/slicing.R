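#' Construct a 2D slice sample
#'
#' One 2D slice cut from a diffusion volume, tagged with the view it was
#' extracted in, its source indices, and an optional binary QC label.
#' Indices are 1-based over the source array axes.
#'
#' @param image 2D numeric matrix of finite intensities.
#' @param view `"axial"` or `"sagittal"`.
#' @param volume_id identifier of the source volume.
#' @param gradient_index 1-based index of the source gradient volume.
#' @param slice_index 1-based index along the slicing axis.
#' @param label optional, `"artifactual"` or `"artifact_free"`.
#' @return object of class `slice_sample`.
#' @export
slice_sample <- function(image, view, volume_id = "vol",
                         gradient_index = 1L, slice_index = 1L,
                         label = NULL) {
  if (!is.matrix(image) || !all(is.finite(image)))
    stop("`image` must be a finite numeric matrix")
  view <- match.arg(view, c("axial", "sagittal"))
  if (!is.null(label))
    label <- match.arg(label, c("artifactual", "artifact_free"))
  structure(
    list(image = image, view = view, volume_id = volume_id,
         gradient_index = as.integer(gradient_index),
         slice_index = as.integer(slice_index), label = label),
    class = "slice_sample"
  )
}

#' @export
print.slice_sample <- function(x, ...) {
  cat("<slice_sample> ", x$view, " ", nrow(x$image), "x", ncol(x$image),
      " vol=", x$volume_id, " grad=", x$gradient_index,
      " slice=", x$slice_index,
      if (!is.null(x$label)) paste0(" [", x$label, "]") else "", "\n",
      sep = "")
  invisible(x)
}

axis_of <- function(vol, anat) match(anat, vol$axis_labels)

#' Detect the head/brain extent of a volume
#'
#' Bounding box of the voxels whose mean-over-gradients intensity exceeds
#' `threshold_fraction` times a robust maximum (the 99th percentile of the
#' mean image). The box is reported per anatomical axis as an inclusive
#' 1-based index range. This intensity bounding box approximates the
#' head/skull boundary that slice-exclusion rules need; it is not a brain
#' segmentation.
#'
#' @param vol a [dwi_volume()].
#' @param threshold_fraction fraction in (0,1) of the robust maximum;
#'   default 0.1.
#' @return object of class `brain_extent`: a named list of `c(lo, hi)`
#'   ranges keyed by anatomical axis, with the volume's spatial dims
#'   attached.
#' @export
compute_brain_extent <- function(vol, threshold_fraction = 0.1) {
  stopifnot(inherits(vol, "dwi_volume"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("`threshold_fraction` must lie in (0,1)")
  d <- dim(vol$data)
  mean_img <- rowMeans(matrix(vol$data, prod(d[1:3]), d[4]))
  dim(mean_img) <- d[1:3]
  thr <- threshold_fraction * as.numeric(quantile(mean_img, 0.99))
  mask <- mean_img > thr
  if (!any(mask))
    stop("no voxel exceeds the extent threshold; volume appears empty")
  ranges <- lapply(1:3, function(ax) {
    present <- apply(mask, ax, any)
    range(which(present))
  })
  names(ranges) <- vol$axis_labels
  structure(ranges[c("L-R", "A-P", "I-S")],
            dims = d[1:3], axis_labels = vol$axis_labels,
            class = "brain_extent")
}

#' @export
print.brain_extent <- function(x, ...) {
  cat("<brain_extent>\n")
  for (ax in names(x))
    cat("  ", ax, ": [", x[[ax]][1], ", ", x[[ax]][2], "]\n", sep = "")
  invisible(x)
}

grab_slice <- function(vol, axis, index, gradient) {
  idx <- list(quote(expr = ), quote(expr = ), quote(expr = ), gradient)
  idx[[axis]] <- index
  as.matrix(do.call(`[`, c(list(vol$data), idx, list(drop = TRUE))))
}

#' Extract retained sagittal slices
#'
#' Sagittal slices entirely outside the head are excluded by construction
#' (only indices inside the L-R extent are considered), and a margin of
#' slices at each left/right edge of the head is additionally dropped,
#' since peripheral slices contain mostly background. Retained indices are
#' `(lo + margin) .. (hi - margin)` of the L-R extent; the result is empty
#' when `hi - lo < 2 * margin`.
#'
#' @param vol a [dwi_volume()].
#' @param extent a [compute_brain_extent()] result.
#' @param margin number of edge slices to drop at each side; default 5.
#' @param volume_id identifier recorded in each sample.
#' @return list of [slice_sample()], one per (retained index, gradient),
#'   ordered gradient-major then slice index.
#' @export
extract_sagittal_slices <- function(vol, extent, margin = 5L,
                                    volume_id = "vol") {
  stopifnot(inherits(vol, "dwi_volume"), inherits(extent, "brain_extent"),
            margin >= 0)
  idx <- retained_indices(extent[["L-R"]], margin, margin)
  ax <- axis_of(vol, "L-R")
  out <- list()
  for (g in seq_len(n_gradients(vol)))
    for (s in idx)
      out[[length(out) + 1L]] <- slice_sample(
        grab_slice(vol, ax, s, g), "sagittal", volume_id, g, s)
  out
}

#' Extract retained axial slices
#'
#' Axial slices below the inferior head boundary (cerebellum and below) and
#' above the superior boundary are excluded by construction; an additional
#' `top_margin` slices just inferior to the superior surface of the skull
#' are dropped. Retained indices are `lo .. (hi - top_margin)` of the I-S
#' extent.
#'
#' @inheritParams extract_sagittal_slices
#' @param top_margin number of slices dropped below the superior boundary;
#'   default 5.
#' @return list of [slice_sample()].
#' @export
extract_axial_slices <- function(vol, extent, top_margin = 5L,
                                 volume_id = "vol") {
  stopifnot(inherits(vol, "dwi_volume"), inherits(extent, "brain_extent"),
            top_margin >= 0)
  idx <- retained_indices(extent[["I-S"]], 0L, top_margin)
  ax <- axis_of(vol, "I-S")
  out <- list()
  for (g in seq_len(n_gradients(vol)))
    for (s in idx)
      out[[length(out) + 1L]] <- slice_sample(
        grab_slice(vol, ax, s, g), "axial", volume_id, g, s)
  out
}

retained_indices <- function(rng, lo_margin, hi_margin) {
  lo <- rng[1] + lo_margin
  hi <- rng[2] - hi_margin
  if (lo > hi) integer(0) else seq.int(lo, hi)
}

#' Retained slice indices for a view
#'
#' The index set that [extract_axial_slices()] / [extract_sagittal_slices()]
#' keep, without materialising the slices.
#'
#' @param extent a `brain_extent`.
#' @param view `"axial"` or `"sagittal"`.
#' @param margin exclusion margin (both edges for sagittal, top only for
#'   axial); default 5.
#' @return integer vector of retained 1-based indices.
#' @export
retained_slice_indices <- function(extent, view, margin = 5L) {
  view <- match.arg(view, c("axial", "sagittal"))
  if (view == "sagittal")
    retained_indices(extent[["L-R"]], margin, margin)
  else
    retained_indices(extent[["I-S"]], 0L, margin)
}

#' Normalize a slice to zero mean and unit variance
#'
#' Intensities are centred by the slice mean and scaled by the population
#' standard deviation. A constant slice (zero variance) maps to an all-zero
#' image rather than erroring. The operation is idempotent and invariant to
#' positive affine rescaling of the input.
#'
#' @param s a [slice_sample()].
#' @return the slice with normalized image; label and indices unchanged.
#' @export
normalize_slice <- function(s) {
  stopifnot(inherits(s, "slice_sample"))
  x <- s$image
  m <- mean(x)
  sd_pop <- sqrt(mean((x - m)^2))
  s$image <- if (sd_pop == 0) array(0, dim(x)) else (x - m) / sd_pop
  dim(s$image) <- dim(x)
  s
}

#' Read a slice-label sidecar CSV
#'
#' Expected columns: `volume_id, view, gradient_index, slice_index, label`.
#'
#' @param path CSV path.
#' @return data.frame with those columns.
#' @export
read_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("volume_id", "view", "gradient_index", "slice_index", "label")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("labels file lacks column(s): ", paste(missing, collapse = ", "))
  df
}

#' Attach labels to extracted slices
#'
#' @param slices list of [slice_sample()].
#' @param labels data.frame as returned by [read_labels()].
#' @return the slices with `label` filled where a matching row exists.
#' @export
apply_labels <- function(slices, labels) {
  key <- function(v, vw, g, s) paste(v, vw, g, s, sep = "\r")
  lut <- stats::setNames(labels$label,
                         key(labels$volume_id, labels$view,
                             labels$gradient_index, labels$slice_index))
  lapply(slices, function(s) {
    k <- key(s$volume_id, s$view, s$gradient_index, s$slice_index)
    if (!is.na(lut[k])) s$label <- unname(lut[k])
    s
  })
}
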