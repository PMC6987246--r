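#' Construct a 4D diffusion MRI volume
#'
#' A `dwi_volume` bundles a 4D intensity array (three spatial axes plus one
#' gradient axis), its voxel-to-world affine, and the mapping from array axes
#' to anatomical axes. Intensities are magnitude data: finite and
#' non-negative. All spatial dimensions must be at least 16 voxels so that
#' slice-exclusion margins remain meaningful.
#'
#' @param data numeric array, 3D (promoted to a single-gradient 4D) or 4D,
#'   ordered (x, y, z, gradient).
#' @param affine 4x4 voxel-to-world transform. The upper-left 3x3 block maps
#'   array axes to world (RAS) directions and determines `axis_labels`.
#' @param axis_labels optional character vector of length 3 naming the
#'   anatomical axis of each array axis, a permutation of
#'   `c("L-R", "A-P", "I-S")`. Derived from `affine` when omitted.
#' @param rim_mask optional 3D logical array marking the fat-rim component
#'   (carried by phantoms; used by the chemical-shift injector).
#'
#' @return An object of class `dwi_volume` with fields `data`, `affine`,
#'   `axis_labels`, and optionally `rim_mask`.
#' @export
dwi_volume <- function(data, affine = diag(4), axis_labels = NULL,
                       rim_mask = NULL) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("`data` must be a 3D or 4D array")
  if (length(dim(data)) == 3L)
    dim(data) <- c(dim(data), 1L)
  d <- dim(data)
  if (any(d[1:3] < 16L))
    stop("all spatial dimensions must be >= 16 voxels (got ",
         paste(d[1:3], collapse = "x"), ")")
  if (d[4] < 1L)
    stop("gradient dimension must be >= 1")
  if (!all(is.finite(data)))
    stop("volume contains non-finite intensities")
  if (min(data) < 0)
    stop("volume contains negative intensities; magnitude data expected")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  if (is.null(axis_labels))
    axis_labels <- axis_labels_from_affine(affine)
  if (!setequal(axis_labels, c("L-R", "A-P", "I-S")))
    stop("`axis_labels` must be a permutation of L-R, A-P, I-S")
  structure(
    list(data = data, affine = affine, axis_labels = axis_labels,
         rim_mask = rim_mask),
    class = "dwi_volume"
  )
}

#' Derive anatomical axis labels from an affine
#'
#' Each array axis is assigned the anatomical axis (L-R, A-P, I-S) along
#' which its world direction (a column of the affine's rotation block) has
#' the largest absolute component.
#'
#' @param affine 4x4 voxel-to-world matrix.
#' @return character vector of length 3.
#' @export
axis_labels_from_affine <- function(affine) {
  lab <- c("L-R", "A-P", "I-S")
  dominant <- vapply(1:3, function(i) which.max(abs(affine[1:3, i])), 1L)
  if (anyDuplicated(dominant))
    stop("affine does not map array axes to distinct anatomical axes")
  lab[dominant]
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<dwi_volume> ", paste(d[1:3], collapse = "x"), " voxels, ",
      d[4], " gradient volume(s)\n", sep = "")
  cat("  axis labels:", paste(x$axis_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Number of gradient volumes
#' @param vol a `dwi_volume`.
#' @return integer count of 3D gradient volumes.
#' @export
n_gradients <- function(vol) dim(vol$data)[4]

#' Load a diffusion volume from a NIfTI file
#'
#' Reads a 3D or 4D NIfTI-1 image (`.nii` or `.nii.gz`); a 3D image is
#' promoted to 4D with a single gradient volume. Axis labels are derived
#' from the dominant directions of the stored affine.
#'
#' @param path path to a readable NIfTI file.
#' @return a [dwi_volume()].
#' @export
load_volume <- function(path) {
  if (!file.exists(path))
    stop("cannot load '", path, "': file does not exist")
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop("cannot load '", path, "' as NIfTI: ",
                         conditionMessage(e), call. = FALSE))
  data <- unclass(img)
  attributes(data) <- list(dim = dim(img))
  nd <- length(dim(data))
  if (nd < 3L)
    stop("cannot load '", path, "': image has ", nd,
         " dimensions, need 3 or 4")
  if (nd > 4L)
    stop("cannot load '", path, "': image has ", nd,
         " dimensions, need 3 or 4")
  if (!all(is.finite(data)))
    stop("cannot load '", path, "': non-finite voxel intensities")
  affine <- structure(RNifti::xform(img), code = NULL)
  dwi_volume(data, affine = matrix(as.numeric(affine), 4, 4))
}

#' Write a diffusion volume to a NIfTI file
#'
#' Voxel data are stored as 64-bit floats so that a write/reload round trip
#' preserves intensities bit-exactly.
#'
#' @param vol a `dwi_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "dwi_volume"))
  img <- RNifti::asNifti(vol$data, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
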