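# Label-preserving geometric augmentation. A single random affine
# (translation, rotation, zoom, shear, flips) is composed per draw and the
# slice is resampled with bilinear interpolation; out-of-frame pixels take
# the nearest edge value so no artificial dark borders (which could mimic
# artifacts) are introduced.

#' Augmentation configuration
#'
#' All ranges are symmetric about zero (a draw of 0 is the identity).
#' Defaults are mild: they simulate acquisition variation without turning
#' an artifact-free slice into an artifact mimic.
#'
#' @param max_translation maximum shift as a fraction of width/height,
#'   in \[0, 1\].
#' @param max_rotation maximum rotation in degrees, in \[0, 180\].
#' @param zoom_range `c(min, max)` scale factors, `min <= max`.
#' @param max_shear maximum shear angle in degrees, in \[0, 180\].
#' @param flip_horizontal,flip_vertical whether random flips are enabled.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(max_translation = 0.1, max_rotation = 15,
                           zoom_range = c(0.9, 1.1), max_shear = 10,
                           flip_horizontal = TRUE, flip_vertical = FALSE) {
  stopifnot(max_translation >= 0, max_translation <= 1,
            max_rotation >= 0, max_rotation <= 180,
            max_shear >= 0, max_shear <= 180,
            length(zoom_range) == 2, zoom_range[1] <= zoom_range[2],
            all(zoom_range > 0))
  structure(list(max_translation = max_translation,
                 max_rotation = max_rotation, zoom_range = zoom_range,
                 max_shear = max_shear,
                 flip_horizontal = isTRUE(flip_horizontal),
                 flip_vertical = isTRUE(flip_vertical)),
            class = "augment_config")
}

identity_config <- function(cfg) {
  cfg$max_translation == 0 && cfg$max_rotation == 0 &&
    all(cfg$zoom_range == 1) && cfg$max_shear == 0 &&
    !cfg$flip_horizontal && !cfg$flip_vertical
}

affine_resample <- function(img, M, tvec) {
  # sample input at Minv %*% (out - centre - t) + centre, bilinear,
  # edge-clamped
  h <- nrow(img); w <- ncol(img)
  cx <- (h + 1) / 2; cy <- (w + 1) / 2
  Minv <- solve(M)
  ox <- rep(seq_len(h), times = w) - cx - tvec[1]
  oy <- rep(seq_len(w), each = h) - cy - tvec[2]
  ix <- Minv[1, 1] * ox + Minv[1, 2] * oy + cx
  iy <- Minv[2, 1] * ox + Minv[2, 2] * oy + cy
  ix <- pmin(pmax(ix, 1), h)
  iy <- pmin(pmax(iy, 1), w)
  x0 <- floor(ix); y0 <- floor(iy)
  x1 <- pmin(x0 + 1, h); y1 <- pmin(y0 + 1, w)
  fx <- ix - x0; fy <- iy - y0
  at <- function(i, j) img[(j - 1) * h + i]
  val <- (1 - fx) * (1 - fy) * at(x0, y0) + fx * (1 - fy) * at(x1, y0) +
    (1 - fx) * fy * at(x0, y1) + fx * fy * at(x1, y1)
  matrix(val, h, w)
}

#' Apply one random augmentation to a slice
#'
#' Draws transform parameters uniformly within the config ranges and
#' resamples the slice once through the composed affine. Shape and label
#' are preserved; the output is deterministic given `draw_seed`.
#'
#' @param s a [slice_sample()].
#' @param cfg an [augment_config()].
#' @param draw_seed integer seed for this draw.
#' @return an augmented `slice_sample`.
#' @export
augment_slice <- function(s, cfg, draw_seed = 1L) {
  stopifnot(inherits(s, "slice_sample"), inherits(cfg, "augment_config"))
  if (identity_config(cfg)) return(s)
  img <- s$image
  h <- nrow(img); w <- ncol(img)
  with_seed(draw_seed, {
    tx <- runif(1, -1, 1) * cfg$max_translation * h
    ty <- runif(1, -1, 1) * cfg$max_translation * w
    th <- runif(1, -1, 1) * cfg$max_rotation * pi / 180
    zm <- runif(1, cfg$zoom_range[1], cfg$zoom_range[2])
    sh <- tan(runif(1, -1, 1) * cfg$max_shear * pi / 180)
    fh <- cfg$flip_horizontal && runif(1) < 0.5
    fv <- cfg$flip_vertical && runif(1) < 0.5
  })
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(1, 0, sh, 1), 2, 2)
  Fm <- diag(c(if (fh) -1 else 1, if (fv) -1 else 1))
  M <- R %*% S %*% (zm * Fm)
  s$image <- affine_resample(img, M, c(tx, ty))
  s
}

#' Augment the minority class to parity
#'
#' Artifactual slices are typically a small fraction of a QC training
#' stream. This expands the minority class with augmented copies (cycling
#' through its samples) until the two classes are balanced, leaving the
#' majority class untouched — augmentation increases the size and
#' heterogeneity of exactly the data that is scarce. A set that is already
#' balanced is returned unchanged.
#'
#' @param samples list of labeled [slice_sample()].
#' @param cfg an [augment_config()].
#' @param seed master seed for the augmentation draws.
#' @param max_copies cap on augmented copies per minority sample.
#' @return list of `slice_sample` with (near-)balanced classes.
#' @export
augment_to_balance <- function(samples, cfg, seed = 1L, max_copies = 10L) {
  labs <- vapply(samples, `[[`, "", "label")
  n_pos <- sum(labs == "artifactual")
  n_neg <- length(labs) - n_pos
  if (n_pos == 0 || n_neg == 0 || n_pos == n_neg) return(samples)
  minority <- which(labs == (if (n_pos < n_neg) "artifactual"
                             else "artifact_free"))
  deficit <- min(abs(n_neg - n_pos), max_copies * length(minority))
  out <- samples
  for (i in seq_len(deficit)) {
    src <- minority[(i - 1L) %% length(minority) + 1L]
    ds <- (seed + i * 7919L) %% .Machine$integer.max
    out[[length(out) + 1L]] <- augment_slice(samples[[src]], cfg, ds)
  }
  out
}

#' Build an augmented training set
#'
#' Returns the original samples plus `multiplier - 1` independently
#' augmented copies of each, so the output size is
#' `multiplier * length(samples)` and the class balance is preserved
#' exactly. Intended for training folds only; never augment validation or
#' test data.
#'
#' @param samples list of [slice_sample()].
#' @param cfg an [augment_config()].
#' @param multiplier integer >= 1; 1 returns the input unchanged.
#' @param seed master seed; per-copy draw seeds derive from it.
#' @return list of `slice_sample`.
#' @export
build_augmented_set <- function(samples, cfg, multiplier = 2L, seed = 1L) {
  stopifnot(multiplier >= 1)
  if (multiplier == 1L) return(samples)
  out <- samples
  for (m in seq_len(multiplier - 1L)) {
    for (i in seq_along(samples)) {
      ds <- (seed + m * 1000003L + i * 7919L) %% .Machine$integer.max
      out[[length(out) + 1L]] <- augment_slice(samples[[i]], cfg, ds)
    }
  }
  out
}
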