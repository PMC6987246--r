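# Ellipsoid head phantoms with tissue contrast, a bright fat rim separated
# from the brain by a dark skull gap, per-gradient signal attenuation and
# Rician magnitude noise. These stand in for scanner data when training and
# testing the artifact detectors.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Specify an ellipsoid head phantom
#'
#' The phantom is a stack of ellipsoids rendered into a voxel grid: a
#' grey-matter shell, a white-matter core, two CSF-like ventricles, and a
#' bright subcutaneous fat rim separated from the brain by a dark gap
#' standing in for skull. Gradient volumes are scaled copies of the base
#' image (diffusion attenuation), each corrupted by Rician noise.
#'
#' Tissue geometry defaults scale with the grid. Intensities are in
#' arbitrary units with CSF = 1.
#'
#' @param dims integer grid size `c(nx, ny, nz)`; in-plane dims >= 32.
#' @param tissues list of ellipsoid components, each
#'   `list(center, semi_axes, intensity)` in voxel units. Later components
#'   overwrite earlier ones. `NULL` for scaled defaults.
#' @param rim_thickness fat-rim thickness in voxels (>= 1).
#' @param rim_intensity intensity of the fat rim.
#' @param gradient_attenuation numeric vector of per-gradient scale factors
#'   in (0, 1]; its length sets the number of gradient volumes.
#' @param noise_sigma Rician noise sigma in intensity units.
#' @param seed integer RNG seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(64L, 64L, 40L), tissues = NULL,
                         rim_thickness = 2, rim_intensity = 1.2,
                         gradient_attenuation = c(1, 0.65, 0.6, 0.7,
                                                  0.55, 0.6),
                         noise_sigma = 0.02, seed = 1L) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3)
  if (any(dims[1:2] < 32L))
    stop("in-plane dimensions must be >= 32")
  if (rim_thickness < 1) stop("rim thickness must be >= 1 voxel")
  if (any(gradient_attenuation <= 0 | gradient_attenuation > 1))
    stop("gradient attenuation factors must lie in (0, 1]")
  if (noise_sigma < 0) stop("noise sigma must be >= 0")
  if (is.null(tissues)) tissues <- default_tissues(dims, rim_thickness)
  for (t in tissues) {
    if (any(t$semi_axes <= 0))
      stop("degenerate ellipsoid: semi-axes must be > 0")
    if (t$intensity < 0) stop("tissue intensities must be >= 0")
  }
  structure(
    list(dims = dims, tissues = tissues, rim_thickness = rim_thickness,
         rim_intensity = rim_intensity,
         gradient_attenuation = gradient_attenuation,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

default_tissues <- function(dims, rim_thickness) {
  ctr <- (dims + 1) / 2
  outer_semi <- c(0.40, 0.44, 0.46) * dims
  brain_semi <- outer_semi - rim_thickness - pmax(2, 0.04 * dims[1:2][1])
  list(
    head  = list(center = ctr, semi_axes = outer_semi, intensity = 0,
                 role = "head"),
    gm    = list(center = ctr, semi_axes = brain_semi, intensity = 0.7,
                 role = "tissue"),
    wm    = list(center = ctr, semi_axes = 0.78 * brain_semi,
                 intensity = 0.5, role = "tissue"),
    vent_l = list(center = ctr + c(-0.12 * dims[1], 0, 0.05 * dims[3]),
                  semi_axes = c(0.05, 0.16, 0.10) * dims, intensity = 1,
                  role = "tissue"),
    vent_r = list(center = ctr + c(0.12 * dims[1], 0, 0.05 * dims[3]),
                  semi_axes = c(0.05, 0.16, 0.10) * dims, intensity = 1,
                  role = "tissue")
  )
}

ellipsoid_mask <- function(dims, center, semi_axes) {
  x <- (seq_len(dims[1]) - center[1]) / semi_axes[1]
  y <- (seq_len(dims[2]) - center[2]) / semi_axes[2]
  z <- (seq_len(dims[3]) - center[3]) / semi_axes[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  r2 <= 1
}

#' Render a phantom into a diffusion volume
#'
#' Deterministic given the spec's seed. With `noise_sigma = 0` the output
#' is piecewise-constant at exactly the specified tissue intensities times
#' the per-gradient attenuation; the fat rim is not attenuated (fat signal
#' is diffusion-insensitive). The rim voxel mask is attached to the result
#' for use by the chemical-shift injector.
#'
#' @param spec a [phantom_spec()].
#' @return a [dwi_volume()] with `rim_mask` set.
#' @export
make_phantom_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  base <- array(0, d)
  head_mask <- NULL
  for (t in spec$tissues) {
    m <- ellipsoid_mask(d, t$center, t$semi_axes)
    if (identical(t$role, "head") && is.null(head_mask)) head_mask <- m
    base[m] <- t$intensity
  }
  if (is.null(head_mask))
    head_mask <- ellipsoid_mask(d, spec$tissues[[1]]$center,
                                spec$tissues[[1]]$semi_axes)
  inner <- spec$tissues[[1]]
  rim_mask <- head_mask & !ellipsoid_mask(
    d, inner$center, pmax(inner$semi_axes - spec$rim_thickness, 1e-6))
  base[rim_mask] <- 0  # rim added per gradient, unattenuated
  g <- spec$gradient_attenuation
  data <- array(0, c(d, length(g)))
  rim_img <- array(0, d)
  rim_img[rim_mask] <- spec$rim_intensity
  with_seed(spec$seed, {
    for (i in seq_along(g)) {
      vol_i <- base * g[i] + rim_img
      if (spec$noise_sigma > 0)
        vol_i <- rician_transform(vol_i, spec$noise_sigma)
      data[, , , i] <- vol_i
    }
  })
  dwi_volume(data, affine = diag(c(2, 2, 2, 1)), rim_mask = rim_mask)
}

rician_transform <- function(x, sigma) {
  n1 <- array(rnorm(length(x), 0, sigma), dim(x))
  n2 <- array(rnorm(length(x), 0, sigma), dim(x))
  sqrt((x + n1)^2 + n2^2)
}

#' Add Rician noise to an image or volume
#'
#' The MR magnitude noise model: `|(x + n1) + i n2|` with `n1`, `n2`
#' independent zero-mean Gaussians of standard deviation `sigma`. In
#' signal-free background this yields Rayleigh-distributed intensities
#' with mean `sigma * sqrt(pi/2)`.
#'
#' @param image numeric array (any shape).
#' @param sigma noise standard deviation in intensity units (>= 0);
#'   `sigma = 0` returns the input unchanged.
#' @param seed integer seed; the output is deterministic given it.
#' @return array of the same shape.
#' @export
add_rician_noise <- function(image, sigma, seed = 1L) {
  if (sigma < 0) stop("noise sigma must be >= 0")
  if (sigma == 0) return(image)
  with_seed(seed, rician_transform(image, sigma))
}
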