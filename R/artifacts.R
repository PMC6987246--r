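# k-space / image-domain artifact injectors. Each injector is the minimal
# physical mechanism producing the corresponding visual phenotype:
#   ghosting            alternate phase-encode line modulation (N/2 ghost)
#   herringbone         conjugate spike pair in k-space (plane-wave stripes)
#   chemical_shift      fat rim translated along the frequency-encode axis
#   susceptibility      smooth Gaussian-bump displacement along phase-encode
#   motion_dropout      attenuated axial slices (dark sagittal bands)
#   multiband_interleave periodic slice attenuation (venetian blinds)
# Zero severity is always the exact identity, and only the affected
# (slice, gradient) pairs are touched.

require_canonical <- function(vol) {
  if (!identical(vol$axis_labels, c("L-R", "A-P", "I-S")))
    stop("artifact injectors require canonical (L-R, A-P, I-S) axis order; ",
         "simulator volumes satisfy this")
}

inplane_axis <- function(axis) {
  # array axis (1 or 2) of an axial slice for an in-plane anatomical axis
  switch(axis, "L-R" = 1L, "A-P" = 2L,
         stop("axis must be an in-plane axial axis: 'L-R' or 'A-P'"))
}

check_affected <- function(vol, slices, gradients) {
  d <- dim(vol$data)
  if (length(slices) == 0 || length(gradients) == 0)
    stop("affected slice and gradient sets must be non-empty")
  if (any(slices < 1 | slices > d[3]))
    stop("affected slice indices out of range")
  if (any(gradients < 1 | gradients > d[4]))
    stop("affected gradient indices out of range")
}

#' Inject Nyquist (N/2) ghosting
#'
#' Even and odd phase-encode lines of each affected axial slice's 2D
#' k-space are modulated by `(1 + alpha)` and `(1 - alpha)`. By linearity
#' of the DFT this equals superimposing an `alpha`-weighted copy of the
#' slice shifted by half the field of view along the phase-encode axis.
#'
#' @param vol a [dwi_volume()] in canonical axis order.
#' @param intensity ghost intensity `alpha` in \[0, 1\]; 0 is the identity.
#' @param pe_axis phase-encode axis, `"A-P"` (default) or `"L-R"`.
#' @param affected_slices 1-based axial (I-S) slice indices to corrupt.
#' @param affected_gradients 1-based gradient indices to corrupt.
#' @return a new `dwi_volume`; unaffected slices are bit-identical.
#' @export
inject_ghosting <- function(vol, intensity, pe_axis = "A-P",
                            affected_slices, affected_gradients) {
  require_canonical(vol)
  if (intensity < 0 || intensity > 1)
    stop("ghost intensity must lie in [0, 1]")
  check_affected(vol, affected_slices, affected_gradients)
  if (intensity == 0) return(vol)
  pa <- inplane_axis(pe_axis)
  for (g in affected_gradients) for (z in affected_slices) {
    sl <- vol$data[, , z, g]
    k <- fft(sl)
    n <- dim(sl)[pa]
    f <- ifelse((seq_len(n) - 1L) %% 2L == 0L,
                1 + intensity, 1 - intensity)
    k <- if (pa == 1L) k * f else sweep(k, 2L, f, `*`)
    vol$data[, , z, g] <- Re(fft(k, inverse = TRUE)) / length(sl)
  }
  vol
}

#' Inject a herringbone (spike) artifact
#'
#' Adds a conjugate-symmetric pair of spurious spikes of the given
#' amplitude to the 2D k-space of each affected axial slice, superimposing
#' a single plane-wave stripe pattern across the image.
#'
#' @inheritParams inject_ghosting
#' @param amplitude spike magnitude in k-space units (>= 0); 0 is the
#'   identity. Visible artifacts need amplitudes of a few times the median
#'   `|k|` of the slice spectrum.
#' @param k_loc integer frequency coordinates `c(kx0, ky0)` (cycles per
#'   field of view, 0-based in the unshifted FFT grid); must not be the DC
#'   term and must lie inside the grid.
#' @return a new `dwi_volume`.
#' @export
inject_herringbone <- function(vol, amplitude, k_loc,
                               affected_slices, affected_gradients) {
  require_canonical(vol)
  if (amplitude < 0) stop("spike amplitude must be >= 0")
  check_affected(vol, affected_slices, affected_gradients)
  d <- dim(vol$data)
  k_loc <- as.integer(k_loc)
  if (all(k_loc %% c(d[1], d[2]) == 0L))
    stop("spike location must differ from the DC term")
  if (any(k_loc < 0) || k_loc[1] >= d[1] || k_loc[2] >= d[2])
    stop("spike location out of the k-space grid")
  if (amplitude == 0) return(vol)
  i1 <- k_loc[1] + 1L; j1 <- k_loc[2] + 1L
  i2 <- (-k_loc[1]) %% d[1] + 1L; j2 <- (-k_loc[2]) %% d[2] + 1L
  for (g in affected_gradients) for (z in affected_slices) {
    sl <- vol$data[, , z, g]
    k <- fft(sl)
    k[i1, j1] <- k[i1, j1] + amplitude
    if (!(i1 == i2 && j1 == j2))
      k[i2, j2] <- k[i2, j2] + amplitude
    vol$data[, , z, g] <- Re(fft(k, inverse = TRUE)) / length(sl)
  }
  vol
}

translate_2d <- function(img, shift, axis) {
  # integer translation with zero fill (non-circular)
  out <- array(0, dim(img))
  n <- dim(img)[axis]
  src <- seq_len(n) - shift
  ok <- src >= 1 & src <= n
  if (!any(ok)) return(out)
  if (axis == 1L) out[which(ok), ] <- img[src[ok], ]
  else out[, which(ok)] <- img[, src[ok]]
  out
}

#' Inject a chemical-shift artifact
#'
#' Fat resonates off-frequency, so its signal maps to a displaced position
#' along the frequency-encode axis. The phantom's fat-rim component of each
#' affected axial slice is translated by `shift_px` voxels along
#' `freq_axis` and re-added with weight `rim_intensity`, leaving a
#' bright/dark band pair at the rim edge.
#'
#' @inheritParams inject_ghosting
#' @param shift_px integer displacement in voxels; `|shift_px| >= 1` and at
#'   most a quarter of the field of view.
#' @param rim_intensity weight of the displaced fat copy.
#' @param freq_axis frequency-encode axis, `"L-R"` (default) or `"A-P"`.
#' @return a new `dwi_volume`. Requires `vol$rim_mask` (phantom volumes
#'   carry one).
#' @export
inject_chemical_shift <- function(vol, shift_px, rim_intensity = 0.5,
                                  freq_axis = "L-R",
                                  affected_slices, affected_gradients) {
  require_canonical(vol)
  shift_px <- as.integer(shift_px)
  if (abs(shift_px) < 1L)
    stop("chemical shift requires |shift_px| >= 1 voxel")
  fa <- inplane_axis(freq_axis)
  if (abs(shift_px) > dim(vol$data)[fa] / 4)
    stop("chemical shift larger than a quarter of the field of view ",
         "is unphysical")
  if (is.null(vol$rim_mask))
    stop("volume carries no rim mask; chemical shift needs the fat-rim ",
         "component (use a phantom volume)")
  check_affected(vol, affected_slices, affected_gradients)
  for (g in affected_gradients) for (z in affected_slices) {
    sl <- vol$data[, , z, g]
    rim <- sl * vol$rim_mask[, , z]
    vol$data[, , z, g] <- sl +
      rim_intensity * translate_2d(rim, shift_px, fa)
  }
  vol
}

#' Susceptibility displacement field
#'
#' Gaussian bump of peak `max_displacement_px` voxels centred at `focus`
#' with width `sigma_px`, evaluated over an in-plane grid.
#'
#' @param dims in-plane grid size `c(nx, ny)`.
#' @param focus in-plane centre `c(x, y)` in voxel coordinates.
#' @param max_displacement_px peak displacement in voxels.
#' @param sigma_px Gaussian width in voxels.
#' @return `nx` by `ny` matrix of displacements.
#' @export
susceptibility_field <- function(dims, focus, max_displacement_px,
                                 sigma_px) {
  x <- seq_len(dims[1]) - focus[1]
  y <- seq_len(dims[2]) - focus[2]
  max_displacement_px * exp(-outer(x^2, y^2, `+`) / (2 * sigma_px^2))
}

#' Inject a susceptibility distortion
#'
#' Affected axial slices are warped by a smooth Gaussian-bump displacement
#' field along the phase-encode axis (pullback resampling with linear
#' interpolation), emulating the local geometric distortion and signal
#' pile-up near air-tissue interfaces.
#'
#' @inheritParams inject_ghosting
#' @param focus in-plane point `c(x, y)` (voxels) where distortion peaks.
#' @param max_displacement_px peak displacement in voxels (>= 0); 0 is the
#'   identity.
#' @param sigma_px width of the distortion bump in voxels.
#' @return a new `dwi_volume`.
#' @export
inject_susceptibility <- function(vol, focus, max_displacement_px,
                                  sigma_px, pe_axis = "A-P",
                                  affected_slices, affected_gradients) {
  require_canonical(vol)
  if (max_displacement_px < 0) stop("max displacement must be >= 0")
  check_affected(vol, affected_slices, affected_gradients)
  if (max_displacement_px == 0) return(vol)
  pa <- inplane_axis(pe_axis)
  d12 <- dim(vol$data)[1:2]
  disp <- susceptibility_field(d12, focus, max_displacement_px, sigma_px)
  for (g in affected_gradients) for (z in affected_slices) {
    sl <- vol$data[, , z, g]
    vol$data[, , z, g] <- warp_along_axis(sl, disp, pa)
  }
  vol
}

warp_along_axis <- function(img, disp, axis) {
  n <- dim(img)[axis]
  if (axis == 2L) {
    idx <- matrix(rep(seq_len(n), each = nrow(img)), nrow(img), n) - disp
  } else {
    idx <- matrix(rep(seq_len(n), times = ncol(img)), n, ncol(img)) - disp
  }
  idx <- pmin(pmax(idx, 1), n)
  lo <- floor(idx); hi <- pmin(lo + 1, n); w <- idx - lo
  pick <- function(src_idx) {
    if (axis == 2L) {
      flat <- (src_idx - 1) * nrow(img) + row(src_idx)
    } else {
      flat <- (col(src_idx) - 1) * nrow(img) + src_idx
    }
    matrix(img[flat], nrow(img), ncol(img))
  }
  (1 - w) * pick(lo) + w * pick(hi)
}

#' Inject motion-induced signal dropout
#'
#' Subject motion during a gradient volume attenuates whole axial slices;
#' in the sagittal view this appears as horizontal dark bands crossing
#' every sagittal slice of the affected gradient, which is why the label
#' applies sagittally.
#'
#' @inheritParams inject_ghosting
#' @param attenuation fraction in \[0, 1\]; affected slices are scaled by
#'   `1 - attenuation`. 0 is the identity.
#' @param affected_axial_slices 1-based axial slice indices attenuated.
#' @return a new `dwi_volume`.
#' @export
inject_motion_dropout <- function(vol, attenuation, affected_axial_slices,
                                  affected_gradients) {
  require_canonical(vol)
  if (attenuation < 0 || attenuation > 1)
    stop("attenuation must lie in [0, 1]")
  check_affected(vol, affected_axial_slices, affected_gradients)
  if (attenuation == 0) return(vol)
  for (g in affected_gradients)
    vol$data[, , affected_axial_slices, g] <-
      vol$data[, , affected_axial_slices, g] * (1 - attenuation)
  vol
}

#' Inject multiband interleave banding
#'
#' Every `period`-th axial slice (offset by `phase`) of the affected
#' gradients is attenuated by `modulation`, producing the slice-periodic
#' venetian-blind banding seen in sagittal views of faulty
#' simultaneous-multislice acquisitions.
#'
#' @inheritParams inject_ghosting
#' @param period slice period (integer >= 2).
#' @param modulation attenuation fraction in \[0, 1\]; 0 is the identity.
#' @param phase integer phase offset (0-based; slice `z` is attenuated when
#'   `(z - 1 - phase) mod period == 0`).
#' @return a new `dwi_volume`.
#' @export
inject_multiband_interleave <- function(vol, period, modulation, phase = 0L,
                                        affected_gradients) {
  require_canonical(vol)
  if (period < 2) stop("interleave period must be >= 2")
  if (modulation < 0 || modulation > 1)
    stop("modulation must lie in [0, 1]")
  d <- dim(vol$data)
  check_affected(vol, 1L, affected_gradients)
  if (modulation == 0) return(vol)
  z_hit <- which(((seq_len(d[3]) - 1L - phase) %% period) == 0L)
  for (g in affected_gradients)
    vol$data[, , z_hit, g] <- vol$data[, , z_hit, g] * (1 - modulation)
  vol
}

#' Views in which each artifact class is labeled
#'
#' Ghosting, herringbone, chemical shift and susceptibility manifest in
#' axial slices; motion dropout and multiband interleave banding manifest
#' in sagittal slices.
#'
#' @param type artifact type string.
#' @return `"axial"` or `"sagittal"`.
#' @export
artifact_view <- function(type) {
  switch(type,
         ghosting = , herringbone = , chemical_shift = ,
         susceptibility = "axial",
         motion_dropout = , multiband_interleave = "sagittal",
         stop("unknown artifact type: ", type))
}
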