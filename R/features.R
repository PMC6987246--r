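# Classical texture features used as comparison detectors: a Gabor filter
# bank (4 scales x 4 orientations, mean + sd of the response magnitude =
# 32 features), Zernike moment magnitudes up to order 4, and a normalized
# histogram of rotation-invariant uniform local binary patterns.

#' Gabor filter bank specification
#'
#' `n_scales * n_orientations` complex Gabor filters. Scale `s` has spatial
#' frequency `base_frequency / scale_multiplier^(s-1)` (cycles/pixel) and an
#' envelope width tied to one octave bandwidth (`sigma = 0.56 / f`);
#' orientations are spaced uniformly over 180 degrees. Kernels are made
#' zero-mean so a constant image yields (numerically) zero response.
#'
#' @param n_scales,n_orientations bank size; defaults 4 and 4.
#' @param base_frequency highest spatial frequency in cycles/pixel.
#' @param scale_multiplier frequency ratio between successive scales.
#' @param gamma spatial aspect ratio of the Gaussian envelope.
#' @return object of class `gabor_bank_spec`.
#' @export
gabor_bank_spec <- function(n_scales = 4L, n_orientations = 4L,
                            base_frequency = 0.25,
                            scale_multiplier = sqrt(2), gamma = 1) {
  stopifnot(n_scales >= 1, n_orientations >= 1, base_frequency > 0,
            scale_multiplier > 1)
  structure(list(n_scales = as.integer(n_scales),
                 n_orientations = as.integer(n_orientations),
                 base_frequency = base_frequency,
                 scale_multiplier = scale_multiplier, gamma = gamma),
            class = "gabor_bank_spec")
}

gabor_kernel <- function(freq, theta, gamma = 1) {
  sigma <- 0.56 / freq
  half <- ceiling(3 * sigma)
  g <- seq(-half, half)
  xr <- outer(g * cos(theta), g * sin(theta), `+`)
  yr <- outer(-g * sin(theta), g * cos(theta), `+`)
  env <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2))
  k <- env * exp(2i * pi * freq * xr)
  k - mean(k)  # zero DC response
}

fft_convolve <- function(img, kernel) {
  # circular convolution, kernel centred; magnitudes only are consumed
  d <- dim(img)
  kd <- dim(kernel)
  big <- matrix(0+0i, d[1], d[2])
  big[seq_len(kd[1]), seq_len(kd[2])] <- kernel
  # rotate so the kernel centre sits at (1,1)
  cshift <- function(m, s1, s2) {
    i <- ((seq_len(nrow(m)) - 1 + s1) %% nrow(m)) + 1
    j <- ((seq_len(ncol(m)) - 1 + s2) %% ncol(m)) + 1
    m[i, j]
  }
  big <- cshift(big, (kd[1] + 1) %/% 2, (kd[2] + 1) %/% 2)
  fft(fft(img) * fft(big), inverse = TRUE) / length(img)
}

#' Gabor bank features
#'
#' For each filter of the bank, the mean and standard deviation of the
#' complex response magnitude, ordered scale-major, then orientation,
#' then statistic — 32 values for the default 4 x 4 bank.
#'
#' @param image 2D numeric matrix, at least as large as the biggest
#'   kernel in the bank.
#' @param spec a [gabor_bank_spec()].
#' @return named numeric vector with attribute `scheme = "gabor"`.
#' @export
gabor_features <- function(image, spec = gabor_bank_spec()) {
  stopifnot(is.matrix(image))
  out <- numeric(0)
  for (s in seq_len(spec$n_scales)) {
    freq <- spec$base_frequency / spec$scale_multiplier^(s - 1)
    ksz <- 2 * ceiling(3 * 0.56 / freq) + 1
    if (any(dim(image) < ksz))
      stop("image (", paste(dim(image), collapse = "x"),
           ") is smaller than the scale-", s, " Gabor kernel (", ksz,
           "x", ksz, ")")
    for (o in seq_len(spec$n_orientations)) {
      theta <- (o - 1) * pi / spec$n_orientations
      mag <- Mod(fft_convolve(image, gabor_kernel(freq, theta,
                                                  spec$gamma)))
      out <- c(out, mean(mag), sd_pop(mag))
      names(out)[length(out) - 1:0] <-
        paste0("gabor_s", s, "_o", o, c("_mean", "_sd"))
    }
  }
  structure(out, scheme = "gabor")
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Zernike moment specification
#'
#' @param order maximum polynomial order `n` (default 4).
#' @param repetition the emphasised repetition `m` (default 2); with
#'   `full_set = FALSE` only the single `(order, repetition)` moment is
#'   returned.
#' @param radius_fraction disk radius as a fraction of the smaller image
#'   dimension (default 0.5, the inscribed disk).
#' @param full_set compute all valid `(n, m)` with `n <= order`, `m >= 0`,
#'   `n - m` even (9 moments for order 4) rather than the single moment.
#' @return object of class `zernike_spec`.
#' @export
zernike_spec <- function(order = 4L, repetition = 2L,
                         radius_fraction = 0.5, full_set = TRUE) {
  if (order < abs(repetition) || (order - abs(repetition)) %% 2 != 0)
    stop("invalid Zernike indices: need n >= |m| and n - |m| even")
  if (radius_fraction <= 0)
    stop("disk radius must be positive")
  structure(list(order = as.integer(order),
                 repetition = as.integer(repetition),
                 radius_fraction = radius_fraction,
                 full_set = isTRUE(full_set)),
            class = "zernike_spec")
}

zernike_nm_list <- function(spec) {
  if (!spec$full_set)
    return(list(c(spec$order, spec$repetition)))
  out <- list()
  for (n in 0:spec$order)
    for (m in seq(n %% 2, n, by = 2))
      out[[length(out) + 1L]] <- c(n, m)
  out
}

zernike_radial <- function(n, m, rho) {
  r <- numeric(length(rho))
  for (k in 0:((n - m) / 2)) {
    coef <- (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) *
         factorial((n - m) / 2 - k))
    r <- r + coef * rho^(n - 2 * k)
  }
  r
}

#' Zernike moment magnitudes
#'
#' The image is masked to a disk centred on the image and projected onto
#' the Zernike polynomial basis; magnitudes `|Z_nm|` are returned. They
#' are invariant to rotation of the image about the disk centre.
#'
#' @param image 2D numeric matrix.
#' @param spec a [zernike_spec()].
#' @return named numeric vector with attribute `scheme = "zernike"`
#'   (9 values for the default full set of order 4).
#' @export
zernike_features <- function(image, spec = zernike_spec()) {
  stopifnot(is.matrix(image))
  h <- nrow(image); w <- ncol(image)
  radius <- spec$radius_fraction * min(h, w)
  if (radius < 1) stop("disk radius below one pixel")
  cx <- (h + 1) / 2; cy <- (w + 1) / 2
  x <- (seq_len(h) - cx) / radius
  y <- (seq_len(w) - cy) / radius
  rho <- sqrt(outer(x^2, y^2, `+`))
  theta <- atan2(rep(y, each = h), rep(x, times = w))
  dim(theta) <- c(h, w)
  inside <- rho <= 1
  f <- image[inside]; rh <- rho[inside]; th <- theta[inside]
  area <- 1 / radius^2  # pixel area in unit-disk coordinates
  nm <- zernike_nm_list(spec)
  out <- vapply(nm, function(p) {
    n <- p[1]; m <- p[2]
    v <- zernike_radial(n, m, rh) * exp(-1i * m * th)
    Mod((n + 1) / pi * sum(f * v) * area)
  }, 1)
  names(out) <- vapply(nm, function(p) paste0("z", p[1], "_", p[2]), "")
  structure(out, scheme = "zernike")
}

#' Uniform local binary pattern histogram
#'
#' Each interior pixel is compared with `n_points` neighbours interpolated
#' on a circle of the given radius; rotation-invariant uniform coding maps
#' each pattern to the number of "1" bits (0..8) when the circular bit
#' string has at most two transitions, and to a residual bin otherwise.
#' The normalized 10-bin histogram is invariant to any monotone gray-level
#' shift of the image.
#'
#' @param image 2D numeric matrix, at least 3x3.
#' @param n_points number of circle samples (default 8).
#' @param radius circle radius in pixels (default 1).
#' @return named numeric vector of length `n_points + 2` summing to 1,
#'   with attribute `scheme = "lbp"`.
#' @export
lbp_features <- function(image, n_points = 8L, radius = 1) {
  stopifnot(is.matrix(image))
  h <- nrow(image); w <- ncol(image)
  if (h < 3 || w < 3) stop("image must be at least 3x3")
  b <- ceiling(radius)
  ci <- (b + 1):(h - b); cj <- (b + 1):(w - b)
  centre <- image[ci, cj]
  n_i <- length(ci); n_j <- length(cj)
  bits <- array(FALSE, c(n_i, n_j, n_points))
  for (p in seq_len(n_points)) {
    ang <- 2 * pi * (p - 1) / n_points
    dx <- radius * cos(ang); dy <- radius * sin(ang)
    x <- outer(ci + dx, rep(1, n_j)); y <- outer(rep(1, n_i), cj + dy)
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    x1 <- pmin(x0 + 1, h); y1 <- pmin(y0 + 1, w)
    at <- function(i, j) matrix(image[(j - 1) * h + i], n_i, n_j)
    nb <- (1 - fx) * (1 - fy) * at(x0, y0) + fx * (1 - fy) * at(x1, y0) +
      (1 - fx) * fy * at(x0, y1) + fx * fy * at(x1, y1)
    # snap near-exact interpolation to kill fp jitter at integer offsets
    nb[abs(nb - centre) < 1e-12] <- centre[abs(nb - centre) < 1e-12]
    bits[, , p] <- nb >= centre
  }
  ones <- apply(bits, c(1, 2), sum)
  transitions <- matrix(0L, n_i, n_j)
  for (p in seq_len(n_points)) {
    q <- if (p == n_points) 1L else p + 1L
    transitions <- transitions + (bits[, , p] != bits[, , q])
  }
  code <- ifelse(transitions <= 2L, ones, n_points + 1L)
  hist <- tabulate(code + 1L, nbins = n_points + 2L)
  hist <- hist / sum(hist)
  names(hist) <- c(paste0("lbp_u", 0:n_points), "lbp_nonuniform")
  structure(hist, scheme = "lbp")
}

#' Compute a feature matrix for a list of slices
#'
#' Applies one feature scheme to the (normalized) image of every slice.
#'
#' @param slices list of [slice_sample()].
#' @param scheme `"gabor"`, `"zernike"`, or `"lbp"`.
#' @param ... passed to the scheme's feature function.
#' @return numeric matrix, one row per slice, named columns.
#' @export
feature_matrix <- function(slices, scheme = c("gabor", "zernike", "lbp"),
                           ...) {
  scheme <- match.arg(scheme)
  fun <- switch(scheme, gabor = gabor_features,
                zernike = zernike_features, lbp = lbp_features)
  rows <- lapply(slices, function(s)
    fun(normalize_slice(s)$image, ...))
  m <- do.call(rbind, rows)
  rownames(m) <- NULL
  m
}

#' Write / read a feature matrix as CSV
#'
#' The header names each feature; values round-trip at full precision.
#'
#' @param features numeric matrix with column names.
#' @param path CSV path.
#' @return `path` (write) or the matrix (read).
#' @export
write_features <- function(features, path) {
  write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  as.matrix(read.csv(path, check.names = FALSE))
}
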