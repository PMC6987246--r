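test_that("phantom rendering is deterministic and exact without noise", {
  spec <- tiny_phantom(seed = 11)
  v1 <- make_phantom_volume(spec)
  v2 <- make_phantom_volume(spec)
  expect_identical(v1$data, v2$data)

  clean <- make_phantom_volume(tiny_phantom(noise_sigma = 0))
  vals <- sort(unique(as.vector(signif(clean$data, 10))))
  # piecewise-constant: background, rim, and each tissue times each
  # gradient attenuation
  tissue <- c(0.7, 0.5, 1)
  expected <- sort(unique(signif(c(0, 1.2, outer(tissue, c(1, 0.6))), 10)))
  expect_true(all(vals %in% expected))
  expect_true(all(expected %in% vals))

  # different seeds differ only in the noise component
  a <- make_phantom_volume(tiny_phantom(seed = 1))
  b <- make_phantom_volume(tiny_phantom(seed = 2))
  noiseless <- make_phantom_volume(tiny_phantom(noise_sigma = 0))$data
  expect_false(identical(a$data, b$data))
  expect_lt(max(abs(a$data - noiseless)), 0.15)  # bounded noise excursion
  expect_lt(abs(sd(a$data - noiseless) - sd(b$data - noiseless)), 0.001)
})

test_that("degenerate phantom specs are rejected", {
  expect_error(phantom_spec(dims = c(16, 64, 40)), ">= 32")
  expect_error(
    phantom_spec(tissues = list(list(center = c(24, 24, 16),
                                     semi_axes = c(10, 0, 5),
                                     intensity = 1))),
    "semi-axes")
  expect_error(phantom_spec(noise_sigma = -1), "sigma")
})

test_that("Rician noise has the Rayleigh background mean and is seeded", {
  img <- array(1, c(10, 10))
  expect_identical(add_rician_noise(img, 0, seed = 3), img)
  expect_error(add_rician_noise(img, -0.1), "sigma")
  n1 <- add_rician_noise(img, 0.5, seed = 9)
  expect_identical(n1, add_rician_noise(img, 0.5, seed = 9))
  expect_false(identical(n1, add_rician_noise(img, 0.5, seed = 10)))
  bg <- add_rician_noise(array(0, c(100, 100, 10)), 1, seed = 5)
  expect_lt(abs(mean(bg) / sqrt(pi / 2) - 1), 0.01)
})

clean_vol <- make_phantom_volume(
  tiny_phantom(dims = c(48L, 48L, 32L), noise_sigma = 0,
               gradients = c(1, 0.6)))

test_that("ghosting equals the image-domain half-FOV superposition", {
  v <- inject_ghosting(clean_vol, 0.4, "A-P", affected_slices = 16L,
                       affected_gradients = 1L)
  sl <- clean_vol$data[, , 16, 1]
  oracle <- sl + 0.4 * sl[, c(25:48, 1:24)]
  expect_lt(max(abs(v$data[, , 16, 1] - oracle)), 1e-8)
  # untouched elsewhere, exact identity at zero severity
  expect_identical(v$data[, , -16, ], clean_vol$data[, , -16, ])
  expect_identical(v$data[, , 16, 2], clean_vol$data[, , 16, 2])
  v0 <- inject_ghosting(clean_vol, 0, "A-P", 16L, 1L)
  expect_identical(v0$data, clean_vol$data)
  expect_error(inject_ghosting(clean_vol, 1.2, "A-P", 16L, 1L), "\\[0, 1\\]")
})

test_that("the ghost replica sits at half the FOV along phase-encode", {
  v <- inject_ghosting(clean_vol, 0.3, "A-P", 16L, 1L)
  diff <- v$data[, , 16, 1] - clean_vol$data[, , 16, 1]
  sl <- clean_vol$data[, , 16, 1]
  # circular cross-correlation along the phase-encode axis via FFT
  xc <- Re(fft(fft(colSums(diff)) * Conj(fft(colSums(sl))),
               inverse = TRUE))
  expect_identical(which.max(xc) - 1L, 24L)
})

test_that("herringbone adds exactly one conjugate spike pair", {
  v <- inject_herringbone(clean_vol, amplitude = 300, k_loc = c(5L, 9L),
                          affected_slices = 16L, affected_gradients = 1L)
  dk <- fft(v$data[, , 16, 1] - clean_vol$data[, , 16, 1])
  support <- which(Mod(dk) > 1e-6, arr.ind = TRUE)
  expect_identical(nrow(support), 2L)
  expect_setequal(paste(support[, 1], support[, 2]),
                  c("6 10", paste(48 - 5 + 1, 48 - 9 + 1)))
  expect_lt(abs(Mod(dk[6, 10]) - 300), 1e-8)

  # linearity: two spikes superpose
  v2 <- inject_herringbone(v, 150, c(11L, 3L), 16L, 1L)
  lone <- inject_herringbone(clean_vol, 150, c(11L, 3L), 16L, 1L)
  both <- (v$data[, , 16, 1] - clean_vol$data[, , 16, 1]) +
    (lone$data[, , 16, 1] - clean_vol$data[, , 16, 1])
  expect_lt(max(abs((v2$data[, , 16, 1] - clean_vol$data[, , 16, 1]) -
                      both)), 1e-8)

  expect_identical(inject_herringbone(clean_vol, 0, c(5L, 9L), 16L,
                                      1L)$data, clean_vol$data)
  expect_error(inject_herringbone(clean_vol, 10, c(0L, 0L), 16L, 1L),
               "DC")
  expect_error(inject_herringbone(clean_vol, 10, c(99L, 0L), 16L, 1L),
               "grid")
})

test_that("chemical shift is supported on the translated rim only", {
  expect_error(inject_chemical_shift(clean_vol, 0, 0.5, "L-R", 16L, 1L),
               ">= 1")
  expect_error(inject_chemical_shift(clean_vol, 40, 0.5, "L-R", 16L, 1L),
               "quarter")
  v <- inject_chemical_shift(clean_vol, 3L, 0.5, "L-R", 16L, 1L)
  diff <- v$data[, , 16, 1] - clean_vol$data[, , 16, 1]
  rim <- clean_vol$rim_mask[, , 16]
  shifted <- rbind(matrix(FALSE, 3, 48), rim[1:45, ])
  expect_true(all((abs(diff) > 1e-12) <= shifted))
  expect_gt(sum(abs(diff) > 1e-12), 0)

  # shifting the added component back restores it (away from edges)
  fwd <- dmriqc:::translate_2d(clean_vol$data[, , 16, 1] * rim, 3L, 1L)
  back <- dmriqc:::translate_2d(fwd, -3L, 1L)
  expect_identical(back, clean_vol$data[, , 16, 1] * rim)
})

test_that("susceptibility warps locally with the declared peak", {
  field <- susceptibility_field(c(48, 48), c(24, 15), 4, 5)
  expect_equal(max(field), 4)
  expect_identical(which(field == max(field), arr.ind = TRUE)[1, ],
                   c(row = 24L, col = 15L))

  v0 <- inject_susceptibility(clean_vol, c(24, 15), 0, 5, "A-P", 16L, 1L)
  expect_identical(v0$data, clean_vol$data)

  # beyond 4 sigma the image changes by < 1e-3 of the dynamic range;
  # checked on a smooth slice (interpolation error scales with gradient)
  smooth <- clean_vol
  for (g in 1:2) for (z in 1:32)
    smooth$data[, , z, g] <- smooth_test_image(48)
  vs <- inject_susceptibility(smooth, c(24, 15), 4, 5, "A-P", 16L, 1L)
  d <- abs(vs$data[, , 16, 1] - smooth$data[, , 16, 1])
  far <- outer((1:48 - 24)^2, (1:48 - 15)^2, `+`) > (4 * 5)^2
  rng <- diff(range(smooth$data[, , 16, 1]))
  expect_lt(max(d[far]), 1e-3 * rng)
  expect_gt(max(d[!far]), 1e-2 * rng)
})

test_that("motion dropout attenuates the listed axial slices", {
  v0 <- inject_motion_dropout(clean_vol, 0, c(10L, 11L), 1L)
  expect_identical(v0$data, clean_vol$data)
  v1 <- inject_motion_dropout(clean_vol, 1, c(10L, 11L), 1L)
  expect_identical(max(v1$data[, , 10:11, 1]), 0)
  expect_identical(v1$data[, , 12, 1], clean_vol$data[, , 12, 1])
  # sagittal rows at the affected z indices go dark in every sagittal slice
  expect_identical(max(v1$data[20, , 10:11, 1]), 0)

  v2 <- inject_motion_dropout(clean_vol, 0.4, c(10L, 11L), 1L)
  ratio <- mean(v2$data[, , 10, 1]) / mean(clean_vol$data[, , 10, 1])
  expect_lt(abs(ratio - 0.6), 1e-12)
})

test_that("multiband interleave hits every period-th slice", {
  cv <- constant_volume(dims = c(32L, 32L, 40L), value = 2)
  v <- inject_multiband_interleave(cv, period = 4L, modulation = 0.3,
                                   phase = 0L, affected_gradients = 1L)
  hit <- vapply(1:40, function(z) any(v$data[, , z, 1] != 2), TRUE)
  expect_identical(sum(hit), as.integer(ceiling(40 / 4)))
  expect_identical(which(hit), seq(1L, 40L, 4L))
  expect_equal(unique(as.vector(v$data[, , 5, 1])), 2 * 0.7)

  # power spectrum of the through-slice mean profile peaks at 1/period
  ph <- tiny_phantom(noise_sigma = 0, gradients = 1)
  vol <- make_phantom_volume(ph)
  vm <- inject_multiband_interleave(vol, 4L, 0.5, 0L, 1L)
  prof <- vapply(1:32, function(z) mean(vm$data[, , z, 1]), 1)
  base <- vapply(1:32, function(z) mean(vol$data[, , z, 1]), 1)
  spec_power <- Mod(fft(prof - base))[2:16]
  expect_identical(which.max(spec_power), 32L %/% 4L)  # 8 cycles/FOV

  expect_identical(inject_multiband_interleave(cv, 4L, 0, 0L, 1L)$data,
                   cv$data)
  expect_error(inject_multiband_interleave(cv, 1L, 0.3, 0L, 1L),
               "period")
})

test_that("injected energy grows with severity", {
  l2 <- function(v) sqrt(sum((v$data - clean_vol$data)^2))
  ghosts <- vapply(c(0.1, 0.25, 0.4),
                   function(a) l2(inject_ghosting(clean_vol, a, "A-P",
                                                  16L, 1L)), 1)
  spikes <- vapply(c(100, 300, 600),
                   function(a) l2(inject_herringbone(clean_vol, a,
                                                     c(5L, 9L), 16L, 1L)),
                   1)
  drops <- vapply(c(0.2, 0.5, 0.9),
                  function(a) l2(inject_motion_dropout(clean_vol, a,
                                                       10:12, 1L)), 1)
  expect_true(all(diff(ghosts) > 0))
  expect_true(all(diff(spikes) > 0))
  expect_true(all(diff(drops) > 0))
})

test_that("dataset generation is deterministic with consistent labels", {
  ph <- tiny_phantom()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  ds <- generate_dataset(ph, artifact_menu_default(), n_volumes = 8,
                         artifact_fraction = 0.5, seed = 7, out_dir = d1)
  ds2 <- generate_dataset(ph, artifact_menu_default(), n_volumes = 8,
                          artifact_fraction = 0.5, seed = 7, out_dir = d2)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))

  art_vols <- unique(ds$manifest$volume_id[ds$manifest$label ==
                                             "artifactual"])
  expect_identical(length(art_vols), 4L)

  # labels agree with the artifact specs that were applied
  for (vid in names(ds$artifact_specs)) {
    for (sp in ds$artifact_specs[[vid]]) {
      vw <- artifact_view(sp$type)
      rows <- ds$manifest[ds$manifest$volume_id == vid &
                            ds$manifest$view == vw &
                            ds$manifest$gradient_index %in%
                              sp$affected_gradients, ]
      if (vw == "sagittal") {
        expect_true(all(rows$label == "artifactual"), info = vid)
      } else {
        hit <- rows[rows$slice_index %in% sp$affected_slices, ]
        expect_true(all(hit$label == "artifactual"), info = vid)
      }
    }
  }
})

test_that("artifact-free datasets carry only clean labels", {
  ds <- generate_dataset(tiny_phantom(), artifact_menu_default(),
                         n_volumes = 3, artifact_fraction = 0,
                         seed = 3, out_dir = withr::local_tempdir())
  expect_true(all(ds$manifest$label == "artifact_free"))
  expect_true(all(ds$manifest$artifact_type == "none"))
})

test_that("manifest slice sets equal the slicing module on written files", {
  ds <- generate_dataset(tiny_phantom(), artifact_menu_default(),
                         n_volumes = 4, artifact_fraction = 0.5,
                         seed = 5, out_dir = withr::local_tempdir())
  for (v in seq_along(ds$files)) {
    vid <- sprintf("vol_%03d", v)
    vol <- load_volume(ds$files[v])
    ext <- compute_brain_extent(vol)
    m <- ds$manifest[ds$manifest$volume_id == vid, ]
    for (vw in c("axial", "sagittal")) {
      idx <- retained_slice_indices(ext, vw, 5L)
      rows <- m[m$view == vw, ]
      expect_identical(sort(unique(rows$slice_index)), idx, info = vid)
      expect_identical(nrow(rows), length(idx) * n_gradients(vol))
    }
  }
})
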