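# Labeled synthetic dataset generation: phantom volumes + randomized
# artifact injection + a slice-level manifest whose rows mirror the
# retention rules of the slicing module exactly.

#' Default artifact menu
#'
#' One template per artifact class with the documented severity ranges:
#' ghost intensity 0.1-0.5, spike amplitude 2-10 times the median |k| of
#' the slice spectrum, chemical shift 2-5 px, susceptibility displacement
#' 2-6 px, dropout attenuation 0.4-1.0, interleave modulation 0.2-0.6.
#' Severities are drawn uniformly within these ranges at generation time.
#'
#' @param types subset of artifact classes to include.
#' @return named list of menu templates.
#' @export
artifact_menu_default <- function(types = c("ghosting", "herringbone",
                                            "chemical_shift",
                                            "susceptibility",
                                            "motion_dropout",
                                            "multiband_interleave")) {
  menu <- list(
    ghosting = list(type = "ghosting", intensity = c(0.1, 0.5)),
    herringbone = list(type = "herringbone", amplitude_rel = c(2, 10)),
    chemical_shift = list(type = "chemical_shift", shift_px = c(2, 5),
                          rim_intensity = c(0.3, 0.7)),
    susceptibility = list(type = "susceptibility",
                          max_displacement_px = c(2, 6),
                          sigma_px = c(4, 8)),
    motion_dropout = list(type = "motion_dropout",
                          attenuation = c(0.4, 1.0), n_slices = c(2, 4)),
    multiband_interleave = list(type = "multiband_interleave",
                                period = c(3, 5), modulation = c(0.2, 0.6))
  )
  menu[match.arg(types, names(menu), several.ok = TRUE)]
}

runif1 <- function(rng) runif(1, rng[1], rng[2])

draw_artifact_spec <- function(template, vol, extent, margin) {
  d <- dim(vol$data)
  n_grad <- d[4]
  type <- template$type
  gradients <- sort(sample.int(n_grad, sample(1:min(2L, n_grad), 1)))
  ax_idx <- retained_slice_indices(extent, "axial", margin)
  params <- list()
  slices <- integer(0)
  if (artifact_view(type) == "axial") {
    n_sl <- min(length(ax_idx), sample(3:6, 1))
    start <- sample(seq_len(length(ax_idx) - n_sl + 1L), 1)
    slices <- ax_idx[start:(start + n_sl - 1L)]
  }
  if (type == "ghosting") {
    params$intensity <- runif1(template$intensity)
    params$pe_axis <- "A-P"
  } else if (type == "herringbone") {
    mid <- ax_idx[ceiling(length(ax_idx) / 2)]
    med_k <- stats::median(Mod(fft(vol$data[, , mid, gradients[1]])))
    params$amplitude <- runif1(template$amplitude_rel) * med_k
    params$k_loc <- c(sample(4:(d[1] %/% 3), 1), sample(4:(d[2] %/% 3), 1))
  } else if (type == "chemical_shift") {
    params$shift_px <- sample(template$shift_px[1]:template$shift_px[2], 1)
    params$rim_intensity <- runif1(template$rim_intensity)
    params$freq_axis <- "L-R"
  } else if (type == "susceptibility") {
    params$focus <- c(runif(1, 0.35, 0.65) * d[1], runif(1, 0.2, 0.4) * d[2])
    params$max_displacement_px <- runif1(template$max_displacement_px)
    params$sigma_px <- runif1(template$sigma_px)
    params$pe_axis <- "A-P"
  } else if (type == "motion_dropout") {
    params$attenuation <- runif1(template$attenuation)
    # draw from the interior band of retained axial indices so that fully
    # zeroed slices cannot shrink the detected head extent
    band <- ax_idx[seq(ceiling(length(ax_idx) * 0.25),
                       floor(length(ax_idx) * 0.75))]
    n_sl <- min(length(band), sample(template$n_slices[1]:template$n_slices[2], 1))
    start <- sample(seq_len(length(band) - n_sl + 1L), 1)
    slices <- band[start:(start + n_sl - 1L)]
  } else if (type == "multiband_interleave") {
    params$period <- sample(template$period[1]:template$period[2], 1)
    params$modulation <- runif1(template$modulation)
    params$phase <- sample(0:(params$period - 1L), 1)
  }
  artifact_spec(type, params, slices, gradients)
}

#' Construct a concrete artifact specification
#'
#' The ground-truth record of one injected artifact: its type, severity
#' parameters, and the affected axial-slice and gradient sets.
#'
#' @param type artifact class (see [artifact_view()]).
#' @param params named list of severity parameters passed to the injector.
#' @param affected_slices axial slice indices (empty for sagittal-class
#'   artifacts, which affect whole gradient volumes).
#' @param affected_gradients gradient indices.
#' @return object of class `artifact_spec`.
#' @export
artifact_spec <- function(type, params, affected_slices,
                          affected_gradients) {
  artifact_view(type)  # validates the type
  if (length(affected_gradients) == 0)
    stop("affected gradient set must be non-empty")
  structure(list(type = type, params = params,
                 affected_slices = as.integer(affected_slices),
                 affected_gradients = as.integer(affected_gradients)),
            class = "artifact_spec")
}

#' Apply an artifact specification to a volume
#'
#' @param vol a [dwi_volume()].
#' @param spec an [artifact_spec()].
#' @return the corrupted `dwi_volume`.
#' @export
apply_artifact <- function(vol, spec) {
  stopifnot(inherits(spec, "artifact_spec"))
  p <- spec$params
  switch(spec$type,
    ghosting = inject_ghosting(vol, p$intensity, p$pe_axis,
                               spec$affected_slices,
                               spec$affected_gradients),
    herringbone = inject_herringbone(vol, p$amplitude, p$k_loc,
                                     spec$affected_slices,
                                     spec$affected_gradients),
    chemical_shift = inject_chemical_shift(vol, p$shift_px,
                                           p$rim_intensity, p$freq_axis,
                                           spec$affected_slices,
                                           spec$affected_gradients),
    susceptibility = inject_susceptibility(vol, p$focus,
                                           p$max_displacement_px,
                                           p$sigma_px, p$pe_axis,
                                           spec$affected_slices,
                                           spec$affected_gradients),
    motion_dropout = inject_motion_dropout(vol, p$attenuation,
                                           spec$affected_slices,
                                           spec$affected_gradients),
    multiband_interleave = inject_multiband_interleave(
      vol, p$period, p$modulation, p$phase, spec$affected_gradients)
  )
}

manifest_rows <- function(volume_id, view, gradients, slice_idx) {
  if (length(slice_idx) == 0 || length(gradients) == 0)
    return(NULL)
  expand.grid(volume_id = volume_id, gradient_index = gradients,
              view = view, slice_index = slice_idx,
              stringsAsFactors = FALSE)
}

#' Generate a labeled synthetic dataset
#'
#' Writes `n_volumes` phantom NIfTI volumes to `out_dir`, injecting one or
#' two randomly drawn artifacts from `artifact_menu` into an
#' `artifact_fraction` of them, and a `manifest.csv` with one row per
#' retained slice per view carrying the ground-truth label. Axial-class
#' artifacts label their affected (slice, gradient) pairs in the axial
#' view; sagittal-class artifacts label every retained sagittal slice of
#' the affected gradients. A `dataset.json` sidecar records the phantom
#' spec, seeds and artifact draws for exact replay.
#'
#' @param phantom a [phantom_spec()]; per-volume noise seeds are derived
#'   from `seed`.
#' @param artifact_menu menu of templates, see [artifact_menu_default()].
#' @param n_volumes number of 4D volumes to write.
#' @param artifact_fraction fraction of volumes receiving artifacts; the
#'   artifactual count is `round(n_volumes * artifact_fraction)`.
#' @param seed master RNG seed; all drawn quantities derive from it.
#' @param out_dir output directory (created if needed).
#' @param margin slice-exclusion margin used for the manifest (default 5).
#' @return object of class `labeled_dataset`: `dir`, `manifest`
#'   (data.frame), `files`, and the per-volume artifact specs.
#' @export
generate_dataset <- function(phantom, artifact_menu = artifact_menu_default(),
                             n_volumes, artifact_fraction, seed = 1L,
                             out_dir, margin = 5L) {
  stopifnot(inherits(phantom, "phantom_spec"))
  if (artifact_fraction < 0 || artifact_fraction > 1)
    stop("artifact_fraction must lie in [0, 1]")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory '", out_dir, "'")
  n_art <- round(n_volumes * artifact_fraction)
  rows <- list(); files <- character(n_volumes); all_specs <- list()
  with_seed(seed, {
    art_ids <- if (n_art > 0) sort(sample.int(n_volumes, n_art)) else integer(0)
    for (v in seq_len(n_volumes)) {
      vid <- sprintf("vol_%03d", v)
      ph <- phantom
      ph$seed <- phantom$seed + v * 1000L + seed
      vol <- make_phantom_volume(ph)
      clean_extent <- compute_brain_extent(vol)
      specs <- list()
      if (v %in% art_ids) {
        n_a <- sample(1:2, 1)
        picks <- sample(seq_along(artifact_menu), n_a,
                        replace = length(artifact_menu) < 2)
        for (p in picks)
          specs[[length(specs) + 1L]] <-
            draw_artifact_spec(artifact_menu[[p]], vol, clean_extent,
                               margin)
        for (sp in specs) vol <- apply_artifact(vol, sp)
        vol$data <- pmax(vol$data, 0)  # magnitude floor after injection
        dim(vol$data) <- c(ph$dims, length(ph$gradient_attenuation))
      }
      path <- file.path(out_dir, paste0(vid, ".nii.gz"))
      write_volume(vol, path)
      files[v] <- path
      extent <- compute_brain_extent(vol)
      ax_idx <- retained_slice_indices(extent, "axial", margin)
      sg_idx <- retained_slice_indices(extent, "sagittal", margin)
      grads <- seq_along(ph$gradient_attenuation)
      df <- rbind(manifest_rows(vid, "axial", grads, ax_idx),
                  manifest_rows(vid, "sagittal", grads, sg_idx))
      df$label <- "artifact_free"
      df$artifact_type <- "none"
      df$severity_json <- ""
      for (sp in specs) {
        vw <- artifact_view(sp$type)
        sev <- as.character(jsonlite::toJSON(sp$params, auto_unbox = TRUE,
                                             digits = NA))
        hit <- if (vw == "axial") {
          df$view == "axial" &
            df$gradient_index %in% sp$affected_gradients &
            df$slice_index %in% sp$affected_slices
        } else {
          df$view == "sagittal" &
            df$gradient_index %in% sp$affected_gradients
        }
        df$label[hit] <- "artifactual"
        df$artifact_type[hit] <- sp$type
        df$severity_json[hit] <- sev
      }
      rows[[v]] <- df
      all_specs[[vid]] <- specs
    }
  })
  manifest <- do.call(rbind, rows)
  ord <- order(manifest$volume_id, manifest$view, manifest$gradient_index,
               manifest$slice_index)
  manifest <- manifest[ord, , drop = FALSE]
  rownames(manifest) <- NULL
  write.csv(manifest, file.path(out_dir, "manifest.csv"),
            row.names = FALSE)
  sidecar <- list(
    phantom = unclass(phantom), seed = seed, n_volumes = n_volumes,
    artifact_fraction = artifact_fraction, margin = margin,
    artifacts = lapply(all_specs, function(sl) lapply(sl, unclass))
  )
  jsonlite::write_json(sidecar, file.path(out_dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(dir = out_dir, manifest = manifest, files = files,
                 artifact_specs = all_specs),
            class = "labeled_dataset")
}

#' Read a dataset manifest
#' @param path manifest CSV or dataset directory.
#' @return data.frame of manifest rows.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  read.csv(path, stringsAsFactors = FALSE)
}
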