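# Calibrated stack input/output. Axis convention throughout the package:
# voxels indexed (z, channel, y, x); y grows downward, x rightward;
# pixel coordinates are 0-based; bounding boxes are half-open.

#' Construct a calibrated multi-channel z-stack
#'
#' @param voxels 4-D numeric array indexed `(z, channel, y, x)`. 2-D or 3-D
#'   input is promoted by inserting singleton z/channel axes.
#' @param pixel_size physical pixel size, micrometres per pixel (isotropic x,y).
#' @param z_spacing micrometres between consecutive z-slices; may be `NA`
#'   for single-slice stacks.
#' @param channel_roles named list/vector mapping roles (`dextran`, `gfp`,
#'   `dapi`) to 1-based channel indices.
#' @return a `CalibratedStack`.
#' @export
calibrated_stack <- function(voxels, pixel_size, z_spacing = NA_real_,
                             channel_roles = list(dextran = 1L)) {
  d <- dim(voxels)
  if (is.null(d)) stop_input("voxels must be an array")
  if (length(d) == 2) dim(voxels) <- c(1L, 1L, d)
  if (length(d) == 3) dim(voxels) <- c(d[1], 1L, d[2], d[3])
  d <- dim(voxels)
  if (length(d) != 4) stop_input("voxels must be (z, channel, y, x)")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop_config("pixel_size must be a single positive number (um/px)")
  if (d[1] > 1 && (is.na(z_spacing) || z_spacing <= 0))
    stop_config("z_spacing must be positive for multi-slice stacks")
  channel_roles <- as.list(channel_roles)
  if (!length(channel_roles) || is.null(names(channel_roles)))
    stop_config("channel_roles must be a named mapping")
  bad <- setdiff(names(channel_roles), c("dextran", "gfp", "dapi"))
  if (length(bad)) stop_config("unknown channel role(s): ", paste(bad, collapse = ", "))
  idx <- unlist(channel_roles)
  if (any(idx < 1 | idx > d[2]))
    stop_config("channel role index out of range (stack has ", d[2], " channel(s))")
  structure(
    list(voxels = voxels, pixel_size = as.numeric(pixel_size),
         z_spacing = as.numeric(z_spacing),
         channel_roles = lapply(channel_roles, as.integer)),
    class = "CalibratedStack"
  )
}

#' @export
print.CalibratedStack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("CalibratedStack: %d slice(s) x %d channel(s) x %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  pixel size %.4g um/px, z spacing %.4g um\n",
              x$pixel_size, x$z_spacing))
  cat("  roles:", paste(names(x$channel_roles), unlist(x$channel_roles),
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}

.default_roles <- function(n_channels) {
  switch(as.character(n_channels),
    `1` = list(dextran = 1L),
    `2` = list(dextran = 1L, dapi = 2L),
    `3` = list(dextran = 1L, gfp = 2L, dapi = 3L),
    stop_config("no default channel-role mapping for ", n_channels,
                " channels; supply channel_roles")
  )
}

.parse_description <- function(desc) {
  out <- list()
  if (is.null(desc)) return(out)
  grab <- function(pattern) {
    m <- regmatches(desc, regexec(pattern, desc))[[1]]
    if (length(m) >= 2) as.numeric(m[2]) else NULL
  }
  # ImageJ hyperstack keys
  out$channels <- grab("channels=([0-9]+)")
  out$slices <- grab("slices=([0-9]+)")
  out$spacing <- grab("spacing=([0-9.eE+-]+)")
  # OME-XML physical sizes
  if (is.null(out$spacing)) out$spacing <- grab("PhysicalSizeZ=\"([0-9.eE+-]+)\"")
  out$pixel_size <- grab("PhysicalSizeX=\"([0-9.eE+-]+)\"")
  if (is.null(out$channels)) out$channels <- grab("SizeC=\"([0-9]+)\"")
  if (is.null(out$slices)) out$slices <- grab("SizeZ=\"([0-9]+)\"")
  out
}

#' Read a calibrated z-stack from TIFF
#'
#' Calibration precedence: `calibration_override` > image description
#' metadata (ImageJ hyperstack / OME physical sizes) > TIFF resolution tags.
#' Missing pixel size after all three is a configuration error: the analysis
#' is calibrated in micrometres and must not silently assume 1 um/px.
#' RGB pages map red->dextran, green->gfp, blue->dapi unless overridden.
#'
#' @param path TIFF or OME-TIFF file (uncompressed baseline).
#' @param calibration_override optional list with any of `pixel_size`,
#'   `z_spacing`, `channel_roles`, `n_channels`.
#' @return a [calibrated_stack()].
#' @export
read_stack <- function(path, calibration_override = NULL) {
  tf <- read_tiff(path)
  ov <- calibration_override %||% list()
  meta <- .parse_description(tf$description)

  rgb <- length(dim(tf$pages[[1]])) == 3
  if (rgb) {
    nz <- length(tf$pages)
    nc <- 3L
    ny <- dim(tf$pages[[1]])[1]; nx <- dim(tf$pages[[1]])[2]
    vox <- array(0, dim = c(nz, nc, ny, nx))
    for (z in seq_len(nz)) for (ch in 1:3) vox[z, ch, , ] <- tf$pages[[z]][, , ch]
    roles <- list(dextran = 1L, gfp = 2L, dapi = 3L)
  } else {
    nc <- as.integer(ov$n_channels %||% meta$channels %||% 1L)
    npg <- length(tf$pages)
    if (npg %% nc != 0)
      stop_input("page count ", npg, " not divisible by channel count ", nc,
                 " in ", path)
    nz <- npg %/% nc
    ny <- nrow(tf$pages[[1]]); nx <- ncol(tf$pages[[1]])
    shapes <- vapply(tf$pages, function(p) paste(dim(p), collapse = "x"), "")
    if (length(unique(shapes)) != 1)
      stop_input("TIFF pages differ in shape in ", path)
    vox <- array(0, dim = c(nz, nc, ny, nx))
    # ImageJ hyperstack page order: channel fastest, then slice
    for (z in seq_len(nz)) for (ch in seq_len(nc))
      vox[z, ch, , ] <- tf$pages[[(z - 1L) * nc + ch]]
    roles <- .default_roles(nc)
  }

  pixel_size <- ov$pixel_size %||% meta$pixel_size %||%
    (if (!is.na(tf$pixel_size)) tf$pixel_size else NULL)
  if (is.null(pixel_size))
    stop_config("no pixel size in metadata of ", path,
                "; supply calibration_override$pixel_size")
  z_spacing <- ov$z_spacing %||% meta$spacing %||% NA_real_
  if (nz > 1 && (is.na(z_spacing) || z_spacing <= 0))
    stop_config("no z spacing in metadata of ", path,
                "; supply calibration_override$z_spacing")
  if (!is.null(ov$channel_roles)) roles <- ov$channel_roles

  st <- calibrated_stack(vox, pixel_size, z_spacing, roles)
  st$bit_depth <- tf$bits
  st$source <- path
  st
}

#' Write a calibrated stack as an ImageJ-style hyperstack TIFF
#'
#' Grayscale multi-page, channel-fastest page order, 16-bit by default;
#' integer voxel data round-trips bit-exactly through [read_stack()].
#'
#' @param stack a `CalibratedStack`.
#' @param path output file.
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "CalibratedStack"))
  d <- dim(stack$voxels)
  pages <- vector("list", d[1] * d[2])
  for (z in seq_len(d[1])) for (ch in seq_len(d[2]))
    pages[[(z - 1L) * d[2] + ch]] <- stack$voxels[z, ch, , ]
  spacing <- if (is.na(stack$z_spacing)) 0 else stack$z_spacing
  desc <- paste0("ImageJ=1.53\nimages=", length(pages),
                 "\nchannels=", d[2], "\nslices=", d[1],
                 "\nhyperstack=true\nmode=grayscale\nunit=micron\nspacing=",
                 format(spacing, digits = 10), "\n")
  write_tiff(path, pages, bits = bits, pixel_size = stack$pixel_size,
             description = desc)
}

#' Extract one channel as a z-ordered list of 2-D images
#'
#' @param stack a `CalibratedStack`.
#' @param role one of the roles declared in `stack$channel_roles`.
#' @return list of `ChannelImage` (fields `pixels`, `pixel_size`, `role`,
#'   `bit_depth`), one per z-slice.
#' @export
split_channel <- function(stack, role) {
  stopifnot(inherits(stack, "CalibratedStack"))
  if (!role %in% names(stack$channel_roles))
    stop_config("channel role '", role, "' not declared in stack (has: ",
                paste(names(stack$channel_roles), collapse = ", "), ")")
  ch <- stack$channel_roles[[role]]
  nz <- dim(stack$voxels)[1]
  bd <- stack$bit_depth %||% (if (max(stack$voxels) > 255) 16L else 8L)
  lapply(seq_len(nz), function(z) {
    channel_image(stack$voxels[z, ch, , ], stack$pixel_size, role, bd)
  })
}

#' @rdname split_channel
#' @param pixels 2-D intensity matrix.
#' @param pixel_size um/px, inherited unchanged from the parent stack.
#' @param bit_depth source bit depth tag (8 or 16).
#' @export
channel_image <- function(pixels, pixel_size, role, bit_depth = 8L) {
  stopifnot(is.matrix(pixels))
  structure(list(pixels = pixels, pixel_size = pixel_size, role = role,
                 bit_depth = as.integer(bit_depth)),
            class = "ChannelImage")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.field_row <- function(r) {
  data.frame(
    image_id = r$image_id, condition = r$condition, replicate = r$replicate,
    mp_count = r$mp_count, mp_total_area_um2 = r$mp_total_area_um2,
    mp_avg_size_um2 = r$mp_avg_size_um2, mp_intden = r$mp_intden_total,
    nucleus_count = r$nucleus_count,
    mp_per_cell = if (r$valid) r$mp_per_cell else NA_real_,
    mp_per_100_cells = if (r$valid) r$mp_per_100_cells else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Write the tabular outputs of a run
#'
#' Produces `per_field.csv` (one row per image), `per_particle.csv`,
#' `summary.csv` (one row per condition) and `manifest.json` recording the
#' single parameter set used for the whole experiment.
#'
#' @param results list of `FieldResult` (see [normalize_per_cell()]).
#' @param summaries list/data.frame of condition summaries
#'   (see [summarize_condition()]).
#' @param out_dir output directory, created if absent.
#' @param manifest named list of run parameters for `manifest.json`.
#' @return named character vector of the written paths, invisibly.
#' @export
write_results <- function(results, summaries, out_dir, manifest = list()) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop_io("output directory not writable: ", out_dir)

  empty_field <- .field_row(list(image_id = "x", condition = "x", replicate = "x",
                                 mp_count = 0L, mp_total_area_um2 = 0,
                                 mp_avg_size_um2 = 0, mp_intden_total = 0,
                                 nucleus_count = 0L, mp_per_cell = 0,
                                 mp_per_100_cells = 0, valid = TRUE))[0, ]
  per_field <- if (length(results)) {
    do.call(rbind, lapply(results, .field_row))
  } else empty_field

  pp_cols <- c("image_id", "particle_id", "area_um2", "equiv_diameter_um",
               "centroid_x_px", "centroid_y_px", "integrated_density",
               "in_gfp_mask")
  per_particle <- do.call(rbind, c(list(
    data.frame(image_id = character(), particle_id = integer(),
               area_um2 = numeric(), equiv_diameter_um = numeric(),
               centroid_x_px = numeric(), centroid_y_px = numeric(),
               integrated_density = numeric(), in_gfp_mask = logical(),
               stringsAsFactors = FALSE)),
    lapply(results, function(r) {
      p <- r$particles
      if (!nrow(p)) return(NULL)
      data.frame(image_id = r$image_id, particle_id = p$particle_id,
                 area_um2 = p$area_um2, equiv_diameter_um = p$equiv_diameter_um,
                 centroid_x_px = p$centroid_x_px, centroid_y_px = p$centroid_y_px,
                 integrated_density = p$integrated_density,
                 in_gfp_mask = p$in_gfp_mask, stringsAsFactors = FALSE)
    })))[, pp_cols]

  summary_df <- if (is.data.frame(summaries)) summaries else
    do.call(rbind, summaries)
  if (is.null(summary_df))
    summary_df <- data.frame(condition = character(),
                             mean_mp_per_100_cells = numeric(), sem = numeric(),
                             n_replicates = integer(), n_cells_total = integer(),
                             under_sampled = logical(), stringsAsFactors = FALSE)

  paths <- c(per_field = file.path(out_dir, "per_field.csv"),
             per_particle = file.path(out_dir, "per_particle.csv"),
             summary = file.path(out_dir, "summary.csv"),
             manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(per_field, paths["per_field"], row.names = FALSE)
  utils::write.csv(per_particle, paths["per_particle"], row.names = FALSE)
  utils::write.csv(summary_df, paths["summary"], row.names = FALSE)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(paths)
}
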