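# Batch orchestration: the identical parameter set applied to every image
# of an experiment, in the published step order, with a JSON manifest.
# There is deliberately no way to override a parameter for a single image.

#' Default experiment configuration
#'
#' One parameter block for the whole experiment. `"auto"` entries resolve
#' once per batch from the (uniform) pixel size:
#' rolling-ball radius = 3x the largest macropinosome diameter in pixels,
#' watershed peak separation = the smallest diameter in pixels.
#' `conversion_mode = "batch_range"` maps the global min/max over all
#' projected images of a channel role onto 0-255 in a first pass, so the
#' 8-bit conversion, like acquisition, is constant across the experiment.
#'
#' @return nested named list of parameters.
#' @export
default_config <- function() {
  list(
    preprocess = list(
      rolling_ball_radius_px = "auto",
      conversion_mode = "batch_range",   # or "source_depth" / "fixed_range"
      conversion_min = NULL,
      conversion_max = NULL
    ),
    segmentation = list(
      dextran_threshold = list(method = "robust_background", value = NULL, k = 6),
      gfp_threshold = list(method = "otsu", value = NULL, k = 6),
      dapi_threshold = list(method = "otsu", value = NULL, k = 6),
      watershed = list(enabled = TRUE, min_peak_separation_px = "auto",
                       tolerance = 0.2),
      mask_mode = "pixel_and",
      overlap_fraction = 0.5,
      min_cell_area_um2 = 50
    ),
    particles = list(
      size_filter = list(min_area_um2 = 0.2, max_area_um2 = 20.0),
      min_nucleus_area_um2 = 30,
      exclude_border_particles = FALSE
    ),
    use_gfp_mask = FALSE,
    continue_on_error = FALSE,
    random_seed = NULL
  )
}

.merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    key <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base))
      stop_config("unknown configuration key: ", key)
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) && is.list(user[[k]])) {
      base[[k]] <- .merge_config(base[[k]], user[[k]], key)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Load and validate an experiment configuration
#'
#' @param config named list of overrides, or path to a YAML file with the
#'   same structure as [default_config()]. Unknown keys are configuration
#'   errors — in particular, per-image overrides do not exist in the schema.
#' @return validated full configuration list.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_config("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- .merge_config(default_config(), config)
  sf <- cfg$particles$size_filter
  size_filter(sf$min_area_um2, sf$max_area_um2)  # validates
  if (!cfg$segmentation$mask_mode %in% c("pixel_and", "whole_particle"))
    stop_config("mask_mode must be pixel_and or whole_particle")
  for (th in c("dextran_threshold", "gfp_threshold", "dapi_threshold")) {
    t <- cfg$segmentation[[th]]
    if (!t$method %in% c("otsu", "fixed", "robust_background"))
      stop_config(th, "$method must be otsu, fixed or robust_background")
    if (t$method == "fixed" && (is.null(t$value) || t$value < 0 || t$value > 255))
      stop_config(th, " fixed value must lie in [0, 255]")
  }
  cfg
}

#' Load and validate a sample sheet
#'
#' @param samples data.frame or CSV path with columns `path`, `condition`,
#'   `replicate` and optionally `image_id` (defaults to the file base name).
#'   Any other column is rejected: parameters are per-experiment, never
#'   per-image.
#' @param check_files require every referenced file to exist.
#' @return validated data.frame.
#' @export
load_samples <- function(samples, check_files = TRUE) {
  if (is.character(samples)) {
    if (!file.exists(samples)) stop_config("sample sheet not found: ", samples)
    samples <- utils::read.csv(samples, stringsAsFactors = FALSE)
  }
  required <- c("path", "condition", "replicate")
  missing <- setdiff(required, names(samples))
  if (length(missing))
    stop_config("sample sheet lacks column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(samples), c(required, "image_id"))
  if (length(extra))
    stop_config("sample sheet has unsupported column(s): ",
                paste(extra, collapse = ", "),
                " (per-image parameter overrides are not part of the schema)")
  if (!nrow(samples)) stop_config("sample sheet is empty")
  if (!"image_id" %in% names(samples))
    samples$image_id <- sub("\\.[^.]*$", "", basename(samples$path))
  if (anyDuplicated(samples$image_id))
    stop_config("duplicate image_id in sample sheet")
  if (check_files) {
    absent <- samples$path[!file.exists(samples$path)]
    if (length(absent))
      stop_config("sample sheet references missing file(s): ",
                  paste(utils::head(absent, 3), collapse = ", "))
  }
  samples$replicate <- as.character(samples$replicate)
  samples$condition <- as.character(samples$condition)
  samples
}

# Project + convert + background-subtract one channel role of a stack.
# The GFP channel is projected and converted but NOT ball-subtracted: cell
# footprints are wider than any practical rolling ball, so the opening
# would classify the footprint itself as background and erase the signal
# the cell mask is built from.
.preprocess_role <- function(stack, role, cfg, conv_range = NULL, radius = NULL) {
  proj <- max_project(split_channel(stack, role))
  pp <- cfg$preprocess
  img8 <- switch(pp$conversion_mode,
    source_depth = to_8bit(proj, "source_depth"),
    fixed_range = to_8bit(proj, "fixed_range", pp$conversion_min, pp$conversion_max),
    batch_range = {
      rng <- conv_range %||% range(proj$pixels)
      if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1
      to_8bit(proj, "fixed_range", rng[1], rng[2])
    },
    stop_config("unknown conversion_mode: ", pp$conversion_mode)
  )
  if (role == "gfp") return(img8)
  radius <- radius %||% (
    if (identical(pp$rolling_ball_radius_px, "auto"))
      default_rolling_ball_radius(stack$pixel_size)
    else as.integer(pp$rolling_ball_radius_px))
  rb <- rolling_ball_subtract(img8, radius)
  rb$corrected
}

# Segment + measure from already-corrected projected images.
.quantify_field <- function(corr, cfg, image_id, condition, replicate,
                            cutoffs = list()) {
  seg <- cfg$segmentation
  ps <- corr$dextran$pixel_size
  thr <- function(img, spec, resolved) {
    if (is.null(resolved))
      resolved <- .resolve_cutoff(.hist256(.pixels_of(img)), spec$method,
                                  spec$value, spec$k %||% 6)
    threshold_binary(img, "fixed", resolved)
  }
  mask <- thr(corr$dextran, seg$dextran_threshold, cutoffs$dextran)
  sep <- if (identical(seg$watershed$min_peak_separation_px, "auto"))
    default_min_peak_separation(ps) else as.integer(seg$watershed$min_peak_separation_px)
  tol <- seg$watershed$tolerance %||% 0.2
  if (isTRUE(seg$watershed$enabled)) mask <- watershed_split(mask, sep, tol)

  gfp_mask <- NULL
  if (isTRUE(cfg$use_gfp_mask)) {
    gcut <- cutoffs$gfp %||% .resolve_cutoff(
      .hist256(corr$gfp$pixels), seg$gfp_threshold$method,
      seg$gfp_threshold$value, seg$gfp_threshold$k %||% 6)
    gfp_mask <- make_cell_mask(corr$gfp, "fixed", gcut, seg$min_cell_area_um2)
    mask <- apply_mask(mask, gfp_mask, seg$mask_mode, seg$overlap_fraction)
  }

  sf <- size_filter(cfg$particles$size_filter$min_area_um2,
                    cfg$particles$size_filter$max_area_um2)
  particles <- analyze_particles(mask, corr$dextran, sf,
                                 cfg$particles$exclude_border_particles,
                                 gfp_mask = gfp_mask)

  dmask <- thr(corr$dapi, seg$dapi_threshold, cutoffs$dapi)
  dmask$pixels <- cpp_fill_holes(dmask$pixels)
  dmask <- watershed_split(dmask, sep, tol)
  nuclei <- count_nuclei(dmask, cfg$particles$min_nucleus_area_um2)

  normalize_per_cell(particles, nuclei, image_id, condition, replicate)
}

#' Quantify a single field
#'
#' Executes the published step order on one stack: dextran channel split ->
#' maximum projection -> 8-bit -> rolling-ball subtraction -> threshold ->
#' optional watershed -> optional GFP-mask superimposition -> particle
#' analysis; DAPI channel likewise through nucleus segmentation and
#' counting; then per-cell normalization. A standalone field resolves
#' auto/otsu parameters from itself; within [run_batch()] they are resolved
#' once per batch instead.
#'
#' @param stack a `CalibratedStack` declaring `dextran` and `dapi` roles
#'   (and `gfp` when `use_gfp_mask`).
#' @param config configuration accepted by [load_config()].
#' @param image_id,condition,replicate identifiers for the outputs.
#' @return a `FieldResult`.
#' @export
run_field <- function(stack, config = list(), image_id = "field",
                      condition = NA_character_, replicate = NA_character_) {
  cfg <- load_config(config)
  roles <- c("dextran", "dapi", if (isTRUE(cfg$use_gfp_mask)) "gfp")
  missing <- setdiff(roles, names(stack$channel_roles))
  if (length(missing))
    stop_config("stack lacks required channel role(s): ",
                paste(missing, collapse = ", "))
  corr <- lapply(stats::setNames(roles, roles), function(role)
    .preprocess_role(stack, role, cfg))
  .quantify_field(corr, cfg, image_id, condition, replicate)
}

#' Run a whole experiment batch
#'
#' Every image of the sample sheet is processed with one parameter set.
#' Batch-resolved parameters: the 8-bit conversion range per channel role
#' (global min/max of the projections, for `batch_range`), the rolling-ball
#' radius, and — for Otsu thresholds — one cutoff per channel role computed
#' from the pooled histogram of all corrected images of that role. An
#' unreadable image aborts the batch (fail-fast) unless
#' `continue_on_error = TRUE`, in which case the field is recorded as
#' failed; silent drop-out would bias per-condition means.
#'
#' @param config configuration accepted by [load_config()].
#' @param samples sample sheet accepted by [load_samples()].
#' @param out_dir optional output directory for
#'   `per_field.csv` / `per_particle.csv` / `summary.csv` / `manifest.json`.
#' @param stacks optional named list of pre-loaded `CalibratedStack`s keyed
#'   by `image_id`, bypassing file reads (used by the simulator).
#' @param verbose emit per-field progress messages.
#' @return list with `fields` (FieldResults), `summaries` (data.frame),
#'   `manifest` (list), `failed` (character vector of failed image ids).
#' @export
run_batch <- function(config = list(), samples, out_dir = NULL, stacks = NULL,
                      verbose = FALSE) {
  cfg <- load_config(config)
  samples <- load_samples(samples, check_files = is.null(stacks))
  samples <- samples[order(samples$image_id), , drop = FALSE]  # order-invariant

  say <- function(...) if (verbose) message(...)
  failed <- character()
  loaded <- list()
  for (i in seq_len(nrow(samples))) {
    id <- samples$image_id[i]
    st <- tryCatch(
      if (!is.null(stacks)) stacks[[id]] else read_stack(samples$path[i]),
      error = function(e) {
        if (isTRUE(cfg$continue_on_error)) {
          warning("field ", id, " failed to load: ", conditionMessage(e),
                  call. = FALSE)
          NULL
        } else stop_input("field ", id, ": ", conditionMessage(e))
      })
    if (is.null(st)) { failed <- c(failed, id); next }
    loaded[[id]] <- st
  }
  if (!length(loaded)) stop_input("no readable fields in the batch")

  ps <- unique(vapply(loaded, `[[`, 0, "pixel_size"))
  if (length(ps) > 1)
    stop_config("mixed pixel sizes in one batch (", paste(ps, collapse = ", "),
                "); an experiment must share acquisition settings")

  roles <- c("dextran", "dapi", if (isTRUE(cfg$use_gfp_mask)) "gfp")
  radius <- if (identical(cfg$preprocess$rolling_ball_radius_px, "auto"))
    default_rolling_ball_radius(ps) else
    as.integer(cfg$preprocess$rolling_ball_radius_px)

  # pass 1: project, resolve the batch conversion range per role
  say("pass 1/3: projecting ", length(loaded), " field(s)")
  projections <- lapply(loaded, function(st)
    lapply(stats::setNames(roles, roles), function(role)
      max_project(split_channel(st, role))))
  conv_range <- lapply(stats::setNames(roles, roles), function(role) {
    rng <- range(vapply(projections, function(p) range(p[[role]]$pixels),
                        numeric(2)))
    if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1
    rng
  })

  # pass 2: 8-bit + rolling ball; pool histograms per role for batch Otsu
  say("pass 2/3: background subtraction (rolling ball r=", radius, " px)")
  pp <- cfg$preprocess
  corrected <- lapply(projections, function(p)
    lapply(stats::setNames(roles, roles), function(role) {
      img8 <- switch(pp$conversion_mode,
        source_depth = to_8bit(p[[role]], "source_depth"),
        fixed_range = to_8bit(p[[role]], "fixed_range", pp$conversion_min,
                              pp$conversion_max),
        batch_range = to_8bit(p[[role]], "fixed_range",
                              conv_range[[role]][1], conv_range[[role]][2]),
        stop_config("unknown conversion_mode: ", pp$conversion_mode))
      # footprint channel keeps its background (see .preprocess_role)
      if (role == "gfp") img8 else rolling_ball_subtract(img8, radius)$corrected
    }))

  spec_of <- function(role) switch(role,
    dextran = cfg$segmentation$dextran_threshold,
    dapi = cfg$segmentation$dapi_threshold,
    gfp = cfg$segmentation$gfp_threshold)
  cutoffs <- lapply(stats::setNames(roles, roles), function(role) {
    spec <- spec_of(role)
    pooled <- Reduce(`+`, lapply(corrected, function(co) .hist256(co[[role]]$pixels)))
    .resolve_cutoff(pooled, spec$method, spec$value, spec$k %||% 6)
  })

  # pass 3: segment and measure
  say("pass 3/3: segmentation and particle analysis")
  fields <- list()
  for (id in names(corrected)) {
    row <- samples[samples$image_id == id, ]
    res <- tryCatch(
      .quantify_field(corrected[[id]], cfg, id, row$condition, row$replicate,
                      cutoffs = cutoffs),
      error = function(e) {
        if (isTRUE(cfg$continue_on_error)) {
          warning("field ", id, " failed: ", conditionMessage(e), call. = FALSE)
          NULL
        } else stop(mq_error(paste0("field ", id, ": ", conditionMessage(e)),
                             "mq_runtime_error"))
      })
    if (is.null(res)) { failed <- c(failed, id); next }
    if (!res$valid) say("field ", id, ": zero nuclei, flagged invalid")
    fields[[id]] <- res
  }

  conds <- unique(vapply(fields, `[[`, "", "condition"))
  summaries <- do.call(rbind, lapply(conds, function(cd) {
    summarize_condition(Filter(function(r) r$condition == cd, fields), cd)
  }))
  for (i in seq_len(nrow(summaries))) {
    if (summaries$under_sampled[i])
      say("condition '", summaries$condition[i],
          "': a replicate has fewer than 200 cells")
  }

  manifest <- list(
    package = "macroquant",
    version = as.character(utils::packageVersion("macroquant")),
    parameters = cfg,
    resolved = list(
      pixel_size_um = ps,
      rolling_ball_radius_px = radius,
      conversion_range = conv_range,
      threshold_cutoffs = cutoffs,
      watershed_min_peak_separation_px =
        if (identical(cfg$segmentation$watershed$min_peak_separation_px, "auto"))
          default_min_peak_separation(ps)
        else cfg$segmentation$watershed$min_peak_separation_px
    ),
    n_fields = length(fields),
    failed_fields = failed
  )
  if (!is.null(out_dir))
    write_results(fields, summaries, out_dir, manifest)
  list(fields = fields, summaries = summaries, manifest = manifest,
       failed = failed)
}
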