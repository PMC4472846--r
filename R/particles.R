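# Step 4-7: connected-component particle analysis with calibrated size
# filtering, nucleus counting and per-cell normalization.

#' Calibrated particle size filter
#'
#' The defaults implement the published filter: an area of 0.2-20.0 um^2,
#' excluding structures below 0.5 um or over 5.0 um in equivalent-circle
#' diameter. Bounds are inclusive at both ends.
#'
#' @param min_area_um2 lower area bound, um^2.
#' @param max_area_um2 upper area bound, um^2.
#' @return a `SizeFilter`.
#' @export
size_filter <- function(min_area_um2 = 0.2, max_area_um2 = 20.0) {
  if (!(min_area_um2 >= 0 && min_area_um2 < max_area_um2))
    stop_config("size filter needs 0 <= min < max (got [",
                min_area_um2, ", ", max_area_um2, "])")
  structure(list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2),
            class = "SizeFilter")
}

.measure_components <- function(lab, ny, nx, ps, intensity) {
  n <- max(lab)
  idx <- which(lab > 0)
  l <- lab[idx]
  # 0-based pixel coordinates
  y0 <- (idx - 1L) %% ny
  x0 <- (idx - 1L) %/% ny
  lf <- factor(l, levels = seq_len(n))
  npx <- tabulate(l, nbins = n)
  sum_y <- rowsum(as.numeric(y0), l)[, 1]
  sum_x <- rowsum(as.numeric(x0), l)[, 1]
  intden <- rowsum(as.numeric(intensity[idx]), l)[, 1]
  bb_y0 <- tapply(y0, lf, min)
  bb_y1 <- tapply(y0, lf, max) + 1L
  bb_x0 <- tapply(x0, lf, min)
  bb_x1 <- tapply(x0, lf, max) + 1L
  area <- npx * ps^2
  data.frame(
    particle_id = seq_len(n),
    n_px = npx,
    area_um2 = area,
    equiv_diameter_um = 2 * sqrt(area / pi),
    centroid_y_px = sum_y / npx,
    centroid_x_px = sum_x / npx,
    bbox_y0 = as.integer(bb_y0), bbox_x0 = as.integer(bb_x0),
    bbox_y1 = as.integer(bb_y1), bbox_x1 = as.integer(bb_x1),
    integrated_density = intden,
    mean_intensity = intden / npx,
    touches_border = bb_y0 == 0L | bb_x0 == 0L | bb_y1 == ny | bb_x1 == nx,
    row.names = NULL
  )
}

#' Particle analysis of a binary structure mask
#'
#' Labels 8-connected components, measures each (area, equivalent-circle
#' diameter, centroid, bounding box, integrated density over the supplied
#' intensity image), and keeps components whose area lies in the size
#' filter's closed range. Border-touching particles are kept by default and
#' flagged (`touches_border`); macropinosomes form at the cell periphery,
#' which may abut the field edge.
#'
#' @param mask `BinaryMask` (or logical matrix) of structures.
#' @param intensity_image `ProjectedImage` (or matrix) the intensities are
#'   measured on — by convention the background-subtracted 8-bit dextran
#'   image that was segmented.
#' @param filter a [size_filter()].
#' @param exclude_border_particles drop border-touching particles.
#' @param gfp_mask optional `BinaryMask` of cell footprints used only to
#'   annotate `in_gfp_mask` (particle counted inside when >= 1/2 of its
#'   pixels lie in the mask); `NULL` leaves the flag `NA`.
#' @return data.frame of kept particles, one row each; attribute
#'   `rejected` holds the filtered-out rows, so that kept + rejected area
#'   conserves the foreground pixel count.
#' @export
analyze_particles <- function(mask, intensity_image, filter = size_filter(),
                              exclude_border_particles = FALSE,
                              gfp_mask = NULL) {
  m <- if (inherits(mask, "BinaryMask")) mask$pixels else mask
  px <- .pixels_of(intensity_image)
  if (!all(dim(m) == dim(px)))
    stop_input("mask and intensity image differ in shape")
  ps <- if (inherits(mask, "BinaryMask")) mask$pixel_size else
    (if (is.matrix(intensity_image)) NA_real_ else intensity_image$pixel_size)
  if (is.na(ps)) stop_config("particle analysis needs a calibrated mask (um/px)")

  lab <- cpp_label(m, 8L)
  if (max(lab) == 0) {
    out <- data.frame(
      particle_id = integer(), n_px = integer(), area_um2 = numeric(),
      equiv_diameter_um = numeric(), centroid_y_px = numeric(),
      centroid_x_px = numeric(), bbox_y0 = integer(), bbox_x0 = integer(),
      bbox_y1 = integer(), bbox_x1 = integer(), integrated_density = numeric(),
      mean_intensity = numeric(), touches_border = logical(),
      in_gfp_mask = logical()
    )
    attr(out, "rejected") <- out
    attr(out, "label_matrix") <- lab
    return(out)
  }
  df <- .measure_components(lab, nrow(m), ncol(m), ps, px)

  if (!is.null(gfp_mask)) {
    gm <- if (inherits(gfp_mask, "BinaryMask")) gfp_mask$pixels else gfp_mask
    ins <- tabulate(lab[lab > 0 & gm], nbins = nrow(df))
    df$in_gfp_mask <- ins / df$n_px >= 0.5
  } else {
    df$in_gfp_mask <- NA
  }

  keep <- df$area_um2 >= filter$min_area_um2 & df$area_um2 <= filter$max_area_um2
  if (exclude_border_particles) keep <- keep & !df$touches_border
  kept <- df[keep, , drop = FALSE]
  kept$particle_id <- seq_len(nrow(kept))
  rownames(kept) <- NULL
  attr(kept, "rejected") <- df[!keep, , drop = FALSE]
  attr(kept, "label_matrix") <- lab
  kept
}

#' Count nuclei in a segmented DAPI mask
#'
#' 8-connected components with area `>= min_nucleus_area_um2` (inclusive)
#' count as nuclei; smaller DAPI-positive structures (mitochondria,
#' speckle) are excluded. The default of 30 um^2 sits well below typical
#' HEK293 nuclear cross-sections and should be overridden with the average
#' nucleus area of the cell line at hand.
#'
#' @param nuclei_mask `BinaryMask` from [segment_nuclei()].
#' @param min_nucleus_area_um2 smallest area counted as a nucleus, um^2.
#' @return integer count.
#' @export
count_nuclei <- function(nuclei_mask, min_nucleus_area_um2 = 30) {
  m <- if (inherits(nuclei_mask, "BinaryMask")) nuclei_mask$pixels else nuclei_mask
  ps <- if (inherits(nuclei_mask, "BinaryMask")) nuclei_mask$pixel_size else NA_real_
  if (is.na(ps)) stop_config("nucleus counting needs a calibrated mask (um/px)")
  lab <- cpp_label(m, 8L)
  if (max(lab) == 0) return(0L)
  areas <- tabulate(lab[lab > 0]) * ps^2
  sum(areas >= min_nucleus_area_um2)
}

#' Per-cell normalization of a field's particle measurements
#'
#' Populates the per-image quantitation record: macropinosome count, total
#' area, average size, total integrated density, nucleus count, and the
#' per-cell / per-100-cells readouts. A field with zero nuclei is flagged
#' invalid (not an error) and excluded from condition means.
#'
#' @param particles data.frame from [analyze_particles()].
#' @param nucleus_count integer >= 0 from [count_nuclei()].
#' @param image_id,condition,replicate identifiers carried into the outputs.
#' @return a `FieldResult`.
#' @export
normalize_per_cell <- function(particles, nucleus_count, image_id,
                               condition = NA_character_,
                               replicate = NA_character_) {
  stopifnot(nucleus_count >= 0)
  mp_count <- nrow(particles)
  total <- sum(particles$area_um2)
  valid <- nucleus_count > 0
  structure(list(
    image_id = as.character(image_id),
    condition = as.character(condition),
    replicate = as.character(replicate),
    particles = particles,
    mp_count = mp_count,
    mp_total_area_um2 = total,
    mp_avg_size_um2 = if (mp_count > 0) total / mp_count else 0,
    mp_intden_total = sum(particles$integrated_density),
    nucleus_count = as.integer(nucleus_count),
    mp_per_cell = if (valid) mp_count / nucleus_count else NA_real_,
    mp_per_100_cells = if (valid) 100 * mp_count / nucleus_count else NA_real_,
    valid = valid
  ), class = "FieldResult")
}

#' @export
print.FieldResult <- function(x, ...) {
  cat(sprintf("FieldResult %s [%s/%s]: %d macropinosomes, %d nuclei",
              x$image_id, x$condition, x$replicate, x$mp_count,
              x$nucleus_count))
  if (x$valid) cat(sprintf(", %.1f per 100 cells\n", x$mp_per_100_cells))
  else cat(" (invalid: no nuclei)\n")
  invisible(x)
}

#' Aggregate fields of one condition across replicates
#'
#' Per replicate, counts are pooled over its fields:
#' `100 * sum(mp_count) / sum(nucleus_count)`. The condition mean is the
#' mean of the replicate values and the SEM their sample standard deviation
#' (n-1) over `sqrt(n_replicates)` — error bars as in the original assay.
#' Replicates with fewer than 200 cells raise the `under_sampled` flag
#' (the protocol asks for at least 200 cells per sample in triplicate).
#'
#' @param results list of `FieldResult` belonging to one condition.
#' @param condition condition name (defaults to the fields' common value).
#' @return one-row data.frame: condition, mean_mp_per_100_cells, sem,
#'   n_replicates, n_cells_total, under_sampled.
#' @export
summarize_condition <- function(results, condition = NULL) {
  if (!length(results)) stop_input("no fields supplied")
  condition <- condition %||% results[[1]]$condition
  valid <- Filter(function(r) isTRUE(r$valid), results)
  if (!length(valid))
    stop_input("condition '", condition, "' has zero valid fields ",
               "(all fields lack nuclei)")
  skipped <- length(results) - length(valid)
  if (skipped > 0)
    message("condition '", condition, "': excluded ", skipped,
            " field(s) with zero nuclei from the mean")
  reps <- vapply(valid, function(r) r$replicate, "")
  per_rep <- vapply(split(valid, reps), function(fields) {
    100 * sum(vapply(fields, `[[`, 0, "mp_count")) /
      sum(vapply(fields, `[[`, 0, "nucleus_count"))
  }, 0)
  cells_rep <- vapply(split(valid, reps), function(fields) {
    sum(vapply(fields, `[[`, 0, "nucleus_count"))
  }, 0)
  n <- length(per_rep)
  data.frame(
    condition = condition,
    mean_mp_per_100_cells = mean(per_rep),
    sem = if (n > 1) stats::sd(per_rep) / sqrt(n) else NA_real_,
    n_replicates = n,
    n_cells_total = as.integer(sum(cells_rep)),
    under_sampled = any(cells_rep < 200),
    stringsAsFactors = FALSE
  )
}
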