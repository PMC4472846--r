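# Step 2 of the workflow: collapse the z-stack by maximum-intensity
# projection, convert to 8-bit grey scale, remove smooth background with a
# rolling-ball (grayscale ball opening) algorithm.

.pixels_of <- function(image) {
  if (is.matrix(image)) image
  else if (inherits(image, c("ChannelImage", "ProjectedImage"))) image$pixels
  else stop_input("expected a matrix, ChannelImage or ProjectedImage")
}

#' Maximum-intensity projection
#'
#' Collapses a z-ordered list of slices to a single 2-D image:
#' `out[y, x] = max over z of slice[y, x]`. Calibration is preserved.
#'
#' @param slices non-empty list of `ChannelImage` (or plain matrices) with
#'   identical shape.
#' @return a `ChannelImage` at the source bit depth, with attribute
#'   `n_slices_projected`.
#' @export
max_project <- function(slices) {
  if (!is.list(slices) || !length(slices))
    stop_input("max_project needs a non-empty list of slices")
  mats <- lapply(slices, .pixels_of)
  dims <- vapply(mats, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1)
    stop_input("slices differ in shape: ", paste(unique(dims), collapse = " vs "))
  proj <- Reduce(pmax, mats)
  first <- slices[[1]]
  out <- if (inherits(first, "ChannelImage")) {
    channel_image(proj, first$pixel_size, first$role, first$bit_depth)
  } else {
    channel_image(proj, NA_real_, "unknown", if (max(proj) > 255) 16L else 8L)
  }
  attr(out, "n_slices_projected") <- length(slices)
  out
}

#' Convert an image to 8-bit grey scale
#'
#' Linear map of `[min, max]` onto `[0, 255]` with clipping, rounding
#' half-up — the conversion every image of an experiment batch must share
#' so that intensity differences between conditions survive processing.
#'
#' @param image `ChannelImage` or matrix.
#' @param mode `"source_depth"` maps `[0, 2^bit_depth - 1]`;
#'   `"fixed_range"` maps the supplied `[min, max]`.
#' @param min,max range for `fixed_range` (required there; `max > min`).
#' @return a `ProjectedImage`: 8-bit pixels plus a provenance record of every
#'   parameter that affected them.
#' @export
to_8bit <- function(image, mode = c("source_depth", "fixed_range"),
                    min = NULL, max = NULL) {
  mode <- match.arg(mode)
  px <- .pixels_of(image)
  if (mode == "source_depth") {
    bd <- if (inherits(image, "ChannelImage")) image$bit_depth
          else if (base::max(px) > 255) 16L else 8L
    lo <- 0
    hi <- 2^bd - 1
  } else {
    if (is.null(min) || is.null(max)) stop_config("fixed_range needs min and max")
    if (max <= min) stop_config("conversion max must exceed min (got [",
                                min, ", ", max, "])")
    lo <- min; hi <- max
  }
  scaled <- (px - lo) / (hi - lo) * 255
  scaled[scaled < 0] <- 0
  scaled[scaled > 255] <- 255
  out <- matrix(floor(scaled + 0.5), nrow(px), ncol(px))
  projected_image(
    out,
    pixel_size = if (inherits(image, "ChannelImage")) image$pixel_size else NA_real_,
    role = if (inherits(image, "ChannelImage")) image$role else "unknown",
    provenance = list(
      n_slices_projected = attr(image, "n_slices_projected") %||% 1L,
      conversion_min = lo, conversion_max = hi,
      rolling_ball_radius_px = NULL
    )
  )
}

#' @rdname to_8bit
#' @param pixels 8-bit 2-D matrix (values 0-255).
#' @param pixel_size um/px.
#' @param role channel role.
#' @param provenance named list of the parameters that produced the pixels.
#' @export
projected_image <- function(pixels, pixel_size, role,
                            provenance = list()) {
  stopifnot(is.matrix(pixels))
  if (any(pixels < 0 | pixels > 255))
    stop_input("ProjectedImage pixels must lie in [0, 255]")
  structure(list(pixels = pixels, pixel_size = pixel_size, role = role,
                 provenance = provenance),
            class = "ProjectedImage")
}

#' Default rolling-ball radius
#'
#' Three times the largest macropinosome diameter (5 um) in pixels — the
#' standard safe rule when the radius must exceed every object of interest.
#'
#' @param pixel_size um/px.
#' @return radius in pixels.
#' @export
default_rolling_ball_radius <- function(pixel_size) {
  as.integer(ceiling(3 * 5.0 / pixel_size))
}

#' Rolling-ball background subtraction
#'
#' Background is the grayscale opening of the image with a ball-shaped
#' structuring element of height profile `h(dy,dx) = sqrt(r^2 - dy^2 - dx^2)`
#' (erosion then dilation); corrected is `clip(image - background, 0, 255)`.
#' This is the exact morphological definition, not ImageJ's
#' shrink-and-interpolate approximation, so bit-exact agreement with ImageJ
#' is not promised. The image is reflect-padded by the radius before the
#' opening to avoid dark rims at the border. The radius should exceed the
#' largest object of interest in pixels (see
#' [default_rolling_ball_radius()]); this contract is documented, not
#' enforced.
#'
#' @param image `ProjectedImage` or 8-bit matrix.
#' @param radius_px ball radius in pixels, >= 1.
#' @return list with `corrected` (same type as input, 8-bit) and
#'   `background` (numeric matrix, everywhere `<=` image).
#' @export
rolling_ball_subtract <- function(image, radius_px) {
  if (!is.numeric(radius_px) || length(radius_px) != 1 || radius_px < 1)
    stop_config("rolling-ball radius must be an integer >= 1")
  radius_px <- as.integer(radius_px)
  px <- .pixels_of(image)
  bg <- cpp_rolling_background(px, radius_px)
  diff <- floor((px - bg) + 0.5)
  diff[diff < 0] <- 0
  diff[diff > 255] <- 255
  corrected <- if (inherits(image, "ProjectedImage")) {
    prov <- image$provenance
    prov$rolling_ball_radius_px <- radius_px
    projected_image(diff, image$pixel_size, image$role, prov)
  } else diff
  list(corrected = corrected, background = bg)
}
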