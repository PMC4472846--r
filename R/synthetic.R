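# Synthetic fluorescence fields with full ground truth: HEK293-like
# adherent cells at 50-75% confluency, one nucleus per cell, macropinosomes
# (0.5-5 um) concentrated near cell peripheries, sub-resolution endocytic
# confounders (0.1-0.2 um), smooth uneven illumination, photon + read noise.

#' Scene parameters for the synthetic-field generator
#'
#' Defaults state the imaging world the assay targets: 512x512 px at
#' 0.3 um/px (40x confocal), 11 z-slices at 0.5 um spacing, moderate
#' confluency, log-uniform macropinosome diameters over the full 0.5-5 um
#' class so both decades of the size filter are exercised, clathrin-scale
#' confounders, and peak-SNR-scaled intensities over a low-order polynomial
#' background with Poisson photon noise plus Gaussian read noise.
#'
#' @param field_px field edge, pixels.
#' @param pixel_size um/px.
#' @param z_slices number of z-slices.
#' @param z_spacing um between slices.
#' @param confluency target cell-footprint fraction of the field (0-1).
#' @param cell_semiaxis_um range of cell ellipse semi-axes, um.
#' @param nucleus_semiaxis_um range of nucleus semi-axes, um.
#' @param gfp_fraction fraction of cells flagged GFP-positive.
#' @param mean_mp_per_cell Poisson mean macropinosomes per cell.
#' @param mp_diameter_um macropinosome diameter range (log-uniform), um.
#' @param annulus_fraction macropinosomes are placed in the outer
#'   `annulus_fraction` of the cell radius (peripheral nascent structures).
#' @param confounders_per_cell Poisson mean sub-resolution vesicles per cell.
#' @param confounder_diameter_um vesicle diameter range (uniform), um.
#' @param background_photons mean background level, photons.
#' @param background_gradient amplitude of the smooth illumination gradient.
#' @param snr peak signal-to-noise ratio of a rendered structure over the
#'   local background noise.
#' @param read_noise_sd Gaussian read-noise standard deviation, photons.
#' @param sigma_xy_um Gaussian optical blur sigma, um.
#' @param gfp_level,dapi_level channel amplitudes, photons.
#' @param noise render photon + read noise (disable for noiseless oracles).
#' @param n_mp_total exact total macropinosome count (overrides the Poisson
#'   draw; `NULL` for per-cell Poisson counts).
#' @param max_retries placement retry bound before giving up.
#' @return named parameter list.
#' @export
scene_params <- function(field_px = 512L, pixel_size = 0.3, z_slices = 11L,
                         z_spacing = 0.5, confluency = 0.6,
                         cell_semiaxis_um = c(5, 10),
                         nucleus_semiaxis_um = c(4, 7),
                         gfp_fraction = 0.7, mean_mp_per_cell = 5,
                         mp_diameter_um = c(0.5, 5.0),
                         annulus_fraction = 0.3,
                         confounders_per_cell = 20,
                         confounder_diameter_um = c(0.1, 0.2),
                         background_photons = 20, background_gradient = 10,
                         snr = 10, read_noise_sd = 2, sigma_xy_um = 0.15,
                         gfp_level = 60, dapi_level = 80, noise = TRUE,
                         n_mp_total = NULL, max_retries = 200L) {
  p <- as.list(environment())
  if (p$confluency <= 0 || p$confluency > 0.85)
    stop_config("confluency must lie in (0, 0.85]; denser monolayers ",
                "cannot be placed without overlap")
  if (p$mp_diameter_um[1] < 0.5 - 1e-9 || p$mp_diameter_um[2] > 5.0 + 1e-9)
    stop_config("macropinosome diameters must stay within [0.5, 5.0] um")
  p
}

# Expected coverage of one hexagonal lattice site for pitch s, given the
# axis-sampling rules; used to solve for the pitch that hits `confluency`.
.site_coverage <- function(s, f, semi_rng, u, q) {
  site <- sqrt(3) / 2 * s^2
  cap <- 0.47 * s
  a <- sqrt(f * site * u / (pi * q))
  a <- pmin(pmax(a, semi_rng[1]), min(semi_rng[2], cap))
  b <- pmin(a * q, cap)
  mean(pi * a * b) / site
}

.render_footprint <- function(cells, field_px, pixel_size) {
  m <- matrix(FALSE, field_px, field_px)
  for (i in seq_len(nrow(cells)))
    m <- .ellipse_fill(m, cells$cy_um[i] / pixel_size, cells$cx_um[i] / pixel_size,
                       cells$a_um[i] / pixel_size, cells$b_um[i] / pixel_size,
                       cells$theta[i])
  m
}

# Set pixels inside an ellipse (semi-axes a >= b, orientation theta) TRUE.
.ellipse_fill <- function(mask, cy, cx, a, b, theta) {
  ny <- nrow(mask); nx <- ncol(mask)
  y0 <- max(1, floor(cy - a)); y1 <- min(ny, ceiling(cy + a) + 1)
  x0 <- max(1, floor(cx - a)); x1 <- min(nx, ceiling(cx + a) + 1)
  if (y0 > ny || x0 > nx || y1 < 1 || x1 < 1) return(mask)
  ys <- y0:y1; xs <- x0:x1
  dy <- (ys - 1) - cy
  dx <- (xs - 1) - cx
  DX <- matrix(dx, length(ys), length(xs), byrow = TRUE)
  DY <- matrix(dy, length(ys), length(xs))
  u <- (DX * cos(theta) + DY * sin(theta)) / a
  v <- (-DX * sin(theta) + DY * cos(theta)) / b
  mask[ys, xs] <- mask[ys, xs] | (u^2 + v^2 <= 1)
  mask
}

# Add an anti-aliased uniform disk of height `value` centred at (cy, cx) px.
.disk_add <- function(img, cy, cx, r, value) {
  ny <- nrow(img); nx <- ncol(img)
  y0 <- max(1, floor(cy - r)); y1 <- min(ny, ceiling(cy + r) + 1)
  x0 <- max(1, floor(cx - r)); x1 <- min(nx, ceiling(cx + r) + 1)
  if (y0 > ny || x0 > nx || y1 < 1 || x1 < 1) return(img)
  ys <- y0:y1; xs <- x0:x1
  dy <- (ys - 1) - cy
  dx <- (xs - 1) - cx
  D <- sqrt(outer(dy^2, dx^2, `+`))
  cov <- pmin(pmax(r - D + 0.5, 0), 1)
  if (r < 0.5) cov <- cov * (pi * r^2) / max(sum(cov), 1e-12)  # conserve flux
  img[ys, xs] <- img[ys, xs] + value * cov
  img
}

#' Generate a synthetic scene description
#'
#' Deterministic for a given `(params, seed)`. Cells are laid out on a
#' jittered hexagonal lattice with axes adapted to the pitch (plain
#' rejection placement of non-overlapping ellipses jams well below 75%
#' coverage, so crowded fields get proportionally smaller cells, as in
#' culture); one calibration pass rescales the axes so the rendered
#' footprint fraction matches the requested confluency. Every rendered
#' structure appears in the ground-truth table.
#'
#' @param params a [scene_params()] list.
#' @param seed integer seed.
#' @return a `SyntheticScene`: `params`, `cells`, `structures` (ground
#'   truth), `background` coefficients, `seed`.
#' @export
generate_scene <- function(params = scene_params(), seed) {
  if (missing(seed)) stop_config("generate_scene requires a seed")
  p <- params
  W <- p$field_px * p$pixel_size
  with_seed(seed, {
    f <- p$confluency
    u <- stats::runif(400, 0.9, 1.1)
    q <- stats::runif(400, 0.7, 1.0)
    ss <- seq(2 * p$cell_semiaxis_um[1], 5 * p$cell_semiaxis_um[2], length.out = 240)
    cov <- vapply(ss, .site_coverage, 0, f = f, semi_rng = p$cell_semiaxis_um,
                  u = u, q = q)
    s <- ss[which.min(abs(cov - f))]
    if (abs(.site_coverage(s, f, p$cell_semiaxis_um, u, q) - f) > 0.1 * f)
      stop(mq_error(paste0("cannot reach confluency ", f,
                           " with the given cell-size range; lower the density"),
                    "mq_runtime_error"))

    jit <- 0.03 * s
    phase <- stats::runif(2, 0, s)
    rows <- seq(-s, W + s, by = sqrt(3) / 2 * s)
    cells <- NULL
    idx <- 0L
    for (r in seq_along(rows)) {
      xs <- seq(-s, W + s, by = s) + (r %% 2) * s / 2 + phase[1]
      yy <- rows[r] + phase[2]
      for (x in xs) {
        cx <- x + stats::runif(1, -jit, jit)
        cy <- yy + stats::runif(1, -jit, jit)
        if (cx < 0 || cx > W || cy < 0 || cy > W) next
        qi <- stats::runif(1, 0.7, 1.0)
        ui <- stats::runif(1, 0.9, 1.1)
        site <- sqrt(3) / 2 * s^2
        cap <- 0.47 * s
        a <- sqrt(f * site * ui / (pi * qi))
        a <- min(max(a, p$cell_semiaxis_um[1]), min(p$cell_semiaxis_um[2], cap))
        b <- min(a * qi, cap)
        idx <- idx + 1L
        cells <- rbind(cells, data.frame(
          cell_id = idx, cx_um = cx, cy_um = cy, a_um = a, b_um = b,
          theta = stats::runif(1, 0, pi),
          gfp_positive = stats::runif(1) < p$gfp_fraction))
      }
    }
    if (is.null(cells) || !nrow(cells))
      stop(mq_error("no cells placed; field too small for the cell size",
                    "mq_runtime_error"))

    # calibration pass: rescale axes so the rendered fraction hits the target
    for (it in 1:3) {
      fr <- mean(.render_footprint(cells, p$field_px, p$pixel_size))
      g <- sqrt(f / fr)
      if (abs(fr - f) < 0.01) break
      cap <- 0.47 * s
      cells$a_um <- pmin(cells$a_um * g, cap)
      cells$b_um <- pmin(cells$b_um * g, cap)
    }

    # one nucleus per cell, inside the footprint
    nuc_a <- pmin(stats::runif(nrow(cells), p$nucleus_semiaxis_um[1],
                               p$nucleus_semiaxis_um[2]),
                  0.85 * cells$b_um)
    nuc_b <- pmin(nuc_a * stats::runif(nrow(cells), 0.75, 1.0), 0.85 * cells$b_um)
    off_r <- stats::runif(nrow(cells), 0, 0.15) * cells$b_um
    off_t <- stats::runif(nrow(cells), 0, 2 * pi)
    cells$nuc_cx_um <- cells$cx_um + off_r * cos(off_t)
    cells$nuc_cy_um <- cells$cy_um + off_r * sin(off_t)
    cells$nuc_a_um <- nuc_a
    cells$nuc_b_um <- nuc_b
    cells$nuc_theta <- cells$theta

    z_height <- (p$z_slices - 1) * p$z_spacing
    z_lo <- min(1, z_height / 4); z_hi <- max(z_height - 1, z_height * 3 / 4)

    # NULL when the structure's disk would cross the field border: callers
    # retry; structures out of view must not be squeezed onto the rim
    place_in_cell <- function(ci, radial_lo, radial_hi, d) {
      ang <- stats::runif(1, 0, 2 * pi)
      uu <- stats::runif(1, radial_lo, radial_hi)
      ex <- cells$a_um[ci] * uu * cos(ang)
      ey <- cells$b_um[ci] * uu * sin(ang)
      th <- cells$theta[ci]
      x <- cells$cx_um[ci] + ex * cos(th) - ey * sin(th)
      y <- cells$cy_um[ci] + ex * sin(th) + ey * cos(th)
      margin <- d / 2 + p$pixel_size
      if (x < margin || x > W - margin || y < margin || y > W - margin)
        return(NULL)
      c(x = x, y = y)
    }

    nmp_per_cell <- if (!is.null(p$n_mp_total)) {
      tabulate(sample.int(nrow(cells), p$n_mp_total, replace = TRUE),
               nbins = nrow(cells))
    } else stats::rpois(nrow(cells), p$mean_mp_per_cell)

    # macropinosomes are membrane-bound vacuoles: enforce 3-D non-overlap
    mp_x <- mp_y <- mp_z <- mp_r <- numeric(0)
    structures <- NULL
    for (ci in seq_len(nrow(cells))) {
      n_mp <- nmp_per_cell[ci]
      if (n_mp > 0) {
        d <- exp(stats::runif(n_mp, log(p$mp_diameter_um[1]),
                              log(p$mp_diameter_um[2])))
        for (k in seq_len(n_mp)) {
          placed <- FALSE
          for (try in seq_len(p$max_retries)) {
            # a vacuole that keeps colliding re-forms smaller (crowding)
            if (try %% 25L == 0L)
              d[k] <- exp(stats::runif(1, log(p$mp_diameter_um[1]),
                                       log(p$mp_diameter_um[2])))
            pos <- place_in_cell(ci, 1 - p$annulus_fraction, 1, d[k])
            if (is.null(pos)) next
            z <- stats::runif(1, z_lo, z_hi)
            if (length(mp_r)) {
              d3 <- sqrt((mp_x - pos["x"])^2 + (mp_y - pos["y"])^2 +
                         (mp_z - z)^2)
              if (any(d3 < mp_r + d[k] / 2)) next
            }
            placed <- TRUE
            break
          }
          if (!placed)
            stop(mq_error(paste0("cannot place macropinosomes without overlap",
                                 " after ", p$max_retries,
                                 " retries; lower the density"),
                          "mq_runtime_error"))
          mp_x <- c(mp_x, pos["x"]); mp_y <- c(mp_y, pos["y"])
          mp_z <- c(mp_z, z); mp_r <- c(mp_r, d[k] / 2)
          structures <- rbind(structures, data.frame(
            class = "macropinosome", x_um = pos["x"], y_um = pos["y"],
            z_um = z, diameter_um = d[k], cell_id = ci))
        }
      }
      n_cf <- stats::rpois(1, p$confounders_per_cell)
      if (n_cf > 0) {
        d <- stats::runif(n_cf, p$confounder_diameter_um[1],
                          p$confounder_diameter_um[2])
        for (k in seq_len(n_cf)) {
          pos <- NULL
          for (try in seq_len(p$max_retries)) {
            pos <- place_in_cell(ci, 0, sqrt(stats::runif(1)), d[k])
            if (!is.null(pos)) break
          }
          if (is.null(pos)) next
          structures <- rbind(structures, data.frame(
            class = "vesicle", x_um = pos["x"], y_um = pos["y"],
            z_um = stats::runif(1, z_lo, z_hi), diameter_um = d[k],
            cell_id = ci))
        }
      }
    }
    if (is.null(structures))
      structures <- data.frame(class = character(), x_um = numeric(),
                               y_um = numeric(), z_um = numeric(),
                               diameter_um = numeric(), cell_id = integer())
    rownames(structures) <- NULL

    bg_coef <- stats::runif(3, -1, 1) * p$background_gradient
    structure(list(params = p, cells = cells, structures = structures,
                   background = list(base = p$background_photons,
                                     coef = bg_coef),
                   seed = as.integer(seed)),
              class = "SyntheticScene")
  })
}

#' @export
print.SyntheticScene <- function(x, ...) {
  cat(sprintf("SyntheticScene (seed %d): %d cells, %d macropinosomes, %d vesicles\n",
              x$seed, nrow(x$cells),
              sum(x$structures$class == "macropinosome"),
              sum(x$structures$class == "vesicle")))
  invisible(x)
}

#' Ground-truth table of a scene
#'
#' One row per rendered structure, classes `macropinosome`, `vesicle`,
#' `nucleus`, `cell`; ellipsoidal structures report the equivalent diameter
#' `2*sqrt(a*b)`.
#'
#' @param scene a `SyntheticScene`.
#' @return data.frame with `class`, `x_um`, `y_um`, `z_um`, `diameter_um`.
#' @export
scene_truth <- function(scene) {
  p <- scene$params
  zmid <- (p$z_slices - 1) * p$z_spacing / 2
  cl <- scene$cells
  rbind(
    scene$structures[, c("class", "x_um", "y_um", "z_um", "diameter_um")],
    data.frame(class = "nucleus", x_um = cl$nuc_cx_um, y_um = cl$nuc_cy_um,
               z_um = zmid, diameter_um = 2 * sqrt(cl$nuc_a_um * cl$nuc_b_um)),
    data.frame(class = "cell", x_um = cl$cx_um, y_um = cl$cy_um,
               z_um = zmid, diameter_um = 2 * sqrt(cl$a_um * cl$b_um))
  )
}

.background_field <- function(scene, ny, nx) {
  co <- scene$background$coef
  xg <- matrix((0:(nx - 1)) / nx, ny, nx, byrow = TRUE)
  yg <- matrix((0:(ny - 1)) / ny, ny, nx)
  b <- scene$background$base + co[1] * xg + co[2] * yg + co[3] * xg * yg
  pmax(b, 0.5)
}

#' Render a scene into a calibrated 3-channel z-stack
#'
#' Dextran channel: every macropinosome/vesicle rendered as a uniform disk
#' in the slices its spherical extent overlaps, Gaussian-blurred
#' (`sigma_xy_um`), amplitude scaled so the post-blur peak over local
#' background equals `snr` times the local noise SD; plus the smooth
#' background and Poisson + Gaussian noise. GFP channel: footprints of
#' GFP-positive cells. DAPI channel: nuclear ellipsoids. Deterministic for
#' a given scene.
#'
#' @param scene a `SyntheticScene`.
#' @return list: `stack` (a `CalibratedStack`, roles dextran/gfp/dapi),
#'   `truth` (see [scene_truth()]).
#' @export
render_stack <- function(scene) {
  p <- scene$params
  n <- p$field_px
  ps <- p$pixel_size
  sig <- p$sigma_xy_um / ps
  nz <- p$z_slices
  bg <- .background_field(scene, n, n)
  noise_sd <- sqrt(bg + p$read_noise_sd^2)
  vox <- array(0, dim = c(nz, 3L, n, n))

  st <- scene$structures
  amp <- numeric(nrow(st))
  ext <- numeric(nrow(st))
  if (nrow(st)) {
    R <- st$diameter_um / 2
    # axial footprint: sphere radius, floored at the optical section
    # half-thickness so sub-slice structures still appear in one plane
    ext <- pmax(R, 0.35)
    slice_z <- (seq_len(nz) - 1) * p$z_spacing
    dz_min <- vapply(st$z_um, function(z) min(abs(slice_z - z)), 0)
    # radius actually rendered in the best-sampled slice, px
    r_best <- R * sqrt(pmax(1 - (dz_min / ext)^2, 0)) / ps
    # post-blur peak of a uniform disk: amp * (1 - exp(-r^2 / 2 sigma^2));
    # scale so the rendered peak over local background is snr * noise SD
    atten <- 1 - exp(-pmax(r_best, 0.2)^2 / (2 * sig^2))
    cyx <- cbind(pmin(pmax(round(st$y_um / ps) + 1, 1), n),
                 pmin(pmax(round(st$x_um / ps) + 1, 1), n))
    # same luminal dextran concentration for every endocytic structure:
    # peak brightness scales with the axial path, so sub-resolution
    # confounders are dimmer than the smallest macropinosome in proportion
    # to their diameter
    peak_scale <- ifelse(st$class == "vesicle",
                         st$diameter_um / p$mp_diameter_um[1], 1)
    amp <- p$snr * peak_scale * noise_sd[cyx] / pmax(atten, 1e-6)
  }

  for (k in seq_len(nz)) {
    zk <- (k - 1) * p$z_spacing
    img <- matrix(0, n, n)
    if (nrow(st)) {
      dz <- abs(zk - st$z_um)
      R <- st$diameter_um / 2
      hit <- which(dz < ext)
      for (i in hit) {
        rz <- R[i] * sqrt(max(1 - (dz[i] / ext[i])^2, 0)) / ps
        if (rz <= 0) next
        img <- .disk_add(img, st$y_um[i] / ps, st$x_um[i] / ps, rz, amp[i])
      }
      img <- cpp_gaussian_blur(img, sig)
    }
    vox[k, 1, , ] <- img + bg
  }

  # GFP: flat footprints of GFP-positive cells through the monolayer
  gmask <- matrix(FALSE, n, n)
  gp <- scene$cells[scene$cells$gfp_positive, , drop = FALSE]
  for (i in seq_len(nrow(gp)))
    gmask <- .ellipse_fill(gmask, gp$cy_um[i] / ps, gp$cx_um[i] / ps,
                           gp$a_um[i] / ps, gp$b_um[i] / ps, gp$theta[i])
  gimg <- cpp_gaussian_blur(matrix(as.numeric(gmask) * p$gfp_level, n, n), sig)
  gbg <- bg / 4
  for (k in seq_len(nz)) vox[k, 2, , ] <- gimg + gbg

  # DAPI: nuclear ellipsoids, semi-depth 2 um about the monolayer midplane
  zmid <- (nz - 1) * p$z_spacing / 2
  semi_z <- 2
  cl <- scene$cells
  dbg <- bg / 4
  for (k in seq_len(nz)) {
    zk <- (k - 1) * p$z_spacing
    sc <- 1 - ((zk - zmid) / semi_z)^2
    dimg <- matrix(0, n, n)
    if (sc > 0) {
      sc <- sqrt(sc)
      dm <- matrix(FALSE, n, n)
      for (i in seq_len(nrow(cl)))
        dm <- .ellipse_fill(dm, cl$nuc_cy_um[i] / ps, cl$nuc_cx_um[i] / ps,
                            pmax(cl$nuc_a_um[i] * sc, 0.5) / ps,
                            pmax(cl$nuc_b_um[i] * sc, 0.5) / ps,
                            cl$nuc_theta[i])
      dimg <- cpp_gaussian_blur(matrix(as.numeric(dm) * p$dapi_level, n, n), sig)
    }
    vox[k, 3, , ] <- dimg + dbg
  }

  if (isTRUE(p$noise)) {
    render_seed <- (scene$seed + 1000003L) %% 2147483647L
    vox <- with_seed(render_seed, {
      noisy <- stats::rpois(length(vox), pmax(vox, 0)) +
        stats::rnorm(length(vox), 0, p$read_noise_sd)
      array(noisy, dim = dim(vox))
    })
  }
  vox <- round(vox)
  vox[vox < 0] <- 0
  vox[vox > 65535] <- 65535

  stack <- calibrated_stack(vox, ps, p$z_spacing,
                            list(dextran = 1L, gfp = 2L, dapi = 3L))
  stack$bit_depth <- 16L
  list(stack = stack, truth = scene_truth(scene))
}

#' Write / read a ground-truth JSON file
#'
#' Format: `{"field_id": ..., "pixel_size": ..., "structures": [...]}`.
#'
#' @param truth data.frame from [scene_truth()].
#' @param path JSON file path.
#' @param field_id field identifier stored alongside.
#' @param pixel_size um/px stored alongside.
#' @return `path` / the truth data.frame with attributes `field_id`,
#'   `pixel_size`.
#' @export
write_truth <- function(truth, path, field_id = "field", pixel_size = NA_real_) {
  jsonlite::write_json(
    list(field_id = field_id, pixel_size = pixel_size,
         structures = truth),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- as.data.frame(obj$structures)
  attr(truth, "field_id") <- obj$field_id
  attr(truth, "pixel_size") <- obj$pixel_size
  truth
}

.derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483587 + 1)
}

#' Simulate a multi-condition experiment
#'
#' One field per design row is generated per `n_fields`, each from an
#' independent sub-seed of the global seed, so batches are reproducible and
#' fields independent.
#'
#' @param design data.frame with columns `condition`, `replicate`,
#'   `n_fields`, and optionally `mean_mp_per_cell` overriding the scene
#'   default per condition.
#' @param params base [scene_params()].
#' @param seed global integer seed.
#' @param out_dir if given, stacks are written as TIFF and truths as JSON
#'   there, and the returned samples sheet points at the files.
#' @return list: `samples` (sample sheet data.frame), `stacks` (named list),
#'   `truths` (named list), `scenes` (named list).
#' @export
simulate_experiment <- function(design, params = scene_params(), seed,
                                out_dir = NULL) {
  stopifnot(all(c("condition", "replicate", "n_fields") %in% names(design)))
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stacks <- truths <- scenes <- list()
  rows <- list()
  counter <- 0L
  for (i in seq_len(nrow(design))) {
    p <- params
    if ("mean_mp_per_cell" %in% names(design) &&
        !is.na(design$mean_mp_per_cell[i]))
      p$mean_mp_per_cell <- design$mean_mp_per_cell[i]
    for (j in seq_len(design$n_fields[i])) {
      counter <- counter + 1L
      id <- sprintf("%s_r%s_f%d", design$condition[i], design$replicate[i], j)
      scene <- generate_scene(p, .derive_seed(seed, counter))
      rend <- render_stack(scene)
      scenes[[id]] <- scene
      truths[[id]] <- rend$truth
      stacks[[id]] <- rend$stack
      path <- NA_character_
      if (!is.null(out_dir)) {
        path <- file.path(out_dir, paste0(id, ".tif"))
        write_stack(rend$stack, path)
        write_truth(rend$truth, file.path(out_dir, paste0(id, "_truth.json")),
                    field_id = id, pixel_size = p$pixel_size)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        path = path, image_id = id, condition = design$condition[i],
        replicate = as.character(design$replicate[i]),
        stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.csv(samples, file.path(out_dir, "samples.csv"),
                     row.names = FALSE)
  list(samples = samples, stacks = stacks, truths = truths, scenes = scenes)
}

#' Score detections against ground truth
#'
#' Greedy nearest-first one-to-one matching between true macropinosome
#' centres and detected centroids within `match_radius_um`.
#'
#' @param truth ground-truth data.frame (see [scene_truth()]) or a truth
#'   JSON path; only rows of class `macropinosome` are matched.
#' @param detections particle data.frame from [analyze_particles()] /
#'   `per_particle.csv` (needs `centroid_x_px`, `centroid_y_px`), or a CSV
#'   path.
#' @param match_radius_um matching radius, um.
#' @param pixel_size um/px used to convert detected centroids; defaults to
#'   the truth attribute when present.
#' @param field_id optional field identity check against a detections
#'   `image_id` column.
#' @return a `DetectionScore`: counts, precision, recall, f1 and
#'   `count_error_fraction = |n_detected - n_truth| / n_truth` (the
#'   in-silico analogue of a manual-vs-automated count comparison).
#' @export
score_detections <- function(truth, detections, match_radius_um = 1.0,
                             pixel_size = NULL, field_id = NULL) {
  if (match_radius_um <= 0) stop_config("match_radius_um must be positive")
  if (is.character(truth)) truth <- read_truth(truth)
  if (is.character(detections))
    detections <- utils::read.csv(detections, stringsAsFactors = FALSE)
  pixel_size <- pixel_size %||% attr(truth, "pixel_size")
  if (is.null(pixel_size) || is.na(pixel_size))
    stop_config("score_detections needs pixel_size to place detections in um")
  fid <- field_id %||% attr(truth, "field_id")
  if (!is.null(fid) && "image_id" %in% names(detections) &&
      nrow(detections) && !all(detections$image_id == fid))
    stop_input("detections belong to field(s) ",
               paste(unique(detections$image_id), collapse = ", "),
               " but truth is for ", fid)

  tr <- truth[truth$class == "macropinosome", , drop = FALSE]
  nt <- nrow(tr)
  nd <- nrow(detections)
  tp <- 0L
  if (nt && nd) {
    dx <- outer(tr$x_um, (detections$centroid_x_px + 0.5) * pixel_size, `-`)
    dy <- outer(tr$y_um, (detections$centroid_y_px + 0.5) * pixel_size, `-`)
    dist <- sqrt(dx^2 + dy^2)
    cand <- which(dist <= match_radius_um, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(dist[cand], cand[, 1], cand[, 2])
      used_t <- logical(nt); used_d <- logical(nd)
      for (k in ord) {
        ti <- cand[k, 1]; di <- cand[k, 2]
        if (!used_t[ti] && !used_d[di]) {
          used_t[ti] <- TRUE; used_d[di] <- TRUE
          tp <- tp + 1L
        }
      }
    }
  }
  fp <- nd - tp
  fn <- nt - tp
  precision <- if (nd > 0) tp / nd else NA_real_
  recall <- if (nt > 0) tp / nt else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(
    n_truth = nt, n_detected = nd, true_positives = tp,
    false_positives = fp, false_negatives = fn,
    precision = precision, recall = recall, f1 = f1,
    count_error_fraction = if (nt > 0) abs(nd - nt) / nt else NA_real_
  ), class = "DetectionScore")
}

#' @export
print.DetectionScore <- function(x, ...) {
  cat(sprintf(paste0("DetectionScore: %d/%d matched (precision %.3f, ",
                     "recall %.3f, F1 %.3f, count error %.1f%%)\n"),
              x$true_positives, x$n_truth, x$precision, x$recall, x$f1,
              100 * x$count_error_fraction))
  invisible(x)
}
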