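# Independent oracles, deliberately implemented with different algorithms
# than the package internals they check.

# Connected-component labelling by queue-based flood fill in plain R.
oracle_label <- function(mask, connectivity = 8) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  nb <- if (connectivity == 8) {
    cbind(c(-1,-1,-1,0,0,1,1,1), c(-1,0,1,-1,1,-1,0,1))
  } else cbind(c(-1,0,0,1), c(0,-1,1,0))
  cur <- 0L
  for (x in seq_len(nx)) for (y in seq_len(ny)) {
    if (!mask[y, x] || lab[y, x] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(y, x), 1)
    lab[y, x] <- cur
    while (nrow(queue)) {
      p <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(nb))) {
        yy <- p[1] + nb[k, 1]; xx <- p[2] + nb[k, 2]
        if (yy < 1 || yy > ny || xx < 1 || xx > nx) next
        if (mask[yy, xx] && lab[yy, xx] == 0L) {
          lab[yy, xx] <- cur
          queue <- rbind(queue, c(yy, xx))
        }
      }
    }
  }
  lab
}

# Otsu's criterion evaluated directly from its definition at every level.
oracle_otsu <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  v <- 0:255
  best <- -Inf; best_t <- NA
  for (t in 0:255) {
    w0 <- sum(p[1:(t + 1)])
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:(t + 1)] * v[1:(t + 1)]) / w0
    mu1 <- sum(p[(t + 2):256] * v[(t + 2):256]) / w1
    s <- w0 * w1 * (mu0 - mu1)^2
    if (s > best + 1e-12) { best <- s; best_t <- t }
  }
  best_t
}

# Grayscale opening with the ball height profile by a direct min-then-max
# sweep over shifted copies (vectorized but structurally independent of the
# C++ padded-loop implementation).
oracle_ball_open <- function(img, r) {
  ny <- nrow(img); nx <- ncol(img)
  reflect <- function(i, n) {
    i <- ((i - 1) %% (2 * n))
    ifelse(i < n, i + 1, 2 * n - i)
  }
  pad <- 2 * r
  P <- img[reflect(seq_len(ny + 2 * pad) - pad, ny),
           reflect(seq_len(nx + 2 * pad) - pad, nx)]
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= r^2, ]
  offs$h <- sqrt(r^2 - offs$dy^2 - offs$dx^2)
  # erosion on the domain extended by r (the dilation pass needs it);
  # extended coordinate u corresponds to original u - r, stored in P at u + r
  eny <- ny + 2 * r; enx <- nx + 2 * r
  E <- matrix(Inf, eny, enx)
  for (k in seq_len(nrow(offs))) {
    E <- pmin(E, P[(1:eny) + r + offs$dy[k], (1:enx) + r + offs$dx[k]] - offs$h[k])
  }
  B <- matrix(-Inf, ny, nx)
  for (k in seq_len(nrow(offs))) {
    B <- pmax(B, E[(1:ny) + r + offs$dy[k], (1:nx) + r + offs$dx[k]] + offs$h[k])
  }
  B
}

# Disk mask helper (pixel centres within radius of the given 1-based centre).
disk_mask <- function(ny, nx, cy, cx, r) {
  outer(seq_len(ny) - cy, seq_len(nx) - cx, function(a, b) a^2 + b^2) <= r^2
}

# A clean three-channel single-slice stack with well-separated structures:
# `n_mp` dextran disks and `n_nuclei` DAPI disks on a flat background.
sparse_test_stack <- function(n_mp = 20, n_nuclei = 8, field = 300,
                              pixel_size = 0.3, mp_r_px = 3, nuc_r_px = 12,
                              gfp_half = FALSE) {
  vox <- array(0, dim = c(1, 3, field, field))
  grid <- expand.grid(y = seq(25, field - 25, by = 50),
                      x = seq(25, field - 25, by = 50))
  stopifnot(nrow(grid) >= n_mp)
  dex <- matrix(10, field, field)
  for (i in seq_len(n_mp))
    dex[disk_mask(field, field, grid$y[i], grid$x[i], mp_r_px)] <- 150
  ngrid <- expand.grid(y = seq(40, field - 40, by = 75),
                       x = seq(40, field - 40, by = 75))
  stopifnot(nrow(ngrid) >= n_nuclei)
  dap <- matrix(5, field, field)
  for (i in seq_len(n_nuclei))
    dap[disk_mask(field, field, ngrid$y[i], ngrid$x[i], nuc_r_px)] <- 200
  gfp <- matrix(5, field, field)
  if (gfp_half) gfp[, seq_len(floor(field / 2))] <- 180
  vox[1, 1, , ] <- dex
  vox[1, 2, , ] <- gfp
  vox[1, 3, , ] <- dap
  calibrated_stack(vox, pixel_size, NA_real_,
                   list(dextran = 1L, gfp = 2L, dapi = 3L))
}
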