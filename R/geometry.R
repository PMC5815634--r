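# Low-level grid geometry shared by the projector, reconstructor and
# resamplers. All angles are in degrees; in-plane rotation is about the
# grid centre of the (x, y) axes with the z axis fixed (transaxial
# rotation, matching a SPECT orbit about the inferior-superior axis).

# Bilinear in-plane rotation weights for a square-pixel (x, y) grid.
# Returns the four neighbour linear indices and weights for every pixel.
rotation_weights <- function(nx, ny, angle_deg) {
  th <- angle_deg * pi / 180
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  x <- rep(seq_len(nx), times = ny) - cx
  y <- rep(seq_len(ny), each = nx) - cy
  # source pixel coordinates that rotate onto each target pixel
  xs <- cos(th) * x + sin(th) * y + cx
  ys <- -sin(th) * x + cos(th) * y + cy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0;   fy <- ys - y0
  w <- cbind((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  ix <- cbind(x0, x0 + 1, x0, x0 + 1)
  iy <- cbind(y0, y0, y0 + 1, y0 + 1)
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  idx <- (pmin(pmax(iy, 1), ny) - 1) * nx + pmin(pmax(ix, 1), nx)
  w[!ok] <- 0
  list(idx = idx, w = w, nx = nx, ny = ny)
}

# Gather rotation: target[p] = sum_k w[p,k] * source[idx[p,k]].
# Applied plane-by-plane to a 3D array (x, y, z).
rotate_gather <- function(vol, rw) {
  d <- dim(vol)
  m <- matrix(vol, nrow = d[1] * d[2])
  out <- rw$w[, 1] * m[rw$idx[, 1], , drop = FALSE] +
         rw$w[, 2] * m[rw$idx[, 2], , drop = FALSE] +
         rw$w[, 3] * m[rw$idx[, 3], , drop = FALSE] +
         rw$w[, 4] * m[rw$idx[, 4], , drop = FALSE]
  array(out, dim = d)
}

# Scatter (splat) rotation: the exact adjoint of rotate_gather with the
# same weights. Splatting conserves the in-plane sum exactly for content
# whose rotated support stays inside the grid, which keeps total
# projected activity independent of view angle.
rotate_scatter <- function(vol, rw) {
  d <- dim(vol)
  npix <- d[1] * d[2]
  m <- matrix(vol, nrow = npix)
  out <- matrix(0, nrow = npix, ncol = ncol(m))
  for (k in 1:4) {
    wk <- rw$w[, k]
    nz <- wk != 0
    if (!any(nz)) next
    contrib <- m[nz, , drop = FALSE] * wk[nz]
    acc <- rowsum(contrib, rw$idx[nz, k])
    ii <- as.integer(rownames(acc))
    out[ii, ] <- out[ii, , drop = FALSE] + acc
  }
  array(out, dim = d)
}

# 1D Gaussian convolution matrix (n x n) for a given FWHM in pixels.
# Rows are renormalised only implicitly by kernel truncation at 4 sigma;
# edges lose mass to outside the grid (open boundary), matching photons
# blurred off the detector edge.
gauss_matrix <- function(n, fwhm_px) {
  if (fwhm_px <= 1e-6) return(diag(n))
  sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sigma))
  off <- (-half):half
  k <- exp(-off^2 / (2 * sigma^2))
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (j in seq_along(off)) {
    d <- off[j]
    i <- seq_len(n)
    tgt <- i + d
    ok <- tgt >= 1 & tgt <= n
    M[cbind(tgt[ok], i[ok])] <- M[cbind(tgt[ok], i[ok])] + k[j]
  }
  M
}

# Separable 2D Gaussian blur of a matrix (open boundary).
blur2d <- function(img, fwhm_px_u, fwhm_px_v = fwhm_px_u) {
  Bu <- gauss_matrix(nrow(img), fwhm_px_u)
  Bv <- gauss_matrix(ncol(img), fwhm_px_v)
  Bu %*% img %*% t(Bv)
}

# Trilinear resampling of a 3D volume onto a new grid. Both grids are
# described by voxel size (mm per axis); grid centres are aligned so the
# physical field of view stays centred. `value` semantics: "density"
# interpolates the per-voxel values as-is (appropriate for concentration
# or attenuation maps); "mass" additionally rescales by the voxel-volume
# ratio so that totals are approximately preserved.
resample_trilinear <- function(vol, voxel_from, dim_to, voxel_to,
                               value = c("density", "mass")) {
  value <- match.arg(value)
  d <- dim(vol)
  ctr_from <- (d + 1) / 2
  ctr_to <- (dim_to + 1) / 2
  xi <- (seq_len(dim_to[1]) - ctr_to[1]) * voxel_to[1] / voxel_from[1] + ctr_from[1]
  yi <- (seq_len(dim_to[2]) - ctr_to[2]) * voxel_to[2] / voxel_from[2] + ctr_from[2]
  zi <- (seq_len(dim_to[3]) - ctr_to[3]) * voxel_to[3] / voxel_from[3] + ctr_from[3]
  out <- array(0, dim = dim_to)
  interp1 <- function(pos, n) {
    p0 <- floor(pos)
    f <- pos - p0
    list(i0 = pmin(pmax(p0, 1), n), i1 = pmin(pmax(p0 + 1, 1), n),
         f = f, inside = pos >= 1 - 1e-9 & pos <= n + 1e-9)
  }
  gx <- interp1(xi, d[1]); gy <- interp1(yi, d[2]); gz <- interp1(zi, d[3])
  for (k in seq_len(dim_to[3])) {
    if (!gz$inside[k]) next
    z0 <- gz$i0[k]; z1 <- gz$i1[k]; fz <- gz$f[k]
    sl0 <- vol[, , z0]; sl1 <- vol[, , z1]
    bil <- function(sl) {
      a <- sl[gx$i0, gy$i0, drop = FALSE] * ((1 - gx$f) %o% (1 - gy$f)) +
           sl[gx$i1, gy$i0, drop = FALSE] * (gx$f %o% (1 - gy$f)) +
           sl[gx$i0, gy$i1, drop = FALSE] * ((1 - gx$f) %o% gy$f) +
           sl[gx$i1, gy$i1, drop = FALSE] * (gx$f %o% gy$f)
      a[!gx$inside, ] <- 0
      a[, !gy$inside] <- 0
      a
    }
    out[, , k] <- (1 - fz) * bil(sl0) + fz * bil(sl1)
  }
  if (value == "mass")
    out <- out * prod(voxel_to) / prod(voxel_from)
  out
}

# Nearest-neighbour resampling of an integer label volume (same centre
# alignment as resample_trilinear). Preserves the exact label set.
resample_nearest <- function(vol, voxel_from, dim_to, voxel_to) {
  d <- dim(vol)
  ctr_from <- (d + 1) / 2
  ctr_to <- (dim_to + 1) / 2
  idx1 <- function(n_to, v_to, v_from, c_to, c_from, n_from) {
    pos <- (seq_len(n_to) - c_to) * v_to / v_from + c_from
    i <- round(pos)
    i[i < 1 | i > n_from] <- NA_integer_
    i
  }
  xi <- idx1(dim_to[1], voxel_to[1], voxel_from[1], ctr_to[1], ctr_from[1], d[1])
  yi <- idx1(dim_to[2], voxel_to[2], voxel_from[2], ctr_to[2], ctr_from[2], d[2])
  zi <- idx1(dim_to[3], voxel_to[3], voxel_from[3], ctr_to[3], ctr_from[3], d[3])
  out <- array(0L, dim = dim_to)
  okx <- !is.na(xi); oky <- !is.na(yi)
  for (k in seq_len(dim_to[3])) {
    if (is.na(zi[k])) next
    sl <- vol[, , zi[k]]
    tk <- array(0L, dim = dim_to[1:2])
    tk[okx, oky] <- sl[xi[okx], yi[oky]]
    out[, , k] <- tk
  }
  out
}
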