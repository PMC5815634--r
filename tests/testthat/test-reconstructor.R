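# Dense-matrix MLEM reference built by projecting unit voxels through
# the projector, then iterating the textbook update with explicit
# linear algebra.
dense_mlem <- function(A, y, n_iter) {
  x <- rep(1, ncol(A))
  s <- colSums(A)
  for (it in seq_len(n_iter)) {
    yh <- as.vector(A %*% x)
    r <- ifelse(yh > 0, y / yh, 0)
    x <- x * as.vector(crossprod(A, r)) / s
  }
  x
}

system_matrix <- function(geom, dims) {
  nvox <- prod(dims)
  zero_mu <- array(0, dims)
  A <- matrix(0, dims[1] * dims[3] * geom$n_views, nvox)
  for (j in seq_len(nvox)) {
    e <- array(0, dims); e[j] <- 1
    A[, j] <- as.vector(ssptwin:::project_views(
      e, zero_mu, geom, no_psf, seq_len(geom$n_views),
      use_attenuation = FALSE, use_psf = FALSE))
  }
  A
}

test_that("OSEM with one subset reproduces dense-matrix MLEM iteration-for-iteration", {
  geom <- acquisition_geometry(views_per_head = 6, heads = 2,
                               matrix_width = 8, bin_mm = 4)
  dims <- c(8, 8, 4)
  A <- system_matrix(geom, dims)
  truth <- array(0, dims)
  truth[4:5, 4:5, 2:3] <- 2
  truth[3, 4, 2] <- 5
  y <- as.vector(A %*% as.vector(truth))
  proj <- projection_set(array(y, c(8, 4, geom$n_views)), geom,
                         kind = "counts")
  for (k in c(1, 3, 7)) {
    ref <- dense_mlem(A, y, k)
    rec <- osem(proj, geom, no_psf,
                recon_settings(iterations = k, subsets = 1,
                               postfilter = FALSE))
    expect_lt(max(abs(rec$data - array(ref, dims))), 1e-9)
  }
})

test_that("MLEM decreases the KL projection divergence monotonically on noiseless data", {
  geom <- acquisition_geometry(views_per_head = 8, heads = 2,
                               matrix_width = 16, bin_mm = 4)
  dims <- c(16, 16, 4)
  act <- array(0, dims)
  ctr <- 8.5
  for (i in 1:16) for (j in 1:16)
    if ((i - ctr)^2 + (j - ctr)^2 <= 25) act[i, j, 2:3] <- 1  # cylinder
  ph <- grid_phantom(act, voxel_mm = 4)
  y <- forward_project(ph, geom, no_psf, sensitivity = 1,
                       use_attenuation = FALSE, use_psf = FALSE)$data
  proj <- projection_set(y, geom, kind = "counts")
  kl <- function(yhat) {
    pos <- y > 0 & yhat > 0
    sum(y[pos] * log(y[pos] / yhat[pos])) - sum(y) + sum(yhat)
  }
  kls <- vapply(1:8, function(k) {
    rec <- osem(proj, geom, no_psf,
                recon_settings(iterations = k, subsets = 1,
                               postfilter = FALSE))
    kl(ssptwin:::project_views(rec$data,
                               array(0, dims), geom, no_psf,
                               seq_len(geom$n_views),
                               use_attenuation = FALSE, use_psf = FALSE))
  }, numeric(1))
  expect_true(all(diff(kls) < 1e-8))
})

test_that("OSEM output is non-negative, zero projections give a zero volume, and bad subset counts error", {
  geom <- small_geom(n = 8, bin = 4, views = 5, heads = 2)
  set.seed(21)
  y <- array(rpois(8 * 4 * 10, 4), c(8, 4, 10))
  proj <- projection_set(y, geom, kind = "counts")
  rec <- osem(proj, geom, no_psf, recon_settings(iterations = 2, subsets = 5,
                                                 postfilter = FALSE))
  expect_true(all(rec$data >= 0))
  zero <- projection_set(array(0, c(8, 4, 10)), geom, kind = "counts")
  expect_warning(z <- osem(zero, geom, no_psf,
                           recon_settings(postfilter = FALSE)), "zero")
  expect_true(all(z$data == 0))
  expect_error(osem(proj, geom, no_psf, recon_settings(subsets = 3)),
               "divide")
})

test_that("a point source is reconstructed at its true position within half a voxel", {
  geom <- acquisition_geometry(views_per_head = 10, heads = 2,
                               matrix_width = 16, bin_mm = 4)
  dims <- c(16, 16, 4)
  act <- array(0, dims); act[11, 7, 2] <- 1
  y <- forward_project(grid_phantom(act, NULL, 4), geom, no_psf,
                       sensitivity = 1, use_attenuation = FALSE,
                       use_psf = FALSE)$data
  rec <- osem(projection_set(y, geom, kind = "counts"), geom, no_psf,
              recon_settings(iterations = 30, subsets = 4,
                             postfilter = FALSE))
  w <- rec$data / sum(rec$data)
  cx <- sum(slice.index(w, 1) * w)
  cy <- sum(slice.index(w, 2) * w)
  cz <- sum(slice.index(w, 3) * w)
  expect_lt(abs(cx - 11), 0.5)
  expect_lt(abs(cy - 7), 0.5)
  expect_lt(abs(cz - 2), 0.5)
})

test_that("the Butterworth filter has unit DC gain, 1/sqrt(2) gain at cut-off and closed-form roll-off", {
  const <- array(3.7, c(12, 10, 8))
  out <- butterworth3d(const, cutoff = 0.7, power = 10, voxel_mm = 3.68)
  expect_lt(max(abs(out - const)), 1e-9)
  # sinusoid exactly at the cut-off frequency: 0.7 cycles/cm on a grid
  # with 0.25 cm voxels, 40 samples -> DFT bin 7 = 0.7 cycles/cm
  n <- 40
  x <- seq_len(n) * 0.25
  s <- sin(2 * pi * 0.7 * x)
  vol <- array(rep(s, times = 6 * 5), c(n, 6, 5))
  f <- butterworth3d(vol, cutoff = 0.7, power = 10, voxel_mm = 2.5)
  gain <- max(abs(f[, 1, 1])) / max(abs(s))
  expect_equal(gain, 1 / sqrt(2), tolerance = 1e-6)
  # at twice the cut-off, power 10: 1/sqrt(1 + 2^20)
  s2 <- sin(2 * pi * 1.4 * x)
  vol2 <- array(rep(s2, times = 6 * 5), c(n, 6, 5))
  f2 <- butterworth3d(vol2, cutoff = 0.7, power = 10, voxel_mm = 2.5)
  gain2 <- max(abs(f2[, 1, 1])) / max(abs(s2))
  expect_equal(gain2, 1 / sqrt(1 + 2^20), tolerance = 1e-6)
  expect_error(butterworth3d(const, cutoff = 0), "positive")
})

test_that("filtering commutes with intensity scaling", {
  set.seed(4)
  v <- array(runif(10 * 12 * 6), c(10, 12, 6))
  f1 <- butterworth3d(v * 5.3, 0.7, 10, 3.68)
  f2 <- 5.3 * butterworth3d(v, 0.7, 10, 3.68)
  expect_lt(max(abs(f1 - f2)), 1e-9)
})
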