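test_that("without attenuation or blur the projector conserves total signal across views", {
  geom <- small_geom(n = 32, bin = 4, views = 15)
  act <- array(0, c(32, 32, 8))
  act[14:18, 15:17, 3:6] <- runif(5 * 3 * 4)
  ph <- grid_phantom(act, voxel_mm = 4)
  ps <- forward_project(ph, geom, no_psf, sensitivity = 2,
                        use_attenuation = FALSE, use_psf = FALSE)
  tots <- apply(ps$data, 3, sum)
  expect_equal(max(abs(tots / (2 * sum(act)) - 1)), 0, tolerance = 1e-6)
})

test_that("attenuation follows the Beer-Lambert law on a single ray (mu = 0.168/cm, 10 cm)", {
  geom <- acquisition_geometry(views_per_head = 60, heads = 2,
                               matrix_width = 64, bin_mm = 2.5)
  act <- array(0, c(64, 64, 8)); act[32, 16, 4] <- 1
  mu <- array(0, c(64, 64, 8))
  mu[32, 17:56, 4] <- 0.168          # 40 voxels x 2.5 mm = 10 cm of water
  ph <- grid_phantom(act, mu, voxel_mm = 2.5)
  ps <- forward_project(ph, geom, no_psf, sensitivity = 1, use_psf = FALSE)
  v0 <- which(geom$angles_deg == 0)
  v180 <- which(geom$angles_deg == 180)
  ratio <- sum(ps$data[, , v0]) / sum(ps$data[, , v180])
  expect_equal(ratio, exp(-0.168 * 10), tolerance = 1e-9)
  # attenuation strictly reduces every view of an embedded source
  mu_all <- array(0.05, c(64, 64, 8))
  ps_att <- forward_project(grid_phantom(act, mu_all, 2.5), geom, no_psf,
                            sensitivity = 1, use_psf = FALSE)
  ps_free <- forward_project(grid_phantom(act, NULL, 2.5), geom, no_psf,
                             sensitivity = 1, use_psf = FALSE)
  expect_true(all(apply(ps_att$data, 3, sum) < apply(ps_free$data, 3, sum)))
})

test_that("the projector is linear and non-negative", {
  geom <- small_geom(n = 16, bin = 4, views = 6)
  set.seed(9)
  mk <- function() {
    a <- array(0, c(16, 16, 4)); a[5:12, 5:12, 2:3] <- runif(8 * 8 * 2); a
  }
  A <- mk(); B <- mk()
  mu <- array(0.02, c(16, 16, 4))
  pj <- function(a) forward_project(grid_phantom(a, mu, 4), geom,
                                    psf_model(4, 0.04), sensitivity = 3)$data
  pa <- pj(A); pb <- pj(B); pab <- pj(A + B)
  expect_equal(max(abs(pab - (pa + pb))), 0, tolerance = 1e-9 * max(pab))
  expect_true(all(pa >= 0))
})

test_that("distance-dependent blur widens projections of a source farther from the detector", {
  geom <- acquisition_geometry(views_per_head = 2, arc_per_head = 180,
                               heads = 2, matrix_width = 32, bin_mm = 4)
  act <- array(0, c(32, 32, 4))
  act[17, 9, 2] <- 1   # off-centre in y: near detector for one view
  ph <- grid_phantom(act, voxel_mm = 4)
  ps <- forward_project(ph, geom, psf_model(3.8, 0.06), sensitivity = 1)
  width <- function(v) {
    prof <- rowSums(ps$data[, , v])
    mu <- sum(seq_along(prof) * prof) / sum(prof)
    sqrt(sum((seq_along(prof) - mu)^2 * prof) / sum(prof))
  }
  v_near <- which(geom$angles_deg == 180)  # detector on the -y side
  v_far <- which(geom$angles_deg == 0)
  expect_lt(width(v_near), width(v_far))
})

test_that("exposure solving hits the count target with integer seconds and scales with rate", {
  geom <- small_geom(n = 8, bin = 4, views = 5, heads = 2)
  rate <- array(5000 / (8 * 4 * 10), c(8, 4, 10))  # 5000 cps over all views
  ps <- projection_set(rate, geom, kind = "rate")
  expect_identical(solve_exposure(ps, 1.5e5), 30L)
  expect_identical(solve_exposure(ps, 0), 1L)
  ps2 <- projection_set(rate * 2, geom, kind = "rate")
  t1 <- solve_exposure(ps, 1.23e5)
  t2 <- solve_exposure(ps2, 1.23e5)
  expect_lte(abs(t2 - ceiling(t1 / 2)), 1)
  expect_error(solve_exposure(projection_set(rate * 0, geom, kind = "rate"),
                              10), "unattainable")
})

test_that("Poisson acquisition is seeded, reproducible and unbiased", {
  geom <- small_geom(n = 8, bin = 4, views = 5, heads = 2)
  rate <- array(10, c(8, 4, 10))
  ps <- projection_set(rate, geom, kind = "rate")
  z <- acquire(ps, 0, seed = 1)
  expect_true(all(z$data == 0))
  a <- acquire(ps, 10, seed = 99)
  b <- acquire(ps, 10, seed = 99)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, acquire(ps, 10, seed = 100)$data))
  # CLT check: mean of 1000 replicates of a bin with expectation 100
  one <- projection_set(array(100, c(1, 1, 1)), geom, kind = "rate")
  draws <- vapply(1:1000, function(s) acquire(one, 1, seed = s)$data[1],
                  numeric(1))
  expect_lt(abs(mean(draws) - 100), 1.0)  # 3 sigma / sqrt(n) margin
  # acquiring must not disturb the caller's RNG stream
  set.seed(5); r1 <- runif(1)
  set.seed(5); invisible(acquire(ps, 10, seed = 42)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("phantoms wider than the field of view are refused, not clipped", {
  geom <- small_geom(n = 16, bin = 4, views = 4)
  act <- array(0, c(16, 16, 4)); act[1, 1, 2] <- 1  # corner: outside orbit circle
  expect_error(forward_project(grid_phantom(act, NULL, 4), geom, no_psf),
               "truncation")
})

test_that("projection sets round-trip through NIfTI + JSON sidecar", {
  geom <- small_geom(n = 8, bin = 4, views = 3)
  ps <- projection_set(array(runif(8 * 4 * 6), c(8, 4, 6)), geom,
                       kind = "rate", sensitivity = 18)
  prefix <- tempfile("proj")
  write_projections(ps, prefix)
  back <- read_projections(prefix)
  expect_equal(back$data, ps$data, tolerance = 1e-6)
  expect_equal(back$geom$angles_deg, geom$angles_deg)
  expect_identical(back$kind, "rate")
})
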