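test_that("profile fit reproduces a noiseless linear response and matches a PAVA oracle", {
  pts <- linear_calibration(slope = 100)
  curve <- fit_profile_curve(pts)
  grid <- sort(unique(pts$greyscale))
  expect_lt(max(abs(profile_eval(curve, grid) - 100 * grid)), 1e-9)

  # noisy means: monotone fit must equal brute-force PAVA of the means
  set.seed(42)
  g <- rep(seq(0.1, 0.9, by = 0.1), each = 4)
  y <- pmax(0, 50 * rep(seq(0.1, 0.9, by = 0.1), each = 4) +
              rnorm(length(g), sd = 6))
  pts2 <- calibration_points(g, y, rep(1:4, 9))
  curve2 <- fit_profile_curve(pts2)
  gl <- sort(unique(g))
  mu <- vapply(gl, function(l) mean(y[g == l]), numeric(1))
  oracle <- pava(c(0, mu))
  expect_equal(profile_eval(curve2, c(0, gl)), oracle, tolerance = 1e-12)
})

test_that("saturated high-greyscale levels with unstable replicates are flagged and excluded", {
  g <- rep(c(0.3, 0.6, 0.9, 0.95, 1.0), each = 5)
  base <- c(30, 60, 90, 93, 94)
  set.seed(7)
  y <- rep(base, each = 5)
  sat <- g >= 0.95
  y[sat] <- y[sat] * (1 + 0.4 * rnorm(sum(sat)))  # CV far above 0.10
  curve <- fit_profile_curve(calibration_points(g, pmax(y, 0), rep(1:5, 5)))
  expect_setequal(curve$flagged_levels, c(0.95, 1.0))
  expect_false(any(c(0.95, 1.0) %in% curve$support))
})

test_that("degenerate calibrations are handled: zero counts give a flat curve, bad input errors", {
  flat <- fit_profile_curve(calibration_points(c(0, 0.5, 1), c(0, 0, 0)))
  expect_equal(profile_eval(flat, c(0, 0.25, 0.8, 1)), rep(0, 4))
  expect_error(fit_profile_curve(calibration_points(rep(0.5, 4), 1:4)),
               "at least 2 distinct")
  expect_error(calibration_points(c(0.2, 1.4), c(1, 2)), "\\[0, 1\\]")
  expect_error(calibration_points(c(0.2, 0.4), c(1, -2)), "non-negative")
})

test_that("fitted curves are monotone non-decreasing below saturation for random calibrations", {
  set.seed(11)
  for (rep_i in 1:20) {
    nlev <- sample(3:12, 1)
    g <- rep(sort(runif(nlev)), each = 3)
    y <- pmax(0, 80 * rep(sort(runif(nlev)), each = 3) + rnorm(3 * nlev, sd = 15))
    curve <- fit_profile_curve(calibration_points(g, y, rep(1:3, nlev)))
    vals <- profile_eval(curve, seq(0, curve$saturation_threshold, length.out = 50))
    expect_true(all(diff(vals) >= -1e-12))
    expect_identical(profile_eval(curve, 0), 0)
  }
})

test_that("curve inversion solves the design greyscale and round-trips the ratio", {
  curve <- linear_curve(slope = 1)
  expect_equal(invert_for_ratio(curve, 8, 0.9), 0.1125, tolerance = 1e-7)
  expect_identical(invert_for_ratio(curve, 1, 0.9), 0.9)
  # round-trip property across the reachable range
  for (r in c(1.5, 2, 4, 8, 20)) {
    g_low <- invert_for_ratio(curve, r, 0.9)
    achieved <- profile_eval(curve, 0.9) / profile_eval(curve, g_low)
    expect_equal(achieved, r, tolerance = 1e-6)
  }
  # saturating synthetic curve as used in the phantom design
  sat <- fit_profile_curve(make_synthetic_curve(noise_cv = 0, seed = 1))
  g_low <- invert_for_ratio(sat, 8, 0.9)
  expect_lt(g_low, 0.9)
  expect_equal(profile_eval(sat, 0.9) / profile_eval(sat, g_low), 8,
               tolerance = 1e-6)
  expect_error(invert_for_ratio(curve, 3, 0.95), "saturation")
})

test_that("unreachable ratios raise an error", {
  # curve with a positive floor: density never falls below 50
  curve <- structure(list(support = c(0, 0.5, 1),
                          activity_density = c(50, 80, 100),
                          saturation_threshold = 1,
                          flagged_levels = numeric(0)),
                     class = "profile_curve")
  expect_error(invert_for_ratio(curve, 10, 0.9), "unreachable")
})

test_that("cartridge mixing and decay arithmetic follow dilution and half-life laws", {
  expect_equal(cartridge_concentration(cartridge_spec(37, 1, 1)), 18.5)
  expect_equal(cartridge_concentration(cartridge_spec(37, 1, 0)), 37)
  expect_equal(cartridge_concentration(cartridge_spec(37, 2, 1)), 37 * 2 / 3)
  expect_equal(decay_correct(18.5, 0, 13.22), 18.5)
  expect_equal(decay_correct(18.5, 13.22, 13.22), 9.25)
  expect_equal(decay_correct(18.5, 26.44, 13.22), 4.625)
  expect_error(decay_correct(10, -1, 13.22), "non-negative")
  # exact additivity in elapsed time
  set.seed(3)
  for (i in 1:10) {
    a <- runif(1, 0, 30); b <- runif(1, 0, 30)
    expect_equal(decay_correct(decay_correct(7, a), b),
                 decay_correct(7, a + b), tolerance = 1e-12)
  }
})

test_that("phantom budgeting counts complete phantoms and is monotone", {
  expect_identical(phantom_budget(4, 23), 5L)
  expect_identical(phantom_budget(4, 4), 1L)
  expect_identical(phantom_budget(4, 3), 0L)
  expect_error(phantom_budget(0, 23), "positive")
  caps <- seq(0, 40, by = 2.5)
  per <- c(2, 3.5, 4, 7)
  for (p in per) expect_true(all(diff(vapply(caps, function(cp)
    phantom_budget(p, cp), integer(1))) >= 0))
  for (cp in caps[-1]) expect_true(all(diff(vapply(per, function(p)
    phantom_budget(p, cp), integer(1))) <= 0))
})

test_that("calibration and curve CSV round-trips preserve the data", {
  tmp <- tempfile(fileext = ".csv")
  pts <- make_synthetic_curve(seed = 5)
  utils::write.csv(pts, tmp, row.names = FALSE)
  back <- read_calibration_csv(tmp)
  expect_equal(back$counts, pts$counts)
  curve <- fit_profile_curve(pts)
  tmp2 <- tempfile(fileext = ".csv")
  write_profile_csv(curve, tmp2)
  curve2 <- read_profile_csv(tmp2)
  g <- seq(0, 0.9, by = 0.05)
  expect_equal(profile_eval(curve2, g), profile_eval(curve, g))
  expect_equal(curve2$saturation_threshold, curve$saturation_threshold)
})
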