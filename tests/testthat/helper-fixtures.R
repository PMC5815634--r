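# Shared small fixtures built in code.

# Noise-free calibration points from a linear response A(g) = slope * g
# at the standard 12 levels, 3 replicates.
linear_calibration <- function(slope = 100, n_rep = 3) {
  g <- rep(c(seq(0.05, 0.9, length.out = 10), 0.95, 1.0), each = n_rep)
  calibration_points(g, slope * g, rep(seq_len(n_rep), 12))
}

linear_curve <- function(slope = 100) fit_profile_curve(linear_calibration(slope))

# Brute-force pool-adjacent-violators isotonic regression (independent
# oracle for the profile-curve fit).
pava <- function(y, w = rep(1, length(y))) {
  means <- numeric(0); wts <- numeric(0); runs <- integer(0)
  for (i in seq_along(y)) {
    means <- c(means, y[i]); wts <- c(wts, w[i]); runs <- c(runs, 1L)
    while (length(means) > 1 &&
           means[length(means) - 1] > means[length(means)] + 1e-15) {
      k <- length(means)
      nm <- (means[k - 1] * wts[k - 1] + means[k] * wts[k]) /
        (wts[k - 1] + wts[k])
      means[k - 1] <- nm
      wts[k - 1] <- wts[k - 1] + wts[k]
      runs[k - 1] <- runs[k - 1] + runs[k]
      means <- means[-k]; wts <- wts[-k]; runs <- runs[-k]
    }
  }
  rep(means, runs)
}

# A tiny digital phantom directly on an acquisition grid.
grid_phantom <- function(act, mu = NULL, voxel_mm) {
  if (is.null(mu)) mu <- array(0, dim = dim(act))
  structure(list(activity = act, mu = mu,
                 voxel_mm = rep_len(voxel_mm, 3), meta = list()),
            class = "digital_phantom")
}

small_geom <- function(n = 16, bin = 4, views = 8, heads = 2)
  acquisition_geometry(views_per_head = views, heads = heads,
                       matrix_width = n, bin_mm = bin)

no_psf <- psf_model(0, 0)

# Cached default stylised head + noiseless design template, reused
# across test files (building it is deterministic but not free).
default_anatomy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      anat <- make_stylized_head(fixture_spec())
      curve <- fit_profile_curve(make_synthetic_curve(noise_cv = 0, seed = 1))
      tpl <- design_template(anat$labels, curve)
      cache <<- list(anat = anat, curve = curve, template = tpl)
    }
    cache
  }
})
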