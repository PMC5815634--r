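#' Specification of the stylised head fixture
#'
#' Describes a synthetic head used to exercise the whole pipeline
#' without external anatomy: an ellipsoidal brain inside a soft-tissue
#' head with a bone shell, and striata drawn from one of two shape
#' families - anterior-posterior elongated crescents (normal anatomy) or
#' medial-lateral elongated bars (the shape criticised in fixed-cavity
#' striatal phantoms).
#'
#' @param head_axes Outer head ellipsoid semi-axes (x, y, z), mm
#'   (default 80 x 95 x 75).
#' @param shell_mm Bone shell thickness, mm (default 6).
#' @param brain_margin_mm Gap between inner skull surface and brain, mm
#'   (default 4).
#' @param striatal_family `"AP_elongated_crescent"` or
#'   `"ML_elongated_bar"`.
#' @param striatal_volume_ml Striatal volume per side, ml (default 10,
#'   putamen plus caudate).
#' @param voxel_mm Label-volume voxel size, mm (default 2, matching the
#'   print-template slice thickness).
#' @param seed Integer seed (fixtures are deterministic given the seed).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(head_axes = c(80, 95, 75), shell_mm = 6,
                         brain_margin_mm = 4,
                         striatal_family = c("AP_elongated_crescent",
                                             "ML_elongated_bar"),
                         striatal_volume_ml = 10, voxel_mm = 2,
                         seed = 1L) {
  striatal_family <- match.arg(striatal_family)
  if (any(head_axes <= 0) || shell_mm <= 0 || striatal_volume_ml <= 0 ||
      voxel_mm <= 0)
    stop("fixture dimensions must be positive")
  structure(list(head_axes = rep_len(head_axes, 3), shell_mm = shell_mm,
                 brain_margin_mm = brain_margin_mm,
                 striatal_family = striatal_family,
                 striatal_volume_ml = striatal_volume_ml,
                 voxel_mm = voxel_mm, seed = as.integer(seed)),
            class = "fixture_spec")
}

# Points along the crescent arc of one side (s = -1 left, +1 right),
# world mm. The arc runs anterior-medial (caudate head) to
# posterior-lateral (putamen tail), bowing laterally.
crescent_arc <- function(s, n = 80) {
  t <- seq(0, 1, length.out = n)
  list(t = t,
       x = s * (14 + 12 * sin(pi * t)),
       y = 33 - 48 * t,
       z = rep(0, n))
}

# Voxelise a tube of radius r (mm) around an arc into `mask`,
# returning the label array contribution (putamen/caudate split at
# t = 0.45: the anterior-medial portion is caudate).
tube_labels <- function(grid, arc, r, lab_putamen, lab_caudate) {
  nx <- length(grid$x); ny <- length(grid$y); nz <- length(grid$z)
  xr <- range(arc$x) + c(-r, r); yr <- range(arc$y) + c(-r, r)
  zr <- range(arc$z) + c(-r, r)
  ix <- which(grid$x >= xr[1] & grid$x <= xr[2])
  iy <- which(grid$y >= yr[1] & grid$y <= yr[2])
  iz <- which(grid$z >= zr[1] & grid$z <= zr[2])
  pts <- cbind(rep(grid$x[ix], times = length(iy) * length(iz)),
               rep(rep(grid$y[iy], each = length(ix)), times = length(iz)),
               rep(grid$z[iz], each = length(ix) * length(iy)))
  n_arc <- length(arc$x)
  best_d2 <- rep(Inf, nrow(pts))
  best_t <- rep(0, nrow(pts))
  for (k in seq_len(n_arc)) {
    d2 <- (pts[, 1] - arc$x[k])^2 + (pts[, 2] - arc$y[k])^2 +
          (pts[, 3] - arc$z[k])^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_t[upd] <- arc$t[k]
  }
  inside <- best_d2 <= r^2
  lab <- integer(nrow(pts))
  lab[inside & best_t <= 0.45] <- lab_caudate
  lab[inside & best_t > 0.45] <- lab_putamen
  out <- array(0L, dim = c(nx, ny, nz))
  out[ix, iy, iz] <- array(lab, dim = c(length(ix), length(iy), length(iz)))
  out
}

ellipsoid_mask <- function(grid, centre, axes) {
  f2 <- outer(outer(((grid$x - centre[1]) / axes[1])^2,
                    ((grid$y - centre[2]) / axes[2])^2, "+"),
              ((grid$z - centre[3]) / axes[3])^2, "+")
  f2 <= 1
}

#' Generate the stylised head fixture
#'
#' Builds the label volume (brain plus left/right putamen and caudate)
#' and the matching head attenuation model (soft tissue plus bone shell
#' on 1.9 mm slabs). Striatal tube/bar sizes are calibrated so the
#' voxelised per-side volume matches `spec$striatal_volume_ml`; the
#' AP-elongated family has a mask-level AP/ML bounding ratio of at least
#' 1.3 and the ML-elongated family of at most 1.0.
#'
#' @param spec A [fixture_spec].
#' @param slab_thickness Attenuation slab thickness, mm (default 1.9).
#' @return List with `labels` (a [label_volume]) and `head`
#'   (a [head_model]).
#' @export
make_stylized_head <- function(spec = fixture_spec(),
                               slab_thickness = 1.9) {
  stopifnot(inherits(spec, "fixture_spec"))
  v <- spec$voxel_mm
  half <- spec$head_axes + 2 * v
  dims <- 2 * ceiling(half / v)
  grid <- list(x = (seq_len(dims[1]) - (dims[1] + 1) / 2) * v,
               y = (seq_len(dims[2]) - (dims[2] + 1) / 2) * v,
               z = (seq_len(dims[3]) - (dims[3] + 1) / 2) * v)
  brain_axes <- spec$head_axes - spec$shell_mm - spec$brain_margin_mm
  if (any(brain_axes <= 10)) stop("head too small for a brain")
  brain <- ellipsoid_mask(grid, c(0, 0, 0), brain_axes)
  lab <- array(0L, dim = dims)
  lab[brain] <- LABEL_BRAIN
  striatal <- make_striata(grid, spec)
  if (any(striatal > 0L & !brain))
    stop("striata exceed the brain bounds")
  lab[striatal > 0L] <- striatal[striatal > 0L]
  labels <- label_volume(lab, rep(v, 3))
  # attenuation stack on its own 1.9 mm slab grid
  nz_slab <- 2 * ceiling(half[3] / slab_thickness)
  zs <- (seq_len(nz_slab) - (nz_slab + 1) / 2) * slab_thickness
  slab_grid <- list(x = grid$x, y = grid$y, z = zs)
  outer_m <- ellipsoid_mask(slab_grid, c(0, 0, 0), spec$head_axes)
  inner_m <- ellipsoid_mask(slab_grid, c(0, 0, 0),
                            spec$head_axes - spec$shell_mm)
  slabs <- array(HEAD_AIR, dim = c(dims[1], dims[2], nz_slab))
  slabs[outer_m] <- HEAD_BONE
  slabs[inner_m] <- HEAD_SOFT
  head <- head_model(slabs, slab_thickness = slab_thickness,
                     pixel_mm = c(v, v))
  list(labels = labels, head = head)
}

# Striatal label array for either shape family, volume-calibrated.
make_striata <- function(grid, spec) {
  v3 <- spec$voxel_mm^3
  target_vox <- spec$striatal_volume_ml * 1000 / v3
  dims <- c(length(grid$x), length(grid$y), length(grid$z))
  build <- function(r) {
    out <- array(0L, dim = dims)
    if (spec$striatal_family == "AP_elongated_crescent") {
      left <- tube_labels(grid, crescent_arc(-1), r,
                          LABEL_NAMES[["left_putamen"]],
                          LABEL_NAMES[["left_caudate"]])
      right <- tube_labels(grid, crescent_arc(+1), r,
                           LABEL_NAMES[["right_putamen"]],
                           LABEL_NAMES[["right_caudate"]])
      out[left > 0L] <- left[left > 0L]
      out[right > 0L] <- right[right > 0L]
    } else {
      # medial-lateral bar: wider than long, like a fixed-cavity insert
      for (s in c(-1, 1)) {
        ctr <- c(s * 26, 6, 0)
        axes <- c(2.6 * r, r, r)
        m <- ellipsoid_mask(grid, ctr, axes)
        xs <- outer(abs(grid$x) >= 26,
                    rep(TRUE, length(grid$y)))  # lateral split
        lat <- array(xs, dim = dims) & m
        med <- m & !lat
        pl <- if (s < 0) "left_putamen" else "right_putamen"
        cl <- if (s < 0) "left_caudate" else "right_caudate"
        out[lat] <- LABEL_NAMES[[pl]]
        out[med] <- LABEL_NAMES[[cl]]
      }
    }
    out
  }
  r <- if (spec$striatal_family == "AP_elongated_crescent") 7 else 9
  out <- NULL
  for (pass in 1:3) {
    out <- build(r)
    vol <- sum(out %in% c(2L, 4L))  # left side voxels
    if (vol == 0) stop("degenerate striatal shape")
    if (abs(vol - target_vox) / target_vox < 0.02) break
    r <- r * sqrt(target_vox / vol)
  }
  out
}

#' Generate synthetic ink-calibration measurements
#'
#' Emulates the printer calibration experiment: replicate counter
#' measurements of printed patches at `n_levels` greyscale levels drawn
#' from a saturating monotone response
#' `A(g) = c_scale * (1 - exp(-k_shape * g))` with multiplicative
#' Gaussian noise of coefficient of variation `noise_cv`, and with
#' variance inflated (factor `saturation_cv_factor`) above
#' `saturation_g` to emulate paper-saturation variability at the
#' blackest levels.
#'
#' @param c_scale Response scale (relative counts; default 100).
#' @param k_shape Saturation shape constant (default 3).
#' @param saturation_g Greyscale above which replicate variability is
#'   inflated (default 0.95... strictly, levels above 0.9 are affected;
#'   the default flags the 0.95 and 1.0 levels).
#' @param noise_cv Replicate coefficient of variation (default 0.05);
#'   0 gives identical replicates.
#' @param n_levels Number of greyscale levels (default 12).
#' @param n_replicates Replicates per level (default 5).
#' @param seed Integer RNG seed.
#' @param saturation_cv_factor Variance-inflation factor applied to
#'   `noise_cv` at and above `saturation_g` (default 6).
#' @return A [calibration_points] data frame
#'   (`n_levels * n_replicates` rows).
#' @export
make_synthetic_curve <- function(c_scale = 100, k_shape = 3,
                                 saturation_g = 0.95, noise_cv = 0.05,
                                 n_levels = 12, n_replicates = 5,
                                 seed = 1L,
                                 saturation_cv_factor = 6) {
  if (c_scale <= 0 || k_shape <= 0 || n_levels < 2 || n_replicates < 1)
    stop("invalid synthetic-curve parameters")
  g <- if (n_levels >= 4)
    c(seq(0.05, 0.9, length.out = n_levels - 2), 0.95, 1.0)
  else seq(0.1, 0.9, length.out = n_levels)
  mu <- c_scale * (1 - exp(-k_shape * g))
  cv <- ifelse(g >= saturation_g, noise_cv * saturation_cv_factor,
               noise_cv)
  gg <- rep(g, each = n_replicates)
  mm <- rep(mu, each = n_replicates)
  cc <- rep(cv, each = n_replicates)
  counts <- with_local_seed(seed,
    pmax(0, mm * (1 + cc * stats::rnorm(length(mm)))))
  calibration_points(gg, counts, rep(seq_len(n_replicates), n_levels))
}
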