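#' Resample a label volume onto another grid
#'
#' Nearest-neighbour resampling (centre-aligned grids) so ground-truth
#' VOIs can be placed on the reconstruction grid.
#'
#' @param labels A [label_volume].
#' @param dim_to Target grid dimensions (length 3).
#' @param voxel_to Target voxel size, mm (length 1 or 3).
#' @return A `label_volume` on the target grid.
#' @export
resample_labels <- function(labels, dim_to, voxel_to) {
  stopifnot(inherits(labels, "label_volume"))
  voxel_to <- rep_len(voxel_to, 3)
  out <- resample_nearest(labels$data, labels$voxel_mm, dim_to, voxel_to)
  label_volume(out, voxel_to)
}

# Binary dilation by a Euclidean ball of the given radius (mm),
# implemented as a shift-union over all voxel offsets inside the ball.
dilate_mask <- function(mask, radius_mm, voxel_mm) {
  voxel_mm <- rep_len(voxel_mm, 3)
  r <- floor(radius_mm / voxel_mm)
  d <- dim(mask)
  out <- mask
  for (dx in seq(-r[1], r[1])) for (dy in seq(-r[2], r[2]))
    for (dz in seq(-r[3], r[3])) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (sum((c(dx, dy, dz) * voxel_mm)^2) > radius_mm^2) next
    xs <- seq_len(d[1]) - dx; ys <- seq_len(d[2]) - dy; zs <- seq_len(d[3]) - dz
    okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
    okz <- zs >= 1 & zs <= d[3]
    sub <- mask[xs[okx], ys[oky], zs[okz], drop = FALSE]
    out[okx, oky, okz] <- out[okx, oky, okz] | sub
  }
  out
}

#' Volume-of-interest set from ground-truth labels
#'
#' Builds the four striatal VOIs plus a reference region defined as the
#' brain minus the striata dilated by `margin_mm` (to limit spill-in from
#' striatal activity).
#'
#' @param labels A [label_volume] on the grid of the volume to be
#'   quantified (see [resample_labels]).
#' @param margin_mm Dilation margin around the striata excluded from the
#'   reference region, mm (default 10).
#' @return An object of class `voi_set`: named list of logical masks
#'   (`left_putamen`, `right_putamen`, `left_caudate`, `right_caudate`,
#'   `reference`) plus `voxel_mm` and `brain`.
#' @export
voi_set <- function(labels, margin_mm = 10) {
  stopifnot(inherits(labels, "label_volume"))
  m <- label_masks(labels)
  dil <- dilate_mask(m$striatum, margin_mm, labels$voxel_mm)
  reference <- m$brain & !dil
  if (!any(reference))
    stop("reference region is empty; reduce margin_mm")
  structure(list(left_putamen = m$left_putamen,
                 right_putamen = m$right_putamen,
                 left_caudate = m$left_caudate,
                 right_caudate = m$right_caudate,
                 reference = reference, brain = m$brain,
                 voxel_mm = labels$voxel_mm, margin_mm = margin_mm),
            class = "voi_set")
}

#' Striatal binding ratios
#'
#' The specific-uptake ratio
#' `SBR = (mean_VOI - mean_reference) / mean_reference` for each striatal
#' region against the remainder-of-brain reference. Invariant to global
#' intensity scaling.
#'
#' @param volume 3D array or `recon_volume`.
#' @param vois A [voi_set] on the same grid.
#' @return Named numeric vector of SBRs (left/right putamen and caudate).
#' @export
binding_ratios <- function(volume, vois) {
  v <- volume_data(volume)
  stopifnot(inherits(vois, "voi_set"))
  if (!all(dim(v) == dim(vois$reference)))
    stop("volume and VOI grids differ")
  ref <- mean(v[vois$reference])
  if (!is.finite(ref) || ref == 0)
    stop("undefined SBR: reference mean is zero")
  regions <- c("left_putamen", "right_putamen", "left_caudate",
               "right_caudate")
  out <- vapply(regions, function(r) {
    (mean(v[vois[[r]]]) - ref) / ref
  }, numeric(1))
  names(out) <- regions
  out
}

volume_data <- function(volume) {
  if (inherits(volume, "recon_volume")) volume$data
  else if (is.array(volume) && length(dim(volume)) == 3) volume
  else stop("volume must be a 3D array or recon_volume")
}

#' Sum the central transaxial slices into a 2D slab
#'
#' Sums `n_slices` transaxial slices centred on the brain's z-centroid
#' (the intensity-weighted centroid of the volume, or of `weight` if
#' given), mimicking the summed display slab used for striatal shape
#' measurements.
#'
#' @param volume 3D array or `recon_volume`.
#' @param n_slices Number of slices to sum (default 10).
#' @param weight Optional 3D array (e.g. a brain mask) whose z-centroid
#'   centres the window instead of the volume's own intensity.
#' @return 2D matrix (x, y) of summed intensities, with attribute
#'   `slices` (the z indices used).
#' @export
central_slab <- function(volume, n_slices = 10, weight = NULL) {
  v <- volume_data(volume)
  nz <- dim(v)[3]
  if (n_slices > nz) stop("volume has fewer than n_slices slices")
  w <- if (is.null(weight)) v else weight
  zw <- apply(w, 3, sum)
  if (sum(zw) <= 0) stop("cannot locate brain: weight sums to zero")
  zc <- sum(seq_len(nz) * zw) / sum(zw)
  first <- round(zc - n_slices / 2 + 0.5)
  first <- min(max(first, 1), nz - n_slices + 1)
  idx <- first:(first + n_slices - 1)
  slab <- apply(v[, , idx, drop = FALSE], c(1, 2), sum)
  attr(slab, "slices") <- idx
  slab
}

#' Striatal extents and AP/ML aspect ratio on a summed slab
#'
#' Mimics manual caliper measurement of striatal shape: per side, the
#' striatal footprint is defined as pixels above
#' `threshold_fraction * (side maximum - reference level)` after
#' subtracting the reference level, the anterior-posterior extent is the
#' footprint's bounding extent along y, and the medial-lateral extent is
#' measured from the brain midline to the lateral edge of the footprint
#' (`ml_mode = "from_midline"`, the default) or as the footprint's own
#' bounding width (`ml_mode = "bbox"`).
#'
#' @param slab 2D matrix (x = medial-lateral, y = anterior-posterior).
#' @param side `"left"` (lower x half) or `"right"` (upper x half).
#' @param threshold_fraction Half-maximum by default (0.5).
#' @param pixel_mm Pixel size, mm (length 1 or 2).
#' @param ref_level Reference (non-striatal brain) intensity level;
#'   estimated as the median of pixels above 5% of the slab maximum when
#'   NULL.
#' @param midline_x Midline x-coordinate in pixel units; the slab's
#'   intensity x-centroid when NULL.
#' @param ml_mode `"from_midline"` or `"bbox"` (see Details).
#' @return List with `ap_mm`, `ml_mm`, `aspect` (AP/ML) and the
#'   footprint pixel count.
#' @export
striatal_extents <- function(slab, side = c("left", "right"),
                             threshold_fraction = 0.5, pixel_mm = 3.68,
                             ref_level = NULL, midline_x = NULL,
                             ml_mode = c("from_midline", "bbox")) {
  side <- match.arg(side)
  ml_mode <- match.arg(ml_mode)
  pixel_mm <- rep_len(pixel_mm, 2)
  nx <- nrow(slab); ny <- ncol(slab)
  if (is.null(midline_x)) {
    w <- pmax(slab, 0)
    if (sum(w) <= 0) stop("empty slab")
    midline_x <- sum(rep(seq_len(nx), times = ny) * as.vector(w)) / sum(w)
  }
  if (is.null(ref_level)) {
    pos <- slab[slab > 0.05 * max(slab)]
    ref_level <- if (length(pos)) stats::median(pos) else 0
  }
  xs <- seq_len(nx)
  side_sel <- if (side == "left") xs < midline_x else xs > midline_x
  sub <- slab[side_sel, , drop = FALSE] - ref_level
  mx <- max(sub)
  if (mx <= 0) stop("not detected: no supra-reference signal on ", side)
  fp <- sub >= threshold_fraction * mx
  if (!any(fp)) stop("not detected: empty striatal footprint on ", side)
  ij <- which(fp, arr.ind = TRUE)
  ix <- xs[side_sel][ij[, 1]]
  iy <- ij[, 2]
  ap_mm <- (max(iy) - min(iy) + 1) * pixel_mm[2]
  ml_mm <- if (ml_mode == "from_midline")
    (max(abs(ix - midline_x)) + 0.5) * pixel_mm[1]
  else
    (max(ix) - min(ix) + 1) * pixel_mm[1]
  list(ap_mm = ap_mm, ml_mm = ml_mm, aspect = ap_mm / ml_mm,
       n_pixels = sum(fp))
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two masks on the same grid.
#' Two empty masks are defined to overlap perfectly (Dice 1).
#'
#' @param maskA,maskB Logical arrays of identical dimension.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(maskA, maskB) {
  if (!all(dim(maskA) == dim(maskB))) stop("masks are on different grids")
  a <- as.logical(maskA); b <- as.logical(maskB)
  tot <- sum(a) + sum(b)
  if (tot == 0) return(1)
  2 * sum(a & b) / tot
}

#' Planar print-fidelity check (template vs simulated planar image)
#'
#' Simulates a static planar acquisition of each print sheet at the
#' camera face (Gaussian detector blur plus Poisson counting at
#' `counts_level` expected counts per sheet), segments both the template
#' sheet and the noisy image by thresholding, and returns per-sheet and
#' mean whole-brain Dice overlap. Image segmentation thresholds at half
#' the non-striatal (brain plateau) level, estimated as the median image
#' intensity over the template's printed footprint; the template
#' segmentation is its printed footprint.
#'
#' @param template A [print_template].
#' @param psf A [psf_model]; blur uses the FWHM at `face_distance_mm`.
#' @param counts_level Expected total counts per sheet image (`> 0`).
#' @param seed Integer RNG seed.
#' @param curve Optional `profile_curve` mapping greyscale to activity
#'   density (identity mapping when NULL).
#' @param sheets Sheet indices to image (default: all sheets).
#' @param face_distance_mm Sheet-to-collimator distance, mm (default 0).
#' @param smooth_fwhm_mm Optional Gaussian pre-smoothing applied to the
#'   noisy image before thresholding, mm FWHM (default 0, none); useful
#'   at low count densities where single-pixel counting noise crosses
#'   the threshold.
#' @param poisson_noise Draw Poisson counts (default TRUE); FALSE images
#'   the noise-free expectation, for blur-only studies.
#' @return List with `per_sheet` (data frame: sheet, dice_brain) and
#'   `mean_dice` (mean whole-brain Dice).
#' @export
planar_print_check <- function(template, psf, counts_level, seed,
                               curve = NULL, sheets = NULL,
                               face_distance_mm = 0, smooth_fwhm_mm = 0,
                               poisson_noise = TRUE) {
  stopifnot(inherits(template, "print_template"))
  if (counts_level <= 0) stop("degenerate image: counts_level must be > 0")
  if (is.null(sheets)) sheets <- seq_along(template$sheets)
  px <- template$pixel_mm
  fw_px <- psf_fwhm(psf, face_distance_mm) / px[1]
  sm_px <- smooth_fwhm_mm / px[1]
  res <- with_local_seed(seed, {
    vapply(sheets, function(s) {
      g <- template$sheets[[s]]
      act <- g
      if (!is.null(curve)) {
        act <- matrix(0, nrow(g), ncol(g))
        pos <- g > 0
        act[pos] <- profile_eval(curve, g[pos])
      }
      if (sum(act) <= 0) return(NA_real_)
      expected <- blur2d(act, fw_px)
      expected <- expected * counts_level / sum(expected)
      img <- if (poisson_noise)
        matrix(stats::rpois(length(expected), expected), nrow(expected))
      else expected
      if (sm_px > 0) img <- blur2d(img, sm_px)
      footprint <- g > 0
      plateau <- stats::median(img[footprint])
      seg <- img >= 0.5 * plateau
      dice(seg, footprint)
    }, numeric(1))
  })
  list(per_sheet = data.frame(sheet = sheets, dice_brain = res),
       mean_dice = mean(res, na.rm = TRUE))
}

#' Indices of the central sheets of a template
#'
#' Selects `n` sheets centred on the template's printed z-centroid,
#' matching the "central slices" convention of planar print checks.
#'
#' @param template A [print_template].
#' @param n Number of sheets (default 5).
#' @return Integer vector of sheet indices.
#' @export
central_sheets <- function(template, n = 5) {
  stopifnot(inherits(template, "print_template"))
  tot <- vapply(template$sheets, sum, numeric(1))
  if (sum(tot) <= 0) stop("template is blank")
  zc <- sum(seq_along(tot) * tot) / sum(tot)
  first <- round(zc - n / 2 + 0.5)
  first <- min(max(first, 1), length(tot) - n + 1)
  first:(first + n - 1)
}

#' Full quantification report
#'
#' Convenience wrapper producing the analysis outputs for a
#' reconstructed volume: binding ratios per striatal region, per-side
#' AP/ML extents and aspect ratios on the summed central slab, and
#' whole-brain Dice between the half-reference-threshold reconstruction
#' and the ground-truth brain mask.
#'
#' @param volume `recon_volume` (or 3D array).
#' @param labels Ground-truth [label_volume] on the same grid.
#' @param n_slices Slices in the central slab (default 10).
#' @param margin_mm Reference-region dilation margin, mm.
#' @param pixel_mm In-plane pixel size of the volume, mm; taken from
#'   `volume` when it is a `recon_volume`.
#' @return An object of class `quant_report`: list with `sbr`,
#'   `extents` (data frame per side), and `dice_brain`.
#' @export
quantify_volume <- function(volume, labels, n_slices = 10,
                            margin_mm = 10, pixel_mm = NULL) {
  v <- volume_data(volume)
  if (is.null(pixel_mm))
    pixel_mm <- if (inherits(volume, "recon_volume"))
      volume$voxel_mm[1:2] else rep(3.68, 2)
  vois <- voi_set(labels, margin_mm = margin_mm)
  sbr <- binding_ratios(v, vois)
  slab <- central_slab(v, n_slices = n_slices)
  ext <- lapply(c("left", "right"), function(s)
    striatal_extents(slab, side = s, pixel_mm = pixel_mm))
  extents <- data.frame(side = c("left", "right"),
                        ap_mm = vapply(ext, `[[`, numeric(1), "ap_mm"),
                        ml_mm = vapply(ext, `[[`, numeric(1), "ml_mm"),
                        aspect = vapply(ext, `[[`, numeric(1), "aspect"))
  ref_lvl <- mean(v[vois$reference])
  seg <- v >= 0.5 * ref_lvl
  structure(list(sbr = sbr, extents = extents,
                 dice_brain = dice(seg, vois$brain)),
            class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat("Striatal binding ratios:\n")
  print(round(x$sbr, 3))
  cat("Striatal shape (summed central slab):\n")
  print(x$extents, row.names = FALSE)
  cat("Whole-brain Dice (half-reference threshold):",
      round(x$dice_brain, 3), "\n")
  invisible(x)
}

#' Write a quantification report as CSV
#'
#' One row per striatal region with its SBR, plus per-side shape rows.
#'
#' @param report A `quant_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_quant_csv <- function(report, path) {
  stopifnot(inherits(report, "quant_report"))
  sbr <- data.frame(region = names(report$sbr), sbr = unname(report$sbr),
                    ap_mm = NA_real_, ml_mm = NA_real_,
                    aspect = NA_real_)
  shp <- data.frame(region = paste0(report$extents$side, "_striatum"),
                    sbr = NA_real_, ap_mm = report$extents$ap_mm,
                    ml_mm = report$extents$ml_mm,
                    aspect = report$extents$aspect)
  utils::write.csv(rbind(sbr, shp), path, row.names = FALSE)
  invisible(path)
}
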