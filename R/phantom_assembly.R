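HEAD_AIR <- 0L
HEAD_SOFT <- 1L
HEAD_BONE <- 2L

#' Head attenuation model (stack of printed slabs)
#'
#' Per-slab 2D compartment maps over {air, soft tissue, bone} with the
#' linear attenuation coefficients of the printed materials. Defaults are
#' the measured values of the printed head: 0.168/cm for the
#' polylactic-acid soft-tissue compartment and 0.225/cm for the
#' bronze-doped bone shell, both at 140 keV.
#'
#' @param slabs 3D integer array (x, y, slab) with values 0 (air),
#'   1 (soft tissue), 2 (bone).
#' @param slab_thickness Slab thickness in mm (default 1.9).
#' @param pixel_mm In-plane pixel size, mm (length 2).
#' @param mu_soft,mu_bone Linear attenuation coefficients, cm^-1.
#' @param energy_keV Reference photon energy for the mu values.
#' @return An object of class `head_model`.
#' @export
head_model <- function(slabs, slab_thickness = 1.9, pixel_mm = c(2, 2),
                       mu_soft = 0.168, mu_bone = 0.225,
                       energy_keV = 140) {
  if (length(dim(slabs)) != 3) stop("slabs must be a 3D array")
  if (slab_thickness <= 0) stop("slab_thickness must be positive")
  if (!(mu_bone > mu_soft && mu_soft > 0))
    stop("need mu_bone > mu_soft > 0")
  structure(list(slabs = slabs, slab_thickness = slab_thickness,
                 pixel_mm = rep_len(pixel_mm, 2),
                 mu_soft = mu_soft, mu_bone = mu_bone,
                 energy_keV = energy_keV),
            class = "head_model")
}

# World z of slab centres (grid centred at the origin).
head_slab_z <- function(head) {
  n <- dim(head$slabs)[3]
  (seq_len(n) - (n + 1) / 2) * head$slab_thickness
}

#' @export
print.head_model <- function(x, ...) {
  cat("Head model:", paste(dim(x$slabs), collapse = " x "), "at",
      x$slab_thickness, "mm slabs; mu_soft", x$mu_soft,
      "/ mu_bone", x$mu_bone, "cm^-1 @", x$energy_keV, "keV\n")
  invisible(x)
}

#' Assemble template and head into a voxelised digital phantom
#'
#' Maps each sheet's greyscale through the ink profile curve to an areal
#' activity density, scales by pixel area and `areal_scale` to MBq per
#' pixel, and deposits each sheet into the attenuation-slab layer nearest
#' its z-position (the digital analogue of interleaving printed sheets
#' between slabs). The attenuation volume is filled from the head
#' compartments.
#'
#' @param template A [print_template] on the head's in-plane grid.
#' @param head A [head_model].
#' @param curve A `profile_curve` mapping greyscale to relative activity
#'   density per unit area.
#' @param areal_scale MBq per unit activity density per mm^2 of printed
#'   sheet; calibrates the curve's relative units to absolute activity.
#' @return An object of class `digital_phantom` with fields `activity`
#'   (MBq per voxel), `mu` (cm^-1 per voxel), `voxel_mm`, and provenance
#'   metadata including the maximum sheet-to-slab z misregistration.
#' @export
assemble <- function(template, head, curve, areal_scale) {
  stopifnot(inherits(template, "print_template"),
            inherits(head, "head_model"),
            inherits(curve, "profile_curve"))
  if (areal_scale <= 0) stop("areal_scale must be positive")
  if (!all(dim(template$sheets[[1]]) == dim(head$slabs)[1:2]))
    stop("template sheets and head slabs must share the in-plane grid")
  zs_sheet <- template_z(template)
  zs_slab <- head_slab_z(head)
  half <- head$slab_thickness / 2
  slab_of <- vapply(zs_sheet, function(z) which.min(abs(zs_slab - z)),
                    integer(1))
  miss <- abs(zs_sheet - zs_slab[slab_of])
  out_of_range <- which(miss > half + 1e-9)
  if (length(out_of_range))
    stop("sheets outside the head stack z-range: ",
         paste(out_of_range, collapse = ", "))
  dh <- dim(head$slabs)
  activity <- array(0, dim = dh)
  px_area <- prod(head$pixel_mm)
  for (s in seq_along(template$sheets)) {
    g <- template$sheets[[s]]
    a <- matrix(0, nrow(g), ncol(g))
    pos <- g > 0
    if (any(pos)) a[pos] <- profile_eval(curve, g[pos]) * px_area * areal_scale
    k <- slab_of[s]
    activity[, , k] <- activity[, , k] + a
  }
  mu <- array(0, dim = dh)
  mu[head$slabs == HEAD_SOFT] <- head$mu_soft
  mu[head$slabs == HEAD_BONE] <- head$mu_bone
  structure(list(activity = activity, mu = mu,
                 voxel_mm = c(head$pixel_mm, head$slab_thickness),
                 meta = list(areal_scale = areal_scale,
                             n_sheets = length(template$sheets),
                             max_z_misregistration_mm = max(miss),
                             g_striatum = template$g_striatum,
                             g_brain = template$g_brain)),
            class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat("Digital phantom", paste(dim(x$activity), collapse = " x "),
      "voxels at", paste(signif(x$voxel_mm, 4), collapse = " x "), "mm;",
      "total activity", signif(sum(x$activity), 5), "MBq\n")
  invisible(x)
}

#' Check the subresolution sheet-spacing condition
#'
#' The sandwich design requires the sheet pitch to be below half the
#' extrinsic resolution of the gamma camera so individual layers cannot
#' be resolved in the image.
#'
#' @param template A [print_template].
#' @param extrinsic_fwhm Extrinsic system resolution (FWHM), mm.
#' @return List with `pass` (logical; spacing strictly below
#'   `extrinsic_fwhm / 2`), `spacing_mm`, `limit_mm` and a `message`.
#'   A boundary spacing equal to the limit counts as a violation.
#' @export
check_subresolution <- function(template, extrinsic_fwhm) {
  stopifnot(inherits(template, "print_template"))
  if (extrinsic_fwhm <= 0) stop("extrinsic_fwhm must be positive")
  spacing <- template$sheet_thickness
  limit <- extrinsic_fwhm / 2
  pass <- spacing < limit
  msg <- if (pass)
    sprintf("sheet spacing %.3g mm < %.3g mm: subresolution condition met",
            spacing, limit)
  else
    sprintf("sheet spacing %.3g mm >= %.3g mm: layers may be resolved",
            spacing, limit)
  if (!pass) warning(msg)
  list(pass = pass, spacing_mm = spacing, limit_mm = limit, message = msg)
}

#' Save / load a digital phantom as paired NIfTI volumes
#'
#' Writes `<prefix>_activity.nii.gz`, `<prefix>_mu.nii.gz` and a JSON
#' metadata sidecar `<prefix>_meta.json`.
#'
#' @param phantom A `digital_phantom`.
#' @param prefix Output path prefix.
#' @return `write_phantom` returns the prefix invisibly; `read_phantom`
#'   returns a `digital_phantom`.
#' @export
write_phantom <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "digital_phantom"))
  act <- RNifti::asNifti(phantom$activity)
  RNifti::pixdim(act) <- phantom$voxel_mm
  RNifti::writeNifti(act, paste0(prefix, "_activity.nii.gz"))
  mu <- RNifti::asNifti(phantom$mu)
  RNifti::pixdim(mu) <- phantom$voxel_mm
  RNifti::writeNifti(mu, paste0(prefix, "_mu.nii.gz"))
  jsonlite::write_json(phantom$meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(prefix) {
  act <- RNifti::readNifti(paste0(prefix, "_activity.nii.gz"))
  mu <- RNifti::readNifti(paste0(prefix, "_mu.nii.gz"))
  voxel <- RNifti::pixdim(act)
  meta_path <- paste0(prefix, "_meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  structure(list(activity = array(as.numeric(act), dim = dim(act)),
                 mu = array(as.numeric(mu), dim = dim(mu)),
                 voxel_mm = as.numeric(voxel)[1:3], meta = meta),
            class = "digital_phantom")
}
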