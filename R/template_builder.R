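#' Label volume of head anatomy
#'
#' A voxelised integer label map with the convention 0 = background,
#' 1 = brain, 2 = left putamen, 3 = right putamen, 4 = left caudate,
#' 5 = right caudate. Axes follow x = medial-lateral, y =
#' anterior-posterior, z = inferior-superior; world coordinates are in mm
#' at voxel centres with the grid centre at the origin.
#'
#' @param data 3D integer array of labels.
#' @param voxel_mm Numeric length-3 voxel size in mm per axis.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, voxel_mm) {
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3)
  if (length(dim(data)) != 3) stop("data must be a 3D array")
  if (any(voxel_mm <= 0)) stop("voxel sizes must be positive")
  lv <- structure(list(data = data, voxel_mm = voxel_mm),
                  class = "label_volume")
  striatal <- lv$data >= 2L & lv$data <= 5L
  if (any(striatal & !(lv$data >= 1L)))
    stop("internal label inconsistency")
  lv
}

LABEL_BRAIN <- 1L
LABEL_STRIATAL <- 2L:5L
LABEL_NAMES <- c("left_putamen" = 2L, "right_putamen" = 3L,
                 "left_caudate" = 4L, "right_caudate" = 5L)

#' Masks derived from a label volume
#'
#' @param labels A [label_volume].
#' @return Named list of logical arrays: `brain` (whole brain including
#'   striata), each striatal region, and `striatum` (their union).
#' @export
label_masks <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  d <- labels$data
  out <- list(brain = d >= 1L)
  for (nm in names(LABEL_NAMES)) out[[nm]] <- d == LABEL_NAMES[[nm]]
  out$striatum <- array(d %in% LABEL_STRIATAL, dim = dim(d))
  out
}

#' @export
print.label_volume <- function(x, ...) {
  cat("Label volume", paste(dim(x$data), collapse = " x "),
      "voxels at", paste(x$voxel_mm, collapse = " x "), "mm\n")
  invisible(x)
}

#' Build a two-level greyscale print template from a label volume
#'
#' Slices the label volume into transaxial print sheets of the requested
#' thickness covering the full z-extent of the brain, using
#' nearest-neighbour sampling at each sheet's z-centre so that the
#' two-level design (striatum at `g_striatum`, remainder of brain at
#' `g_brain`, background white) is preserved exactly.
#'
#' @param labels A [label_volume].
#' @param g_striatum Greyscale printed inside the striatal labels
#'   (at most the profile-curve saturation threshold, typically 0.9).
#' @param g_brain Greyscale printed in the remainder of the brain;
#'   must be below `g_striatum`.
#' @param sheet_thickness Sheet pitch in mm (default 2).
#' @return An object of class `print_template`: list of 2D greyscale
#'   matrices (`sheets`), `sheet_thickness`, `pixel_mm` (in-plane pixel
#'   size), `z0_mm` (world z of the first sheet centre) and the greyscale
#'   levels used.
#' @export
build_template <- function(labels, g_striatum = 0.9, g_brain,
                           sheet_thickness = 2) {
  stopifnot(inherits(labels, "label_volume"))
  if (!(g_brain < g_striatum)) stop("g_brain must be below g_striatum")
  if (g_striatum > 1 || g_brain < 0) stop("greyscales must lie in [0, 1]")
  if (sheet_thickness <= 0) stop("sheet_thickness must be positive")
  d <- labels$data
  vz <- labels$voxel_mm[3]
  brain_z <- which(apply(d >= 1L, 3, any))
  if (length(brain_z) == 0) stop("empty template: brain mask has no voxels")
  ctr <- (dim(d) + 1) / 2
  # world z-extent of the brain (outer faces of its extreme voxels)
  z_lo <- (min(brain_z) - ctr[3]) * vz - vz / 2
  z_hi <- (max(brain_z) - ctr[3]) * vz + vz / 2
  n_sheets <- ceiling((z_hi - z_lo) / sheet_thickness)
  z0 <- z_lo + sheet_thickness / 2
  sheets <- vector("list", n_sheets)
  for (s in seq_len(n_sheets)) {
    zc <- z0 + (s - 1) * sheet_thickness
    k <- round(zc / vz + ctr[3])
    sl <- if (k >= 1 && k <= dim(d)[3]) d[, , k] else
      matrix(0L, dim(d)[1], dim(d)[2])
    g <- matrix(0, nrow(sl), ncol(sl))
    g[sl >= 1L] <- g_brain
    g[sl %in% LABEL_STRIATAL] <- g_striatum
    sheets[[s]] <- g
  }
  structure(list(sheets = sheets,
                 sheet_thickness = sheet_thickness,
                 pixel_mm = labels$voxel_mm[1:2],
                 z0_mm = z0,
                 g_striatum = g_striatum, g_brain = g_brain),
            class = "print_template")
}

#' @export
print.print_template <- function(x, ...) {
  cat("Print template:", length(x$sheets), "sheets of",
      paste(dim(x$sheets[[1]]), collapse = " x "), "pixels;",
      "pitch", x$sheet_thickness, "mm\n")
  cat("  greyscales: striatum", x$g_striatum, "/ brain", x$g_brain, "\n")
  invisible(x)
}

# Stack the sheets into a 3D array (x, y, sheet).
template_array <- function(template) {
  d2 <- dim(template$sheets[[1]])
  arr <- array(0, dim = c(d2, length(template$sheets)))
  for (s in seq_along(template$sheets)) arr[, , s] <- template$sheets[[s]]
  arr
}

# World z coordinates of sheet centres.
template_z <- function(template) {
  template$z0_mm + (seq_along(template$sheets) - 1) * template$sheet_thickness
}

#' Map a print template into head-stack geometry by an affine transform
#'
#' Resamples the template with nearest-neighbour interpolation into the
#' sheet grid of a head model under a user-supplied affine transform
#' (voxel-centre world coordinates, mm). The transform plays the role of
#' the registration that fits an atlas-space template onto an individual
#' head; any pixels mapped outside the head's soft-tissue compartment are
#' cleared and counted in a clipping report.
#'
#' @param template A [print_template].
#' @param transform 4x4 affine matrix mapping template world coordinates
#'   (mm) to head world coordinates; must be invertible.
#' @param head A [head_model].
#' @return A `print_template` on the head grid with attribute
#'   `clipping` (list: `n_clipped`, `n_printed`).
#' @export
map_template_to_head <- function(template, transform, head) {
  stopifnot(inherits(template, "print_template"), inherits(head, "head_model"))
  transform <- as.matrix(transform)
  if (!all(dim(transform) == c(4, 4)) ||
      abs(det(transform)) < 1e-12) stop("transform must be an invertible 4x4 affine")
  inv <- solve(transform)
  arr <- template_array(template)
  dt <- dim(arr)
  ctr_t <- (dt[1:2] + 1) / 2
  zs_t <- template_z(template)
  dh <- dim(head$slabs)
  ctr_h <- (dh[1:2] + 1) / 2
  zs_h <- head_slab_z(head)
  px_h <- head$pixel_mm
  px_t <- template$pixel_mm
  out <- array(0, dim = dh)
  # head grid world coordinates
  xw <- (seq_len(dh[1]) - ctr_h[1]) * px_h[1]
  yw <- (seq_len(dh[2]) - ctr_h[2]) * px_h[2]
  grid_x <- rep(xw, times = dh[2])
  grid_y <- rep(yw, each = dh[1])
  for (k in seq_len(dh[3])) {
    pts <- rbind(grid_x, grid_y, zs_h[k], 1)
    src <- inv %*% pts
    ix <- round(src[1, ] / px_t[1] + ctr_t[1])
    iy <- round(src[2, ] / px_t[2] + ctr_t[2])
    iz <- round((src[3, ] - template$z0_mm) / template$sheet_thickness) + 1
    ok <- ix >= 1 & ix <= dt[1] & iy >= 1 & iy <= dt[2] &
          iz >= 1 & iz <= dt[3]
    vals <- numeric(length(ok))
    vals[ok] <- arr[cbind(ix[ok], iy[ok], iz[ok])]
    out[, , k] <- matrix(vals, dh[1], dh[2])
  }
  soft <- head$slabs == HEAD_SOFT
  n_printed <- sum(out > 0)
  clipped <- out > 0 & !soft
  out[clipped] <- 0
  sheets <- lapply(seq_len(dh[3]), function(k) out[, , k])
  res <- structure(list(sheets = sheets,
                        sheet_thickness = head$slab_thickness,
                        pixel_mm = px_h,
                        z0_mm = zs_h[1],
                        g_striatum = template$g_striatum,
                        g_brain = template$g_brain),
                   class = "print_template")
  attr(res, "clipping") <- list(n_clipped = sum(clipped),
                                n_printed = n_printed)
  res
}

#' Export template sheets as greyscale images plus a manifest
#'
#' Writes one greyscale raster per sheet (print greyscale: 0 = white
#' paper, 1 = full black ink, stored as image intensity `1 - g` so the
#' files preview like the physical printout) and a CSV manifest
#' recording sheet order, z-positions and the greyscale levels. 8-bit
#' output is PNG; 16-bit output uses TIFF (PNG writing is 8-bit).
#'
#' @param template A [print_template].
#' @param dpi Print resolution used to record physical size (metadata
#'   only; pixels are written 1:1). Default 600.
#' @param directory Output directory (created if missing).
#' @param bit_depth 8 (PNG) or 16 (TIFF) bit greyscale output.
#' @return Invisibly, the manifest data frame.
#' @export
export_print_sheets <- function(template, dpi = 600, directory,
                                bit_depth = 8) {
  stopifnot(inherits(template, "print_template"))
  if (dpi <= 0) stop("dpi must be positive")
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16")
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", directory)
  zs <- template_z(template)
  files <- character(length(template$sheets))
  for (s in seq_along(template$sheets)) {
    g <- template$sheets[[s]]
    # image rows run top-to-bottom = anterior-to-posterior
    img <- t(1 - g)[rev(seq_len(ncol(g))), , drop = FALSE]
    if (bit_depth == 8) {
      files[s] <- sprintf("sheet_%03d.png", s)
      png::writePNG(img, file.path(directory, files[s]),
                    dpi = dpi, text = c(sheet = as.character(s)))
    } else {
      files[s] <- sprintf("sheet_%03d.tif", s)
      tiff::writeTIFF(img, file.path(directory, files[s]),
                      bits.per.sample = 16L)
    }
  }
  manifest <- data.frame(sheet_index = seq_along(zs), z_mm = zs,
                         file = files,
                         g_brain = template$g_brain,
                         g_striatum = template$g_striatum)
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read exported print sheets back into a template
#'
#' Restores a [print_template] from a directory written by
#' [export_print_sheets] (used for round-trip checks and archival).
#'
#' @param directory Directory containing `manifest.csv` and sheet PNGs.
#' @param pixel_mm In-plane pixel size of the sheets, mm.
#' @return A `print_template`.
#' @export
import_print_sheets <- function(directory, pixel_mm = c(2, 2)) {
  manifest <- utils::read.csv(file.path(directory, "manifest.csv"))
  sheets <- lapply(manifest$file, function(f) {
    img <- if (grepl("\\.tiff?$", f))
      tiff::readTIFF(file.path(directory, f))
    else png::readPNG(file.path(directory, f))
    if (length(dim(img)) == 3) img <- img[, , 1]
    1 - t(img[rev(seq_len(nrow(img))), , drop = FALSE])
  })
  zs <- manifest$z_mm
  pitch <- if (length(zs) > 1) zs[2] - zs[1] else 2
  structure(list(sheets = sheets, sheet_thickness = pitch,
                 pixel_mm = rep_len(pixel_mm, 2), z0_mm = zs[1],
                 g_striatum = manifest$g_striatum[1],
                 g_brain = manifest$g_brain[1]),
            class = "print_template")
}
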