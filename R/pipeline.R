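#' Design a print template from a profile curve and a design ratio
#'
#' Solves the remainder-of-brain greyscale from the ink profile curve so
#' the printed striatum:brain activity-density ratio equals
#' `design_ratio` with the striatum printed at `g_max`, then renders the
#' two-level template from the label volume.
#'
#' @param labels A [label_volume].
#' @param curve A `profile_curve`.
#' @param design_ratio Target striatum:brain count-density ratio
#'   (default 8, a normal-subject design).
#' @param g_max Striatal greyscale (default 0.9, the highest level below
#'   paper saturation).
#' @param sheet_thickness Sheet pitch, mm (default 2).
#' @return A [print_template]; the solved brain greyscale is in
#'   `$g_brain`.
#' @export
design_template <- function(labels, curve, design_ratio = 8,
                            g_max = 0.9, sheet_thickness = 2) {
  g_low <- invert_for_ratio(curve, design_ratio, g_max)
  build_template(labels, g_striatum = g_max, g_brain = g_low,
                 sheet_thickness = sheet_thickness)
}

#' Areal activity scale for a target total phantom activity
#'
#' The per-sheet ink volume distribution of a printed phantom is not an
#' observable of the template, so the absolute calibration (MBq per unit
#' activity density per mm^2) is chosen to make the assembled phantom's
#' total activity equal `target_MBq`.
#'
#' @param template A [print_template].
#' @param curve A `profile_curve`.
#' @param target_MBq Desired total phantom activity (default 70).
#' @return The `areal_scale` to pass to [assemble].
#' @export
areal_scale_for_activity <- function(template, curve, target_MBq = 70) {
  px_area <- prod(template$pixel_mm)
  tot <- 0
  for (g in template$sheets) {
    pos <- g > 0
    if (any(pos)) tot <- tot + sum(profile_eval(curve, g[pos])) * px_area
  }
  if (tot <= 0) stop("template prints no activity")
  target_MBq / tot
}

#' Run the full digital SSP study
#'
#' Convenience driver covering the whole digital twin: generate (or use)
#' the stylised head, fit the synthetic ink profile curve, solve the
#' greyscale design, render and assemble the phantom, simulate the SPECT
#' acquisition at the clinical count target, reconstruct with OSEM plus
#' Butterworth filtering, and quantify binding ratios and striatal
#' shape.
#'
#' @param spec A [fixture_spec] describing the head.
#' @param seed Integer seed for all stochastic steps (calibration noise
#'   and Poisson counting).
#' @param design_ratio Striatum:brain count-density design ratio
#'   (default 8).
#' @param g_max Striatal greyscale (default 0.9).
#' @param target_counts Total-count target for the exposure solver
#'   (default 1.5e6).
#' @param target_MBq Total phantom activity, MBq (default 70).
#' @param geom An [acquisition_geometry].
#' @param psf A [psf_model].
#' @param settings A [recon_settings].
#' @param sensitivity Detector sensitivity, cps/MBq (default 18).
#' @param curve_noise_cv Replicate noise of the synthetic calibration
#'   (default 0.05).
#' @return List with all intermediate objects (`labels`, `head`,
#'   `curve`, `template`, `phantom`, `expected`, `exposure_s`, `counts`,
#'   `recon`, `labels_on_grid`, `report`).
#' @export
run_ssp_study <- function(spec = fixture_spec(), seed = 1L,
                          design_ratio = 8, g_max = 0.9,
                          target_counts = 1.5e6, target_MBq = 70,
                          geom = acquisition_geometry(),
                          psf = psf_model(),
                          settings = recon_settings(),
                          sensitivity = 18,
                          curve_noise_cv = 0.05) {
  anat <- make_stylized_head(spec)
  pts <- make_synthetic_curve(noise_cv = curve_noise_cv, seed = seed)
  curve <- fit_profile_curve(pts)
  template <- design_template(anat$labels, curve,
                              design_ratio = design_ratio, g_max = g_max)
  scale <- areal_scale_for_activity(template, curve, target_MBq)
  phantom <- assemble(template, anat$head, curve, scale)
  expected <- forward_project(phantom, geom, psf,
                              sensitivity = sensitivity)
  exposure <- solve_exposure(expected, target_counts)
  counts <- acquire(expected, exposure, seed)
  recon <- osem(counts, geom, psf, settings,
                mu = if (settings$model_attenuation)
                  phantom_on_grid(phantom, geom)$mu else NULL)
  lab_grid <- resample_labels(anat$labels, dim(recon$data),
                              recon$voxel_mm)
  report <- quantify_volume(recon, lab_grid)
  list(labels = anat$labels, head = anat$head, curve = curve,
       template = template, phantom = phantom, expected = expected,
       exposure_s = exposure, counts = counts, recon = recon,
       labels_on_grid = lab_grid, report = report, seed = seed)
}
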