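#' Calibration points for the ink profile curve
#'
#' Bundles background-subtracted counter measurements of printed test
#' patches into a validated data frame. Each row is one replicate
#' measurement of one greyscale level (0 = white, 1 = black).
#'
#' @param greyscale Numeric vector of print greyscale levels in `[0, 1]`.
#' @param counts Numeric vector of background-subtracted measured counts
#'   (one value per patch), non-negative.
#' @param replicate Integer vector identifying the replicate print run of
#'   each patch. Recycled if scalar.
#' @return A `data.frame` of class `calibration_points` with columns
#'   `greyscale`, `replicate`, `counts`.
#' @examples
#' calibration_points(rep(c(0.1, 0.5, 0.9), each = 2),
#'                    c(9, 11, 48, 52, 88, 92), rep(1:2, 3))
#' @export
calibration_points <- function(greyscale, counts, replicate = 1L) {
  greyscale <- as.numeric(greyscale)
  counts <- as.numeric(counts)
  replicate <- rep_len(as.integer(replicate), length(greyscale))
  if (length(counts) != length(greyscale))
    stop("greyscale and counts must have equal length")
  if (any(!is.finite(greyscale)) || any(greyscale < 0 | greyscale > 1))
    stop("greyscale values must lie in [0, 1]")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  out <- data.frame(greyscale = greyscale, replicate = replicate,
                    counts = counts)
  class(out) <- c("calibration_points", "data.frame")
  out
}

#' Read ink calibration measurements from CSV
#'
#' The file must have a header with columns `greyscale`, `replicate`
#' and `counts`.
#'
#' @param path Path to the CSV file.
#' @return A [calibration_points] data frame.
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("greyscale", "replicate", "counts")
  if (!all(need %in% names(df)))
    stop("calibration CSV must have columns: ", paste(need, collapse = ", "))
  calibration_points(df$greyscale, df$counts, df$replicate)
}

#' Fit a monotone ink profile curve from calibration points
#'
#' Replicate measurements are averaged per greyscale level, levels whose
#' replicate coefficient of variation exceeds `cv_threshold` above the
#' saturation region are flagged (paper-saturation variability) and
#' excluded from the fit, and the remaining level means are passed through
#' isotonic (monotone non-decreasing) regression followed by
#' piecewise-linear interpolation. The curve is anchored at
#' `activity_density(0) = 0`: measurements are assumed
#' background-subtracted by the caller.
#'
#' @param points A [calibration_points] data frame (or any data frame
#'   with columns `greyscale`, `replicate`, `counts`).
#' @param saturation_threshold Greyscale above which printed output is
#'   considered unreliable (paper saturation). Default 0.9.
#' @param cv_threshold Replicate coefficient-of-variation limit used to
#'   flag unstable levels above the saturation threshold. Default 0.10.
#' @return An object of class `profile_curve` with fields `support`
#'   (greyscale grid), `activity_density` (relative printed activity per
#'   unit area), `saturation_threshold` and `flagged_levels`.
#' @examples
#' pts <- calibration_points(rep(seq(0, 1, length.out = 12), each = 3),
#'                           rep(100 * seq(0, 1, length.out = 12), each = 3))
#' fit_profile_curve(pts)
#' @export
fit_profile_curve <- function(points, saturation_threshold = 0.9,
                              cv_threshold = 0.10) {
  if (!all(c("greyscale", "counts") %in% names(points)))
    stop("points must have greyscale and counts columns")
  g <- as.numeric(points$greyscale)
  y <- as.numeric(points$counts)
  if (any(g < 0 | g > 1)) stop("greyscale outside [0, 1]")
  if (any(y < 0)) stop("counts must be non-negative")
  levels_g <- sort(unique(g))
  if (length(levels_g) < 2)
    stop("invalid calibration: need at least 2 distinct greyscale levels")
  mu <- vapply(levels_g, function(l) mean(y[g == l]), numeric(1))
  sdv <- vapply(levels_g, function(l) stats::sd(y[g == l]), numeric(1))
  cv <- ifelse(mu > 0, sdv / mu, 0)
  cv[is.na(cv)] <- 0
  flagged <- levels_g > saturation_threshold & cv > cv_threshold
  keep <- !flagged
  if (sum(keep) < 2)
    stop("invalid calibration: fewer than 2 usable levels after flagging")
  gk <- levels_g[keep]
  mk <- mu[keep]
  # anchor at the origin: zero ink prints zero activity
  if (gk[1] > 0) {
    gk <- c(0, gk)
    mk <- c(0, mk)
  } else {
    mk[1] <- 0
  }
  iso <- stats::isoreg(gk, mk)
  fit <- iso$yf[order(order(gk))]  # isoreg sorts internally; gk already sorted
  structure(list(support = gk,
                 activity_density = fit,
                 saturation_threshold = saturation_threshold,
                 flagged_levels = levels_g[flagged]),
            class = "profile_curve")
}

#' @export
print.profile_curve <- function(x, ...) {
  cat("Ink profile curve:", length(x$support), "support points;",
      "saturation threshold", x$saturation_threshold, "\n")
  if (length(x$flagged_levels))
    cat("  flagged (saturated/unstable) levels:",
        paste(x$flagged_levels, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate an ink profile curve
#'
#' Piecewise-linear interpolation of the fitted activity density on the
#' curve support. Values beyond the last support point are held constant
#' (rule-2 extrapolation); values below 0 are an error.
#'
#' @param curve A `profile_curve`.
#' @param g Greyscale values in `[0, 1]`.
#' @return Relative printed activity density per unit area at `g`.
#' @export
profile_eval <- function(curve, g) {
  stopifnot(inherits(curve, "profile_curve"))
  if (any(g < 0 | g > 1)) stop("greyscale outside [0, 1]")
  stats::approx(curve$support, curve$activity_density, xout = g,
                rule = 2, ties = "ordered")$y
}

#' Invert the profile curve for a target compartment activity ratio
#'
#' Given the greyscale printed in the high-uptake compartment (striatum),
#' finds the lower greyscale whose printed activity density is
#' `target_ratio` times smaller, by bisection on the monotone curve. This
#' yields the remainder-of-brain greyscale for a chosen striatum:brain
#' count-density design ratio.
#'
#' @param curve A `profile_curve`.
#' @param target_ratio Desired high:low activity-density ratio, `>= 1`.
#' @param g_high Greyscale of the high compartment; must not exceed the
#'   curve's saturation threshold.
#' @param tol Relative tolerance on the achieved ratio. Default 1e-9
#'   (far below any 8-bit greyscale quantisation step).
#' @return The greyscale `g_low` with
#'   `profile_eval(curve, g_high) / profile_eval(curve, g_low)`
#'   equal to `target_ratio` within `tol`.
#' @export
invert_for_ratio <- function(curve, target_ratio, g_high, tol = 1e-9) {
  stopifnot(inherits(curve, "profile_curve"))
  if (target_ratio < 1) stop("target_ratio must be >= 1")
  if (g_high > curve$saturation_threshold)
    stop("g_high exceeds the saturation threshold")
  if (target_ratio == 1) return(g_high)
  a_high <- profile_eval(curve, g_high)
  if (a_high <= 0) stop("curve is zero at g_high; ratio undefined")
  target <- a_high / target_ratio
  eps_g <- 1e-12
  if (profile_eval(curve, eps_g) > target &&
      profile_eval(curve, 0) >= target)
    stop("unreachable ratio: curve does not fall below target density")
  lo <- 0; hi <- g_high
  # bisection: activity density is monotone non-decreasing on [0, g_high]
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    val <- profile_eval(curve, mid)
    if (val > target) hi <- mid else lo <- mid
    if (abs(val - target) <= tol * target && val > 0) return(mid)
  }
  g_low <- (lo + hi) / 2
  achieved <- a_high / profile_eval(curve, g_low)
  if (abs(achieved - target_ratio) > 1e-6 * target_ratio)
    stop("unreachable ratio: bisection could not attain the target within ",
         "tolerance (achieved ", format(achieved), ")")
  g_low
}

#' Radioactive concentration of a mixed ink cartridge
#'
#' Volume-weighted dilution of the radionuclide stock by non-radioactive
#' ink: `stock_concentration * parts_stock / (parts_stock + parts_ink)`.
#'
#' @param spec A [cartridge_spec].
#' @return Concentration in MBq/ml at mixing time.
#' @examples
#' # 37 MBq/ml iodine-123 stock mixed 1:1 with black ink
#' cartridge_concentration(cartridge_spec(37, 1, 1))  # 18.5 MBq/ml
#' @export
cartridge_concentration <- function(spec) {
  stopifnot(inherits(spec, "cartridge_spec"))
  spec$stock_concentration * spec$parts_stock /
    (spec$parts_stock + spec$parts_ink)
}

#' Specification of a radioactive ink cartridge
#'
#' @param stock_concentration Radionuclide stock concentration, MBq/ml.
#' @param parts_stock,parts_ink Volume parts of stock and of ink in the
#'   mixture (e.g. 1 and 1 for a 1:1 mix). `parts_ink` may be zero.
#' @param fill_volume Cartridge fill volume, ml.
#' @param half_life Radionuclide half-life in hours
#'   (default 13.22 h, iodine-123).
#' @return An object of class `cartridge_spec`.
#' @export
cartridge_spec <- function(stock_concentration, parts_stock = 1,
                           parts_ink = 1, fill_volume = 16,
                           half_life = 13.22) {
  if (stock_concentration <= 0 || fill_volume <= 0 || half_life <= 0)
    stop("stock_concentration, fill_volume and half_life must be positive")
  if (parts_stock < 0 || parts_ink < 0 || parts_stock + parts_ink <= 0)
    stop("mixture parts must be non-negative with positive total")
  structure(list(stock_concentration = stock_concentration,
                 parts_stock = parts_stock, parts_ink = parts_ink,
                 fill_volume = fill_volume, half_life = half_life),
            class = "cartridge_spec")
}

#' Decay-correct a radioactive concentration
#'
#' @param concentration Concentration (any activity unit).
#' @param elapsed Elapsed time in hours, `>= 0`.
#' @param half_life Half-life in hours (default 13.22 h, iodine-123).
#' @return `concentration * 2^(-elapsed / half_life)`.
#' @export
decay_correct <- function(concentration, elapsed, half_life = 13.22) {
  if (any(elapsed < 0)) stop("elapsed time must be non-negative")
  if (half_life <= 0) stop("half_life must be positive")
  concentration * 2^(-elapsed / half_life)
}

#' Number of complete phantoms printable from one cartridge
#'
#' @param ml_per_phantom Ink solution used per full phantom, ml, `> 0`.
#' @param capacity Cartridge capacity, ml, `>= 0`.
#' @return `floor(capacity / ml_per_phantom)`, an integer count.
#' @examples
#' phantom_budget(4, 23)  # 5
#' @export
phantom_budget <- function(ml_per_phantom, capacity) {
  if (ml_per_phantom <= 0) stop("ml_per_phantom must be positive")
  if (capacity < 0) stop("capacity must be non-negative")
  as.integer(floor(capacity / ml_per_phantom))
}

#' Write / read a fitted profile curve as CSV
#'
#' Serialises the curve support and activity density so a calibration can
#' be reused across sessions; `read_profile_csv` restores it.
#'
#' @param curve A `profile_curve`.
#' @param path Output CSV path.
#' @return `write_profile_csv` returns `path` invisibly;
#'   `read_profile_csv` returns a `profile_curve`.
#' @export
write_profile_csv <- function(curve, path) {
  stopifnot(inherits(curve, "profile_curve"))
  df <- data.frame(greyscale = curve$support,
                   activity_density = curve$activity_density)
  attr_line <- sprintf("# saturation_threshold=%.6f",
                       curve$saturation_threshold)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  first <- readLines(path, n = 1)
  sat <- 0.9
  skip <- 0
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("saturation_threshold=([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2) sat <- as.numeric(m[2])
    skip <- 1
  }
  df <- utils::read.csv(path, skip = skip)
  structure(list(support = df$greyscale,
                 activity_density = df$activity_density,
                 saturation_threshold = sat,
                 flagged_levels = numeric(0)),
            class = "profile_curve")
}
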