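## PSF calibration: bead FWHM estimation and the small-object
## intensity-correction curve.
##
## Objects at or near the diffraction limit appear dimmer than their true
## profile because the PSF spreads their intensity outward. The
## calibration renders discs of known intensity (255) and diameter
## (1-50 px) on a zero background, blurs them with the measured Gaussian
## PSF, re-measures them through the same Otsu mask the droplet pipeline
## uses, and fits correction factor = 255/measured against the measured
## diameter with a one-phase exponential association. That curve is then
## used to de-bias small-droplet intensities.

FWHM_SIGMA <- 2 * sqrt(2 * log(2))  # FWHM = 2.3548 sigma

#' Select the in-focus plane of a bead z-stack
#'
#' Returns the plane maximizing total intensity in a small window around
#' the bead centre; ties break to the lower index.
#'
#' @param bead_stack 3D `ImageStack` `(z, y, x)`.
#' @param bead_centre `(y, x)` centre in pixels.
#' @param window_px half-width of the window.
#' @return plane index (1-based).
#' @export
select_focus_plane <- function(bead_stack, bead_centre, window_px = 2L) {
  d <- dim(bead_stack$pixels)
  if (length(d) == 2L) return(1L)
  if (d[1L] < 3L) stopf("bead stack needs >= 3 planes")
  cy <- round(bead_centre[1L]); cx <- round(bead_centre[2L])
  if (cy < 1L || cy > d[2L] || cx < 1L || cx > d[3L])
    stopf("bead centre (%g, %g) outside image bounds", bead_centre[1L],
          bead_centre[2L])
  ys <- max(1L, cy - window_px):min(d[2L], cy + window_px)
  xs <- max(1L, cx - window_px):min(d[3L], cx + window_px)
  tot <- vapply(seq_len(d[1L]), function(z) sum(bead_stack$pixels[z, ys, xs]),
                numeric(1))
  which.max(tot)  # ties -> lower index
}

## Gaussian fit to a 1D linescan: amplitude, centre, sigma, baseline free.
fit_gaussian_linescan <- function(x, y) {
  base0 <- min(y)
  amp0 <- max(y) - base0
  mu0 <- x[which.max(y)]
  sig0 <- max(sum(y - base0 > amp0 / 2) / FWHM_SIGMA, 0.5)
  fit <- try(minpack.lm::nlsLM(
    y ~ base + amp * exp(-(x - mu)^2 / (2 * sig^2)),
    start = list(base = base0, amp = amp0, mu = mu0, sig = sig0),
    lower = c(base = -Inf, amp = 0, mu = min(x), sig = 0.1),
    upper = c(base = Inf, amp = Inf, mu = max(x), sig = diff(range(x))),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  as.list(stats::coef(fit))
}

#' Measure the PSF FWHM from bead linescans
#'
#' For each bead, a horizontal linescan through the centre (optionally
#' averaged with the vertical one) is fit with a Gaussian (amplitude,
#' centre, sigma, baseline free); the per-bead FWHM is
#' `2 * sqrt(2 * log(2)) * sigma` and the model stores the mean over beads.
#' Beads whose fit fails are dropped with a warning.
#'
#' @param image 2D `ImageStack` (the in-focus plane).
#' @param bead_centres matrix or data.frame of `(y, x)` centres.
#' @param halfwidth_px linescan half-length in pixels.
#' @param axis `"horizontal"` (default) or `"both"` (average of the
#'   horizontal and vertical scans' FWHMs).
#' @param channel_name channel label for the model.
#' @return a `PsfModel` list: `channel_name`, `fwhm_px`, `sigma_px`,
#'   `n_beads_used`, `per_bead_fwhm`.
#' @export
measure_fwhm <- function(image, bead_centres, halfwidth_px = 10L,
                         axis = c("horizontal", "both"),
                         channel_name = image$channel_name) {
  axis <- match.arg(axis)
  bead_centres <- as.matrix(bead_centres)
  if (nrow(bead_centres) < 1L) stopf("need >= 1 bead centre")
  img <- get_frame(image, 1L)
  per_bead <- numeric(0)
  for (b in seq_len(nrow(bead_centres))) {
    cy <- round(bead_centres[b, 1L]); cx <- round(bead_centres[b, 2L])
    xs <- max(1L, cx - halfwidth_px):min(ncol(img), cx + halfwidth_px)
    fit_h <- fit_gaussian_linescan(xs, img[cy, xs])
    fw <- if (is.null(fit_h)) NA_real_ else FWHM_SIGMA * fit_h$sig
    if (axis == "both") {
      ys <- max(1L, cy - halfwidth_px):min(nrow(img), cy + halfwidth_px)
      fit_v <- fit_gaussian_linescan(ys, img[ys, cx])
      fw <- mean(c(fw, if (is.null(fit_v)) NA_real_ else FWHM_SIGMA * fit_v$sig),
                 na.rm = FALSE)
    }
    if (is.na(fw)) {
      warning(sprintf("bead %d: Gaussian fit failed; bead dropped", b))
    } else {
      per_bead <- c(per_bead, fw)
    }
  }
  if (length(per_bead) == 0L)
    stopf("calibration failed: Gaussian fit converged for no bead")
  fwhm <- mean(per_bead)
  structure(list(channel_name = channel_name, fwhm_px = fwhm,
                 sigma_px = fwhm / FWHM_SIGMA,
                 n_beads_used = length(per_bead),
                 per_bead_fwhm = per_bead),
            class = "PsfModel")
}

#' @export
print.PsfModel <- function(x, ...) {
  cat(sprintf("PsfModel '%s': FWHM %.3f px (sigma %.3f px) from %d beads\n",
              x$channel_name, x$fwhm_px, x$sigma_px, x$n_beads_used))
  invisible(x)
}

#' Normalized 2D Gaussian PSF kernel
#'
#' Isotropic Gaussian of the given FWHM, sampled at pixel centres,
#' truncated at `>= 4 sigma` and renormalized to unit sum (truncation at
#' 4 sigma leaves less than 1e-4 of the mass outside the support, which
#' renormalization folds back in).
#'
#' @param fwhm_px FWHM in pixels (> 0).
#' @param support_radius_px optional half-width of the kernel; defaults to
#'   `ceiling(4 * sigma)`; an error if smaller than that.
#' @return odd-sized unit-sum kernel matrix.
#' @export
gaussian_psf <- function(fwhm_px, support_radius_px = NULL) {
  if (fwhm_px <= 0) stopf("fwhm_px must be > 0")
  sigma <- fwhm_px / FWHM_SIGMA
  rmin <- ceiling(4 * sigma)
  if (is.null(support_radius_px)) support_radius_px <- rmin
  if (support_radius_px < rmin)
    stopf("support radius %g px too small to hold +/- 4 sigma (%g px)",
          support_radius_px, rmin)
  r <- as.integer(support_radius_px)
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Build the small-object intensity-correction curve
#'
#' Renders discs of intensity `disc_intensity` on a zero background for
#' each diameter, convolves with the PSF kernel, masks the convolved image
#' with Otsu's global threshold, measures equivalent-area diameter and
#' mean intensity inside the mask, and computes correction factor =
#' `disc_intensity` / measured mean. The factors are fit against measured
#' diameter with a one-phase exponential association
#' `f(d) = plateau + (f0 - plateau) * exp(-k * d)` (plateau free; a
#' well-formed calibration has plateau close to 1).
#'
#' All sample points are measured and stored, but the association is fit
#' only over measured diameters at or above `fit_support_min_px`
#' (default 12 px, the droplet discard floor): the correction is never
#' applied below that floor, and the steep mask-geometry regime of
#' near-PSF-sized discs would otherwise dominate the least squares and
#' ruin the fit over the diameters the curve is actually used for.
#'
#' @param psf unit-sum PSF kernel (from [gaussian_psf()]).
#' @param diameters ascending true disc diameters in pixels.
#' @param disc_intensity rendered disc intensity.
#' @param fit_support_min_px smallest measured diameter included in the
#'   association fit; also the lower edge of the curve's support.
#' @param channel_name channel label.
#' @return a `CorrectionCurve` list: fitted `plateau`, `f0`, `k`, the
#'   sample-point table (true/measured diameter, measured mean,
#'   correction factor) and the measured-diameter support.
#' @export
build_correction_curve <- function(psf, diameters = 1:50,
                                   disc_intensity = 255,
                                   fit_support_min_px = 12,
                                   channel_name = "ch1") {
  if (is.unsorted(diameters)) stopf("diameters must be sorted ascending")
  if (abs(sum(psf) - 1) > 1e-6) stopf("psf kernel must be normalized to unit sum")
  rows <- lapply(diameters, function(d) {
    m <- measure_convolved_disc(psf, d, disc_intensity)
    if (is.null(m)) {
      warning(sprintf("diameter %g px: empty Otsu mask; point skipped", d))
      return(NULL)
    }
    data.frame(true_diameter_px = d, measured_diameter_px = m$diameter,
               measured_mean = m$mean_intensity,
               correction_factor = disc_intensity / m$mean_intensity)
  })
  pts <- do.call(rbind, rows)
  if (is.null(pts) || nrow(pts) < 5L)
    stopf("calibration failed: fewer than 5 usable diameters")
  fit_pts <- pts[pts$measured_diameter_px >= fit_support_min_px, , drop = FALSE]
  if (nrow(fit_pts) < 5L)
    stopf("calibration failed: fewer than 5 usable diameters in the fit support")
  f0_0 <- max(fit_pts$correction_factor)
  fit <- minpack.lm::nlsLM(
    correction_factor ~ plateau + (f0 - plateau) * exp(-k * measured_diameter_px),
    data = fit_pts,
    start = list(plateau = 1, f0 = f0_0, k = 0.1),
    lower = c(plateau = 0, f0 = 0, k = 1e-6),
    upper = c(plateau = 2, f0 = 10 * f0_0, k = 5),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- as.list(stats::coef(fit))
  structure(list(channel_name = channel_name, plateau = cf$plateau,
                 f0 = cf$f0, k = cf$k,
                 support = range(fit_pts$measured_diameter_px),
                 sample_points = pts),
            class = "CorrectionCurve")
}

## Render, convolve and measure one calibration disc; NULL if the Otsu
## mask is empty. Field size leaves a full kernel support margin.
measure_convolved_disc <- function(psf, diameter_px, disc_intensity = 255) {
  r <- (nrow(psf) - 1L) %/% 2L
  sz <- as.integer(ceiling(diameter_px) + 2L * r + 8L)
  disc <- disc_coverage(sz, sz, c((sz + 1) / 2, (sz + 1) / 2), diameter_px) *
    disc_intensity
  conv <- convolve2d(disc, psf)
  thr <- otsu_threshold(conv)
  if (is.na(thr)) return(NULL)
  mask <- conv > thr
  if (!any(mask)) return(NULL)
  area <- sum(mask)
  list(diameter = 2 * sqrt(area / pi), mean_intensity = mean(conv[mask]))
}

#' @export
print.CorrectionCurve <- function(x, ...) {
  cat(sprintf(paste0("CorrectionCurve '%s': f(d) = %.4f + (%.4f - %.4f)",
                     " exp(-%.4f d), support %.1f-%.1f px (%d points)\n"),
              x$channel_name, x$plateau, x$f0, x$plateau, x$k,
              x$support[1L], x$support[2L], nrow(x$sample_points)))
  invisible(x)
}

#' Evaluate a correction curve at measured diameters
#'
#' The fitted factor, floored at 1: blur can only dilute a bright object
#' on a darker surround, so a factor below 1 is fit wiggle, not signal.
#'
#' @param curve a `CorrectionCurve`.
#' @param diameter_px measured diameters.
#' @return correction factors (>= 1).
#' @export
correction_factor <- function(curve, diameter_px) {
  f <- curve$plateau + (curve$f0 - curve$plateau) * exp(-curve$k * diameter_px)
  pmax(f, 1)
}

#' Apply the PSF intensity correction to droplet records
#'
#' Multiplies each record's bulk-subtracted excess intensity by the
#' curve factor at its measured diameter and updates the partition
#' coefficient: `corrected = bulk + (raw - bulk) * f(d)`. On the
#' calibration's zero background this reduces to the plain
#' `raw * f(d)` rescaling; on a nonzero bulk only the excess above bulk
#' is diluted by blur, so only the excess is corrected. Records flagged
#' `discarded` (below the 12-px floor) are never corrected; records with
#' diameters below the curve's support are flagged and left uncorrected.
#'
#' @param records a droplet record table (see [partition_coefficients()]).
#' @param curve a `CorrectionCurve` for the table's intensity channel, or
#'   a named list of curves keyed by channel for multi-channel tables.
#' @return the table with `corrected_mean`, `partition_coefficient` and
#'   `below_support` updated.
#' @export
apply_intensity_correction <- function(records, curve) {
  if (nrow(records) == 0L) return(records)
  curves <- if (inherits(curve, "CorrectionCurve")) {
    stats::setNames(list(curve), unique(records$channel))
  } else curve
  records$below_support <- FALSE
  for (ch in unique(records$channel)) {
    cv <- curves[[ch]]
    if (is.null(cv)) stopf("no correction curve supplied for channel '%s'", ch)
    sel <- records$channel == ch & !records$discarded
    below <- sel & records$diameter_px < cv$support[1L]
    records$below_support[below] <- TRUE
    use <- sel & !below
    f <- correction_factor(cv, records$diameter_px[use])
    records$corrected_mean[use] <- records$bulk_mean[use] +
      (records$raw_mean[use] - records$bulk_mean[use]) * f
    records$partition_coefficient[use] <-
      records$corrected_mean[use] / records$bulk_mean[use]
  }
  records
}
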