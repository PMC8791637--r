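## Synthetic-image generators with attached ground truth.
##
## Every generator is deterministic in (parameters, seed) and returns the
## rendered image(s) together with a GroundTruth record sufficient to
## compute, without the image, the value each downstream stage should
## report.

ground_truth <- function(kind, true_parameters, seed) {
  structure(list(kind = kind, true_parameters = true_parameters,
                 seed = as.integer(seed)),
            class = "GroundTruth")
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("GroundTruth '%s' (seed %d): %s\n", x$kind, x$seed,
              paste(names(x$true_parameters), collapse = ", ")))
  invisible(x)
}

#' Anti-aliased disc raster
#'
#' Fractional pixel coverage of a disc of given centre and diameter, so
#' that "diameter" stays well defined for small discs. Rim pixels are
#' resolved by 4x4 subpixel sampling; interior/exterior pixels are exact.
#'
#' @param nrow,ncol raster size (y, x).
#' @param centre `(y, x)` centre in pixel coordinates (1-based).
#' @param diameter_px disc diameter in pixels (>= 1).
#' @return matrix of coverage fractions in \[0, 1\].
#' @export
disc_coverage <- function(nrow, ncol, centre, diameter_px) {
  if (diameter_px < 1) stopf("disc diameter must be >= 1 px")
  r <- diameter_px / 2
  cy <- centre[1L]; cx <- centre[2L]
  y <- matrix(seq_len(nrow), nrow, ncol)
  x <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  d <- sqrt((y - cy)^2 + (x - cx)^2)
  cov <- matrix(0, nrow, ncol)
  cov[d <= r - 0.75] <- 1
  rim <- which(d > r - 0.75 & d < r + 0.75)
  if (length(rim)) {
    sub <- seq(-0.375, 0.375, by = 0.25)
    yy <- y[rim]; xx <- x[rim]
    acc <- numeric(length(rim))
    for (dy in sub) for (dx in sub) {
      acc <- acc + ((yy + dy - cy)^2 + (xx + dx - cx)^2 <= r^2)
    }
    cov[rim] <- acc / 16
  }
  cov
}

#' Linear 2D convolution
#'
#' FFT-based 2D convolution (via [EBImage::filter2]). The default
#' replicate boundary treats the scene as extending beyond the field of
#' view (a specimen does not drop to zero at the camera edge); pass
#' `boundary = 0` for plain zero-padded linear convolution. On images
#' whose margin is empty over the kernel support the two agree exactly.
#' Kernel must have odd dimensions.
#'
#' @param img numeric matrix.
#' @param kernel odd-sized kernel matrix.
#' @param boundary `"replicate"`, `"circular"`, or a numeric pad value.
#' @return matrix of the same size as `img`.
#' @export
convolve2d <- function(img, kernel, boundary = "replicate") {
  if (any(dim(kernel) %% 2L == 0L)) stopf("kernel dimensions must be odd")
  out <- EBImage::filter2(img, kernel, boundary = boundary)
  ## FFT round-off can leave tiny negatives on a non-negative input
  if (min(img) >= 0 && min(kernel) >= 0) out[out < 0] <- 0
  as.matrix(out)
}

#' Synthetic sub-resolution bead field (3D z-stack)
#'
#' Point emitters rendered as 3D Gaussians of known lateral sigma,
#' brightest at the central z-plane, placed without overlap on a uniform
#' baseline, with additive Gaussian read noise. Emulates a TetraSpeck
#' bead acquisition used to calibrate the PSF.
#'
#' @param n_beads number of beads (>= 1).
#' @param sigma_true lateral Gaussian sigma in pixels.
#' @param z_planes number of z planes (>= 3).
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param seed integer seed.
#' @param image_size `(y, x)` size in pixels.
#' @param amplitude peak intensity of a bead at focus.
#' @param baseline constant background level.
#' @param sigma_z axial Gaussian sigma in planes.
#' @return list with `image` (`ImageStack`, `(z, y, x)`) and `truth`
#'   (`GroundTruth` with bead centres, focal plane and `sigma_true`).
#' @export
make_bead_field <- function(n_beads, sigma_true, z_planes = 11L, noise_sd = 0,
                            seed = 1L, image_size = c(128L, 128L),
                            amplitude = 1000, baseline = 100, sigma_z = 2) {
  if (n_beads < 1) stopf("n_beads must be >= 1")
  if (sigma_true <= 0) stopf("sigma_true must be > 0")
  if (z_planes < 3) stopf("need >= 3 z planes")
  margin <- ceiling(6 * sigma_true) + 2
  min_dist <- 10 * sigma_true
  centres <- with_seed(seed, {
    pts <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(pts) < n_beads) {
      cand <- c(runif(1, margin, image_size[1L] - margin),
                runif(1, margin, image_size[2L] - margin))
      ok <- nrow(pts) == 0L ||
        all(sqrt(rowSums(sweep(pts, 2, cand)^2)) >= min_dist)
      if (ok) pts <- rbind(pts, cand)
      tries <- tries + 1L
      if (tries > 10000L)
        stopf("cannot place %d beads without overlap on a %dx%d field",
              n_beads, image_size[1L], image_size[2L])
    }
    pts
  })
  zc <- (z_planes + 1) / 2
  arr <- array(baseline, c(z_planes, image_size))
  y <- matrix(seq_len(image_size[1L]), image_size[1L], image_size[2L])
  x <- matrix(seq_len(image_size[2L]), image_size[1L], image_size[2L],
              byrow = TRUE)
  for (z in seq_len(z_planes)) {
    zfac <- exp(-(z - zc)^2 / (2 * sigma_z^2))
    for (b in seq_len(n_beads)) {
      arr[z, , ] <- arr[z, , ] + amplitude * zfac *
        exp(-((y - centres[b, 1L])^2 + (x - centres[b, 2L])^2) /
              (2 * sigma_true^2))
    }
  }
  if (noise_sd > 0) {
    arr <- arr + with_seed(derive_seed(seed, 1L),
                           array(stats::rnorm(length(arr), 0, noise_sd), dim(arr)))
    arr[arr < 0] <- 0
  }
  truth <- ground_truth("beads", list(
    centres = centres, sigma_true = sigma_true,
    fwhm_true = 2 * sqrt(2 * log(2)) * sigma_true,
    focal_plane = as.integer(round(zc)), amplitude = amplitude,
    baseline = baseline,
    noise_sd = noise_sd), seed)
  list(image = image_stack(arr, channel_name = "beads", corrected = TRUE),
       truth = truth)
}

#' Sample a non-overlapping droplet layout
#'
#' Convenience sampler for [make_droplet_image()]: places `n` droplet
#' centres with diameters drawn uniformly from `diameter_range`, keeping a
#' clearance of `gap_px` between disc rims so each droplet's ground truth
#' stays uncorrupted by its neighbours' blur halos.
#'
#' @param n number of droplets.
#' @param diameter_range `(min, max)` diameter in pixels.
#' @param image_size `(y, x)` field size.
#' @param gap_px minimum rim-to-rim clearance.
#' @param seed integer seed.
#' @return data.frame with `cy`, `cx`, `diameter_px`.
#' @export
sample_droplet_layout <- function(n, diameter_range, image_size,
                                  gap_px = 12, seed = 1L) {
  with_seed(seed, {
    out <- data.frame(cy = numeric(0), cx = numeric(0), diameter_px = numeric(0))
    tries <- 0L
    while (nrow(out) < n) {
      d <- stats::runif(1, diameter_range[1L], diameter_range[2L])
      m <- d / 2 + gap_px
      cand <- c(stats::runif(1, m, image_size[1L] - m),
                stats::runif(1, m, image_size[2L] - m))
      ok <- nrow(out) == 0L ||
        all(sqrt((out$cy - cand[1L])^2 + (out$cx - cand[2L])^2) >=
              (out$diameter_px + d) / 2 + gap_px)
      if (ok) out <- rbind(out, data.frame(cy = cand[1L], cx = cand[2L],
                                           diameter_px = d))
      tries <- tries + 1L
      if (tries > 20000L)
        stopf("cannot place %d droplets without overlap", n)
    }
    out
  })
}

#' Synthetic multi-channel droplet field
#'
#' Renders bright discs ("droplets") of known interior level on a uniform
#' bulk, blurs with a normalized Gaussian PSF of the given FWHM, applies a
#' multiplicative illumination field, adds a constant camera offset and
#' optional Poisson shot noise (on the pre-offset signal) plus Gaussian
#' read noise. The ground truth stores each droplet's true per-channel
#' partition ratio interior/bulk.
#'
#' @param droplets data.frame with `cy`, `cx`, `diameter_px` and one
#'   `interior_<channel>` column per channel (see `bulk_level` names).
#' @param bulk_level named per-channel bulk intensity (>= 0).
#' @param psf_fwhm Gaussian PSF FWHM in pixels (0 = no blur).
#' @param image_size `(y, x)` size in pixels.
#' @param illumination_field `"uniform"` or a matrix of factors in (0, 1].
#' @param background_offset constant additive offset (camera dark level).
#' @param noise_model `"none"`, `"gaussian"` or `"poisson"`; Poisson is
#'   applied to the pre-offset signal, Gaussian read noise (sd
#'   `noise_sd`) after.
#' @param noise_sd Gaussian read-noise sd.
#' @param seed integer seed.
#' @param pixel_size_um pixel size forwarded to the ImageStacks.
#' @return list with `channels` (named list of `ImageStack`s) and `truth`;
#'   the truth holds the droplet table with per-channel true partition
#'   ratios, the bulk levels, the illumination field and the offset.
#' @export
make_droplet_image <- function(droplets, bulk_level, psf_fwhm = 0,
                               image_size = c(256L, 256L),
                               illumination_field = "uniform",
                               background_offset = 0,
                               noise_model = c("none", "gaussian", "poisson"),
                               noise_sd = 0, seed = 1L, pixel_size_um = 0.25) {
  noise_model <- match.arg(noise_model)
  channels <- names(bulk_level)
  if (is.null(channels)) stopf("bulk_level must be a named vector")
  icol <- paste0("interior_", channels)
  missing_cols <- setdiff(icol, names(droplets))
  if (length(missing_cols))
    stopf("droplets table lacks columns: %s", paste(missing_cols, collapse = ", "))
  if (nrow(droplets) > 0) {
    if (any(droplets$diameter_px < 1)) stopf("diameters must be >= 1 px")
    for (j in seq_along(channels)) {
      if (any(droplets[[icol[j]]] < bulk_level[j]))
        stopf("interior levels must be >= bulk level (channel %s)", channels[j])
    }
    ## reject overlapping discs: overlap corrupts per-droplet truth
    if (nrow(droplets) > 1) {
      dd <- as.matrix(stats::dist(droplets[, c("cy", "cx")]))
      rr <- outer(droplets$diameter_px, droplets$diameter_px, "+") / 2
      diag(dd) <- Inf
      if (any(dd < rr)) stopf("overlapping discs in droplet layout")
    }
  }
  if (identical(illumination_field, "uniform")) {
    illum <- matrix(1, image_size[1L], image_size[2L])
  } else {
    illum <- illumination_field
    if (any(illum <= 0) || any(illum > 1))
      stopf("illumination field values must lie in (0, 1]")
  }
  kern <- if (psf_fwhm > 0) gaussian_psf(psf_fwhm) else NULL
  cov_list <- lapply(seq_len(nrow(droplets)), function(i)
    disc_coverage(image_size[1L], image_size[2L],
                  c(droplets$cy[i], droplets$cx[i]), droplets$diameter_px[i]))
  out <- list()
  for (j in seq_along(channels)) {
    ideal <- matrix(bulk_level[j], image_size[1L], image_size[2L])
    for (i in seq_along(cov_list)) {
      ideal <- ideal + (droplets[[icol[j]]][i] - bulk_level[j]) * cov_list[[i]]
    }
    sig <- if (is.null(kern)) ideal else convolve2d(ideal, kern)
    sig <- sig * illum
    sub <- derive_seed(seed, 10L + j)
    if (noise_model == "poisson") {
      sig <- with_seed(sub, matrix(stats::rpois(length(sig), lambda = sig),
                                   nrow(sig), ncol(sig)))
    }
    sig <- sig + background_offset
    if (noise_model %in% c("gaussian", "poisson") && noise_sd > 0) {
      sig <- sig + with_seed(derive_seed(seed, 20L + j),
                             matrix(stats::rnorm(length(sig), 0, noise_sd),
                                    nrow(sig), ncol(sig)))
    }
    sig[sig < 0] <- 0
    out[[channels[j]]] <- image_stack(sig, channel_name = channels[j],
                                      pixel_size_um = pixel_size_um,
                                      corrected = TRUE)
  }
  tp <- droplets
  for (j in seq_along(channels)) {
    tp[[paste0("true_pc_", channels[j])]] <-
      if (nrow(droplets)) droplets[[icol[j]]] / bulk_level[j] else numeric(0)
  }
  truth <- ground_truth("droplets", list(
    droplets = tp, bulk_level = bulk_level, psf_fwhm = psf_fwhm,
    illumination_field = illum, background_offset = background_offset,
    noise_model = noise_model, noise_sd = noise_sd), seed)
  list(channels = out, truth = truth)
}

#' Synthetic FRAP time series
#'
#' Generates a photobleaching-recovery trace table (time, ROI, reference,
#' background) following a one- or two-component exponential recovery with
#' whole-field acquisition photobleaching. Time is reported with t = 0 at
#' the first post-bleach frame; prebleach frames carry negative times.
#' The reference region decays only by acquisition bleaching.
#'
#' @param mobile_fractions `(f1)` or `(f1, f2)`; together with the
#'   immobile fraction they sum to 1.
#' @param rate_constants matching `(k1)` or `(k1, k2)` in 1/s, `k1 > k2`.
#' @param bleach_depth post-bleach ROI intensity as a fraction of
#'   prebleach, in \[0, 1).
#' @param acquisition_bleach_rate 1/s, applied to the whole field from the
#'   first acquired frame.
#' @param n_prebleach number of prebleach frames (>= 3).
#' @param interval_s frame interval (s).
#' @param duration_s post-bleach observation window (s).
#' @param noise_sd additive Gaussian noise sd on ROI and reference.
#' @param seed integer seed.
#' @param i_pre prebleach ROI plateau intensity (a.u.).
#' @param i_background constant background level (a.u.).
#' @return list with `trace` (data.frame `t`, `roi_intensity`,
#'   `reference_intensity`, `background_intensity`) and `truth`
#'   (fractions, rates, per-component half-times `ln(2)/k`).
#' @export
make_frap_series <- function(mobile_fractions, rate_constants,
                             bleach_depth = 0.1,
                             acquisition_bleach_rate = 0,
                             n_prebleach = 3L, interval_s = 1,
                             duration_s = 90, noise_sd = 0, seed = 1L,
                             i_pre = 1000, i_background = 100) {
  f <- as.numeric(mobile_fractions)
  k <- as.numeric(rate_constants)
  if (length(f) != length(k) || !length(f) %in% 1:2)
    stopf("mobile_fractions and rate_constants must both have length 1 or 2")
  if (any(f < 0) || any(f > 1) || sum(f) > 1)
    stopf("fractions must lie in [0,1] and sum to <= 1")
  if (any(k <= 0)) stopf("rate constants must be > 0")
  if (length(k) == 2L && !(k[1L] > k[2L]))
    stopf("biexponential rates must satisfy k1 > k2")
  if (bleach_depth < 0 || bleach_depth >= 1)
    stopf("bleach_depth must lie in [0, 1)")
  if (n_prebleach < 3) stopf("need >= 3 prebleach frames")
  t_post <- seq(0, duration_s, by = interval_s)
  t_pre <- -rev(seq_len(n_prebleach)) * interval_s
  t_all <- c(t_pre, t_post)
  t_acq <- t_all - t_all[1L]  # time since first acquired frame
  i_post <- bleach_depth * i_pre
  recov <- function(t) {
    r <- rep(0, length(t))
    for (j in seq_along(f)) r <- r + f[j] * (1 - exp(-k[j] * t))
    r
  }
  roi_clean <- ifelse(
    t_all < 0, i_pre,
    i_post + (i_pre - i_post) * recov(pmax(t_all, 0)))
  bleach_fac <- exp(-acquisition_bleach_rate * t_acq)
  roi <- i_background + roi_clean * bleach_fac
  ref <- i_background + i_pre * bleach_fac
  if (noise_sd > 0) {
    roi <- roi + with_seed(derive_seed(seed, 1L),
                           stats::rnorm(length(roi), 0, noise_sd))
    ref <- ref + with_seed(derive_seed(seed, 2L),
                           stats::rnorm(length(ref), 0, noise_sd))
  }
  trace <- data.frame(t = t_all, roi_intensity = roi,
                      reference_intensity = ref,
                      background_intensity = i_background)
  truth <- ground_truth("frap", list(
    fractions = f, rate_constants = k, t_half = log(2) / k,
    bleach_depth = bleach_depth,
    acquisition_bleach_rate = acquisition_bleach_rate,
    n_prebleach = as.integer(n_prebleach), interval_s = interval_s,
    duration_s = duration_s, noise_sd = noise_sd,
    normalized_clean = recov(t_post), t_post = t_post), seed)
  list(trace = trace, truth = truth)
}

#' Elliptical cell mask
#'
#' @param image_size `(y, x)` size.
#' @param centre `(y, x)` centre; defaults to the image centre.
#' @param semi_axes `(a_y, a_x)` semi-axes in pixels; defaults to 40% of
#'   each image dimension.
#' @return logical matrix.
#' @export
make_cell_mask <- function(image_size, centre = NULL, semi_axes = NULL) {
  if (is.null(centre)) centre <- (image_size + 1) / 2
  if (is.null(semi_axes)) semi_axes <- 0.4 * image_size
  y <- matrix(seq_len(image_size[1L]), image_size[1L], image_size[2L])
  x <- matrix(seq_len(image_size[2L]), image_size[1L], image_size[2L],
              byrow = TRUE)
  ((y - centre[1L]) / semi_axes[1L])^2 + ((x - centre[2L]) / semi_axes[2L])^2 <= 1
}

#' Synthetic cell image with punctate adhesions
#'
#' Places elliptical puncta ("adhesions") of sampled areas inside a cell
#' mask without touching, on a cytoplasmic plateau over an off-cell
#' background, with light optical blur and Gaussian noise. Emulates a
#' paxillin-immunostained spreading cell used for adhesion counting.
#'
#' @param cell_mask logical matrix (the cell region), e.g. from
#'   [make_cell_mask()].
#' @param n_adhesions number of puncta (>= 0).
#' @param area_range `(min, max)` punctum area in px^2.
#' @param adhesion_level punctum intensity (> `cytoplasm_level`).
#' @param cytoplasm_level cytoplasm intensity (> `background_level`).
#' @param background_level off-cell intensity.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed integer seed.
#' @param blur_fwhm_px optical blur FWHM (0 disables).
#' @param edge_softness_fwhm_px width of the cell-body edge falloff: a
#'   real cytoplasmic immunofluorescence background fades over roughly
#'   0.5-1 um (several pixels), not a one-pixel step, so the cell outline
#'   is rendered through a Gaussian of this FWHM (0 gives a hard edge).
#' @param min_gap_px minimum clearance between puncta rims.
#' @param aspect_range `(min, max)` ellipse axis ratio.
#' @return list with `image` (`ImageStack`) and `truth` (punctum count,
#'   centres, areas, the true adhesion/cytoplasm ratio and the levels).
#' @export
make_adhesion_image <- function(cell_mask, n_adhesions, area_range = c(8, 60),
                                adhesion_level = 1000, cytoplasm_level = 300,
                                background_level = 100, noise_sd = 10,
                                seed = 1L, blur_fwhm_px = 2,
                                edge_softness_fwhm_px = 8,
                                min_gap_px = 12, aspect_range = c(1, 2)) {
  if (!(adhesion_level > cytoplasm_level && cytoplasm_level > background_level))
    stopf("need adhesion_level > cytoplasm_level > background_level")
  sz <- dim(cell_mask)
  ## erode the cell mask so puncta sit fully inside
  inner <- EBImage::erode(cell_mask * 1L, EBImage::makeBrush(11L, "disc")) > 0
  body <- cell_mask * 1
  if (edge_softness_fwhm_px > 0)
    body <- convolve2d(body, gaussian_psf(edge_softness_fwhm_px))
  img <- background_level + (cytoplasm_level - background_level) * body
  puncta <- data.frame(cy = numeric(0), cx = numeric(0), area_px2 = numeric(0))
  cov_total <- matrix(0, sz[1L], sz[2L])
  if (n_adhesions > 0) {
    y <- matrix(seq_len(sz[1L]), sz[1L], sz[2L])
    x <- matrix(seq_len(sz[2L]), sz[1L], sz[2L], byrow = TRUE)
    ok_idx <- which(inner)
    puncta <- with_seed(seed, {
      placed <- data.frame(cy = numeric(0), cx = numeric(0),
                           a = numeric(0), b = numeric(0),
                           theta = numeric(0))
      tries <- 0L
      while (nrow(placed) < n_adhesions) {
        area <- stats::runif(1, area_range[1L], area_range[2L])
        asp <- stats::runif(1, aspect_range[1L], aspect_range[2L])
        b <- sqrt(area / (pi * asp)); a <- asp * b  # semi-axes, area = pi a b
        idx <- ok_idx[sample.int(length(ok_idx), 1L)]
        cy <- y[idx]; cx <- x[idx]
        clear <- a + min_gap_px
        sep_ok <- nrow(placed) == 0L ||
          all(sqrt((placed$cy - cy)^2 + (placed$cx - cx)^2) >=
                (placed$a + clear))
        if (sep_ok) {
          placed <- rbind(placed, data.frame(
            cy = cy, cx = cx, a = a, b = b,
            theta = stats::runif(1, 0, pi)))
        }
        tries <- tries + 1L
        if (tries > 50000L)
          stopf("cannot place %d puncta disjointly inside the cell", n_adhesions)
      }
      placed
    })
    for (i in seq_len(nrow(puncta))) {
      ct <- cos(puncta$theta[i]); st <- sin(puncta$theta[i])
      u <- (x - puncta$cx[i]) * ct + (y - puncta$cy[i]) * st
      v <- -(x - puncta$cx[i]) * st + (y - puncta$cy[i]) * ct
      inside <- (u / puncta$a[i])^2 + (v / puncta$b[i])^2 <= 1
      cov_total[inside] <- 1
    }
    img[cov_total > 0] <- adhesion_level
    puncta$area_px2 <- pi * puncta$a * puncta$b
  }
  if (blur_fwhm_px > 0) img <- convolve2d(img, gaussian_psf(blur_fwhm_px))
  if (noise_sd > 0) {
    img <- img + with_seed(derive_seed(seed, 3L),
                           matrix(stats::rnorm(length(img), 0, noise_sd),
                                  sz[1L], sz[2L]))
    img[img < 0] <- 0
  }
  truth <- ground_truth("adhesions", list(
    n_adhesions = as.integer(n_adhesions),
    puncta = puncta[, intersect(c("cy", "cx", "area_px2"), names(puncta))],
    adhesion_level = adhesion_level, cytoplasm_level = cytoplasm_level,
    background_level = background_level,
    true_ratio = (adhesion_level - background_level) /
      (cytoplasm_level - background_level),
    cell_mask = cell_mask, noise_sd = noise_sd,
    blur_fwhm_px = blur_fwhm_px), seed)
  list(image = image_stack(img, channel_name = "paxillin", corrected = TRUE),
       truth = truth)
}

#' Synthetic flat-field calibration pair
#'
#' A dye image (uniform fluorophore solution seen through the instrument's
#' shading field) plus a dark frame, from which the flat-field correction
#' is recovered.
#'
#' @param gradient either `"uniform"`, a matrix of multiplicative factors
#'   in (0, 1], or `"ramp"` for a linear 0.5 -> 1.0 left-to-right ramp.
#' @param image_size `(y, x)` size (ignored when `gradient` is a matrix).
#' @param dye_level uniform dye intensity before shading.
#' @param dark_level camera dark level.
#' @param noise_sd additive Gaussian noise sd on both frames.
#' @param seed integer seed.
#' @return list with `dye_image`, `dark_image` (`ImageStack`s) and `truth`
#'   (the gradient field).
#' @export
make_flatfield_pair <- function(gradient = "uniform",
                                image_size = c(256L, 256L),
                                dye_level = 2000, dark_level = 100,
                                noise_sd = 0, seed = 1L) {
  if (is.matrix(gradient)) {
    field <- gradient
    image_size <- dim(field)
  } else if (identical(gradient, "uniform")) {
    field <- matrix(1, image_size[1L], image_size[2L])
  } else if (identical(gradient, "ramp")) {
    field <- matrix(seq(0.5, 1, length.out = image_size[2L]),
                    image_size[1L], image_size[2L], byrow = TRUE)
  } else stopf("gradient must be 'uniform', 'ramp' or a matrix")
  if (any(field <= 0) || any(field > 1))
    stopf("gradient field values must lie in (0, 1]")
  dye <- dye_level * field + dark_level
  dark <- matrix(dark_level, image_size[1L], image_size[2L])
  if (noise_sd > 0) {
    dye <- dye + with_seed(derive_seed(seed, 1L),
                           matrix(stats::rnorm(length(dye), 0, noise_sd),
                                  image_size[1L], image_size[2L]))
    dark <- dark + with_seed(derive_seed(seed, 2L),
                             matrix(stats::rnorm(length(dark), 0, noise_sd),
                                    image_size[1L], image_size[2L]))
    dye[dye < 0] <- 0; dark[dark < 0] <- 0
  }
  truth <- ground_truth("flatfield", list(
    gradient = field, dye_level = dye_level, dark_level = dark_level,
    noise_sd = noise_sd), seed)
  list(dye_image = image_stack(dye, channel_name = "dye", corrected = TRUE),
       dark_image = image_stack(dark, channel_name = "dark", corrected = TRUE),
       truth = truth)
}

#' Synthetic TIRF cluster field
#'
#' Countable bright clusters on a membrane-level background at a
#' specified surface density; a thin wrapper over the droplet renderer
#' with cluster-scale defaults, for validating cluster-density and
#' enrichment measurements.
#'
#' @param n_clusters number of clusters.
#' @param image_size `(y, x)` pixels.
#' @param pixel_size_um pixel size (sets the field area).
#' @param membrane_level background membrane intensity.
#' @param cluster_level in-cluster intensity.
#' @param diameter_range cluster diameter range (px).
#' @param psf_fwhm blur FWHM (px).
#' @param noise_sd Gaussian noise sd.
#' @param seed integer seed.
#' @return list with `image` (`ImageStack`) and `truth` (count, layout,
#'   true density per mm^2, true fold enrichment).
#' @export
make_cluster_field <- function(n_clusters, image_size = c(256L, 256L),
                               pixel_size_um = 0.2, membrane_level = 200,
                               cluster_level = 400,
                               diameter_range = c(14, 20), psf_fwhm = 2,
                               noise_sd = 5, seed = 1L) {
  layout <- if (n_clusters > 0) {
    sample_droplet_layout(n_clusters, diameter_range, image_size,
                          gap_px = 10, seed = seed)
  } else data.frame(cy = numeric(0), cx = numeric(0), diameter_px = numeric(0))
  layout$interior_mem <- rep(cluster_level, nrow(layout))
  gen <- make_droplet_image(layout, bulk_level = c(mem = membrane_level),
                            psf_fwhm = psf_fwhm, image_size = image_size,
                            noise_model = if (noise_sd > 0) "gaussian" else "none",
                            noise_sd = noise_sd, seed = derive_seed(seed, 7L),
                            pixel_size_um = pixel_size_um)
  area_mm2 <- prod(image_size) * (pixel_size_um / 1000)^2
  truth <- ground_truth("clusters", list(
    n_clusters = as.integer(n_clusters), layout = layout,
    field_area_mm2 = area_mm2,
    true_density_per_mm2 = n_clusters / area_mm2,
    true_fold_enrichment = cluster_level / membrane_level,
    membrane_level = membrane_level, cluster_level = cluster_level), seed)
  list(image = gen$channels$mem, truth = truth)
}
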