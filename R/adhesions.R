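## Adhesion morphometrics: the ImageJ-style segmentation chain for
## counting nascent adhesions (rolling-ball background, CLAHE,
## exponential remap, contrast stretch, LoG filtering, intermeans
## thresholding, particle analysis), the fixed-threshold total-adhesion-
## area measurement, the adhesion partition coefficient, and GFP
## expression gating.

#' Sliding-paraboloid ("rolling ball") background subtraction
#'
#' Estimates the background as a grayscale opening with a paraboloid of
#' the given radius of curvature slid along image rows and then columns
#' (the 1D-sliding variant of rolling-ball background subtraction), and
#' subtracts it. The paraboloid height profile is `s^2 / (2 r)` in gray
#' levels on a 0-255 scale; the image is mapped to that scale internally
#' so the behaviour is independent of the input's absolute gain. Affine
#' backgrounds (constants, gentle ramps) are removed exactly; puncta
#' narrower than the paraboloid pass through.
#'
#' @param image 2D `ImageStack` or matrix.
#' @param radius_px paraboloid radius of curvature in pixels (default 50).
#' @param sliding must be `TRUE` (only the sliding-paraboloid variant is
#'   implemented).
#' @return background-subtracted matrix (non-negative, original units).
#' @export
rolling_ball_background <- function(image, radius_px = 50, sliding = TRUE) {
  img <- if (inherits(image, "ImageStack")) get_frame(image, 1L) else image
  if (!isTRUE(sliding)) stopf("only the sliding-paraboloid variant is implemented")
  if (radius_px >= min(dim(img)))
    stopf("radius (%g px) must be smaller than the image extent", radius_px)
  rng <- diff(range(img))
  if (rng == 0) return(img * 0)
  lo <- min(img)
  g <- (img - lo) / rng * 255
  bg <- paraboloid_pass(g, radius_px, along = "cols")
  bg <- paraboloid_pass(bg, radius_px, along = "rows")
  out <- pmax(g - bg, 0)
  out / 255 * rng
}

## 1D grayscale opening with structuring function s^2/(2r) along rows or
## columns of a matrix, vectorized over shifts.
paraboloid_pass <- function(m, r, along = c("cols", "rows")) {
  along <- match.arg(along)
  if (along == "rows") return(t(paraboloid_pass(t(m), r, "cols")))
  w <- min(2L * as.integer(ceiling(r)), ncol(m) - 1L)
  shifts <- seq.int(-w, w)
  pen <- shifts^2 / (2 * r)
  e <- m
  for (i in seq_along(shifts)) {
    s <- shifts[i]
    if (s == 0L) next
    e <- pmin(e, shift_matrix(m, 0L, s, fill = Inf) + pen[i])
  }
  d <- e
  for (i in seq_along(shifts)) {
    s <- shifts[i]
    if (s == 0L) next
    d <- pmax(d, shift_matrix(e, 0L, s, fill = -Inf) - pen[i])
  }
  d
}

#' Contrast-limited adaptive histogram equalization
#'
#' CLAHE (via [EBImage::clahe]) with an ImageJ-style parameterization:
#' `blocksize` is the local tile size in pixels, `histogram_bins` the
#' number of histogram bins and `max_slope` the clip limit. The image is
#' normalized to \[0, 1\] by its own range before equalization, so the
#' result is invariant under global gain changes.
#'
#' @param image 2D `ImageStack` or matrix.
#' @param blocksize tile size in pixels (>= 3).
#' @param histogram_bins histogram bins.
#' @param max_slope clip limit.
#' @return equalized matrix in \[0, 1\].
#' @export
clahe_local_contrast <- function(image, blocksize = 19, histogram_bins = 256,
                                 max_slope = 6) {
  img <- if (inherits(image, "ImageStack")) get_frame(image, 1L) else image
  if (blocksize < 3) stopf("blocksize must be >= 3")
  rng <- diff(range(img))
  if (rng == 0) return(img * 0 + 0.5)  # no contrast to stretch
  v <- (img - min(img)) / rng
  nx <- max(2L, as.integer(round(ncol(v) / blocksize)))
  ny <- max(2L, as.integer(round(nrow(v) / blocksize)))
  ## EBImage::clahe needs dimensions divisible by the tile counts:
  ## pad by edge replication, equalize, crop back
  nr2 <- as.integer(ceiling(nrow(v) / ny) * ny)
  nc2 <- as.integer(ceiling(ncol(v) / nx) * nx)
  vp <- v[c(seq_len(nrow(v)), rep(nrow(v), nr2 - nrow(v))),
          c(seq_len(ncol(v)), rep(ncol(v), nc2 - ncol(v))), drop = FALSE]
  out <- EBImage::clahe(EBImage::Image(vp), nx = nx, ny = ny,
                        bins = histogram_bins, limit = max_slope)
  m <- as.matrix(EBImage::imageData(out))[seq_len(nrow(v)), seq_len(ncol(v))]
  pmin(pmax(m, 0), 1)
}

#' Monotone exponential intensity remap
#'
#' `v -> M (exp(c v / M) - 1) / (exp(c) - 1)` with curvature `c`:
#' preserves the endpoints 0 and `M`, preserves ordering, and compresses
#' the lower half-range (dim background) while expanding bright values.
#' The default curvature `c = 8 ln 2` maps the midpoint to `M/16`.
#'
#' @param image 2D `ImageStack` or matrix.
#' @param max_value display maximum `M` (defaults to the image max).
#' @param curvature exponent `c` (> 0).
#' @return remapped matrix.
#' @export
exp_transform <- function(image, max_value = NULL, curvature = 8 * log(2)) {
  img <- if (inherits(image, "ImageStack")) get_frame(image, 1L) else image
  if (curvature <= 0) stopf("curvature must be > 0")
  m <- if (is.null(max_value)) max(img) else max_value
  if (m <= 0) return(img * 0)
  m * (exp(curvature * img / m) - 1) / (exp(curvature) - 1)
}

#' Linear contrast stretch with tail saturation
#'
#' Rescales linearly so that `saturated_percent` percent of pixels (split
#' between the two tails) clip at the new extremes `0` and `max_value`.
#' A constant image is returned unchanged (logged).
#'
#' @param image 2D `ImageStack` or matrix.
#' @param saturated_percent percentage of pixels to saturate.
#' @param max_value top of the output range (defaults to the image max).
#' @return stretched matrix in \[0, max_value\].
#' @export
enhance_contrast <- function(image, saturated_percent = 0.35,
                             max_value = NULL) {
  img <- if (inherits(image, "ImageStack")) get_frame(image, 1L) else image
  if (diff(range(img)) == 0) {
    cq_log("enhance_contrast", "constant image: no stretch possible")
    return(img)
  }
  m <- if (is.null(max_value)) max(img) else max_value
  n <- length(img)
  k <- floor(saturated_percent / 100 * n / 2)
  srt <- sort(as.vector(img))
  ## clip at the midpoint between the k-th and (k+1)-th order statistics
  ## so that exactly k pixels saturate in each tail (ties aside)
  lo <- if (k >= 1L) (srt[k] + srt[k + 1L]) / 2 else srt[1L]
  hi <- if (k >= 1L) (srt[n - k] + srt[n - k + 1L]) / 2 else srt[n]
  if (hi <= lo) {
    cq_log("enhance_contrast", "degenerate quantiles: image unchanged")
    return(img)
  }
  pmin(pmax((img - lo) / (hi - lo), 0), 1) * m
}

#' Laplacian-of-Gaussian blob filter
#'
#' Convolves with a zero-sum LoG kernel at scale `sigma`, with the sign
#' flipped so bright blobs are response maxima. The negative undershoot
#' rings around blobs carry no information for bright-blob detection but
#' would dominate the histogram range fed to the subsequent global
#' threshold, so the response is half-wave rectified (clipped at 0) and
#' then rescaled to \[0, 1\]. Maximal for blobs whose radius matches
#' `sigma * sqrt(2)`.
#'
#' @param image 2D `ImageStack` or matrix.
#' @param sigma blob scale in pixels (default 2).
#' @return rectified, rescaled response matrix in \[0, 1\].
#' @export
log_filter <- function(image, sigma = 2) {
  img <- if (inherits(image, "ImageStack")) get_frame(image, 1L) else image
  r <- as.integer(ceiling(4 * sigma))
  s <- seq(-r, r)
  r2 <- outer(s^2, s^2, "+")
  k <- -(r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k <- k - mean(k)  # exact zero response to a constant
  resp <- as.matrix(EBImage::filter2(img, k, boundary = "replicate"))
  resp <- pmax(resp, 0)
  mx <- max(resp)
  ## a flat image leaves only FFT round-off dust; do not rescale that
  if (mx <= 1e-8 * max(abs(img), 1)) return(resp * 0)
  resp / mx
}

round_half_up <- function(x) floor(x + 0.5)

#' Intermeans ("Default dark") global threshold
#'
#' Iterative intermeans (IsoData-variant) threshold on a 256-bin
#' histogram: starting from the lowest occupied bin, the candidate is
#' repeatedly replaced by the rounded mean of the two class means until
#' it no longer moves up; foreground is everything strictly above the
#' threshold (dark-background convention, so bright adhesions come out
#' as foreground and no mask inversion step is needed).
#'
#' @param image 2D `ImageStack` or matrix.
#' @param bins histogram bins.
#' @return logical foreground mask with attributes `threshold` (intensity
#'   units) and `threshold_bin` (0-based bin index).
#' @export
threshold_default_dark <- function(image, bins = 256L) {
  img <- if (inherits(image, "ImageStack")) get_frame(image, 1L) else image
  rng <- range(img)
  if (diff(rng) == 0) {
    cq_log("threshold", "constant image: empty mask")
    mask <- matrix(FALSE, nrow(img), ncol(img))
    attr(mask, "threshold") <- NA_real_
    return(mask)
  }
  bw <- diff(rng) / bins
  bin <- pmin(floor((img - rng[1L]) / bw), bins - 1L)
  h <- tabulate(as.vector(bin) + 1L, bins)
  tbin <- as.integer(intermeans_bin(h))
  mask <- bin > tbin
  attr(mask, "threshold") <- rng[1L] + (tbin + 1) * bw
  attr(mask, "threshold_bin") <- tbin
  mask
}

## Iterative intermeans on a histogram of counts; returns the 0-based bin
## index T of the smallest fixed point (mask = bin > T).
intermeans_bin <- function(h) {
  bins <- length(h)
  idx <- seq_len(bins) - 1L
  nz <- which(h > 0L)
  f <- idx[nz[1L]]; l <- idx[nz[length(nz)]]
  if (f == l) return(f)  # single occupied bin
  cs <- cumsum(h); csx <- cumsum(h * idx)
  mean_update <- function(T) {
    i <- T + 1L
    m0 <- csx[i] / cs[i]
    m1 <- (csx[bins] - csx[i]) / (cs[bins] - cs[i])
    round_half_up((m0 + m1) / 2)
  }
  T <- f
  while (T < l) {
    Tn <- mean_update(T)
    if (Tn <= T) return(T)
    T <- Tn
  }
  l - 1L
}

#' ImageJ-style particle analysis of a binary mask
#'
#' 8-connected components filtered by area (px^2) and circularity
#' `4 pi area / perimeter^2` (clipped at 1 for discretized small objects).
#'
#' @param mask logical/binary matrix.
#' @param min_area,max_area area window in px^2 (default 5-1000).
#' @param min_circ,max_circ circularity window (default 0-1).
#' @param intensity optional matrix for per-particle mean intensity.
#' @return list with `count` and `records` (per-particle `adhesion_id`,
#'   `area_px2`, `circularity`, `cy`, `cx`, `mean_intensity`).
#' @export
count_particles <- function(mask, min_area = 5, max_area = 1000,
                            min_circ = 0, max_circ = 1, intensity = NULL) {
  lab <- label_components(mask, connectivity = 8L)
  feats <- region_features(lab, intensity)
  keep <- feats$area_px2 >= min_area & feats$area_px2 <= max_area &
    feats$circularity >= min_circ & feats$circularity <= max_circ
  rec <- feats[keep, , drop = FALSE]
  rec <- data.frame(adhesion_id = seq_len(nrow(rec)),
                    area_px2 = rec$area_px2, circularity = rec$circularity,
                    cy = rec$cy, cx = rec$cx,
                    mean_intensity = rec$mean_intensity)
  list(count = nrow(rec), records = rec)
}

#' Count nascent adhesions with the full segmentation chain
#'
#' Composes, with their standard parameters: sliding-paraboloid
#' background subtraction (radius 50), CLAHE (blocksize 19, 256 bins,
#' max slope 6), exponential remap, linear contrast stretch (0.35%
#' saturated), LoG filtering (sigma 2), intermeans dark-background
#' thresholding and particle analysis (area 5-1000 px^2, circularity
#' 0-1). The chain operates on a range-normalized copy of the image, so
#' the count is invariant under global intensity scaling.
#'
#' @param image 2D `ImageStack` or matrix (punctate adhesion staining,
#'   e.g. paxillin).
#' @param rolling_radius_px background radius.
#' @param clahe_blocksize,clahe_bins,clahe_max_slope CLAHE parameters.
#' @param exp_curvature exponential remap curvature.
#' @param saturated_percent contrast-stretch saturation.
#' @param log_sigma LoG scale (px).
#' @param min_area,max_area particle area window (px^2).
#' @return list with `count`, `records`, and `mask` (the final binary
#'   mask, for visual confirmation against the original image).
#' @export
count_adhesions <- function(image, rolling_radius_px = 50,
                            clahe_blocksize = 19, clahe_bins = 256,
                            clahe_max_slope = 6,
                            exp_curvature = 8 * log(2),
                            saturated_percent = 0.35, log_sigma = 2,
                            min_area = 5, max_area = 1000) {
  img <- if (inherits(image, "ImageStack")) get_frame(image, 1L) else image
  v <- rolling_ball_background(img, rolling_radius_px, sliding = TRUE)
  rng <- diff(range(v))
  if (rng == 0) {
    return(list(count = 0L,
                records = count_particles(matrix(FALSE, nrow(img), ncol(img)))$records,
                mask = matrix(FALSE, nrow(img), ncol(img))))
  }
  v <- (v - min(v)) / rng
  v <- clahe_local_contrast(v, clahe_blocksize, clahe_bins, clahe_max_slope)
  v <- exp_transform(v, max_value = 1, curvature = exp_curvature)
  v <- enhance_contrast(v, saturated_percent, max_value = 1)
  v <- log_filter(v, log_sigma)
  mask <- threshold_default_dark(v)
  res <- count_particles(mask, min_area, max_area, intensity = img)
  res$mask <- mask
  res
}

#' Total adhesion area by fixed thresholding
#'
#' Area of pixels within the fixed 16-bit window `[lower, upper]`
#' (defaults 5500-65535), in px^2 or um^2 when a pixel size is given.
#'
#' @param image 2D `ImageStack` or matrix (16-bit scale).
#' @param lower,upper threshold window.
#' @param pixel_size_um optional; converts the area to um^2.
#' @return total thresholded area.
#' @export
total_adhesion_area <- function(image, lower = 5500, upper = 65535,
                                pixel_size_um = NULL) {
  img <- if (inherits(image, "ImageStack")) get_frame(image, 1L) else image
  if (lower > upper) stopf("lower threshold exceeds upper threshold")
  npx <- sum(img >= lower & img <= upper)
  if (is.null(pixel_size_um)) npx else npx * pixel_size_um^2
}

#' Adhesion partition coefficient of a single cell
#'
#' Two-stage Otsu segmentation: a first global threshold separates the
#' cell from the off-cell background (the cell region is the largest
#' connected component, holes filled); a second Otsu threshold inside the
#' cell separates adhesions from cytoplasm. The partition coefficient is
#' `(mean_adhesion - background) / (mean_cytoplasm - background)` with the
#' off-cell background supplied by the caller. The cytoplasm mean excludes
#' a dilated ring around each adhesion (its blur halo) and an eroded band
#' at the cell rim (partial-volume pixels), which would otherwise
#' contaminate it. The cell region is found automatically rather than by
#' manual thresholding; results carry the segmentation masks so they can
#' be checked visually.
#'
#' @param image 2D `ImageStack` or matrix (single-cell field).
#' @param background off-cell background intensity.
#' @param halo_dilation_px dilation of the adhesion mask excluded from
#'   the cytoplasm.
#' @param edge_erosion_px erosion of the cell mask for the cytoplasm
#'   measurement.
#' @return list with `pc`, `mean_adhesion`, `mean_cytoplasm`, `cell_mask`,
#'   `adhesion_mask`.
#' @export
adhesion_partition_coefficient <- function(image, background = 0,
                                           halo_dilation_px = 3,
                                           edge_erosion_px = 3) {
  img <- if (inherits(image, "ImageStack")) get_frame(image, 1L) else image
  t_cell <- otsu_threshold(img)
  if (is.na(t_cell)) stopf("segmentation failed: constant image")
  lab <- label_components(img > t_cell, connectivity = 8L)
  if (max(lab) == 0L) stopf("segmentation failed: no cell region found")
  areas <- tabulate(lab[lab > 0L], max(lab))
  cell <- EBImage::fillHull((lab == which.max(areas)) * 1L) > 0
  cell_core <- if (edge_erosion_px > 0) {
    EBImage::erode(cell * 1L,
                   EBImage::makeBrush(2L * as.integer(edge_erosion_px) + 1L,
                                      "disc")) > 0
  } else cell
  if (!any(cell_core)) stopf("cell region vanished after edge erosion")
  ## secondary threshold from the cell core: partial-volume rim pixels
  ## must not drive the adhesion/cytoplasm split
  t_adh <- otsu_threshold(matrix(img[cell_core]))
  if (is.na(t_adh)) stopf("segmentation failed: uniform cell interior")
  adh <- cell_core & img > t_adh
  cyto <- cell_core & !dilate_union(adh, halo_dilation_px)
  if (!any(cyto)) stopf("cytoplasm mask empty after excluding adhesions")
  if (!any(adh)) stopf("no adhesions above the secondary threshold")
  ma <- mean(img[adh]); mc <- mean(img[cyto])
  list(pc = (ma - background) / (mc - background),
       mean_adhesion = ma, mean_cytoplasm = mc,
       cell_mask = cell, adhesion_mask = adh)
}

#' Gate cells by GFP expression level
#'
#' Retains cells whose background-subtracted mean GFP intensity lies in
#' the inclusive window `[low, high]` (defaults 1000-5000 a.u.), to
#' reduce noise from expression-level differences.
#'
#' @param cells data.frame with a `gfp_mean` column.
#' @param low,high inclusive gating bounds (a.u.).
#' @return the filtered table, with a `retention` attribute (fraction of
#'   cells retained) and a `gated_in` column added to the input rows.
#' @export
gate_cells_by_gfp <- function(cells, low = 1000, high = 5000) {
  if (!"gfp_mean" %in% names(cells)) stopf("cells table lacks 'gfp_mean'")
  gated <- cells$gfp_mean >= low & cells$gfp_mean <= high
  cells$gated_in <- gated
  out <- cells[gated, , drop = FALSE]
  attr(out, "retention") <- if (nrow(cells)) mean(gated) else NA_real_
  out
}
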