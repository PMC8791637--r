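## Droplet/cluster quantification: flat-field correction, Otsu
## segmentation, bulk intensity, partition coefficients, TIRF cluster
## densities and in-cluster enrichment.

#' Pixel-by-pixel flat-field correction factors from a dye image
#'
#' Dark-subtracted dye image normalized to its own maximum: factors in
#' (0, 1] describing relative illumination and detector sensitivity.
#' Experimental images are divided by this field.
#'
#' @param dye_image `ImageStack` of a uniform dye solution.
#' @param dark_image `ImageStack` dark frame of the same shape.
#' @return matrix of correction factors in (0, 1].
#' @export
flatfield_from_dye <- function(dye_image, dark_image) {
  dye <- get_frame(dye_image, 1L)
  dark <- get_frame(dark_image, 1L)
  if (!all(dim(dye) == dim(dark)))
    stopf("dye and dark frames have different shapes")
  diff <- dye - dark
  mx <- max(diff)
  if (mx <= 0) stopf("flat-field calibration failed: dye <= dark everywhere")
  field <- diff / mx
  field[field <= 0] <- min(field[field > 0])  # guard holes for later division
  field
}

#' Divide an image by a flat-field correction field
#'
#' After this a uniformly lit specimen is spatially constant. Division is
#' not idempotent: correcting twice overcorrects.
#'
#' @param image background-subtracted `ImageStack`.
#' @param field correction factors in (0, 1] (from [flatfield_from_dye()]).
#' @return corrected `ImageStack`.
#' @export
correct_illumination <- function(image, field) {
  if (any(field <= 0)) stopf("correction field contains non-positive values")
  d <- dim(image$pixels)
  yx <- if (length(d) == 2L) d else d[2:3]
  if (!all(dim(field) == yx)) stopf("field shape does not match image")
  out <- image
  if (length(d) == 2L) {
    out$pixels <- image$pixels / field
  } else {
    for (i in seq_len(d[1L])) out$pixels[i, , ] <- image$pixels[i, , ] / field
  }
  out$corrected <- TRUE
  out
}

#' Segment droplets by Otsu's global threshold
#'
#' Binary Otsu mask of the (corrected) reference channel, connected
#' components labelled 8-connected and ordered by centroid. A blank
#' (zero-variance) image yields an empty labelling, logged, not an error.
#'
#' @param reference_channel 2D `ImageStack` (typically the 647 scaffold
#'   channel from which the droplet mask is drawn).
#' @return integer label matrix with attributes `features` (a
#'   [region_features()] table) and `threshold`.
#' @export
segment_droplets <- function(reference_channel) {
  img <- get_frame(reference_channel, 1L)
  thr <- otsu_threshold(img)
  if (is.na(thr)) {
    cq_log("segment", "blank image: empty droplet mask")
    lab <- matrix(0L, nrow(img), ncol(img))
    attr(lab, "features") <- region_features(lab)
    attr(lab, "threshold") <- NA_real_
    return(lab)
  }
  lab <- label_components(img > thr, connectivity = 8L)
  attr(lab, "features") <- region_features(lab, img)
  attr(lab, "threshold") <- thr
  lab
}

#' Mean bulk intensity outside the dilated droplet mask
#'
#' The droplet mask is dilated (to clear the blur halo around each
#' droplet) and inverted; the bulk is the mean intensity over the
#' remaining pixels.
#'
#' @param mask label or binary matrix of droplets.
#' @param image `ImageStack` or matrix, co-registered with the mask.
#' @param dilation_radius_px dilation radius (default 5 px clears the
#'   halo at the 2-5 px FWHM range typical here).
#' @return mean bulk intensity.
#' @export
bulk_mean <- function(mask, image, dilation_radius_px = 5) {
  img <- if (inherits(image, "ImageStack")) get_frame(image, 1L) else image
  if (!all(dim(mask) == dim(img))) stopf("mask and image shapes differ")
  outside <- !dilate_union(mask, dilation_radius_px)
  if (!any(outside))
    stopf("dilated droplet mask covers the whole image; no bulk region left")
  mean(img[outside])
}

#' Per-droplet partition coefficients
#'
#' For every labelled droplet and channel: the raw mean intensity inside
#' the mask, the PSF-corrected mean (`bulk + (raw - bulk) * f(d)` when a
#' correction curve is supplied), and the partition coefficient
#' corrected mean / bulk mean. Droplets whose mask-channel equivalent
#' diameter is below `min_diameter_px` are kept in the table with
#' `discarded = TRUE` (their intensity cannot be accurately measured or
#' corrected) and must be excluded from summaries.
#'
#' @param mask label matrix from [segment_droplets()] (defines the
#'   diameters shared by all channels).
#' @param channels named list of 2D `ImageStack`s (or matrices).
#' @param bulk named per-channel bulk intensity (> 0), e.g. from
#'   [bulk_mean()].
#' @param curves optional named list of `CorrectionCurve`s per channel.
#' @param min_diameter_px discard floor on the equivalent diameter
#'   (default 12 px).
#' @param apply_correction `"always"` applies the curve whenever supplied;
#'   `"trend"` first requires a significant Spearman correlation between
#'   raw mean and diameter (the intensity-vs-diameter trend that signals
#'   blur dilution); `"never"` disables correction.
#' @param trend_alpha significance level for the trend pre-test.
#' @return data.frame with one row per droplet x channel: `droplet_id`,
#'   `channel`, `diameter_px`, `raw_mean`, `corrected_mean`, `bulk_mean`,
#'   `partition_coefficient`, `discarded`, `discard_reason`,
#'   `below_support`, `params`.
#' @export
partition_coefficients <- function(mask, channels, bulk, curves = NULL,
                                   min_diameter_px = 12,
                                   apply_correction = c("always", "trend",
                                                        "never"),
                                   trend_alpha = 0.05) {
  apply_correction <- match.arg(apply_correction)
  feats <- attr(mask, "features")
  if (is.null(feats)) feats <- region_features(mask)
  if (any(bulk[names(channels)] <= 0)) stopf("bulk intensity must be > 0")
  digest <- param_digest(list(min_diameter_px = min_diameter_px,
                              apply_correction = apply_correction,
                              dilation = NA, trend_alpha = trend_alpha))
  rows <- list()
  for (ch in names(channels)) {
    img <- channels[[ch]]
    img <- if (inherits(img, "ImageStack")) get_frame(img, 1L) else img
    idx <- which(mask > 0L)
    raw <- if (nrow(feats)) as.numeric(
      tapply(img[idx], factor(mask[idx], levels = feats$label), mean)
    ) else numeric(0)
    rows[[ch]] <- data.frame(
      droplet_id = feats$label, channel = ch,
      diameter_px = feats$diameter_px, raw_mean = raw,
      corrected_mean = raw, bulk_mean = bulk[[ch]],
      partition_coefficient = raw / bulk[[ch]],
      discarded = feats$diameter_px < min_diameter_px,
      discard_reason = ifelse(feats$diameter_px < min_diameter_px,
                              sprintf("diameter < %g px", min_diameter_px), ""),
      below_support = FALSE, params = digest,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  if (is.null(records)) return(records)
  if (!is.null(curves) && apply_correction != "never") {
    for (ch in unique(records$channel)) {
      sel <- records$channel == ch & !records$discarded
      do_corr <- TRUE
      if (apply_correction == "trend" && sum(sel) >= 4L) {
        ct <- stats::cor.test(records$diameter_px[sel], records$raw_mean[sel],
                              method = "spearman", exact = FALSE,
                              alternative = "greater")
        do_corr <- ct$p.value < trend_alpha
      }
      if (do_corr) {
        sub <- records[records$channel == ch, , drop = FALSE]
        sub <- apply_intensity_correction(sub, curves[[ch]])
        records[records$channel == ch, ] <- sub
      }
    }
  }
  records
}

#' Summarize partition coefficients per channel
#'
#' Mean, SEM and n of the partition coefficient over non-discarded
#' droplets, per channel.
#'
#' @param records output of [partition_coefficients()].
#' @return data.frame with `channel`, `mean_pc`, `sem_pc`, `n`.
#' @export
summarize_partition <- function(records) {
  keep <- records[!records$discarded, , drop = FALSE]
  out <- lapply(split(keep, keep$channel), function(d) {
    data.frame(channel = d$channel[1L],
               mean_pc = mean(d$partition_coefficient),
               sem_pc = stats::sd(d$partition_coefficient) / sqrt(nrow(d)),
               n = nrow(d))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cluster density on a TIRF field
#'
#' Segments each field (Otsu + 8-connected labelling, applying the same
#' minimum-size rule as the droplet pipeline) and converts counts to
#' clusters per mm^2 using the field area
#' `(ny * pixel_size_um) * (nx * pixel_size_um)` scaled to mm^2.
#'
#' @param field_images list of 2D `ImageStack`s (one per field).
#' @param pixel_size_um pixel size; defaults to the stacks' own.
#' @param surface surface label (e.g. `"PEG"`, `"lipids"`,
#'   `"lipids+integrin"`).
#' @param timepoints_min optional per-field timepoints (minutes).
#' @param min_diameter_px minimum equivalent diameter counted.
#' @return data.frame with one row per field: `surface`, `timepoint_min`,
#'   `field_area_mm2`, `cluster_count`, `density_per_mm2`.
#' @export
cluster_density <- function(field_images, pixel_size_um = NULL,
                            surface = "lipids+integrin",
                            timepoints_min = NA_real_,
                            min_diameter_px = 12) {
  if (inherits(field_images, "ImageStack")) field_images <- list(field_images)
  timepoints_min <- rep_len(timepoints_min, length(field_images))
  rows <- lapply(seq_along(field_images), function(i) {
    im <- field_images[[i]]
    px <- if (is.null(pixel_size_um)) im$pixel_size_um else pixel_size_um
    if (px <= 0) stopf("pixel size must be > 0")
    d <- dim(get_frame(im, 1L))
    area_mm2 <- prod(d) * (px / 1000)^2
    if (area_mm2 <= 0) stopf("zero field area")
    lab <- segment_droplets(im)
    feats <- attr(lab, "features")
    count <- sum(feats$diameter_px >= min_diameter_px)
    data.frame(surface = surface, timepoint_min = timepoints_min[i],
               field_area_mm2 = area_mm2, cluster_count = count,
               density_per_mm2 = count / area_mm2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fold enrichment inside clusters versus the unclustered membrane
#'
#' Per cluster: mean intensity inside the component divided by the mean
#' of the unclustered membrane (outside the dilated union of all
#' clusters).
#'
#' @param image `ImageStack` or matrix (e.g. labelled integrin channel).
#' @param cluster_mask label matrix of clusters.
#' @param dilation_radius_px halo clearance around clusters.
#' @return data.frame per cluster: `cluster_id`, `in_cluster_mean`,
#'   `unclustered_mean`, `fold_enrichment`.
#' @export
enrichment_in_clusters <- function(image, cluster_mask,
                                   dilation_radius_px = 5) {
  img <- if (inherits(image, "ImageStack")) get_frame(image, 1L) else image
  if (!all(dim(cluster_mask) == dim(img)))
    stopf("mask and image shapes differ")
  outside <- !dilate_union(cluster_mask, dilation_radius_px)
  if (!any(outside)) stopf("no unclustered region left after dilation")
  un <- mean(img[outside])
  n <- max(cluster_mask)
  if (n == 0L) {
    return(data.frame(cluster_id = integer(0), in_cluster_mean = numeric(0),
                      unclustered_mean = numeric(0),
                      fold_enrichment = numeric(0)))
  }
  idx <- which(cluster_mask > 0L)
  mi <- as.numeric(tapply(img[idx],
                          factor(cluster_mask[idx], levels = seq_len(n)),
                          mean))
  data.frame(cluster_id = seq_len(n), in_cluster_mean = mi,
             unclustered_mean = un, fold_enrichment = mi / un)
}
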