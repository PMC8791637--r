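## Shared segmentation primitives: Otsu threshold, connected-component
## labelling with ImageJ-style 8-connectivity, and region features.

#' Otsu global threshold of a numeric image
#'
#' Between-class-variance maximizing threshold (via [EBImage::otsu]) on a
#' 256-bin histogram over the image's own range. Returns `NA` for a
#' zero-variance image.
#'
#' @param img numeric matrix.
#' @param levels histogram bins.
#' @return threshold value (pixels strictly above are foreground), or `NA`.
#' @export
otsu_threshold <- function(img, levels = 256L) {
  rng <- range(img)
  if (diff(rng) <= 0) return(NA_real_)
  as.numeric(EBImage::otsu(EBImage::Image(img), range = rng, levels = levels))
}

#' Label connected components
#'
#' 4- or 8-connected labelling of a binary mask. EBImage's `bwlabel` is
#' 4-connected; 8-connectivity (the ImageJ particle-analysis convention)
#' is obtained by merging labels that touch diagonally.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels (0 = background), relabelled
#'   consecutively and ordered by the `(y, x)` of each component's centroid.
#' @export
label_components <- function(mask, connectivity = 8L) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n > 1L && connectivity == 8L) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
    for (sh in list(c(1L, 1L), c(1L, -1L))) {
      shifted <- shift_matrix(lab, sh[1L], sh[2L], fill = 0L)
      sel <- lab > 0L & shifted > 0L & lab != shifted
      if (any(sel)) {
        pairs <- unique(cbind(lab[sel], shifted[sel]))
        for (r in seq_len(nrow(pairs))) union2(pairs[r, 1L], pairs[r, 2L])
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    lab[lab > 0L] <- roots[lab[lab > 0L]]
  }
  relabel_by_centroid(lab)
}

## consecutive labels ordered by centroid (y, then x)
relabel_by_centroid <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) return(lab)
  idx <- which(lab > 0L)
  yy <- (idx - 1L) %% nrow(lab) + 1L
  xx <- (idx - 1L) %/% nrow(lab) + 1L
  v <- lab[idx]
  cy <- tapply(yy, v, mean)
  cx <- tapply(xx, v, mean)
  ord <- order(cy, cx)
  map <- integer(max(ids))
  map[as.integer(names(cy))[ord]] <- seq_along(ord)
  lab[idx] <- map[v]
  lab
}

#' Per-component region features
#'
#' Area, equivalent-area diameter `2 * sqrt(area / pi)`, centroid,
#' perimeter-based circularity `4 * pi * area / perimeter^2` (clipped at 1,
#' as discretized small objects can exceed it), and mean intensity in an
#' optional reference image.
#'
#' @param lab integer label matrix from [label_components()].
#' @param intensity optional numeric matrix for per-component mean intensity.
#' @return data.frame with one row per label.
#' @export
region_features <- function(lab, intensity = NULL) {
  n <- max(lab)
  if (n == 0L) {
    return(data.frame(label = integer(0), area_px2 = numeric(0),
                      diameter_px = numeric(0), cy = numeric(0),
                      cx = numeric(0), circularity = numeric(0),
                      mean_intensity = numeric(0)))
  }
  idx <- which(lab > 0L)
  v <- lab[idx]
  yy <- (idx - 1L) %% nrow(lab) + 1L
  xx <- (idx - 1L) %/% nrow(lab) + 1L
  area <- tabulate(v, n)
  cy <- as.numeric(tapply(yy, factor(v, levels = seq_len(n)), mean))
  cx <- as.numeric(tapply(xx, factor(v, levels = seq_len(n)), mean))
  shp <- EBImage::computeFeatures.shape(lab)
  perim <- shp[, "s.perimeter"]
  circ <- ifelse(perim > 0, pmin(4 * pi * area / perim^2, 1), 1)
  mi <- if (is.null(intensity)) rep(NA_real_, n) else
    as.numeric(tapply(intensity[idx], factor(v, levels = seq_len(n)), mean))
  data.frame(label = seq_len(n), area_px2 = area,
             diameter_px = 2 * sqrt(area / pi), cy = cy, cx = cx,
             circularity = as.numeric(circ), mean_intensity = mi)
}

#' Dilate the union of labelled components
#'
#' @param lab label or binary matrix.
#' @param radius_px dilation radius in pixels.
#' @return logical matrix of the dilated union.
#' @export
dilate_union <- function(lab, radius_px) {
  m <- (lab > 0) * 1
  if (radius_px <= 0) return(m > 0)
  brush <- EBImage::makeBrush(2L * as.integer(ceiling(radius_px)) + 1L, "disc")
  EBImage::dilate(m, brush) > 0
}
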