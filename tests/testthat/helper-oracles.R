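## Independent oracles and simulation helpers shared across the suite.

## Brute-force direct-space linear convolution (shift-and-add over the
## kernel support) with replicate padding, matching the scene convention;
## independent of the FFT path used by the package.
oracle_direct_conv <- function(img, k) {
  r <- (nrow(k) - 1L) / 2
  out <- matrix(0, nrow(img), ncol(img))
  padded <- img[c(rep(1, r), seq_len(nrow(img)), rep(nrow(img), r)),
                c(rep(1, r), seq_len(ncol(img)), rep(ncol(img), r))]
  for (dy in -r:r) for (dx in -r:r) {
    out <- out + k[dy + r + 1, dx + r + 1] *
      padded[(r + 1 - dy):(r + nrow(img) - dy),
             (r + 1 - dx):(r + ncol(img) - dx)]
  }
  out
}

## Render one calibration disc, convolve with the oracle, and measure the
## Otsu-masked mean and equivalent diameter (mirrors the pipeline's
## geometry, computes the convolution independently).
oracle_disc_measurement <- function(k, d, intensity = 255) {
  r <- (nrow(k) - 1L) / 2
  sz <- as.integer(ceiling(d) + 2 * r + 8)
  disc <- disc_coverage(sz, sz, c((sz + 1) / 2, (sz + 1) / 2), d) * intensity
  conv <- oracle_direct_conv(disc, k)
  thr <- otsu_threshold(conv)
  mask <- conv > thr
  list(mean = mean(conv[mask]), diameter = 2 * sqrt(sum(mask) / pi))
}

## Exhaustive intermeans fixed-point scan over all candidate thresholds
## of a 256-bin histogram: smallest T with round((mu_low + mu_high)/2)
## <= T, half-up rounding; falls back to the top occupied bin - 1.
oracle_intermeans_scan <- function(h) {
  bins <- length(h)
  idx <- 0:(bins - 1)
  nz <- which(h > 0)
  f <- idx[nz[1]]; l <- idx[nz[length(nz)]]
  if (f == l) return(f)
  for (T in f:(l - 1)) {
    m0 <- sum((h * idx)[1:(T + 1)]) / sum(h[1:(T + 1)])
    m1 <- sum((h * idx)[(T + 2):bins]) / sum(h[(T + 2):bins])
    if (floor((m0 + m1) / 2 + 0.5) <= T) return(T)
  }
  l - 1
}

## One normalized FRAP trace from the generator's standard acquisition
## design (1 s interval, 90 s, 3 prebleach frames).
sim_norm_trace <- function(seed, fractions, rates, noise_sd = 10) {
  g <- make_frap_series(fractions, rates, bleach_depth = 0.1,
                        noise_sd = noise_sd, seed = seed)
  tr <- frap_trace(g$trace$t, g$trace$roi_intensity,
                   g$trace$reference_intensity, g$trace$background_intensity)
  normalize_trace(tr)
}

## Averaged normalized curve over n replicates (the paper-style design
## fits the average of >= 8 repeats).
sim_avg_trace <- function(seed, fractions, rates, noise_sd = 10, nrep = 8) {
  average_traces(lapply(seq_len(nrep), function(i)
    sim_norm_trace(derive_seed(seed, i), fractions, rates, noise_sd)))
}

## A standard synthetic adhesion cell for chain tests.
sim_adhesion_cell <- function(seed, n = 80, image_size = c(400, 400)) {
  make_adhesion_image(make_cell_mask(image_size), n,
                      area_range = c(8, 60), adhesion_level = 1000,
                      cytoplasm_level = 300, background_level = 100,
                      noise_sd = 30, seed = seed)
}
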