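# condquant

Quantitative image analysis for in vitro phase-separation and
cell-adhesion experiments: PSF-calibrated droplet partition
coefficients, FRAP kinetics with statistical model selection,
supported-bilayer cluster densities, and an ImageJ-style adhesion
segmentation and counting chain — all validated end to end on a
synthetic-image generator with exact ground truth.

## Who this is for

Labs measuring biomolecular condensates (droplet assays, supported
phospholipid bilayers imaged by TIRF) and integrin adhesion complexes
(paxillin-stained spreading cells) who need the standard quantification
chain as tested, scriptable functions rather than a sequence of manual
ImageJ/MATLAB steps.

## The methods at the core

**Partition coefficient.** For each droplet segmented by Otsu's method
on the scaffold channel, PC = mean intensity inside the mask / bulk mean
outside the dilated mask, after dark-frame subtraction and flat-field
division. Objects near the diffraction limit appear dimmed by the point
spread function; the package calibrates the PSF from bead fields
(FWHM = 2√(2 ln 2) σ from Gaussian linescan fits, 20 beads per channel)
and builds a correction curve f(d) = plateau + (f0 − plateau)·exp(−k·d)
by re-measuring blurred discs of known intensity, then corrects each
droplet's bulk-excess intensity by f(measured diameter). Droplets under
12 px diameter are discarded.

**FRAP.** Normalized Intensity = (I − I_post)/(I_pre − I_post) after
background subtraction and reference-region photobleaching correction;
recovery fit with N(t) = P(1−e^(−kt)) or its two-component extension;
single vs double decided by the extra sum-of-squares F test
(F = ((SS1−SS2)/(df1−df2))/(SS2/df2), α = 0.05); t½ = ln 2/k per
component, immobile fraction 1 − P; plateaus that do not resolve within
the 90 s window are flagged "nd". Bilayer experiments are gated on
t½ < 10 s (strict).

**Cluster density and enrichment.** Otsu + 8-connected labelling per
TIRF field, counts scaled to clusters/mm² by the field area; per-cluster
fold enrichment over the unclustered membrane.

**Adhesion counting.** The printed operator chain — rolling-ball
(sliding paraboloid, radius 50), CLAHE (19/256/6), exponential remap,
contrast stretch (0.35 % saturated), Laplacian-of-Gaussian (σ = 2),
"Default dark" intermeans threshold, particle analysis (5–1000 px²,
circularity 0–1) — plus fixed-threshold (5500–65535) total adhesion
area, a two-stage-Otsu adhesion partition coefficient, and GFP
expression gating (1000–5000 a.u., inclusive).

## Worked example

Simulate a three-channel droplet field with known partition ratios,
calibrate a correction curve, and quantify:

```r
library(condquant)

lay <- sample_droplet_layout(12, c(13, 40), c(300, 300), gap_px = 14, seed = 9)
lay$interior_m <- 500; lay$interior_a <- 300; lay$interior_c <- 100
gen <- make_droplet_image(lay, bulk_level = c(m = 100, a = 100, c = 100),
                          psf_fwhm = 3, image_size = c(300, 300),
                          noise_model = "poisson", noise_sd = 3, seed = 10)

seg   <- segment_droplets(gen$channels$m)
bulks <- sapply(gen$channels, function(ch) bulk_mean(seg, ch, 8))
curve <- build_correction_curve(gaussian_psf(3), 1:50)
rec   <- partition_coefficients(seg, gen$channels, bulks,
                                list(m = curve, a = curve, c = curve))
summarize_partition(rec)
#>   channel   mean_pc      sem_pc  n
#> 1       a 3.0008805 0.006094123 12
#> 2       c 0.9989337 0.001563335 12
#> 3       m 5.0126544 0.013573926 12
```

The generator's true PCs were 5, 3 and 1; the corrected estimates
recover them to a few tenths of a percent (the uncorrected estimates for
the enriched channels are biased ~5–10 % low, increasingly so for small
droplets). A FRAP example:

```r
g  <- make_frap_series(c(0.45, 0.35), c(log(2)/2, log(2)/39),
                       noise_sd = 10, seed = 1)
tr <- frap_trace(g$trace$t, g$trace$roi_intensity,
                 g$trace$reference_intensity, g$trace$background_intensity)
res <- fit_frap(normalize_trace(tr))
res$selection
#> ModelSelection: F = 576.716, p = 6.29e-51 (alpha 0.05) -> double
res$fit
#> FrapFit (double): plateau 0.815, t1/2 = 2.14/44.13 s, immobile 0.185
```

A single noisy trace recovers the generator's 2 s / 39 s half-times to
within the expected single-trace scatter (averaging 8 replicates, as the
analysis drivers do, tightens this to a few percent); the F test selects
the two-component model decisively.

## The analysis workflow

Numbered drivers under `analysis/` run each pipeline on synthetic data
and write tables under `results/`:

| script | what it does | writes |
| --- | --- | --- |
| `01_calibrate_psf.R` | bead FWHM per channel + correction curves | `psf_calibration.csv`, `psf_correction_curves.csv` |
| `02_quantify_droplets.R` | multi-channel PC recovery with shading/noise | `droplet_records.csv`, `droplet_pc_summary.csv` |
| `03_fit_frap.R` | fits in the reported kinetic regimes + F test + QC gate | `frap_fits.csv` |
| `04_bilayer_clusters.R` | cluster densities per surface + enrichment | `cluster_density.csv`, `cluster_enrichment.csv` |
| `05_count_adhesions.R` | counting chain, total area, adhesion PC, GFP gate | `adhesion_cells.csv`, `adhesion_cells_gated.csv` |

Run any of them from the repository root, e.g.
`Rscript analysis/02_quantify_droplets.R`.

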