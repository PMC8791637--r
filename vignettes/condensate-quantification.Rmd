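---
title: "Quantifying condensates, FRAP kinetics and adhesions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying condensates, FRAP kinetics and adhesions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condquant)
```

# What this package measures

`condquant` implements the image-quantification chain used to
characterize liquid–liquid phase separation of adhesion proteins in
vitro and integrin adhesion complexes in cells:

1. **PSF calibration** from sub-resolution bead fields, and a
   **small-object intensity-correction curve** that removes the blur
   bias in measured droplet intensities.
2. **Droplet partition coefficients** (PC): per-droplet mean intensity
   over bulk mean intensity, after background subtraction, flat-field
   correction, Otsu segmentation and PSF correction.
3. **FRAP analysis**: trace normalization, single- and bi-exponential
   recovery fits, extra sum-of-squares F-test model selection, and a
   bilayer fluidity gate.
4. **TIRF cluster densities** (clusters/mm^2) and **in-cluster
   enrichment** on supported bilayers.
5. **Adhesion morphometrics**: an ImageJ-style operator chain for
   counting nascent adhesions, a fixed-threshold total-area measurement,
   the adhesion partition coefficient, and GFP expression gating.

Every stage is validated against a synthetic-image generator that
attaches exact ground truth to each image, because the quantities the
pipeline reports (ratios, densities, counts, half-times) can then be
checked against known values rather than against other software.

# The optics problem: why small objects need correction

A microscope blurs the scene with its point spread function (PSF),
well approximated laterally by a Gaussian with
$\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$. An object whose diameter is
within a few FWHM of the diffraction limit loses a fraction of its peak
intensity to its surroundings, so a small droplet looks dimmer than its
true interior concentration. The calibration renders discs of known
intensity (255) and diameter 1–50 px on an empty background, convolves
them with the measured PSF, re-measures them through the same Otsu mask
the droplet pipeline uses, and records

$$f(d) = \frac{255}{\text{measured mean inside the mask}}$$

against the *measured* equivalent-area diameter
$d = 2\sqrt{A/\pi}$. The factors are fit with a one-phase exponential
association $f(d) = p + (f_0 - p)\,e^{-kd}$ with the plateau $p$ free; a
well-formed calibration has $p \approx 1$.

Two design choices matter here:

* **Fit support.** The sample points are measured over the full 1–50 px
  range, but the association is fit only over measured diameters at or
  above the 12-px discard floor. Near the PSF scale the factor rises
  steeply into mask-geometry territory (factors of 3–6), and a single
  exponential cannot span both regimes; an unweighted full-range fit
  leaves the curve essentially useless exactly where it is applied
  (factors clamped to ~1 for 12–30 px droplets). Since droplets below
  12 px are discarded and never corrected, fitting over the applied
  support is the consistent choice.
* **What gets corrected.** The calibration is built on a zero
  background, where the blur deficit applies to the whole disc
  intensity. A droplet sits on a fluorescent bulk, and blur dilutes only
  its *excess* over that bulk, so the correction is applied as
  $\text{corrected} = \text{bulk} + (\text{raw} - \text{bulk})\cdot f(d)$.
  On the calibration geometry this reduces to the plain $\text{raw}
  \cdot f(d)$ rescaling; on a nonzero bulk it leaves an unenriched
  channel (PC = 1) uncorrupted, whereas multiplying the raw mean would
  push PC = 1 droplets up to $f(d)$ (10–30 % error at small diameters).
* **Rasterization.** Discs are anti-aliased by fractional pixel
  coverage, so "diameter" stays well defined at small sizes. A
  consequence is that even a delta-function PSF yields factors slightly
  above 1 (1–6 %, shrinking with diameter): the Otsu mask includes rim
  pixels whose coverage is partial. Calibration and application share
  the same rasterizer, so the effect cancels in use.

The correction factor is floored at 1 when evaluated: blur can only
dilute a bright object on a darker surround, so fitted values below 1
are wiggle, not signal.

# Partition coefficients

The droplet pipeline follows the standard chain: subtract a dark
background frame (clipped at zero); divide by a flat-field computed from
a dye/dark pair as $(\text{dye}-\text{dark})/\max(\text{dye} -
\text{dark})$; segment the scaffold channel by Otsu's global threshold;
label components 8-connected; compute the bulk as the mean outside the
mask dilated by 5 px (clearing the blur halo at the 2–5 px FWHM range —
the dilation amount is configurable because the source protocol states
"dilated" without a radius); and report per droplet and channel

$$\mathrm{PC} = \frac{\text{corrected mean inside the mask}}{\text{bulk mean}}.$$

Droplets with mask-channel equivalent diameter below 12 px are kept in
the record table flagged `discarded` and excluded from every summary;
their intensity cannot be accurately measured or corrected. The PSF
correction is applied whenever a curve is supplied (deterministic and
conservative, given a monotone curve near 1 at large diameters); an
optional Spearman trend pre-test (`apply_correction = "trend"`,
$\alpha = 0.05$) reproduces the protocol reading in which correction is
applied only "if intensity increased with increasing diameter".

PC and fold-enrichment are ratios, hence exactly invariant under global
gain; the suite asserts this, along with PC $\approx$ 1 on uniform
fields and recovery within 10 % (in practice ~0.6 % mean absolute
relative error) on 800+ synthetic droplets spanning PC 1–5, diameters
13–50 px, FWHM 2–5 px, shading ramps and Poisson + read noise.

# FRAP

Traces carry time with $t = 0$ at the first post-bleach frame.
Normalization background-subtracts the ROI and the reference region,
divides the ROI frame-wise by the reference rescaled to its prebleach
mean (multiplicative photobleaching correction — the standard reading of
using a bulk region "to correct for photobleaching"), and applies

$$N(t) = \frac{I(t) - I_{\text{post}}}{I_{\text{pre}} - I_{\text{post}}},$$

with $I_{\text{pre}}$ the mean of the three prebleach measurements and
$I_{\text{post}}$ the corrected ROI at $t = 0$. By construction
$N(0) = 0$ and the prebleach level is 1.

Recovery models are $N(t) = P(1 - e^{-kt})$ and
$N(t) = P[\varphi(1-e^{-k_1 t}) + (1-\varphi)(1-e^{-k_2 t})]$, fit by
bounded Levenberg–Marquardt least squares ($P \in [0, 1.2]$ to tolerate
noise overshoot; $k \in [10^{-4}, 10]$ s$^{-1}$, spanning half-times
from ~0.07 s to ~2 h) from a deterministic multi-start grid seeded by
the time to half of the final observed recovery. One start sits at the
embedded single-exponential solution, which guarantees the double fit
never ends worse than the single fit — the nesting the F test requires.
Reported quantities: $t_{1/2} = \ln 2 / k$ per component (fast first),
mobile fractions $P\varphi_i$, immobile fraction $1 - P$.

Model selection uses the extra sum-of-squares F test,
$F = \frac{(SS_1 - SS_2)/(df_1 - df_2)}{SS_2/df_2}$, choosing the double
model iff $p < \alpha$ with $\alpha = 0.05$ (the significance level is
not printed in the source protocol; 0.05 is the conventional default).
On simulations at the published acquisition design (1 s interval, 90 s,
3 prebleach frames, 8 averaged replicates) the test selects the double
model in ~6.5 % of single-exponential data sets. The F machinery itself
is slightly conservative on iid-noise regression (~2 %); the mild
liberality is induced by the normalization (the reference division makes
the noise heteroscedastic), i.e. it is a property of the published
procedure, and it sits within the expected $5\% \pm 2\%$ calibration
band. Power at rate separation $k_1/k_2 = 20$ is effectively 100 %.

**The "nd" flag.** When recovery has not plateaued within the window the
plateau (and hence percent recovery) is not determined. The fit flags
`plateau_resolved = FALSE` when the fitted slow $t_{1/2}$ exceeds half
the observation window or the Wald 95 % interval for $P$ is wider
than 0.3. A Wald interval is used rather than a profile-likelihood
interval: on bounded multi-start fits the profile is fragile and slow,
and the width only feeds a flag, not an estimate. Half-times near the
window edge (e.g. ~98 s in a 90 s experiment) are intrinsically poorly
identified — at 3 % per-frame noise their RMSE is ~30 % even with 8
averaged replicates — which is exactly why such entries are reported
"nd" rather than trusted.

**Bilayer QC.** Supported-bilayer experiments are gated on lipid/integrin
FRAP $t_{1/2} < 10$ s, strict: 10 s fails.

# Cluster densities and enrichment

TIRF fields are segmented with the same Otsu + labelling machinery,
counts are divided by the field area $(n_y \cdot s)(n_x \cdot s)$
(pixel size $s$ in mm), and the minimum counted size defaults to the
droplet 12-px floor (no size rule is printed for the cluster counts;
sharing the droplet rule keeps one convention, and it is overridable).
Enrichment is the per-cluster mean over the mean of the membrane outside
the dilated cluster union.

# The adhesion counting chain

The counting chain reproduces a printed ImageJ macro sequence with its
stated parameters: sliding-paraboloid background subtraction
(radius 50), CLAHE (blocksize 19, 256 bins, max slope 6), an exponential
intensity remap, linear contrast stretch saturating 0.35 % of pixels,
Laplacian-of-Gaussian filtering at $\sigma = 2$ px, "Default dark"
(iterative intermeans) thresholding, and particle analysis with area
5–1000 px² and circularity 0–1 (interpreted in pixel units; the macro
sets no spatial calibration). Implementation decisions, in chain order:

* **Rolling ball.** The sliding-paraboloid variant is implemented as 1D
  grayscale openings with structuring function $s^2/(2r)$ along rows
  then columns, on an internal 0–255 scale (so behaviour is independent
  of absolute gain, matching the operator's 8-bit semantics). Affine
  backgrounds are removed exactly; puncta narrower than the paraboloid
  pass through.
* **CLAHE.** Delegated to `EBImage::clahe` with tile counts derived from
  the 19-px blocksize (the image is edge-padded to a tile multiple and
  cropped back). With clip limit 6, equalization of near-flat regions is
  intentionally bounded: a dim punctum's local contrast moves
  substantially toward a bright punctum's but does not reach parity;
  unclipped equalization does reach parity. Tests assert both.
* **Exp.** The remap $v \mapsto M\,(e^{cv/M}-1)/(e^c-1)$ with curvature
  $c = 8\ln 2 \approx 5.545$ — numerically the curvature of the classic
  8-bit exponential display LUT ($\ln 255 \approx 5.54$) — preserves the
  endpoints and ordering while crushing the lower half-range (midpoint
  to $M/16$). Counts are robust to $c$ within ~3–8.
* **Enhance contrast.** Clips at the midpoint between the $k$-th and
  $(k{+}1)$-th order statistics in each tail so that exactly the stated
  pixel fraction saturates, then rescales linearly.
* **LoG.** Zero-sum kernel at $\sigma = 2$ (the "3D" plugin applied to a
  2D image degenerates to 2D), sign-flipped so bright blobs are maxima.
  The response is half-wave rectified before rescaling: the negative
  undershoot rings around blobs carry no information for bright-blob
  detection, but without rectification they stretch the histogram fed to
  the global threshold so far that the intermeans fixed point lands
  below the bulk mode and the mask floods (measured: an 89 %-foreground
  mask that swallows rim puncta).
* **Threshold.** "Default dark" is the iterative intermeans fixed point
  on a 256-bin histogram over the image's own range: starting from the
  lowest occupied bin, replace the candidate with
  $\lfloor(\mu_{\le T} + \mu_{> T})/2 + 0.5\rfloor$ until it stops
  moving up. Foreground is strictly above the threshold, so adhesions
  come out as foreground directly and the macro's mask-inversion step is
  absorbed. The iteration provably reaches the smallest fixed point,
  which an exhaustive 256-candidate scan verifies exactly in the tests.
* **Particles.** 8-connected labelling (ImageJ's wand convention;
  `EBImage::bwlabel` is 4-connected, so diagonally touching labels are
  merged by union–find), circularity $4\pi A/P^2$ clipped at 1 for
  discretized small objects.

The chain normalizes its input by range up front, making the final count
exactly invariant under global intensity scaling — asserted as an
identity in the tests.

The **adhesion partition coefficient** automates what the source
protocol did manually: a first Otsu threshold separates cell from
off-cell background (largest component, holes filled), a second Otsu
*within the eroded cell core* separates adhesions from cytoplasm, and
$\mathrm{PC} = (\bar I_{\text{adh}} - B)/(\bar I_{\text{cyto}} - B)$
with the off-cell background $B$ supplied by the caller. The cytoplasm
mean excludes a 3-px dilated halo around adhesions and a 3-px band at
the cell rim (partial-volume pixels); the secondary threshold is
computed on the eroded core so the rim band cannot masquerade as the
cytoplasm class. The automated surrogate is flagged in outputs. GFP
gating retains cells with background-subtracted mean GFP in the
inclusive window 1000–5000 a.u. (inclusivity is not stated in the
protocol; inclusive is chosen and documented).

# The synthetic-data generator

Every input class the pipelines consume is generated with attached
ground truth: bead z-stacks (3D Gaussians, brightest at the central
plane), multi-channel droplet fields (anti-aliased discs on a uniform
bulk, Gaussian blur, multiplicative shading, camera offset, Poisson shot
noise on the pre-offset signal plus Gaussian read noise), FRAP trace
tables (exponential recovery with whole-field acquisition bleaching),
flat-field dye/dark pairs, adhesion cells (elliptical puncta inside a
soft-edged cell body) and TIRF cluster fields. Identical parameters and
seed reproduce every image bit for bit.

Choices that deserve justification:

* **Convolution boundary.** Scene blur uses replicate padding: a
  specimen does not fall to zero at the camera edge, and zero padding
  would vignette the bulk and bias edge measurements. On zero-background
  calibration discs, replicate and zero padding coincide, so the
  direct-space convolution oracle (shift-and-add) agrees with the FFT
  path to machine precision. Kernels are truncated at $\pm 4\sigma$ and
  renormalized to unit sum (truncation error below $10^{-4}$ of mass).
* **FRAP noise, 1 % of the prebleach ROI intensity.** The noise
  magnitude is not stated in the source and is a free parameter. The
  bleached ROI is a 19-px-diameter disc, so its mean averages ~280
  pixels; at typical spinning-disk photon budgets the shot noise of that
  mean is below 1 % of signal. At a pessimistic 3 % the half-time grid
  still recovers well below 100 s, but window-edge components degrade to
  ~30 % RMSE — the regime the "nd" flag exists for.
* **Adhesion cells.** Puncta are placed with ≥12 px rim clearance
  ("well-separated" relative to the chain's own $\sigma = 2$ LoG
  support, which bridges smaller gaps), with contrast ~3.3x cytoplasm
  and noise ~4 % of punctum contrast. The cell-body edge falls off over
  a Gaussian of 8 px FWHM: a real cytoplasmic immunofluorescence
  background fades over ~0.5–1 µm, and a razor-sharp synthetic step
  produces an edge artifact (a giant LoG ring component) that no real
  image shows.
* **Cluster fields** place 25–30 clusters on a 250 × 250 px field at
  0.2 µm/px (0.0025 mm²), matching the dense-condition density scale of
  ~12,000 clusters/mm²; sparse conditions use a few clusters per field.

What the generator does **not** emulate: bilayer diffusion physics,
droplet coarsening or fusion, actin, vendor metadata, spatially varying
PSFs, or sub-resolution adhesion substructure. Passing tests therefore
demonstrate that the measurement chain is unbiased under the stated
image-formation model, not that it is robust to every artifact real
microscopes produce.

# Problem sizes and numerical conventions

The validation suite runs ~800 droplets (17 fields of 12–14), 2000
single-truth FRAP simulations for the type-I estimate plus 100 power
runs, the full 1–50 px × FWHM 2–5 px calibration grid against the
direct-space oracle, 100 random histograms for the threshold oracle, and
a handful of 400 × 400 px adhesion cells — a few minutes on one core.
Ties in focus selection break to the lower plane index; component labels
are ordered by centroid (y, then x); intermediate intensities are
carried as doubles after the first correction stage; all RNG flows
through per-stage seeds derived deterministically from one master seed.

# Known limitations

* The FWHM linescan is horizontal by default (the protocol does not
  state an axis); `axis = "both"` averages horizontal and vertical.
* The intensity-correction transfer assumes the droplet Otsu mask sees
  the same geometry as the calibration mask; strongly overlapping or
  clumped droplets violate this and are excluded by the generators.
* The adhesion-PC segmentation is an automated surrogate for a manual
  procedure; on small, heavily blurred puncta the Otsu mask dilutes the
  adhesion mean by up to ~15 % (no PSF correction is defined for this
  measurement in the source).
* Percent recovery / plateau for slow components near the observation
  window is reported with `plateau_resolved = FALSE` rather than
  suppressed; downstream users decide how to treat "nd" entries.
* The duration of the FRAP experiment is stated as 90 s in the protocol
  and 100 s in one figure legend; the generator takes the duration as a
  parameter (default 90 s) and leaves the discrepancy to the caller.
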