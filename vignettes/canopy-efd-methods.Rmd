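---
title: "Canopy outline analysis with elliptic Fourier descriptors: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy outline analysis with elliptic Fourier descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyefd)
```

## The problem

Top-down photographs of crop canopies are routinely collected in field
phenotyping trials. The *outline* of a canopy — its elongation, lobedness,
raggedness — relates to light interception and canopy closure, and differs
among genotypes. Two practical obstacles stand between a folder of
photographs and a genetic analysis: the outline must be extracted reliably
from a noisy soil background, and an outline of tens of thousands of
boundary pixels must be reduced to a representation that is compact,
comparable across plants, and faithful enough to recover conventional
morphometric traits. `canopyefd` addresses both with a classical pipeline:
HSV segmentation, chain coding, elliptic Fourier expansion, Kuhl–Giardina
standardization, and downstream diversity/heritability statistics.

## Segmentation model and its assumptions

A pixel is foreground iff its saturation is at least `saturation_min` and
its hue lies in the band `[hue_min, hue_max]` (wrap-around bands are
supported because hue is circular). The assumptions are that foliage is
green-to-yellow and reasonably saturated while soil is brown/gray; no
illumination or color-chart correction is attempted, so thresholds are
**configuration, not constants** — the defaults (hue 0.15–0.5, saturation
≥ 0.25, on the [0,1) hue wheel) accept typical vegetation hues but any
real campaign should tune them on sample images. Cleanup then keeps the
largest 8-connected component (size ties break to the component whose
first pixel comes earliest in row-major order, for determinism), fills
4-connected background regions that do not touch the image border, and
traces the outer boundary with Moore neighbor tracing. The complementary
8/4 connectivity pairing avoids the standard topological paradoxes.

Contours are reported in a y-up coordinate frame (image rows flipped) and
traced counter-clockwise, so the shoelace area is positive and all planar
geometry downstream follows the usual mathematical conventions. The trace
starts at the boundary pixel first met in row-major scan and stops when it
re-enters that pixel, which is correct for the filled, single-component
masks the pipeline produces (it would truncate a boundary that passes
through its start pixel twice, a situation filled blobs do not create).

## The descriptor model

For a closed contour sampled at points p = 1..s with steps Δx, Δy of
length Δt (1 or √2 for pixel chains; the Euclidean segment length for
analytic curves, the contour being treated as piecewise linear), the
coefficients of harmonic n are the exact integrals of the piecewise-linear
curve against the Fourier basis:

$$a_n = \frac{T}{2n^2\pi^2}\sum_{p=1}^{s}\frac{\Delta x_p}{\Delta t_p}
\left(\cos\frac{2n\pi t_p}{T}-\cos\frac{2n\pi t_{p-1}}{T}\right),$$

and analogously $b_n$ (sin, x), $c_n$ (cos, y), $d_n$ (sin, y). The DC
terms $A_0, C_0$ are never given explicitly in the classical presentation
we follow for the harmonics; we define them as the arc-length averages of
x(t) and y(t) (trapezoid rule over the segments), in absolute image
coordinates. This makes $(A_0, C_0)$ the center of the first-harmonic
ellipse, which is what the standardization step treats it as, and makes
reconstructions land directly in image coordinates.

**Reconstruction error.** The deviation of the N-harmonic reconstruction is

$$E_N = \max_p \left\| (x_p, y_p) - (x_{Np}, y_{Np}) \right\| / (2L)
\times 100\%$$

with the reconstruction evaluated at the *same* arc-length positions
$t_p$ (pointwise correspondence, not nearest-neighbor matching) and L the
semi-major axis of the first-harmonic ellipse. Taking the maximum of the
Euclidean point deviation and then normalizing is the dimensionally
consistent reading of the error used here; the normalizer 2L is the full
major-axis length.

**Harmonic selection.** Following the batch design, all outlines are first
probed at N = 10; the outline with the largest probe error is the most
complex; the harmonic count is swept (default 10..1000 step 10) on that
outline alone and the smallest N with $E_N \le$ 1 % is applied to every
outline in the batch. This keeps descriptors comparable across plants. If
the sweep never reaches the threshold the sweep maximum is returned with a
warning and a non-convergence flag rather than an error, so batch runs
complete. A per-contour sweep is available but off by default.

**Standardization.** Each harmonic block is transformed as

$$\begin{bmatrix} a_n^* & b_n^* \\ c_n^* & d_n^* \end{bmatrix} =
\frac{1}{L}
\begin{bmatrix} \cos\psi & \sin\psi \\ -\sin\psi & \cos\psi \end{bmatrix}
\begin{bmatrix} a_n & b_n \\ c_n & d_n \end{bmatrix}
\begin{bmatrix} \cos n\theta & -\sin n\theta \\ \sin n\theta & \cos n\theta \end{bmatrix}$$

where θ is the start-point phase (the arc position of the first-harmonic
ellipse's major-axis tip) obtained from the extremum condition
$\theta = \tfrac{1}{2}\operatorname{atan2}\!\big(2(a_1b_1+c_1d_1),\,
a_1^2+c_1^2-b_1^2-d_1^2\big)$, and ψ = atan2(c₁′, a₁′) is the major-axis
orientation after that phase shift. With these choices a₁\* = 1, b₁\* = 0,
c₁\* = 0 *identically* (verified to 1e−12 in the tests). Two ambiguities
are resolved explicitly: θ is defined modulo π/2 by the extremum
condition, and the candidate maximizing the first-harmonic radius is taken
(major, not minor axis); the residual modulo-π ambiguity of (θ, ψ) is fixed
by requiring the semi-major axis to align with +x, i.e. a₁\* > 0. The sign
convention of the right-hand rotation matters: with θ from the extremum
formula above, the transpose of this matrix does **not** null b₁\* and
c₁\* — an easy trap when transcribing the classical formulas. No
reflection is ever applied, so mirrored shapes deliberately standardize to
different descriptors (chirality is preserved).

Standardization is idempotent: re-embedding a standardized set (A0 = C0 =
0, T = 1) and standardizing again reproduces it to 1e−9.

## Morphometric traits

All four traits are computed on the polygon bounded by the contour —
**the same convention for originals and reconstructions**, so fidelity
comparisons are apples-to-apples:

* area: shoelace formula; perimeter: summed segment lengths;
* ellipse: the moment-equivalent ellipse (same area-normalized second
  central moments as the polygon, axes $4\sqrt{\lambda_i}$ of the
  covariance eigenvalues). This is the convention of mainstream image
  analysis tools, is well defined for any simple polygon (we therefore
  accept any non-collinear contour with ≥ 3 vertices), and needs no
  iterative fitting;
* aspect ratio = major/minor; roundness = 4A/(π·major²); circularity =
  4πA/P²; solidity = A/A_hull (hull via `grDevices::chull`).

**Digitization biases, stated plainly.** A pixel chain's staircase
perimeter overestimates the smooth boundary's length by roughly 5 %
(orientation-dependent), and no smoothing correction is applied. Three
measurable consequences, all verified and bounded in the test suite:

1. circularity of a digitized shape is biased *down* by ~10 % relative to
   the analytic shape, at any resolution;
2. a truncated reconstruction of a pixel chain smooths part of the
   staircase: at N = 500 on 256-px fixtures the reconstructed perimeter is
   1–3 % shorter, so reconstructed-vs-original circularity deviates by up
   to ~6 % while aspect ratio, roundness and solidity agree within 2 %
   (and all four correlate > 0.99 across shapes);
3. sharp lobe tips erode by about a pixel when rasterized, which lowers
   convex-hull area; the deliberately extreme 12-lobe fixture's solidity
   sits ~2.5 % from its analytic truth at 256 px.

Because E_N is a sup norm and Fourier partial sums are only L2-monotone,
E_N is not exactly non-increasing in N once it reaches the discretization
floor; the observed ripple is ≤ 3e−5 percentage points on smooth polygon
contours and ≤ 3e−3 on pixel chains, and the tests assert monotonicity up
to that ripple.

## Diversity statistics and heritability

* **PCA** on the canopies × coefficients matrix of standardized
  descriptors, mean-centred but *not* variance-scaled: after Eq.-10-style
  normalization all coefficients share one dimensionless scale, and
  rescaling would inflate the noise-dominated high harmonics. The three
  constant columns (a₁\*, b₁\*, c₁\*) are dropped automatically.
* **Group spread** as the convex-hull area of each group's (PC1, PC2)
  scores; groups with < 3 points or collinear scores get area 0 plus a
  degenerate flag.
* **CV** = sd/mean per group × trait; size-1 groups and zero-mean cells
  are flagged, not errors.
* **Outliers** by Tukey fences (1.5 × IQR beyond the quartiles) within
  each group, the convention matching standard boxplot whiskers, with a
  per-genotype count of how many replicates were flagged for the same
  trait (outliers consistent across replicates suggest genetics;
  single-replicate outliers suggest field accidents).
* **Heritability**: the RCBD model y_ik = μ + g_i + b_k + e_ik with all
  effects random; balanced two-way ANOVA (cross-checked against
  `stats::aov` in the tests), variance components by expected mean
  squares: σ²_e = MSE, σ²_g = max(0, (MSG − MSE)/k), and the entry-mean
  heritability H² = σ²_g/(σ²_g + σ²_e/k). Method-of-moments rather than
  REML keeps the estimate in closed form and reproducible; truncation at
  zero is the standard guard against negative component estimates.
  Unbalanced tables are handled by restricting to genotypes observed with
  the modal replication count (that count is the k in H²); dropped
  genotypes are reported. Significance stars for F_G = MSG/MSE use the F
  distribution with (g−1, (g−1)(k−1)) df at 0.05 and 0.001.

## The synthetic world

`simulate_canopy()` renders a star-convex radial shape
r(φ) = R(φ)·(1 + A·cos(mφ) + η(φ)) — R(φ) the base-ellipse radius, m lobes
of relative depth A, η a smooth random cosine-series perturbation —
as green-hued foreground (hue 0.22–0.38, saturation 0.5–0.9) on brown
background (hue 0.05–0.11), with optional small foreground-colored debris
disks away from the canopy and background-colored holes inside it. The
constraint A + 3·sd(η) < 1 keeps the radius positive, hence the polygon
simple, and star-convexity gives analytic ground truth: the truth mask,
the truth boundary polygon and its traits are returned alongside the
image. Defaults (256×256 px, base radius ≈ 69 px, 6 lobes of depth 0.15,
boundary noise sd 0.02) were chosen once to emulate a mid-season hill plot
at desk scale. A fixture suite ramps lobe count 0→8 and depth 0→0.22
across n shapes, with a designated most-complex shape (12 lobes, depth
0.3) for the probe/select workflow; per-image seeds derive from one master
seed.

What the generator does **not** emulate: photorealistic texture, shadows,
specular leaves, overlapping neighbor plots, perspective, illumination
drift, or weeds touching the canopy. A green test therefore establishes
that the geometry and statistics are computed correctly, not that the
default segmentation thresholds survive arbitrary field conditions.

`simulate_rcbd()` draws the RCBD model with chosen σ²_g, σ²_b, σ²_e;
recovery tests confirm the ANOVA pipeline returns H² within ±0.03 of truth
at 300 genotypes and that the null model gives mean F ≈ 1.

The storage-saving property of the descriptor representation is
demonstrated at realistic capture resolution: a 1200×1200 synthetic
photograph (with per-pixel color noise, as a camera image would have)
written as PNG is ≥ 100× larger than the binary 500-harmonic record
(4 + 8·2002 bytes ≈ 16 kB). At 256-px fixture scale the ratio is naturally
smaller; the claim concerns photographs.

## Numerical and degenerate-input policy

* Zero-perimeter or < 3-point contours, all-background masks, < 3-pixel
  blobs, degenerate first harmonics (L = 0), collinear ellipse fits and
  self-intersection-suggesting zero areas raise errors with specific
  messages; batch runs convert per-image errors into manifest entries and
  continue.
* CSV writers print doubles with `%.17g`, so every table (EFD,
  standardized, traits, contours) round-trips bit-exactly; the binary
  record format is little-endian float64.
* All randomness flows through explicit integer seeds; identical seeds
  give bit-identical images, tables and pipeline outputs.

## Known limitations

* PNG and JPEG only (the deployment environment lacks a TIFF reader); RAW
  formats are out of scope.
* The Moore trace assumes the cleaned, filled mask is one 8-connected
  component, which `run_pipeline` guarantees; calling `trace_outline`
  directly on multi-component masks traces the component containing the
  first row-major boundary pixel.
* Circularity comparisons between digitized and analytic versions of the
  same shape inherit the staircase perimeter bias discussed above; compare
  like with like.
* Heritability assumes a single-trial RCBD; multi-environment designs,
  spatial trend correction and REML-based component estimation are out of
  scope.
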