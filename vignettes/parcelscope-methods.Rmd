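---
title: "Methods: object-based VHSR image processing for smallholder fields"
author: "parcelscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: object-based VHSR image processing for smallholder fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parcelscope)
```

## The problem

Smallholder farm fields are small (often well under a hectare), spectrally
heterogeneous, and scattered through landscapes dotted with isolated trees.
Following their crops through a season with very-high-spatial-resolution
(VHSR, sub-metre to few-metre) satellite imagery requires three things
before any statistic is worth computing: the multi-temporal scenes must be
co-registered to well under a pixel, cloud-contaminated pixels must be
removed, and the spectral contribution of tree crowns must be separated
from that of the crops. `parcelscope` implements that processing chain —
tree-crown blob detection with automatic scale selection, tie-point
registration onto a master scene, metadata-driven cloud masking, blob-based
tree masking — and the per-field signature extraction that rides on it
(spectral moments, vegetation indices, grey-level co-occurrence texture),
orchestrated by a make-like incremental driver.

Because VHSR imagery is proprietary, the package ships a synthetic-scene
generator with complete ground truth; every algorithm is validated against
quantities that are known exactly by construction.

## Scene model and conventions

A scene is a set of equally sized surface-reflectance matrices (one per
band role: blue, green, red, red-edge, NIR, NIR2, panchromatic, ...), a
north-up affine geotransform in a projected CRS (metres), and a nodata
convention. Reflectance is unitless in $[0,1]$. Pixel $(r,c)$ (1-based,
row 1 at the northern edge) has its *centre* at

$$x = x_0 + (c - \tfrac12)\,w, \qquad y = y_0 - (r - \tfrac12)\,h,$$

where $(x_0, y_0)$ is the top-left corner of the raster and $w,h$ the pixel
sizes. All point-in-polygon and resampling logic uses this centre
convention; grids are half-open. Rasters are stored as multi-page float32
TIFF with a JSON sidecar carrying the georeferencing, plus a validity page
encoding nodata (nodata is scene-wide: a pixel missing in one band is
treated as missing everywhere).

## Tree-crown detection

Tree crowns at metre resolution appear as approximately isotropic,
bell-shaped intensity bumps on the NIR band. The detector computes the
scale-normalized Laplacian-of-Gaussian response

$$R(x, y, \sigma) = -\sigma^2 \, \nabla^2 (G_\sigma * I)(x, y)$$

over a geometric ladder of scales (defaults: 2–12 m in 12 steps) and takes
local maxima over the $(x, y, \sigma)$ volume. For a Gaussian bump of scale
$s$ and amplitude $A$ the response peaks at $\sigma = s$ with value close
to $A/2$, which is how the response threshold default (0.02) should be
read: it admits bumps down to roughly 4% reflectance amplitude. Maxima are
refined to sub-voxel precision by independent quadratic fits along $x$,
$y$ and $\log\sigma$; scale refinement happens in the log domain because
the ladder is geometric.

Each detection also carries a **curvature anisotropy** score: the ratio
$\mathrm{tr}(H)^2 / \det(H)$ of the Hessian of the scale-smoothed image at
the peak. An isotropic maximum scores exactly 4; parcel corners, field
edges and other non-crown structures score higher (or have indefinite
Hessians, reported as `Inf`). Filtering at 4.1 (`strong_blobs()`,
`register_scene(max_anisotropy = )`) removes structures whose sub-pixel
position estimates are systematically biased by their geometry — exactly
the detections that degrade a translation estimate or stamp spurious tree
footprints over crops. The bound is calibrated on synthetic Gaussian
crowns; real crowns are rougher, and users working with real imagery may
need to relax it.

## Co-registration

One scene per site is the **master**; all others are registered onto it.
The master is chosen to maximize tree-shadow visibility, proxied by
$\cot(\text{sun elevation})$ — shadow length grows as the sun drops — with
deterministic tie-breaks (earliest acquisition, then scene id). The exact
shadow computation from joint sun/satellite geometry is not specified in
the tradition this follows; the cotangent proxy is this package's stand-in
and is isolated in `select_master()`.

Crown centroids are first corrected for parallax: an elevated object
viewed off-nadir appears displaced by $h \tan\theta$ along the satellite
azimuth ($h$ = canopy height, default 10 m, configurable; $\theta$ =
off-nadir angle). This is first-order geometry with a single site-wide
height — individual tree heights are unknown.

Tie points are formed by mutual-nearest-neighbour matching within a search
radius (after subtracting any coarse a-priori shift); the pairing is
one-to-one by construction, and each pair is scored
$\min(\text{resp}_m, \text{resp}_t) \cdot
\min(\sigma_m,\sigma_t)/\max(\sigma_m,\sigma_t)$.

The geometric correction (translation by default; affine by flag) is
estimated by random-sample consensus with a fixed seed, using only the
strongest `max_gcps` pairs (default 20) as ground control. After the
consensus stage the fit is polished by iterated trimming: refit, halve the
tolerance, re-select inliers, three rounds by default. The trimming exists
because pair quality is strongly bimodal — crown pairs localize to a
fraction of a pixel while residual non-crown pairs carry metre-level,
geometry-dependent bias that does not average out. Reported RMSE and
inlier counts refer to the caller's tolerance (default 1.5 pixels);
translation is the default model because multi-temporal misregistration of
orthorectified VHSR products is dominated by a consistent shift.
Resampling onto the master grid is nearest-neighbour or bilinear, with
nodata propagation.

Registration quality is assessed in the style of a control-point survey:
signed per-axis residuals at control locations, summarised as mean and
standard deviation of absolute residuals (sample, $n-1$ denominator),
min/max signed residuals, and per-axis RMSE.

## Cloud masking

VHSR sensors lack thermal bands, so the cloud mask assumes cloud pixels
are the brightest blue-band pixels of the scene and takes the *number* of
cloudy pixels from the provider metadata percentage $p$: masked pixels are
exactly those strictly above the $(1 - p/100)$ order-statistic (type-1)
quantile of the valid blue pixels. The strict inequality makes the rule
conservative under ties — the masked fraction never exceeds $p/100$, and a
constant blue band masks nothing. Whether the original workflow used a
per-scene quantile or a fixed sensor threshold is not documented; the
quantile is chosen here because it is exactly consistent with
"the brightest $p\%$" and parameter-free. The assumption fails over snow,
ice or bright sand; that limitation is inherited.

## Tree masking

On the master scene, each confident crown detection stamps a disc of
radius $2\sigma$ (a Gaussian's visually apparent edge; configurable), and
a pixel is masked only if its NDVI also exceeds a deliberately *lowered*
threshold (default 0.2 against the conventional 0.3): the design accepts
false positives to avoid missed crowns, since an unmasked tree
contaminates crop spectra silently while an over-masked pixel merely
reduces the sample. The master mask is adapted to other acquisitions by
translating it $h\tan\theta$ along the satellite azimuth, rounded per axis
to whole pixels; pixels shifted off-grid are dropped, so adaptation never
grows a mask. The method works for isolated crowns; tree rows and forest
patches are out of scope.

## Per-field statistics

Fields enter as polygons with crop labels. A 2 m inward (negative) buffer
discards boundary-mixed pixels; buffering is implemented as half-plane
intersection and therefore supports convex rings (the generator produces
rectangles). Pixel membership is centre-in-polygon on the buffered ring;
`n_total` counts member pixels that are not nodata, `n_used` additionally
removes masked pixels. A fully masked field still produces a record, with
counts present and statistics empty — an empty cell is recoverable, a
silent zero is not.

Spectral statistics use population ($n$-denominator) moments: mean,
variance $m_2$, moment-ratio skewness $g_1 = m_3/m_2^{3/2}$, and
population covariance/correlation between bands. Constant bands have zero
variance and undefined skewness/correlation (NA).

Nine vegetation indices are computed pixelwise and summarised as mean and
population SD over used pixels (pixelwise rather than from band means,
because the mean of a ratio is not the ratio of means): NDVI, green NDVI,
EVI, TCARI, the NIR/red simple ratio, SARVI (with
$R_{RB} = R_R - \gamma(R_B - R_R)$, $\gamma = 1$), SAVI and SARVI sharing
the soil constant $L = 0.5$, MSAVI2, and NDVI on the second NIR band.
Indices whose bands a sensor lacks are omitted rather than imputed;
division by zero yields NA for that pixel.

## Texture

Texture is measured on the panchromatic band (fallback: NIR) via the
grey-level co-occurrence matrix over the field's irregular support: only
pixel pairs fully inside the field contribute. Choices the literature
leaves open, fixed here and configurable:

* **Quantization**: linear stretch of the field's own min–max range into
  $G \in \{64, 256\}$ levels. Texture is a within-field property; a global
  stretch would couple fields through scene-wide extremes.
* **Displacement**: distance 1 pixel, angles 0/45/90/135 degrees (to
  catch directions along and across sowing rows), symmetric counting.
* Thirteen descriptors per matrix: angular second moment, contrast,
  correlation, variance (centred on the marginal mean), local homogeneity,
  sum average, sum variance (centred on the sum average — the historical
  formula centres it on sum entropy, widely regarded as a typo), sum
  entropy, entropy, difference variance, difference entropy, the first
  information measure of correlation (`f_imc`), and the maximal
  correlation coefficient $\sqrt{\lambda_2(Q)}$ (computed on the
  non-empty-level submatrix; NA on numerical failure). The second
  information measure is also computed and written to an auxiliary column
  `f_imc2`.
* Entropies are reported in **bits**. The exponential form of the second
  information measure is only scale-correct under natural logarithms, so
  `f_imc2` is computed from nat-log entropies internally.

Eight records per field (2 grey-level settings × 4 angles); fields with
fewer than 4 usable pixels or no co-occurring pairs yield NA descriptors.

## The incremental pipeline

Each scene expands into a fixed chain — register onto the master, cloud
mask, tree mask, field statistics — forming a DAG whose nodes carry
fingerprints: the md5 of input files, canonicalized parameters, and parent
fingerprints. A node is stale when its stored fingerprint differs or its
output is missing, and staleness is closed under descendants. Content
hashes rather than timestamps drive re-execution, so copying or touching a
file never rebuilds anything, while adding one scene re-executes exactly
that scene's chain and changing, say, the NDVI threshold re-executes all
tree masks and downstream statistics but no cloud masks. A failed stage
skips its descendants and flags the run; a second run over unchanged
inputs executes nothing, and full and incremental runs produce
byte-identical outputs under the same seed.

## The synthetic-scene generator

The generator emulates the features each module consumes, with full ground
truth:

* **Parcels**: axis-aligned rectangles on a regular grid, homogeneous
  per-band reflectance with a per-field brightness factor — so moments and
  pixel counts are analytically checkable.
* **Crowns**: additive isotropic Gaussians (amplitude 0.15 by default) on
  the NIR, green and panchromatic bands, with scales drawn from 4–7 m,
  realistic for savanna parkland trees at 2 m GSD. Crowns are placed
  *isolated*: separation at least $6\max(\sigma_i,\sigma_j)$ between
  crowns and $3.5\sigma$ clearance from parcel boundaries, because the
  detector's premise — and the upstream method's stated domain — is the
  isolated bell-shaped crown; a crown straddling a reflectance step is a
  different (and harder) object that the chain does not claim to handle.
* **Clouds**: connected patches grown from random seeds to *exactly*
  $\mathrm{round}(f \cdot n_{px})$ pixels, then assigned blue reflectance
  strictly above every background pixel, so the metadata-percentage
  premise of the cloud mask holds by construction.
* **Noise**: i.i.d. Gaussian per pixel and band (default SD 0.01), clamped
  to $[0,1]$. A separate noise seed lets repeat acquisitions share the
  landscape while differing in noise, which is what makes registration
  pairs honest.
* **Shifts**: applied by resampling with the same machinery the
  registration uses, recorded as ground truth.

Default scene size is 128 × 128 px at 2 m GSD (256 m on a side) with 12
crowns and 5 parcels; registration studies use 20 seeded pairs with 2%
noise and shifts up to 10 px. These sizes keep a full multi-scene site
run in the tens of seconds while leaving every property measurable.

What the generator does **not** emulate: sensor PSF and saturation,
BRDF and illumination gradients, atmospheric residuals, terrain
displacement, mixed pixels at parcel edges beyond plain averaging, crop
row structure, and trees inside closed crop canopy. Passing tests
therefore demonstrate algorithmic correctness under the stated model, not
performance on real imagery; in particular the anisotropy bound (4.1) and
the response threshold are calibrated to clean Gaussian crowns.

## Numerical choices and degenerate inputs

* Quantile type 1 (inverse empirical CDF) for the cloud threshold; strict
  inequality at the threshold.
* Quadratic sub-voxel refinement offsets are clamped to ±0.5 voxel;
  degenerate (flat) denominators fall back to the grid position.
* Consensus estimation restores the caller's RNG state; all seeds are
  explicit arguments.
* Division by zero in any index yields NA for that pixel, never ±Inf;
  undefined statistics are written as empty CSV cells, never 0.
* Affine estimation refuses collinear minimal samples (QR rank test).
* `stitch_tiles` requires co-aligned grids (origins differing by whole
  pixels at 1e-6 tolerance) and resolves overlaps by input order
  ("first wins"), making mosaics deterministic and order-documented.

## Known limitations

* Negative buffering is exact for convex rings only; concave field
  polygons are refused rather than mis-buffered.
* The cloud rule trusts the provider percentage; a wrong percentage
  masks the wrong number of (still brightest) pixels.
* Tree masking inherits the isolated-crown assumption; at coarser GSD
  (e.g. 6.5 m) crown detection degrades and the mask thins.
* The shadow-length master proxy ignores satellite-side occlusion
  geometry.
* GeoTIFF interchange uses a TIFF + JSON-sidecar representation; scenes
  written by other software need their georeferencing supplied through
  the sidecar convention.
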