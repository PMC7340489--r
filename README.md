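# parcelscope

Object-based processing of very-high-spatial-resolution (VHSR) satellite
imagery over smallholder agricultural landscapes.

Smallholder fields are small, irregular, and scattered through landscapes
of isolated trees; following their crops through a season with sub-metre
to few-metre imagery requires sub-pixel co-registration of the scene
stack, removal of cloud-contaminated pixels, and separation of tree-crown
spectra from crop spectra before any per-field statistic is meaningful.
`parcelscope` implements that chain and the signature extraction on top of
it:

* **Tree-crown detection** — scale-normalized Laplacian-of-Gaussian blob
  detection with automatic scale selection
  (`R(x,y,\sigma) = -\sigma^2 \nabla^2 (G_\sigma * I)`), sub-voxel
  refinement, and a curvature-anisotropy test that separates bell-shaped
  crowns (trace²/det of the Hessian ≈ 4) from corner/edge artifacts.
* **Co-registration** — master selection by a shadow-length proxy
  (cot of sun elevation), parallax adjustment of crown centroids
  (h·tan θ along the satellite azimuth), mutual-nearest-neighbour tie
  points, and a seeded random-sample-consensus translation/affine fit
  with iterated trimming; accuracy is summarised control-point style
  (per-axis RMSE of signed residuals).
* **Cloud masking** — the brightest blue-band pixels, with the masked
  count fixed by the metadata cloud percentage via a strict
  order-statistic quantile rule.
* **Tree masking** — discs of radius 2σ around confident crowns, gated by
  a deliberately lowered NDVI threshold (0.2), adapted across
  acquisitions through the sensor-target geometry.
* **Per-field signatures** — 2 m negative buffer, centre-in-polygon pixel
  selection, population spectral moments with band correlation/covariance,
  nine vegetation indices (NDVI, green NDVI, EVI, TCARI, simple ratio,
  SARVI, SAVI, MSAVI2, NDVI-NIR2) summarised pixelwise, and grey-level
  co-occurrence texture (64 and 256 levels × 4 angles, thirteen Haralick
  descriptors, entropies in bits) — written as per-scene CSVs.
* **Incremental pipeline** — a make-like DAG keyed on content
  fingerprints (file md5 + canonical parameters + parent fingerprints):
  adding a scene re-executes exactly that scene's chain, a second run is
  a no-op, and full vs incremental runs are byte-identical.
* **Synthetic scenes** — a generator with complete ground truth
  (Gaussian crowns, homogeneous parcels, exact-count bright cloud
  patches, known inter-scene shifts), so the whole chain is testable
  without proprietary imagery.

## Worked example

```r
library(parcelscope)

sim <- simulate_scene(sim_config(seed = 42, cloud_fraction = 0.05))
sim$scene
#> <ps_scene> SYN000042
#>   128 x 128 px, 7 band(s): blue, green, red, rededge, nir1, nir2, pan
#>   pixel 2 x 2 m, origin (500000.00, 1500000.00), EPSG:32630

blobs <- strong_blobs(detect_blobs(sim$scene))
nrow(blobs)                       # confident crown detections
#> [1] 9                           # (12 injected; 3 lie under the clouds)

cloud_mask(sim$scene, sim$metadata)
#> <ps_mask:cloud> 128 x 128 px, 819 masked (5.00%)
```

The cloud mask recovers exactly the 819 injected bright pixels
(`round(0.05 * 128^2)`). Extracting per-field signatures:

```r
tm <- tree_mask_master(sim$scene, blobs)
cm <- cloud_mask(sim$scene, sim$metadata)
ex <- extract_all(sim$scene, sim$metadata, sim$truth$field_polygons,
                  list(cm, tm))
r <- ex$spectral[[1]]
#> field F001 (maize): n_total 225, n_used 225,
#> NDVI 0.666 +/- 0.031, nir1 mean 0.449
```

`n_total` counts pixel centres inside the 2 m-buffered polygon; `n_used`
removes masked pixels. NDVI ≈ 0.67 with SD ≈ 0.03 is the vegetated-parcel
signal plus the 1% simulated sensor noise. Registering a repeat
acquisition that was shifted by a known (7.0, −4.5) m:

```r
t2 <- simulate_scene(sim_config(seed = 42, cloud_fraction = 0.05,
                                noise_seed = 99))
target <- shift_scene(t2$scene, c(7.0, -4.5), "bilinear")
register_scene(sim$scene, target, seed = 1)$correction
#> <ps_correction> translation
#>   parameters: tx=6.9759 ty=-4.5144
#>   9 inliers, RMSE (0.106, 0.185) m
```

The recovered translation is within 0.03 m (0.015 px) of truth; the
residual RMSE of ~0.1–0.2 m is the crown-localization noise floor at 2%
reflectance noise.

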