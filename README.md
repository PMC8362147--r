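# efovct

Extended field-of-view CT reconstruction at desk scale: simulation of
truncated fan-beam acquisitions and two detruncation pipelines, with the
quantitative evaluation protocol used to compare them.

## The problem

A CT scanner measures a cylindrical *scan field of view* (sFoV) — here
500 mm diameter for a scanner with focus-to-isocenter distance
RF = 595 mm and focus-to-detector distance RFD = 1086 mm — while its bore
admits objects up to 800 mm wide.  A patient or phantom wider than the
sFoV produces *truncated* projections: every ray that should have crossed
the anatomy beyond the detector edge is missing, and a plain filtered
backprojection (FBP) shows a bright rim at the sFoV boundary and no
usable contour in the annulus between the sFoV and the bore (the
*extended field of view*, eFoV).  In radiotherapy planning that annulus
matters: body contour and tissue there enter the dose calculation.

`efovct` implements, on simulated 2D fan-beam slices, the two
reconstruction strategies this package exists to compare:

* **HDFoV** (mass-consistency detruncation).  For an untruncated scan
  the parallel-equivalent projection mass
  `M(θ) = Σ_t p(θ, t) Δt` is the same at every view angle; truncation
  makes the normalized profile `M(θ)/max M` drop below 1.  Each
  truncated view is extended with a cosine-squared lobe
  `p_edge · cos²((π/2) d / W)` whose width `W` is solved so the added
  mass equals the view's deficit.  A first-pass reconstruction of the
  extended data is Gaussian-smoothed and binarized into an object mask,
  the mask is forward-projected as water, and the projections merge with
  the measured data (which stay bit-exact) for the final FBP.
* **HDeepFoV** (projection-domain fusion with a learned estimate).  The
  measured data are reconstructed with a linear-times-cos² extrapolation
  used *only during the convolution step*, downsampled to the 256×256
  estimator grid, and passed to an image-domain estimator — a small
  U-Net trained on synthetic bodies, or the `identity`/`oracle`
  baselines that bracket it.  The estimate is forward-projected onto the
  bore-wide channel grid and fused with the measured data in the
  projection domain, so the final image is a genuine 512² FBP
  reconstruction, never an upsampled network output.

The package also provides the synthetic training-data procedure
(random body-like slices that exceed the sFoV but fit the bore, forward
projection, truncation, conv-only reconstruction; DSSIM loss
`(1 − SSIM)/2`, ADAM, leaky-ReLU) and the evaluation protocol:
eFoV-restricted Jaccard conformity index, per-slice eFoV volumes and
their RMSD, HU statistics in cylindrical ROIs, and eFoV HU histograms,
measured against the analytic phantom mask and a stitched two-scan
reference.

## Worked example

```r
library(efovct)

geom    <- scan_geometry()                      # RF 595, RFD 1086, 720 views
phantom <- make_thorax_phantom(thorax_spec(n_slices = 1))   # 560 x 270 mm

# simulate the truncated acquisition
wide     <- forward_project(phantom$image, extend_geometry(geom))
measured <- truncate_sinogram(wide, geom)
min(projection_mass(measured)$normalized)
#> [1] 0.9494384            # truncation: the mass profile drops below 1

detrunc <- cosine_detruncate(measured)
max(abs(projection_mass(detrunc$sinogram)$normalized - 1))
#> [1] 0.000315171          # mass consistency restored (tolerance 1e-3)

truth <- efovct:::analytic_mask(phantom$spec, 512, 800)
jac <- function(rec) jaccard_efov(truth, object_mask(rec), geom)
jac(fbp_reconstruct(measured, fov_mm = 800, matrix = 512))
#> [1] 0.05290102           # naive zero-padded FBP: no eFoV contour
jac(hdfov_reconstruct(measured))
#> [1] 0.96                 # mass-consistency pipeline
jac(hdeepfov_reconstruct(measured, estimator_oracle(phantom$image)))
#> [1] 1                    # upper bound: oracle estimate
```

The numbers are the eFoV-restricted Jaccard index (1 = perfect contour
outside the sFoV) of each reconstruction against the analytic body mask;
they reproduce the ordering naive < HDFoV < HDeepFoV-with-oracle.  The
full three-couch-height comparison, including the stitched reference and
volume RMSDs, runs via `run_experiment(run_config())`, and a trained
estimator comes from `train_estimator(generate_training_corpus(cfg), cfg)`
with `cfg <- training_config()`.

A thin command-line wrapper (`inst/cli/efovct.R`) exposes `simulate`,
`train`, `reconstruct`, `evaluate` and `reproduce-experiment`.

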