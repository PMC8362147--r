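---
title: "Extended field-of-view CT reconstruction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended field-of-view CT reconstruction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`efovct` simulates fan-beam CT acquisition of objects wider than the scan
field of view (sFoV) and reconstructs them on an extended field of view
(eFoV) with two pipelines: mass-consistency detruncation (HDFoV) and
projection-domain fusion of an image-domain estimate (HDeepFoV).  This
vignette records the models, their assumptions, the parameters that
matter, and the choices made where the design was genuinely open.  All
empirical statements below are the ones the package's test suite and
acceptance script themselves compute.

## Scan model and geometry

The scanner is modeled as a stack of independent 2D fan-beam slices with
a flat, equally spaced detector:

* `RF = 595` mm focus-to-isocenter, `RFD = 1086` mm focus-to-detector;
* sFoV radius 250 mm, bore radius 400 mm;
* default detector: 504 channels of 2 mm at the detector
  (half-width 504 mm, just covering the sFoV since
  `RFD·tan(asin(250/595)) = 502.9` mm — the detector half-width is not an
  independent datum; it is derived from the sFoV-coverage condition);
* default angular sampling: 720 views over a full rotation.

The true scanner is a 3D multi-slice system; every operation implemented
here is per-projection-row, so 2D stacked slices lose nothing except
cone-angle effects, which no claim in the package depends on.  Only
full-scan (360°) reconstruction is implemented; short-scan weighting is
out of scope.  Slices couple only where HDFoV's cross-slice Gaussian
smoothing makes them.

The forward projector integrates linear attenuation along each
source-to-channel ray by fixed-step sampling (default half the image
pixel spacing) with bilinear interpolation.  Rays are clipped to a circle
slightly beyond the bore: any physical object must fit inside the bore,
so attenuation outside it is zero by construction.  HU and attenuation
relate by `mu = mu_water·(1 + HU/1000)`, with `mu_water = 0.02/mm`
(roughly a 70 keV effective energy) as a configurable default.

Reconstruction is flat-detector fan-beam filtered backprojection: cosine
pre-weighting on the virtual detector through the isocenter, row
convolution with the band-limited discrete ramp (Ram-Lak; optional
Shepp-Logan/cosine/Hamming apodization, default plain ramp since clinical
kernels are out of scope), and distance-weighted backprojection with the
`RF²/L²` factor and a factor 1/2 for the double coverage of a full scan.
Before filtering, the channel grid is always zero-extended to cover the
bore, which makes "plain FBP of truncated data" and "merged sinogram
with all-zero extension" literally the same computation — the equality
the measured-data-preservation tests assert bit-exactly.

## Projection mass and the parallel-equivalent measure

The mass-consistency condition says the integral of a projection row is
the same at every view for untruncated data.  That statement is exact
only for *parallel* projections.  For fan rays no per-channel weight can
make the per-fan-angle channel sum angle-invariant (the weight would
have to depend on position along the ray); for the 560 mm × 270 mm
thorax at this fan angle the best per-channel weighting still varies by
several percent over angles, far above the tolerance at which truncation
must be detected.  `projection_mass()` therefore evaluates the mass in
the parallel-equivalent domain: each fan ray `(β, u)` is rebinned to the
parallel view `θ = β − atan(u/RFD)` at offset `t = RF·sin(atan(u/RFD))`,
and the mass of a view is the rebinned row sum times `Δt`.  At 720 views
this measure is angle-invariant to ~3×10⁻⁴ for untruncated simulations
(the residual is bilinear interpolation error, shrinking with angular
sampling), and it equals the object's attenuation area integral — the
oracle the tests compare against at 0.5%.

`cosine_detruncate()` works in the same domain: per view, the deficit
relative to the reference (maximum) mass is split between the two
truncated edges in proportion to the edge values, and each edge gets a
`p_edge·cos²((π/2)·d/W)` lobe whose width `W` is solved by bisection so
the added mass equals the share.  If even the bore-wide width cannot
absorb the deficit the amplitude is boosted by a recorded correction
factor.  The parallel-domain lobes are then resampled onto the fan
sinogram's extension channels (measured channels stay bit-exact), and
lobe amplitudes are rescaled in a short fixed-point iteration until the
fan sinogram's mass profile is flat to `mass_tol = 2×10⁻⁴` — comfortably
inside the 10⁻³ acceptance tolerance at the default sampling.  The
reference-by-maximum estimator is the natural choice because truncation
can only remove mass; it is itself an untruncated view for every
phantom in the package (two thirds of the thorax's views are
untruncated).

## HDFoV

Pipeline: cosine detruncation → first-pass FBP on the bore-wide 800 mm
FoV (default matrix 256; the kernel question — clinical kernel vs smooth
kernel for the first pass — is resolved as "same ramp as the final
pass") → 3D Gaussian smoothing (defaults `sigma_mm = 5` in-plane,
`sigma_slices = 1` across slices) and binarization at `threshold_hu =
−400`, keeping the largest connected component per slice with holes
filled → forward projection of the mask as water (`mu_water` inside) on
the bore-wide channel grid → projection-domain merge → final FBP
(default 512² over 800 mm, pixel spacing 1.5625 mm).  The smoothing,
threshold, and first-pass matrix are stated defaults rather than values
inherited from any product implementation, whose exact normalizations
are proprietary; the package is an emulation of the published principle.

The merge keeps measured channels untouched and feathers only the
simulated side: the boundary jump (measured edge minus adjacent
simulated value) decays linearly to zero over `feather = 3` channels.
When the junction is already continuous — in particular for objects
fully inside the sFoV, where both sides are zero — feathering is a
no-op, which is what makes the in-sFoV equality with plain FBP exact.
An empty first-pass mask (nothing above threshold) falls back to the
cosine-detruncated reconstruction with a warning.

## HDeepFoV

The network input is the measured sinogram reconstructed with the
linear-times-cos² extrapolation — slope-matched at the truncation point,
windowed to reach zero at the bore — used *only during the convolution
step*; the backprojection uses measured channels exclusively.  The
result on the 800 mm FoV is area-averaged down to the fixed 256×256
estimator grid.  The same procedure serves training and inference, which
is the consistency the method relies on.

The estimator is a pluggable contract (256² HU in, 256² HU out, output
clipped to [−1000, 3000]) with three implementations: `identity` (lower
baseline), `oracle` (returns the true image; the upper bound that
validates the pipeline independently of any training run), and
`trained`.  The estimate is forward-projected directly on the bore-wide
grid — the open question of whether to upsample before projecting is
resolved as direct projection, since the projector accepts any grid and
upsampling adds nothing — fused with the measured data (bit-exact on
measured channels, same feathering), and reconstructed by a standard
FBP at 512².  No image-domain scaling or blending exists anywhere in
the path; the eFoV content reaches the image only through the projector,
so resolution and noise texture come from the final reconstruction, not
from the network.

## Estimator training

Training pairs are synthetic: a random body-like slice (elliptical body
with half-width beyond the 250 mm sFoV but fitting the bore, two lung
ellipses, up to three random circular structures; pose, size and HU
drawn per pair) is rasterized on the 800 mm grid as ground truth,
forward-projected, truncated, and pushed through the network-input
procedure.  The generator applies its scale/rotation/shift analytically
to the component parameters rather than resampling images, so the exact
body mask stays available for evaluation; the procedure can emit
unlimited pairs, and every pair is bit-reproducible from
`(config, index)`.  The corpus uses a reduced desk-scale sampling of the
same scanner (144 views, 4 mm channels, 256² intermediate
reconstruction) — these sizes, like the 500-pair default corpus (versus
tens of thousands at production scale), are the package's desk-scale
study conditions, stated here once; claims about the trained network are
therefore ordinal (better than untrained, better than identity), never
absolute.

The loss is structural dissimilarity, `DSSIM = (1 − SSIM)/2`, with the
standard constants (k1 = 0.01, k2 = 0.03, data range 1, 11-pixel Gaussian
window of sigma 1.5).  Local statistics use periodic boundary handling,
which makes the Gaussian windowing self-adjoint so the analytic gradient
(verified against finite differences in the tests) is exact; the
brute-force reference implementation in the test suite implements the
same definition independently.  Images are normalized to [0, 1] over
[−1000, 3000] HU at the network interface.

The network is a U-Net with three resolution levels, base 8 channels,
two 3×3 convolutions per level, leaky-ReLU (slope 0.01), average-pool
down, nearest-neighbor up with skip concatenation, and a residual 1×1
head.  It runs on an internal 64×64 grid: the 256² interface input is
area-averaged down, and the network's *correction* (output minus input)
is bilinearly upsampled and added back to the full-resolution input, so
fine detail in the input is never destroyed by the bottleneck.  A deeper
4-level/base-16 network at full 256² resolution was considered and
rejected: on a single CPU its training cost exceeds the package's
per-run compute target by more than an order of magnitude, while the
body-contour completion task is dominated by structures tens of
millimeters wide, well resolved at 12.5 mm pixels.  Optimization is
plain ADAM (learning rate 10⁻³, batch 10, 30 epochs over 500 pairs by
default, validation fraction 0.2); weight initialization, shuffling and
the train/validation split all derive from the config seed, making
training bitwise reproducible; the best-validation-epoch weights are
kept, and a non-finite loss aborts with the log.

## Evaluation protocol

Object masks are thresholded at −400 HU, reduced to the largest
connected component per slice, hole-filled; an exclusion predicate
exists for interface parity with physical-scan masks (patient table)
and is a no-op on synthetic data.  The Jaccard conformity index is
computed after intersecting both masks with the eFoV region, defined as
distance-from-isocenter > 250 mm in the scanner frame (couch shifts move
the phantom, not the region, matching the physical setup).  An empty
union is defined as Jaccard 1 with a flag — the case is degenerate and
the paperless choice here is the conservative one for "both empty means
agreement".  Per-slice eFoV volumes count mask voxels outside the sFoV
circle times the voxel volume; RMSDs are taken over all slices and couch
positions per algorithm.  Insert HU statistics average a cylindrical ROI
(default radius 10 mm over 5 consecutive slices).  Histograms use 10 HU
bins anchored at multiples of the bin width so a uniform HU shift moves
occupied bins by exactly that shift.

The reference image stitches two laterally shifted scans (±60 mm
default), each reconstructed from untruncated-in-sFoV data, shifted back
and joined at the phantom midline.  At raised couch positions the tall
phantom cannot fit either half inside the sFoV, so the reference is
acquired at couch height 0 and aligned to other heights by the known
translation — registration is unnecessary for simulated data where
transforms are known by construction.  How the published protocol's
masks treat internal air is not stated; the package fills the body
outline (lungs count as body), consistently for reference and test.

`run_experiment()` orchestrates the three-couch-height comparison
(0, +90, +120 mm) with all of the above; the desk default uses a 3-slice
phantom stack and 512² reconstructions.  The acceptance suite runs the
ordinal comparison on a single representative slice per height — the
qualitative couch-height pattern, not any physical-scan Jaccard value,
is the reproducible claim at desk scale.

## What the synthetic data do and do not show

The phantom emulates the published evaluation object's dimensions
(560 × 270 mm body, lung-like inclusions, PLA-like +100 HU bulk, optional
tissue-mimicking inserts with nominal HU values) but its internal layout
is procedural, not a copy of any physical phantom; the per-slice outline
scaling (a shallow quadratic dome, 7% at the stack ends) emulates a
smooth superior-inferior contour.  The simulation contains no detector
noise, scatter, beam hardening, or clinical kernels.  Passing tests
therefore demonstrate the *algorithmic* claims — mass-consistency
restoration, measured-data preservation, the ordinal ranking of the
pipelines and its couch-height sensitivity — not clinical image quality.
Published Jaccard/volume/HU figures from physical scans with a
production-trained network are not reproducible at desk scale and are
not targeted; the package's acceptance criteria are property-based and
analytic instead.

## Numerical choices and degenerate inputs

* Ray step: half the image pixel spacing (corpus generation uses one
  pixel, adequate for training data at half the cost).
* Bisection for the lobe width: 60 iterations on (0, W_bore]; the mass
  function is continuous and monotone in W, so the solve is exact to
  float precision; amplitude boost handles the unabsorbable tail.
* Detruncation fixed-point: at most 8 amplitude-correction iterations,
  stopping when the mass profile is flat to 2×10⁻⁴.
* All-zero sinograms reconstruct to air and are rejected by
  `projection_mass()` (undefined reference).
* An angular grid is always a full rotation by construction; FBP rejects
  anything below 8 views as degenerate.
* Ties in largest-component selection resolve to the first label
  (deterministic).
* Empty masks signal a typed condition (`efovct_empty_mask`) so
  pipelines can fall back deliberately rather than crash.

## Known limitations

2D fan-beam only (no cone/helical geometry); full-scan only; no detector
physics; the stitched reference inherits FBP's own discretization; the
trained estimator is a desk-scale network whose value is demonstrated
ordinally on synthetic bodies, and nothing here should be read as a
clinical validation.
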