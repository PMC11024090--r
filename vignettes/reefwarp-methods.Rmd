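---
title: "Recovering top-down reef views from oblique imagery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering top-down reef views from oblique imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Oblique reefscape photographs compress distant substrate: a coral colony
ten metres away subtends far fewer pixels than the same colony at one
metre, so abundance, size, and cover cannot be read off the image.
Inverse-perspective mapping (IPM) removes this distortion by re-projecting
the image of a planar scene into its top-down view with a 3 x 3 projective
homography

$$ \lambda \, (x', y', 1)^\top = H \, (x, y, 1)^\top, \qquad
   H = \begin{pmatrix} h_1 & h_2 & h_3 \\ h_4 & h_5 & h_6 \\ h_7 & h_8 & 1 \end{pmatrix}, $$

where $\lambda$ is the per-point projective scaling. With a known camera
pose, $H$ follows directly from four point correspondences. Reefscape
archives carry no pose metadata, so `reefwarp` estimates the scene's
perspective geometry from the image itself and then searches for $H$.

## The pipeline

Seven stages, each a documented function:

1. **Lens calibration** (`calibrate_camera`) — once per lens, from
   checkerboard views: saddle-point corner detection, plane-homography
   initialization of the pinhole intrinsics, and Levenberg-Marquardt
   refinement of the five-coefficient Brown distortion model
   (`minpack.lm`). Underwater housings change the effective focal length;
   calibrating in situ absorbs the refraction into the intrinsics.
2. **Undistortion** (`undistort_image`) — forward-model remapping with
   bilinear sampling, then a crop to the maximum inscribed axis-aligned
   rectangle of valid pixels (`largest_rect_in_mask`).
3. **Horizon detection** (`detect_horizon`) — the water column produces no
   edges while reef texture produces many, so the horizon is the
   demarcation in local edge density. The chain: grayscale, Gaussian blur
   (5 x 5, sigma 2), adaptive mean thresholding (block 51, offset 2/255),
   Canny (50/150 on 8-bit gradients), windowed edge-density rate normalized
   to [0, 1], a Theil-Sen "water-column line" through 100 randomly sampled
   zero-density pixels with everything above it zeroed, Otsu binarization,
   external-boundary tracing of the longest contour, border-point removal,
   a z-score cut (2.5) on the y-coordinates, and a final Theil-Sen fit.
   The horizon must intersect the left image edge.
4. **Roll removal** (`remove_roll`) — rotate by the negative arctangent of
   the horizon slope about the image centre, crop to the closed-form
   largest inscribed axis-aligned rectangle, and carry the intercept
   through the same point transformation.
5. **Source-plane detection** (`anisotropy_profile`,
   `select_anisotropy_index`) — anisotropy $A = [\sigma^2(\arctan \nabla
   E_n)]^{-1}$, the reciprocal variance of edge-tangent orientations, is
   computed in a full-width window (height one-fifth of the
   horizon-to-bottom distance) sliding from the horizon to half the image
   height. Near the horizon foreshortening collapses orientations toward
   horizontal (high $A$); closer to the camera texture is isotropic (low
   $A$). The "anisotropy index" marks the top of the reliably
   transformable plane.
6. **Perspective-grid detection** (`detect_line_segments` through
   `build_perspective_grid`) — probabilistic Hough segments (deliberately
   relaxed: 10 votes, 20 px minimum, 5 px gap), logical-angle filtering
   keyed to the horizon intercept (10-25 degrees minimum, 80 maximum),
   left/right split with the slope-sign rule, seeded downsampling to
   balance sides, all left-right intersections filtered to a +/-1% H band
   around the horizon and the central quarter of the width, their mean as
   the overall vanishing point, and the segment whose infinite line passes
   closest to it as the vanishing line (extended to 500 px and slid along
   its direction to stay on the source plane). A horizontal line through
   its y-midpoint completes the axis-aligned perspective grid.
7. **Brute-force IPM** (`search_compression_factor`) — destination corners
   pin the far edge to the top-source corners and place the near corners
   symmetrically with separation $d = x_{cf} \, w$. Stepping $x_{cf}$ down
   from 1 in increments of 0.005, the grid-bearing plane is warped and the
   angle between the two warped grid lines re-measured (HSV segmentation
   of the reserved yellow, 5 x 5 morphological closing, two dominant Hough
   lines refined by total least squares). The search halts when the grid
   measures 90 degrees within 0.5; if two consecutive iterates bracket 90,
   the closer one is kept. At 90 degrees the vanishing line has become
   parallel to the depth axis: the perspective is gone.

## What the synthetic scenes emulate

`render_reefscape` images a textured ground plane with a pinhole camera of
known height, pitch, roll, and intrinsics, and exports analytic ground
truth (horizon line, vanishing point, true top-down homography, marker
coordinates, and the true compression factor via back-projection of row
endpoints). The texture is built from what the detection stages actually
consume:

- **Fractal value-noise octaves** (0.0125-6.4 world units) band-limited at
  the local ground footprint. The vertical footprint grows quadratically
  with range (grazing-angle squash), so octaves fade exactly where a real
  camera stops resolving them; without this the rendered texture aliases
  into per-pixel speckle near the horizon and edge density peaks in a
  fictitious band.
- **Elliptical colony blobs** with apparent (pixel) radii drawn directly
  (5-25 px) and converted to world radii at depth: colonies of many
  physical sizes, with roughly uniform image-space edge density — the
  texture assumption the horizon demarcation relies on. Colonies whose
  foreshortened height falls below a few pixels fade out, as optics would
  blur them.
- **Elongated groove/branch features**, 60% aligned with the depth axis
  (spur-and-groove fashion, sd 1.5 degrees): the straight structures whose
  images converge at the vanishing point. Without some world-straight
  content no vanishing geometry is detectable — on featureless rubble the
  real method would abort too.
- **Range-dependent haze** (attenuation length 60 camera heights) toward
  the water color, which makes the horizon demarcation faint — the reason
  the detection chain needs adaptive thresholding — plus backscatter
  grain added *after* the haze blend (path radiance is not attenuated),
  which is what keeps the demarcation detectable right up to the horizon.
- A **low-texture water column** above the analytic horizon with optional
  bright clutter blobs to exercise water-column suppression.

Not emulated: wave caustics, turbidity, color attenuation spectra,
non-planar reef relief. Passing tests therefore show geometric
correctness of the pipeline under its own planarity and visibility
assumptions, not robustness to turbid or rugose scenes.

## Numerical and design choices

- **Coordinates**: raster-native, origin at top-left, y increasing
  downward; pixel (row r, col c) sits at (x = c, y = r). "Above the
  horizon" means smaller y; right-side vanishing lines have positive
  slopes in this convention.
- **Homographies** are solved as an 8-unknown linear system with the
  [3,3] element fixed to 1; warping inverse-maps each destination pixel
  and samples bilinearly, black outside the source.
- **Edge-density rate**: the per-window count is divided by the in-image
  window area before normalizing by the global maximum. Raw counts bias
  truncated border windows low, which detaches the reef class from the
  image border and derails the longest-contour step.
- **Density radius** defaults to 4% of the image diagonal. At 2% the
  window-rate variance inside the reef leaves a large fraction of reef
  pixels under the Otsu threshold; the reef class fragments and the
  longest contour follows interior fjords instead of the horizon.
- **Adaptive threshold offset** is 2/255 rather than 0: with 8-bit input a
  smooth water gradient quantizes into one-level bands, and a zero offset
  binarizes every band boundary into spurious edges that erase the
  zero-density water column.
- **Contours** are external boundaries only (holes filled first), the
  behaviour of standard external contour retrieval.
- **Anisotropy index**: consecutive profile windows share almost all of
  their pixels, so profile noise is correlated over tens of rows; the
  moving-average window and derivative stencil scale with the profile
  length (about n/4 and n/16). The derivative rule reads "-1 in
  normalized space" as the first contiguous run of derivative <= -1, and
  the index is the row *below* that run: rapid information loss begins
  there as seen from the camera, and everything above is too distant to
  transform reliably. Taking instead the top of the run leaves the whole
  low-information band inside the source plane and yields compression
  factors near zero, unresolvable at the 0.005 search step.
- **Search robustness**: isolated grid-measurement dropouts (the thinning
  lines alias at strong compression) are skipped, up to 25 consecutive;
  bracket stops require both angles within 5 degrees of 90; once inside
  the tolerance band the search keeps stepping while the angle still
  closes in on 90 and saves the minimizer, so the halt is unbiased. Hough
  segments are refined by a total-least-squares fit of their inlier edge
  pixels before any vanishing-point work (endpoints are pixel-quantized).
  Among candidate vanishing lines passing (nearly) equally close to the
  vanishing point, the longest segment is preferred — it pins the
  direction most precisely.
- **Degenerate inputs**: vertical point sets are rejected by the
  Theil-Sen fit; a zero-variance orientation sample returns the anisotropy
  cap (1e6); images under 0.75 megapixels are refused; every stage failure
  carries one typed code from the batch taxonomy.

## Problem sizes used in the tests

The test suite renders scenes at 1000 x 750 px (most checks) and
1600 x 1200 px (the reference convergence and transect checks), uses
640 x 480 px checkerboards with 12 views for calibration, and 1024 x 768
px images for batch checks — sizes chosen so the whole suite completes in
minutes on a single CPU while remaining above the pipeline's resolution
floor. The acceptance script (`scripts/acceptance.R`) re-renders the
reference 1600 x 1200 scene from scratch and reports the grid angle at
the search halt.

## Known limitations

- The anisotropy-index rule is the least stable stage: on scenes whose
  anisotropy declines smoothly it can place the plane top high, giving a
  small true compression factor; the search then operates near its
  resolution limit.
- The vanishing-point estimate inherits any bias in the candidate-line
  population; scenes without world-straight features abort with
  `NO_CANDIDATE_LINES`, which is the intended behaviour rather than a
  defect.
- Only PNG and TIFF input is supported.
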