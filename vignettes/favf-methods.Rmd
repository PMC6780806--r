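---
title: "Autofocusing visual feedback for fluorescent cell sorting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autofocusing visual feedback for fluorescent cell sorting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(favf)
```

# The problem

Sorting rare fluorescent cells with a robotic micropipette under an
inverted microscope requires three-dimensional locations of every target
in real time. The lateral position comes from template matching in the
image plane; the hard part is depth. A microscope objective has a
shallow depth of field, so a cell even a few micrometres off the focal
plane appears as a blurred disc, and its blur diameter grows — to a good
approximation linearly — with its distance from the plane. `favf`
implements the complete visual side of such a system, together with the
virtual microscope needed to exercise every part of it without hardware:

* a defocus imaging simulator (`render_scene()`, `render_defocus_stack()`,
  `make_mixture_scene()`, `make_cluster_scene()`);
* scalable correlation-coefficient (SCC) matching for rough and precise
  planar locating (`correlation_map()`, `build_scalable_templates()`,
  `rough_locate()`, `precise_locate()`);
* watershed instance segmentation of overlapping cells
  (`overlap_judgement()`, `segment_overlapped()`);
* multiple depth from defocus (MDFD) with contrast-trend symmetry
  screening (`mdfd_estimate()`, `mdfd_single_pass()`,
  `depth_from_defocus()`, `focused_diameter()`);
* neighborhood-search tracking of the pipette tip (`init_track()`,
  `track_step()`, `evaluate_tracking()`);
* a closed-loop virtual sorter with purity and recovery metrics
  (`virtual_rig()`, `sort_fov()`, `scan_dish()`, `compute_metrics()`).

# The imaging model

## Defocus blur

A point source at distance $z$ from the focal plane images as a blur
spot. We model the point spread function as an isotropic 2D Gaussian
(`gaussian_psf()`),

$$h(x,y) = \frac{1}{2\pi\sigma^2}\exp\!\left(-\frac{x^2+y^2}{2\sigma^2}\right),$$

with spread proportional to the defocus. The apparent (blur) diameter of
a cell of focused diameter $D$ follows the linear law

$$D_n = D + s\, p\, |z|,$$

where $s$ is the blur slope (px/µm) and $p$ the pixel size (µm/px);
`model_blur_diameter()` is the analytic oracle every depth test is
checked against. The observed image is the focused image convolved with
the PSF, $g = h * \mathrm{im}$; because the discrete kernel is
renormalized to unit sum, the total brightness energy of a cell is
conserved as it defocuses — only dispersed. Both properties (energy
conservation to < 0.5 %, measured-diameter linearity) are asserted in
the test suite.

## Cell photometry

Cells are rendered as a sharp-edged stained body at 72 % of the peak
intensity plus a Gaussian "perinuclear" core that carries the remaining
28 %. Both features are deliberate:

* the **sharp boundary** makes the grey profiles of the same cell taken
  at different planes intersect at an (almost) fixed pair of points —
  the focused boundary — which is what the focused-diameter estimator
  relies on;
* the **bright core** makes the profile contrast $c = \max - \min$
  decay strictly and immediately with defocus, which the sharpness
  judgement and the symmetry screen require. A perfectly uniform disc
  would keep its peak (and hence $c$) constant until the blur reaches
  deep into the plateau, leaving the contrast statistic blind exactly
  where it is needed most.

Dye heterogeneity of this kind (bright perinuclear accumulation over a
dimmer uniformly stained body) is the common appearance of
membrane-dye-labelled cells in practice.

## Default optics and what they emulate

| parameter | default | meaning |
|---|---|---|
| `pixel_size` | 0.25 µm/px | lateral sampling of the camera |
| `blur_slope` | 1.0 px/µm | growth of blur diameter per µm defocus |
| `psf_sigma_per_blur` | 1.0 | $\sigma = \texttt{psf\_sigma\_per\_blur}\cdot(D_n-D)/2$ |
| `valid_depth_range` | 40 µm | beyond it fluorescence is undetectably weak |
| `noise_sigma` | 2 grey | additive Gaussian read noise (8-bit scale) |
| `background_level` | 8 grey | camera offset + stray light |

`psf_sigma_per_blur` was calibrated once so that the blur diameter
*measured by the package's own pipeline* grows at approximately the
nominal slope; it is a simulator self-consistency choice, not a
physical constant. Cells beyond `valid_depth_range` are attenuated
below the noise floor, encoding the observation that such cells cannot
be recognized at all; depth estimates that travel past this range are
reported `out_of_range` (OOR) rather than returned as numbers. Noise is
additive Gaussian with clipping; Poisson shot noise, photobleaching
kinetics, diffraction and aberrations are not modelled. Consequences:
passing tests demonstrate correctness of the *algorithms* under the
stated imaging model, not performance on any particular physical
microscope.

Scenes are generated with excluded volume — solid cells may touch
(centers down to ~0.7–0.8 of the radius sum, as membrane contact
allows) but never interpenetrate. The mixture generator reproduces the
study condition of a 1:100 target-to-background mixture, two colors,
with a configurable fraction of targets in touching contact.

# Planar locating

`correlation_map()` slides a mean-subtracted template over the image
and normalizes by the L2 norms of the mean-subtracted template and
window, so scores live in $[-1, 1]$ and one acceptance threshold
(default 0.6) transfers across template sizes. The exhaustive
brute-force evaluation is kept in the test suite as the oracle; both
the direct and the FFT evaluation path must agree with it to $10^{-9}$.

For rough locating of defocused cells, the focused reference template
is enlarged into a pyramid (default 5 scales, size step 1.13, blur step
3 px) emulating increasing defocus; local maxima above threshold across
all scales are merged by non-maximum suppression. Two NMS radii are
used: half the smaller template width for neighbouring scales
(duplicates of one cell), a quarter width for distant scales — so a
large-scale match covering a merged cluster cannot swallow its member
cells, whose boxes then trigger the segmentation path. Ties are broken
deterministically (score, then x, then y).

Precise locating matches the focused template at a few pure size
variants (0.85–1.3×): cell diameters vary, and a symmetric template of
the wrong size peaks on an edge-alignment ring a few pixels off-center
rather than at the true center. The winning peak is refined to
sub-pixel accuracy by a parabolic fit of the correlation surface.

# Instance segmentation of overlapping cells

Detections whose boxes intersect (transitively) form a group; each
group of two or more runs the chain: keep the red channel, Otsu
binarization, morphological opening (disc, radius 2 px),
distance-transform markers, marker-controlled watershed on the inverted
smoothed intensity (bright cell centers are basins), restricted to the
union bounding box with 1.5× margin. A background "water hole" marker
occupies the top-left 5×5 corner (or the emptiest corner if foreground
touches it).

Markers deserve one numerical note: thresholding the distance map at a
global fraction of its maximum starves the smaller cells of a cluster
(their center distance can sit below the threshold set by the largest
cell) and cannot split pairs whose saddle lies above it. The distance
map is therefore first split into basins (watershed with a 1.5 px
saddle tolerance) and the threshold (default 0.8) is applied within
each basin against its own maximum. Pairs with center separation down
to ~0.7 of the radius sum then split reliably; deeper interpenetration
is geometrically ambiguous, is not produced by the excluded-volume
generators, and would be flagged as under-segmentation rather than
guessed.

# Depth from defocus

## The core relation

With the focused diameter $D$ and blur diameters $D_n, D_{n+1}$
measured at two planes a step $d$ apart, similar triangles give

$$d_n = \frac{D_n - D}{D_{n+1} - D_n}\, d,$$

implemented by `depth_from_defocus()` and verified *exact* on the
analytic blur law. Because blur is symmetric about the focal plane, two
planes cannot tell front from back: the package always takes three
images (at $z$, $z+d$, $z+2d$). The trend of the contrast statistic
$c$ across them disambiguates: rising $c$ means moving toward focus,
falling away, and an interior maximum means the focal plane was crossed
between the outer planes — the symmetric case, which is screened and
re-estimated from the two same-side planes.

## Measurement pipeline

Per plane: grayscale transform (the target's fluorescence channel —
taking a max over channels would inflate the background, since the max
of independently noisy channels is biased upward), Gaussian smoothing
(σ = 1 px), k-means clustering of grey values into background / blur
edge / body (k = 3, quantile-seeded and hence deterministic), merge of
edge+body, small-component removal, convex hull, moment center, and the
blur diameter as the mask width along the horizontal line through the
center — refined to sub-pixel by locating where the 5-row-averaged
profile crosses a fixed isophote 10 grey above background. Two
numerical choices matter:

* the **fixed isophote**: a fraction-of-peak level makes the measured
  width grow convexly with depth (the peak itself decays with blur),
  while a fixed absolute level in the energy-spreading tail settles to
  constant growth per micrometre;
* **isotonic regression** of the monotone outward tail before
  interpolating the crossing: a first-raw-crossing rule is biased
  inward under spatially correlated noise.

The focused diameter $D$ comes from the intersections of the grey
profiles of the two least-blurred planes (`focused_diameter()`), found
as the largest positive-to-negative swing of the sharper-minus-blurrier
profile difference on each side of the center.

## Calibration and the estimator

Eq.-style inversion is only as good as the linearity of the measured
widths and the accuracy of $D$. The package therefore calibrates its
own measurement pipeline once per optics configuration on noise-free
reference renders (diameters 10, 12, 14 µm; depths 0–46 µm):

* the growth curve $g(z)$ of measured width over focused width;
* the focused-width offset $u_0 = W(0) - D$;
* the geometry-dependent bias of the intersection-based $D$, tabulated
  for every pair of plane defocuses and interpolated bilinearly.

A pass then solves a one-parameter weighted least-squares problem: find
the focal-plane position $\zeta$ such that
$W_i = (D_{\mathrm{int}} - b(\zeta) + u_0) + g(|t_i - \zeta|)$ best
fits the three measured widths ($t_i = 0, d, 2d$; weights from the
measured edge gradients, which set each width's precision). On a
linear $g$ this reduces algebraically to the two-plane relation above;
the curve handles the toe near focus and the mild saturation at large
defocus. The anchor through $D_{\mathrm{int}}$ is essential — with a
free anchor the problem is degenerate wherever $g$ is locally linear,
which is precisely why depth from defocus needs the focused diameter.

The sign of $\zeta$ carries the direction; $\zeta$ strictly between
the outer planes marks the screened symmetric case. `mdfd_estimate()`
iterates: move the plane by $\zeta$, re-acquire, stop when the residual
move is below `focus_tol` (0.6 µm) or when the estimate leaves the
valid range (status `out_of_range`). Convergence typically takes 2–3
cycles. The relative error uses the corrected formula
$e = |d_n - d_i| / (|d_n| + D) \times 100\,\%$ with $D$ in µm.

## Protocols

* `evaluate_blur_linearity()`: 10 cells, unequally spaced planes
  {8, 12, 18, 24, 31, 38} µm, mild noise, per-cell first-order fit.
  The planes avoid the immediate-focus toe, where the measured width
  departs from the linear law by construction.
* `evaluate_depth_convergence()`: iterative estimates at step 6 µm for
  initial depths spread over 4–20 µm (the convergent regime).
* `run_error_sweep()`: single-pass errors over a grid of initial depths
  and step intervals, OOR recorded where planes leave the valid range —
  reproducing the qualitative structure of the published sweep (small
  errors for shallow starts, OOR for deep starts with long travels).

# Pipette tracking

`init_track()` crops a template around the focused tip; the search
area is three times the template area (side × √3), centered on the
last position. Each `track_step()` matches only inside the search
area, re-centers, and refreshes the template every 5 frames when the
score is at least 0.8 — adapting to slow appearance change
(fluorescence quenching, impurity adsorption). Every refresh is
re-registered against the original template: unanchored updates drift
by roughly a pixel per hundred frames, which over long sequences walks
the overlap below the 70 % accuracy criterion. Overlap is intersection
over union; a best score below 0.45 flags the track lost (the closed
loop then re-initializes from a precise locate). The simulated
evaluation uses 5 µm/frame — the pixel equivalent of 300 µm/s at
60 fps — over 1500 frames with gradual intensity fade.

# The closed loop

`sort_fov()` runs, per field of view: rough locating → MDFD on the
first region of interest → refocus → precise locating → overlap
judgement and watershed separation → tracked pipette approach →
aspiration of the nearest cell within the capture radius (9.5 µm, the
pipette's inner radius). The tip is driven to within 2 µm of the
target before aspirating, since stopping at the capture-radius edge
risks slurping an adjacent non-target. Cells whose depth is out of
range are remembered and skipped. `scan_dish()` rasters the field
serpentine-fashion with 25 % overlap — enough that a cell clipped at
one field's border is comfortably interior, with template margin, in
the next — and stops at the requested quota. Purity (targets aspirated
/ all aspirated) and recovery (targets aspirated / targets present)
are computed against ground truth; speed is reported per simulation
step, never wall-clock.

# Problem sizes and determinism

All randomness flows through explicit integer seeds; scenes and
renders are bit-reproducible. The shipped test-suite and acceptance
protocols use: 10 cells for the linearity and convergence protocols,
10 cells × 18 conditions for the error sweep, 9 depth groups × 20
targets for detection, 1500 frames for tracking, 50 seeded cluster
trials for segmentation, and a 250 µm virtual dish with 20 targets for
the end-to-end run — sizes chosen so the full suite completes in
minutes while keeping every rate estimate's resolution (1/20 per
group, 1/50 for clusters) matched to the bounds being checked.

# Known limitations

* The simulator's linear-blur/Gaussian-PSF model omits diffraction,
  aberration, chromatic effects and shot noise; all performance
  numbers are internal to that model.
* Blur-growth calibration assumes cells in the 9–15 µm diameter range;
  far smaller cells enter the Gaussian-dominated blur regime earlier
  and their large-defocus widths deviate from the reference curve.
* Deeply interpenetrating footprints (center separation below ~0.7 of
  the radius sum) are reported as under-segmentation, not resolved.
* Rotation of the pipette and multi-object tracking are out of scope;
  the tracker assumes frame-to-frame displacements within its search
  margin.
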