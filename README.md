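# favf — autofocusing visual feedback for fluorescent rare-cell sorting

`favf` implements the visual side of an automated rare-cell sorting rig
under a fluorescence microscope — and the virtual microscope needed to
drive and validate it without hardware. It is aimed at researchers in
robotic micromanipulation and microscopy image analysis who need a
fully testable, deterministic reference implementation of:

* **SCC planar locating** — scalable correlation coefficient matching.
  The normalized correlation score of a mean-subtracted template `T'`
  against a mean-subtracted window `I'`,
  `R(x, y) = Σ T'·I' / (‖T'‖·‖I'‖)`, matched over a size/blur template
  pyramid so cells are found at any defocus ("rough"), then refined
  sub-pixel on the focused view ("precise").
* **Watershed instance segmentation** — overlapping detections trigger
  red-channel thresholding, Otsu binarization, morphological opening,
  distance-transform markers and marker-controlled watershed, yielding
  one center per touching cell.
* **MDFD depth detection** — multiple depth from defocus. A cell's
  blur diameter grows linearly with its distance from the focal plane,
  `D_n = D + s·p·|z|`; with the focused diameter `D` (from the fixed
  intersections of grey profiles taken at different planes) and two
  blur diameters a step `d` apart, depth follows from
  `d_n = (D_n − D)/(D_{n+1} − D_n) · d`. Three images and the trend of
  the profile contrast `c = max − min` resolve the front/back
  ambiguity; estimates beyond the 40 µm fluorescence-detectability
  range are reported out of range (OOR).
* **Neighborhood-search tip tracking** — correlation matching of the
  dyed pipette tip restricted to a search area of three times the
  template area, with drift-corrected template update.
* **A closed-loop virtual sorter** — detect → autofocus → precise
  locate → separate overlaps → tracked approach → aspirate, field by
  field over a dish, with purity and recovery computed against ground
  truth.

Everything runs on the package's own defocus imaging simulator
(energy-conserving Gaussian-PSF rendering with linear blur growth,
two-color 1:100 mixtures, touching clusters, a translating pipette),
so every claim is reproducible from a seed.

## Worked example

```r
library(favf)

optics <- optics_config()        # 0.25 um/px, blur slope 1 px/um, 40 um range

## a field with one target cell 10 um above focus
sc  <- scene(list(cell_spec(1, x = 25, y = 25, z = 10, focused_diameter = 12,
                            color = "red")),
             fov_width = 50, fov_height = 50, rng_seed = 1)
img <- render_scene(sc, focal_z = 0, optics)

## rough planar locating with the scalable template pyramid
tset <- build_scalable_templates(reference_template(optics))
rough <- rough_locate(image_channel(img, "red"), tset)
rough$detections[, c("center_x", "center_y", "score", "scale_index")]
#>   center_x center_y     score scale_index
#> 1    100.5    100.5 0.9588999           1
## (truth: 25 um / 0.25 um/px = pixel 100; matched at a defocused scale)

## depth by iterative MDFD
est <- mdfd_estimate(function(z) render_scene(sc, z, optics),
                     d = 6, optics = optics, start_z = 0)
c(depth = est$d_n, iterations = est$iterations, status = est$status)
#>              depth         iterations             status
#> "9.92130861989522"                "4"          "focused"

relative_error(abs(est$d_n), 10, est$D_um)
#> [1] 0.3592335
```

The printed numbers are what the code produces with these seeds: the
rough stage finds the defocused cell half a pixel from its true
position at a blurred pyramid scale, and the depth loop recovers the
10 µm defocus to 0.08 µm (0.36 % relative error).

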