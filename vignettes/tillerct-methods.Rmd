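---
title: "Methods: simulated micro-CT and RGB phenotyping of rice tillers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated micro-CT and RGB phenotyping of rice tillers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tillerct)
```

## The measurement problem

Tiller number, tiller cross-sectional size, and tiller angle are
yield-determining architecture traits in rice, but counting and measuring
tillers by hand is destructive and slow. A bimodal imaging chamber solves
this by combining a micro-CT unit — which reconstructs transverse sections
of the culm bundle a few centimetres above the soil — with a side-view RGB
camera for whole-shoot traits. `tillerct` implements the full analysis chain
of such an instrument *and* a synthetic plant simulator, so that every stage
can be validated by parameter recovery on phantoms with exactly known
geometry.

The chain is:

1. **Geometry** — the acquisition equations of the scanner (fields of view
   from the source–detector and source–center distances, the cone-beam
   footprint, the camera magnification).
2. **Phantom simulation** — virtual plants whose tillers are inclined
   circular cylinders (hollow annuli when the tiller has booted), plus
   leaf-blade clutter; analytic ground truth at every height.
3. **Projection and reconstruction** — parallel-beam line integrals of a
   slice at each rotation angle, and filtered back-projection (FBP) of the
   resulting sinogram over the limited ~228° scan.
4. **CT traits** — segmentation of culm sections, removal of artefacts and
   blades, and the per-slice trait catalogue (TN, TTA, CHA, THR, TCR,
   diameter / area statistics, effective tiller count).
5. **Tiller angle** — optimal matching of sections between two
   reconstruction heights and `atan(displacement / dz)`.
6. **RGB traits** — the 58 side-view traits: color and digital biomass,
   architecture profile, fractal dimension, histogram and co-occurrence
   texture.
7. **Growth statistics** — absolute/relative growth rates, six growth-model
   families with agreement metrics, tiller senescence and stepwise yield
   models.

## Acquisition geometry

With source-to-detector distance $D_{sd}$, source-to-rotation-center
distance $D_{sc}$ and detector extents $VL \times HL$, the cylindrical field
of view at the rotation center is

$$VL_{FOV} = VL \cdot D_{sc} / D_{sd}, \qquad HL_{FOV} = HL \cdot D_{sc} / D_{sd},$$

and a source with full cone angle $\gamma$ illuminates a footprint
$2 D_{sd} \tan(\gamma/2)$ at the detector. The default
`scanner_geometry()` (634 mm, 484 mm, 33°, 195 × 244 mm detector, 380
projections at 0.6°) reproduces the production instrument: a 149 × 186 mm
field of view, a 376 mm cone footprint, and a 228° total scan — a
*limited-angle* protocol, 48° short of a half-turn plus fan.

## The phantom and what it does (not) emulate

`sample_plant()` draws tiller bases uniformly in a circular crown
(default radius 18 mm), outer diameters in 4.5–7.5 mm and wall thicknesses
in 0.8–1.6 mm (typical of indica culms at tillering), inclinations uniform
in 0–30° from vertical, and a 0.7 probability that a tiller is fertile
(booted), rendered as a hollow annulus. Azimuths lean outward from the
crown center with ±45° jitter, as real tillers fan outward; together with
rejection sampling this guarantees that culm sections never overlap at the
soil surface or at the two analysis heights, so ground truth is unambiguous.
Leaf blades are elongated rectangles (length ≥ 10 × width) kept clear of
culm sections. Attenuation is relative only: wall 1.0, leaf 0.4, pith 0.05,
background 0.

The phantom deliberately omits beam hardening, scatter, detector blur,
touching culms, and curved culm axes. Passing recovery tests therefore
demonstrates that the *algorithmic* chain is unbiased at realistic geometry
and sampling — not that the device's physics corrections are reproduced.

## Projection and filtered back-projection

Projection is parallel-beam: the cone-beam magnification is absorbed into
the reconstructed pixel size, which is adequate because the trait
computations are geometry-independent and the downstream math never uses
ray divergence. `forward_project()` computes line integrals by bilinear
sampling (one sample per pixel step, in Rcpp); `fbp_reconstruct()` applies
the standard discrete Ram–Lak ramp (built from its spatial-domain kernel to
avoid DC bias, optional Hann apodization), back-projects with linear
interpolation, and normalizes by $\pi / (2\,n_{\text{angles}})$. Grid
conventions (floor-center, rotation sense) follow the widely used
scikit-image implementation, which the test suite uses as an independent
reference: on a 256² disk with 180° coverage the two reconstructions agree
to well under 0.1% normalized RMS.

The 228° scan is handled by plain FBP with the same normalization — no
iterative completion. The resulting low-level streaks are exactly what the
morphological cleanup removes. Negative reconstructed values are clipped to
zero before segmentation (attenuation is non-negative).

## Segmentation and the trait catalogue

`segment_tillers()` chains: global threshold (Otsu by default) → binary
opening with a disc of radius 1 px (erases 1-px streaks) → hole filling (a
hollow culm becomes one object, its cavity bookkept as a hole) →
8-connected labeling → removal of small particles and of components with
circularity $4\pi A / P^2$ below 0.3 (leaf blades are far below; culm
sections are ≈ 0.95) → a relative-attenuation gate that drops components
whose mean reconstructed intensity is below 70% of the brightest retained
section. The last step uses the physical contrast between dense culm wall
and thin leaf lamina (~2.5× in attenuation; measured section means cluster
at 0.90–1.04 for culms versus 0.40–0.56 for blade remnants), and removes
the occasional stubby blade segment whose shape alone is ambiguous.
Perimeter is the 8-connected contour chain length
(orthogonal steps 1, diagonal $\sqrt 2$); a plain boundary-crossing count
would give a digitized disk a circularity of ~0.62 and break the blade
gate, so the chain-length estimator is used and documented.

The *section area* of a region is its filled area (outer contour, cavity
included); wall and cavity areas are reported separately, and the wall
thickness is the difference of outer and cavity equivalent radii. This
makes TTA, THR, and the per-tiller area statistics mutually consistent (a
single hollow culm has THR ≈ 1). Convex-hull and circumcircle areas are
*counted in covered pixels* rather than taken as polygon areas, so
$TCR \le THR \le 1$ holds exactly by set inclusion; the circumcircle is the
exact minimum enclosing circle (Welzl's algorithm over hull vertices,
verified against a brute-force oracle). On an empty slice the ratio traits
are missing values, never zeros.

The pipeline-level default for the small-particle cutoff is physical:
6 mm², converted to pixels at the working resolution. The smallest
plausible culm section is ~16 mm² (a solid 4.5 mm culm), while the bright
remnants a thin leaf blade can leave after thresholding are ~3 mm², so the
cutoff separates the two populations by a wide margin on either side.
`seg_config()` itself defaults to a scale-agnostic 20 px for use on
arbitrary images.

## Tiller angle

Sections are matched between the two reconstruction heights by an optimal
one-to-one assignment (an $O(n^3)$ Hungarian solver, checked against
brute-force enumeration), gated by a maximum plausible displacement; the
angle from vertical is $\arctan(d / \Delta z)$ with
$\Delta z = 4.85\ \mathrm{mm}$ by default (50 detector rows at 0.097 mm,
the standard two-row protocol). Plant-level statistics are the mean,
maximum, and *population* standard deviation — the SD convention is fixed
to make results bit-reproducible. Unmatched sections are excluded from the
statistics rather than imputed.

## RGB traits

The side-view extractor fixes documented, conventional definitions for the
trait families whose original formulas live only in the instrument's
supplementary code:

* plant mask by excess-green ($2G - R - B$) thresholding;
* GPA via a hue window (70–170°) on plant pixels; GCV is the mean green
  channel on a 0–1 scale;
* F1–F20 are plant-pixel fractions in 20 equal-height bands of the bounding
  box (bottom = F1), PC1–PC6 the band-wise area / convex-hull-area ratios
  on 6 bands — both measured over the bounding box so they are
  scale-independent;
* fractal dimensions by dyadic box counting (FDNIC on the full frame, FDIC
  after cropping), clamped to the planar range [0, 2];
* histogram texture follows the Gonzalez–Woods conventions (smoothness and
  third moment on unit-normalized levels, entropy in bits);
* T1–T15 are Haralick statistics of the symmetric distance-1 co-occurrence
  matrix averaged over 4 directions at 32 gray levels, in a fixed documented
  order; gray conversion uses the 0.299/0.587/0.114 luminance weights.

All of these sit behind one extractor (`rgb_traits()`) so alternative
definitions can be swapped without touching the pipeline. Consistency, not
identity with the original binaries, is the design goal — downstream
association analyses need stable, reproducible trait definitions.

## Growth statistics

Growth rates use the classical plant-growth-analysis definitions: AGR is
the per-day difference, RGR the per-day log-difference, over the 3-day
sampling interval; CT trait columns are indexed i = 2..9 and RGB ones
i = 1..8, matching the trait-table naming convention. Agreement metrics are
MAPE (undefined when a reference value is zero — an error, not a silent
zero), RMSE, and the population SD of absolute percentage errors.

Six model families are fitted per trajectory: linear, power, exponential,
logarithmic, quadratic, and logistic $K/(1 + a e^{-bt})$. Linear-in-
parameters families are closed-form least squares; the rest are
log-linearized for starting values and refined by Levenberg–Marquardt. Time
point $i$ is mapped to $i \times \mathrm{interval}$ days so the power and
logarithmic families (which need $t > 0$) stay admissible. A
non-convergent refinement returns the log-linearized fit flagged
`converged = FALSE` rather than failing.

One numerical caveat is tested explicitly: at 1% noise the logistic shape
parameter $a$ is exponentially sensitive, and *no* correct estimator can
pin it to 5% from nine samples; the low-noise recovery property is
therefore checked on a densely sampled sigmoid (n = 200), where the bound
is attainable, while noiseless nine-point recovery is required to 1%.

Stepwise yield modeling is forward selection with partial-F entry at
p < 0.05 and removal at p > 0.10 (the common SPSS defaults), reporting
predictors in entry order with both R and R². Type-I behaviour is verified
by simulation (pure-noise responses select nothing in ≥ 90% of runs).

Tiller senescence is $(TN_9 - TN_{\mathrm{effective}})/TN_9$, with the
effective count taken from hollow-pith (booted) sections; a negative value
(effective exceeding late-stage count) is allowed but flagged.

## Study sizes and reproducibility

The validation protocol mirrors the fixed-pipe repeatability design of the
physical instrument: 50 seeded phantoms with 3–15 tillers, simulated at the
full 380 × 0.6° protocol on a 544² grid at 0.2 mm/px (a 108.8 mm field that
contains the worst-case 53.5 mm reach of a 30°-inclined edge tiller at
55 mm height). Reconstruction fidelity is checked on a 256² disk at 180°;
trait-algebra invariants on 1 000 random masks; texture oracles on ≤ 8×8
images by exhaustive pair counting. These sizes were chosen so the whole
suite runs comfortably on a single CPU while keeping every bound
statistically meaningful.

Every stochastic step is seeded (`with_seed` restores global RNG state),
configs serialize to YAML with an md5 hash, and identical config + seed
yields byte-identical trait CSVs — asserted at byte level in the tests.

## Known limitations

* Parallel-beam simulation: cone-beam effects (magnification gradients
  along the axis, FDK weighting) are out of scope.
* Circular cross-sections: at 30° inclination the true section is an
  ellipse with ~7% eccentricity error; the round-section approximation
  follows the instrument's own pipe-phantom validation.
* Two-point angle estimation assumes straight culm axes between the two
  heights.
* The RGB renderer produces sparse, non-overlapping canopies; occlusion-
  induced biases of real canopies are not modelled.
* Trait definitions for PC/F/T families are conventional reconstructions,
  not the instrument's original binaries.
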