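# tillerct

Micro-CT + RGB phenotyping of rice tillers, with a built-in phantom
simulator for end-to-end validation.

Tiller number, tiller cross-sectional area, and tiller angle drive rice
yield and plantable density, but measuring them by hand is destructive.
A bimodal imaging chamber measures them in vivo: a micro-CT unit
reconstructs transverse sections of the culm bundle ~50–55 mm above the
soil, and a side-view RGB camera captures whole-shoot traits. `tillerct`
implements the complete analysis chain of such an instrument in R — and,
because real scans come with no ground truth, a synthetic plant generator
whose tillers are inclined annular cylinders with exactly known positions,
diameters, wall thicknesses, and angles, so every stage can be validated by
parameter recovery.

**What the package computes**

* **Acquisition geometry** — fields of view and cone footprint from the
  scanner distances: `VL_FOV = VL · D_sc / D_sd`,
  `PD = 2 D_sd tan(γ/2)`; camera FOV from thin-lens magnification.
* **Simulation** — `sample_plant()` phantoms, `rasterize_slice()` ground-
  truth sections, `forward_project()` parallel-beam sinograms over the
  228° limited-angle protocol (380 × 0.6°).
* **Reconstruction** — `fbp_reconstruct()`: Ram–Lak ramp filter (optional
  Hann), linear-interpolation back-projection, π/(2·n_angles)
  normalization; agrees with an independent inverse-Radon reference to
  well under 0.1% NRMS on full-coverage phantoms.
* **CT traits** — Otsu threshold, morphological opening, hole filling,
  8-connected labeling, small-particle, irregular-shape (circularity) and
  relative-attenuation filters; per-slice trait record: TN, TTA, CHA,
  THR = TTA/CHA,
  TCR = TTA/circumcircle area (exact minimum enclosing circle), diameter /
  area-perimeter / area statistics, and the effective (hollow-pith, i.e.
  booted) tiller count.
* **Tiller angle** — optimal (Hungarian) matching of sections between two
  reconstruction heights, `angle = atan(displacement / dz)` from vertical,
  and MEANTA / MAXTA / SDTA.
* **RGB traits** — the 58 side-view traits: GCV, GPA, TPA, GPAR; W, H,
  HWR, TBR, PAR; band profiles F1–F20 and band compactness PC1–PC6;
  box-counting fractal dimensions FDNIC/FDIC; 6 histogram-texture and 15
  Haralick co-occurrence statistics.
* **Growth statistics** — AGR/RGR per 3-day interval; six growth families
  (linear, power, exponential, logarithmic, quadratic, logistic
  `K/(1+a·e^{−bt})`) with R², MAPE, RMSE, SD_APE; tiller senescence
  `(TN_9 − TN_effective)/TN_9`; forward stepwise yield regression
  (enter p < 0.05, remove p > 0.10).

## Worked example

```r
library(tillerct)

scanner_geometry()
#> Scanner geometry
#>   D_sd = 634 mm, D_sc = 484 mm, cone angle = 33 deg
#>   detector VL x HL = 195 x 244 mm
#>   FOV  VL x HL = 148.9 x 186.3 mm
#>   380 projections, step 0.6 deg (total 228 deg), pixel 0.097 mm

# simulate a 5-tiller plant and run the whole chain on its bundle
cfg <- run_config(seed = 3, image_size = 256, n_projections = 120,
                  angle_step = 1.9, analysis_heights = c(20, 25),
                  phantom = list(n_tillers = 5,
                                 inclination_range = c(0, 15),
                                 check_heights = c(0, 20, 25)))
simulate_bundle(cfg, "demo_bundle")
traits <- extract_traits("demo_bundle", plant_id = "demo")
round(unlist(traits[c("TN", "TTA", "MEANTD", "MEANTA", "MAXTA",
                      "THR", "TCR", "EFFTN")]), 3)
#>      TN     TTA  MEANTD  MEANTA   MAXTA     THR     TCR   EFFTN
#>   5.000 156.920   6.262   6.768  13.602   0.267   0.100   3.000
```

All five tillers are found; the mean recovered inclination (6.77°) sits
0.09° from the phantom's true mean (6.68°), and three sections show the
pith cavity that marks a booted (effective) tiller — matching the generated
truth. `TTA` is in mm², diameters in mm, angles in degrees from vertical.

Growth modeling on a trait trajectory:

```r
t <- 3 * (1:9)                       # nine time points, every 3 days
y <- 100 / (1 + 20 * exp(-0.13 * t)) # logistic tiller-area growth
fit_growth_model(t, y, "logistic")
#> Growth fit (logistic)
#>      K      a      b
#> 100.00  20.00   0.13
#> R^2 = 1.0000, MAPE = 0.000%, RMSE = 4.746e-15, SD_APE = 0.000%
```

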