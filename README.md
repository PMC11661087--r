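# axoncaliber

Quantification of axon caliber from membrane-labeled fluorescence
microscopy, for researchers studying neurite morphology in vivo —
e.g. zebrafish Rohon-Beard sensory neurons imaged by Airyscan confocal
time lapse.

A membrane label (such as EGFP-CAAX) marks only the plasma membrane, so
an axon seen in a single optical plane shows two bright boundary lines
with a dark lumen. The package scores **caliber** the way it is measured
at the bench: an intensity profile is extracted along a line
perpendicular to the axon's center axis, and caliber is the distance
between the two membrane intensity peaks. Everything downstream builds
on that primitive:

- **Branch architecture** — at a branch point, each segment's caliber is
  the mean of measurements 3, 4 and 5 µm from the branch point. With P
  the primary segment and S1 ≥ S2 the secondary branches, the package
  reports symmetry S2/S1, normalized calibers S1/P and S2/P, and the
  cross-sectional-area taper ratio
  (area<sub>S1</sub> + area<sub>S2</sub>) / area<sub>P</sub>
  = (S1/P)² + (S2/P)², with area = π (caliber/2)².
- **Caliber dynamics** — caliber tracked at fixed locations across a
  time lapse (5-minute frames): absolute dynamicity SD, relative
  dynamicity %RSD = (SD / mean caliber) × 100, fold range, and
  regressions of both against mean caliber; paired day-1 vs day-2
  comparisons.
- **Pearling** — lengthwise thick/thin variation, quantified as the
  sample SD of calibers measured at 1-µm increments.
- **Dividing-cell geometry** — for axons crossing a dividing basal
  epithelial cell: round/flat frame selection from border-to-border
  lengths (the consecutive pair with the largest length increase),
  region comparisons (dividing vs neighbor cells, Mann-Whitney),
  paired round-vs-flat caliber drops, and a circular-arc path model:
  with chord c and sagitta h, R = (c² + 4h²)/(8h) and
  arc = 2R·asin(c/(2R)), compared to the flat chord ℓ.
- **Statistics** — a paired permutation test (sign flips on pair
  differences, exhaustive up to n = 20, Monte Carlo beyond) and a
  rank-sum test with exact small-sample enumeration, both implemented
  from first principles and checked against enumeration oracles.
- **Synthetic scenes** — a generator renders membrane tubes, branched
  arbors, scripted dynamics (traveling pearl, focal inflation/deflation,
  segment widening/narrowing, constriction point) and division
  scenarios with exact ground truth (0.04 µm pixels, 0.14 µm PSF FWHM,
  Poisson + read noise), so every measurement can be validated against
  known geometry.

## Worked example

Render a pearled axon (base diameter 0.30 µm, one 0.16 µm-amplitude
pearl at s = 4 µm) with realistic noise and measure it at 1-µm
increments:

```r
library(axoncaliber)
prof  <- pearled_radius_profile(0.15,
           data.frame(center = 4, amplitude = 0.08, width = 0.8),
           length_um = 10)
truth <- straight_axon_truth(10, profile = prof, origin = c(2, 4))
frame <- render_membrane_frame(truth, scene_config(seed = 42,
                                                   image_shape = c(200, 350)))
m <- measure_along_segment(frame, truth$segments$seg1, positions = 1:9)
m$caliber
#> 0.283 0.308 0.358 0.470 0.370 0.309 0.315 0.300 0.307
true_caliber(truth, "seg1", 1:9)
#> 0.300 0.307 0.373 0.460 0.373 0.307 0.300 0.300 0.300
pearling(m$caliber)
#> 0.0575
```

The measured profile recovers the pearl (0.47 µm at its center vs 0.46
µm true) within a few hundredths of a micrometer despite shot noise;
`pearling()` summarizes the lengthwise variation (0.058 µm SD).

Branch statistics on segment mean calibers:

```r
rec <- assign_branch_roles(0.43, c(a = 0.32, b = 0.20))
rec$symmetry                 # 0.625
tp <- taper_ratios(rec)
c(tp$area_ratio, tp$ratio_S1, tp$ratio_S2)
#> 0.770 0.744 0.465
```

An area ratio below 1 means the arbor tapers in cross-sectional area
across the branch point. A paired permutation test on %RSD values that
all drop between two sessions gives the smallest attainable two-sided
exact p:

```r
paired_permutation_test(c(28,30,25,33,27,31,29,35,26,30,32),
                        c(22,25,21,28,20,26,24,29,23,25,26))
#> paired permutation (sign flip): statistic = 5.182, p = 0.0009766 (exact)
```

## Command line

`inst/cli/axoncaliber.R` wraps the pipeline as subcommands:

```sh
Rscript inst/cli/axoncaliber.R simulate config=scene.yml out=outdir
Rscript inst/cli/axoncaliber.R measure image=outdir/scene.tif out=m.csv
Rscript inst/cli/axoncaliber.R dynamics measurements=m.csv out=dyn.json
```

Scenes are written as 16-bit multi-frame TIFF plus a JSON sidecar
carrying the full ground truth, config echo, hash and seed. Measurement
CSVs use the schema `frame_time_min, segment_id, arc_pos_um,
caliber_um, flag_below_resolution, flag_single_peak, flag_ambiguous`,
with provenance in leading `#` comment lines. All interfaces are in µm;
pixels never cross a module boundary.

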