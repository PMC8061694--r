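---
title: "Quantifying ectopic division, DNA content and divisome dynamics in Streptomyces: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sporometry methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporometry)
```

## The measurement problem

When sporulation-specific cell division goes wrong in *Streptomyces* —
for instance through substitutions in the FtsZ-recruiting protein SsgB —
septa can be laid down at ectopic angles, from diagonal all the way to
longitudinal (parallel to the hyphal wall), and spores can end up severed
in two, with aberrant DNA contents and reduced viability. Quantifying
these phenotypes from micrographs requires a handful of image
measurements that are individually simple but easy to get subtly wrong:
focus-aware spore segmentation, angle measurement against a local
reference axis, per-chain normalization of fluorescence, two-channel
ratio classification, grey-level time series from scanner stacks, and
exponential fits of bleach-recovery curves.

sporometry implements each of these as a small, tested operator, plus a
seeded synthetic-microscopy generator that renders scenes with known
ground truth. None of the original micrographs are machine-readable, so
the package's validation strategy is **parameter recovery**: plant the
published rates and contents in synthetic scenes, run the full pipeline,
and require that it reads them back within the sampling error of the
planted sample size.

## Coordinate and unit conventions

All physical quantities are micrometres; a `pixel_grid` couples a numeric
matrix with a scalar `pixel_size` (um/px). The physical origin is the
centre of the top-left pixel; rows increase downwards, columns to the
right; angles are measured from the image x-axis towards the y-axis,
modulo 180 degrees. Everything downstream is relative (septum versus
local axis), so handedness never matters.

## Spore segmentation

`detect_spores()` reproduces a classic particle-analysis macro as a
composition of six operators:

1. **Upscaling** (`upscale_image`): twenty consecutive 5% bilinear
   enlargements, rounding the pixel dimensions to integers at every step
   (cumulative linear factor 1.05^20 ≈ 2.653). Because row and column
   factors can differ by a fraction of a pixel after rounding, the single
   scalar pixel size is chosen to preserve the total imaged *area*
   exactly; the 0.65 um² size filter therefore stays calibration-exact.
2. **Edge detection** (`find_edges`): 3×3 Sobel gradient magnitude with
   replicate border handling (an ideal step of height *h* responds 4*h*
   on the adjacent pixels; a flat border responds 0).
3. **Auto-thresholding** (`auto_threshold`): iterative intermeans
   (IsoData), `t <- (mean(x <= t) + mean(x > t))/2` from the global mean
   to a fixed point, mask strictly above *t*. The recursion runs on the
   raw values rather than a 256-bin histogram, which makes it exactly
   shift-equivariant.
4. **Hole filling** (`fill_holes`): background components (4-connected,
   the topological dual of the 8-connected foreground) not touching the
   raster border become foreground; cavities open to the border stay
   open. The filled edge map is the "in focus" mask: sharp objects have
   closed gradient rings that fill into discs, defocused objects do not
   cross the gradient threshold at all.
5. **AND combination** (`combine_focus`): a pixel survives only if it is
   both inside the focus mask and above the intensity threshold of the
   (upscaled) original.
6. **Particle analysis** (`analyze_particles`): 8-connected components;
   area = pixel count × pixel_size²; best-fit ellipse from second moments
   (with the 1/12 px² grid-variance correction); roundness
   = 4·area/(π·major²), which is minor/major for an ellipse and 1 for a
   disc. The filter keeps area ≥ 0.65 um² and roundness in [0.75, 1];
   everything is returned, non-conformant components flagged.

Two deliberate interpretations, both configurable: "default threshold"
means iterative intermeans (the documented default of the macro's
original platform — the method name is not stated in the protocol), and
"roundness" means the axis-ratio definition above rather than the
perimeter-based circularity 4π·area/perimeter², which is also available
(`shape_measure = "circularity"`) but uses a cruder boundary-length
estimate. Thresholding is computed on the whole image, not per tile.

The focus mask is a *strong-defocus* rejector: with the generator's
out-of-focus blur at 4× the point-spread sigma, rejection is reliable for
PSF sigma around 0.1 um (a fluorescence-like focal depth, defocus sigma
0.4 um) and not for very sharp TEM-like scenes (sigma 0.025 um), where
even "defocused" objects still carry strong edges. The recovery tests
exercise the former regime.

## Septum rotation measurement

The canonical division plane is perpendicular to the local hyphal axis;
the rotation angle of a septum is the unsigned angle between its plane
and that canonical plane, folded into [0, 90]: 0 = transverse,
90 = longitudinal. Since the original study counted septa on micrographs
without a stated angular protocol, the axis-relative definition here is
an explicit convention; it is validated only against synthetic truth.

* `estimate_chain_axis()` thins the chain mask to a skeleton
  (Zhang–Suen), orders it into a polyline, and assigns each vertex the
  principal-axis orientation of the skeleton points inside a sliding
  window (default radius 1.25 um ≈ one spore). Windowed PCA keeps the
  orientation stable on beads-on-a-string masks where the raw skeleton
  wiggles.
* `detect_septa()` finds septa as dark ridges: the spore mask is dilated
  (default 0.25 um) and hole-filled into a chain footprint; pixels inside
  the footprint darker than `dark_threshold` (default half the median
  intensity outside the footprint) are grouped 8-connected, small groups
  (< 5 px) discarded as noise, and each candidate is measured by
  darkness-weighted second moments. Its rotation angle is taken against
  the axis orientation at the nearest polyline vertex.
* `classify_septum_angle()` applies the class thresholds: canonical
  < 10 deg, longitudinal ≥ 85 deg, diagonal in between. The 10 deg
  boundary is the lower end of the reported rotation range; 90 deg is the
  reported longitudinal angle, and 85 deg leaves a tolerance band around
  it since no explicit class boundary was published. Both thresholds are
  arguments.
* Split spores (`count_split_spores()`) are counted by connectivity: a
  spore is split when the thresholded mask inside its planted footprint
  falls apart into ≥ 2 components of ≥ 5 px — the image signature of
  completed fission along an ectopic plane.

`intensity_profile()` supplies the cross-hypha box profile used to
distinguish wall-associated divisome foci (two peaks whose separation
estimates the hyphal width) from mid-hyphal localisation (a single
central peak): mean intensity along the box width at each cross-hypha
position, bilinearly interpolated, with local-maximum peaks above a
prominence floor (default 10% of the profile's dynamic range).

## DNA quantification

`background_correct()` zeroes everything outside the hyphae mask;
`integrate_per_spore()` sums the stain channel over each detected
particle, resampling the particle label raster to the fluorescence grid
by physical position when detection ran on the upscaled image;
`median_normalize()` divides each chain by its median so the chain
median is exactly 1 (even-length median = mean of the central pair —
the conventional definition; the source protocol does not specify).
Chains shorter than 10 spores carry too little data to normalize and are
excluded, matching the published inclusion rule. Median scaling makes the
result invariant to any positive per-chain gain, which is precisely what
justifies pooling chains across staining variation. Contents are
reported in median-relative units; mapping the median to "1 chromosome"
is a biological calibration left to the user.

For synthetic scenes, chains come from ground truth via nearest-centroid
matching; for real images a user-supplied chain column is preferred, and
`assign_chains_heuristic()` (single-linkage on centroid distance, cutoff
1.6 median major-axis lengths) is provided as an explicitly heuristic
fallback.

## Viability, colony phenotype, FRAP

* `classify_viability()`: dead ⇔ red integral > r × green integral
  (default r = 1, ties live so the rule is deterministic). The decision
  rule in the original study was visual; the ratio rule is an explicit,
  scale-invariant convention with r configurable. No spectral cross-talk
  correction is attempted.
* `classify_phenotype()`: sporulating colonies accumulate the grey spore
  pigment and *darken*, so the darkening statistic is initial − final
  grey value (endpoint difference; a time-integrated variant is a flag
  away since the original statistic is unstated). Class grey when
  darkening ≥ t_hi, white when ≤ t_lo (defaults 65 and 20 grey levels,
  calibrated on the generator's built-in trajectories), light-grey
  between; classification is monotone in the darkening.
* `fit_recovery()`: least-squares fit of I(t) = P − (P − B)·exp(−t/τ) by
  Levenberg–Marquardt on the residual interface (the formula-based
  fitters reject noiseless traces, which must fit exactly).
  Initialisation: B = first sample, P = mean of the last 10%, τ by linear
  interpolation to the 1 − 1/e crossing; convergence tolerance 1e-8 on
  the parameters. "Recovery time" is reported as τ·ln 20 (time to 95% of
  the recoverable signal) with the half-time τ·ln 2 alongside, because
  published "recovery times" may be either; the generator and the fitter
  share one definition so recovery experiments are internally consistent.
  A trace with no average increase raises a fit-failure error rather than
  returning a silent result. No immobile fraction is modelled by default
  (single mobile population), and no 2-D diffusion model is attempted.

## The synthetic generator: what it emulates and what it does not

`make_spore_chain_scene()` renders chains of ellipsoidal spores along a
hyphal axis with septa planted at the inter-spore boundaries. Study
conditions are the generator defaults, chosen once:

| parameter | default | why |
|---|---|---|
| pixel size | 0.05 um/px | TEM-like sampling; ~18 px across a spore |
| spore axes | 1.1 ± 0.05 × 0.9 ± 0.04 um | typical spore dimensions; axis ratio ~0.82 sits inside the 0.75–1 roundness filter |
| inter-spore gap | 0.35 um | separates spores into distinct particles with room for a septum |
| septum width | 0.2 um | must exceed the PSF so the dark line core survives rendering at any subpixel phase (≥ 3 fully covered pixel rows); thin 2-px septa fragment inside bright spores |
| canonical angles | uniform [0, 5] deg | unambiguous separation from the 10 deg class boundary |
| rotated angles | uniform in `rotated_angle_range`; longitudinal exactly 90 deg | planted counterparts of the published 10–90 deg range |
| PSF sigma | 0.025 um (out-of-focus: ×4) | TEM-like sharpness; fluorescence-like tests set 0.1 um |
| TEM levels | background 30, spore 200, septum 0 | 8-bit-like contrast |
| noise | additive Gaussian sd 2 (Poisson optional) | both common in microscopy; TEM noise characteristics were not published, so this is a free parameter |
| DNA gain | 500 a.u. per chromosome-equivalent | arbitrary positive gain; density = amount/area so the *integral* is content × gain for any spore size |

Split spores are rendered as two lengthwise halves separated by a
0.15 um wall-level gap (fission complete, the septum has become wall),
so they register in the mask exactly the way the split counter looks for
them. Geometry is drawn in micrometres before rasterisation, which makes
the planted truth independent of pixel size (the scale-consistency
property tested in the suite). One global seed expands into per-stage
substreams by hashing the stage name (`stage_seed()`), so adding a stage
never perturbs earlier streams, and identical spec + seed reproduces
scenes bit for bit.

The generator does **not** emulate: 3-D structure (everything is a 2-D
projection), FtsZ/divisome dynamics, spore maturation or wall thickness
variation, spectral cross-talk between channels, spatially varying
illumination, or TEM artefacts such as staining gradients and knife
marks. Passing recovery tests therefore demonstrates that the *operators*
are correct and unbiased under the stated image model — not that the
pipeline is robust to every artefact of real micrographs. The septum
detector in particular is validated only against synthetic truth; on real
TEM images septa were counted manually in the original study.

## Problem sizes and numerical choices

The recovery experiments run at the published sample sizes: 1479 septa
(87 chains × 17) for the rotated fraction, 336 rotated septa for the
longitudinal fraction, 2000 spores for split counting, 3000 septa for the
sparse (1.7%) scenario, and ≥ 1011 spores for the zero-rotation
false-positive control; FRAP experiments use 100 traces of 151 samples.
At these sizes the binomial sampling error dominates the pipeline's
measurement error (septum angle MAE ≈ 2 deg, zero class confusion between
planted canonical and longitudinal at the default separation). DNA
recovery uses noiseless 10-spore chains with the planted wild-type-like
(0.83–1.15) and mutant-like (0.4–3.0) content vectors; the residual ~1%
bias comes from PSF bleed between neighbouring spores and sits well
inside the 5% acceptance band.

Tie-breaks and degenerate inputs are fixed and tested: intermeans on a
constant image is an error (degenerate input), viability ties classify
live, empty tallies report `NA` percentages rather than dividing by zero,
zero-length septum segments and non-recovering FRAP traces raise errors
naming the condition.

## Reproducing the headline numbers

`scripts/acceptance.R --seed N --out results/acceptance.json` regenerates
every scenario above from scratch with seed-derived substreams and writes
the measured quantities (percent rotated, percent longitudinal of
rotated, percent split, sparse percent rotated, mean fitted recovery
times at 60 s and 42 s, the per-chain median invariant, and the two
maximum normalized DNA contents) as JSON. The testthat suite runs the
same experiments as assertions, alongside the exact operator oracles
(Sobel step response, intermeans fixed point, shape factors, upscaling
factor, hole-filling border convention, particle filter bounds).

```{r, eval = FALSE}
# a compact end-to-end example
res <- run_scene_analysis(list(
  scene = list(n_chains = 6, spores_per_chain = 15,
               septum_rotation_prob = 336 / 1479),
  seed = 1))
res$summary$pct_rotated
```

## Known limitations

* Septum detection assumes dark septa on bright spores inside a
  connectable chain footprint; detached septum fragments or overlapping
  chains will confuse the chain assignment.
* The angle reference degrades near chain ends and sharp bends, where the
  windowed PCA mixes the two arms (tested to stay within 10 deg on an
  L-shaped mask with a reduced window).
* Circularity (as opposed to roundness) uses a boundary-pixel perimeter
  estimate that is biased for very small particles; roundness is the
  default for exactly this reason.
* Absolute chromosome numbers are out of scope; all DNA contents are
  median-relative.
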