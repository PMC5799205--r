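---
title: "Digital counting with microwell arrays: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital counting with microwell arrays: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wellcount)
```

## The counting model

wellcount implements digital (limiting-dilution) counting: a particle or
cell suspension is partitioned into thousands of micrometer-scale wells, a
micrograph of each panel is classified into occupied and empty wells, and
the number density is recovered from the *fraction* of occupied wells
rather than from counting individual objects. Under random loading the
number of particles in a well of volume $V$ (uL) at number density $c$
(particles/uL) is Poisson with mean $\lambda = cV$, so

$$\Pr(\text{occupied}) \;=\; p \;=\; 1 - e^{-\lambda},$$

and, inverting with the observed occupied fraction $\hat p = k/n$,

$$\hat\lambda = -\ln(1 - \hat p), \qquad \hat c = \hat\lambda / V.$$

Two properties follow. First, the estimator needs no knowledge of how many
particles sit in any well — a well with an aggregate counts once, exactly
like a singlet, which is what makes the approach robust to irregular
samples. Second, $\lambda$ is identifiable only while some wells remain
empty: at $k = n$ the transform diverges and `estimate_density()` raises a
saturation error carrying the one-sided lower density bound instead of a
point estimate.

### Confidence intervals

$k$ is binomial in $n$, so interval estimation happens on $p$ and is mapped
through the monotone transform $-\ln(1-p)/V$, which preserves coverage. The
default interval is the Wilson score interval, which behaves correctly near
$k = 0$ and $k = n$; Clopper–Pearson is available via `ci_method`. The
choice of interval for $p$ is this package's own (the estimator's sampling
distribution admits several constructions); tests verify both against their
standard single-proportion implementations and verify empirical coverage
$\ge 93\%$ at a nominal 95% over $\lambda \in \{0.05, 0.5, 1, 3\}$.

The design figure of merit, `ci_percent_of_mean()`, is the CI *half*-width
as a percentage of the estimated density,
$100\,(\mathrm{hi}-\mathrm{lo})/(2\hat c)$. "CI as a percentage of the
mean" admits either the half- or full-width reading; the half-width
definition is used consistently here and stated prominently because curves
produced with the other convention differ by a factor of 2.

## The default device

The default `array_geometry()` describes a 14,400-well device: sixteen
panels, each a 30 × 30 square array of circular wells 20 um in diameter
and 25 um deep (900 wells per panel). Published descriptions of this
device geometry draw a chip with a 6 × 6 grid of panel positions, which
would hold 32,400 wells — yet every device-level quantity they state
(14,400 wells, a 0.18 uL total well volume) corresponds to sixteen
900-well panels. The default follows the stated quantities; `panels` is
an ordinary parameter, so devices with any panel count are supported and
`wells_per_device = rows * cols * panels` always holds exactly. Two
further parameters of the physical device are not derivable from its
description and are package choices:

* **pitch** (center-to-center spacing within a panel): 40 um — wells
  separated by one well diameter, a typical microfabrication layout. It
  only affects the synthetic images and the pixel-domain geometry, not the
  statistics.
* **pixel_scale**: 2 um/px, giving a 10 px well diameter and ~620 px panel
  images — enough for reliable circle detection at modest cost.

The per-well volume defaults to the cylinder volume
$\pi r^2 h = \pi\,10^2\,25\ \mu m^3 = 7.854\times10^{-6}$ uL. Published
descriptions of this device geometry quote $1.257\times10^{-5}$ uL per
well (and a 0.18 uL device total), which equals $\pi\,20^2\,10\ \mu m^3$
rather than the cylinder volume of the stated dimensions. Both values are
supported: the geometry computes the cylindrical volume by default, and the
config key `well_volume_ul` overrides it explicitly when reproducing
arithmetic based on the quoted value. The package does not guess which is
"right"; density estimates scale inversely with whichever volume is used.

## The synthetic image generator

Because the pipeline's accuracy can only be judged against known truth,
the generator is first-class, tested code. `seed_particles()` draws
per-well particle counts; `render_panel()` draws the micrograph.

* **Loading.** With `aggregation = 0`, counts are i.i.d. Poisson(\(\lambda\))
  (chi-square goodness-of-fit is tested at $n = 14{,}400$ for
  $\lambda \in \{0.1, 0.7, 2\}$). With `aggregation` $= a > 0$, particles
  arrive in clumps: clumps per well are Poisson with mean $\lambda(1-a)$
  and clump sizes are geometric with mean $1/(1-a)$, conserving the
  expected particle count while depressing occupancy below $1-e^{-\lambda}$.
  This is the simplest mechanism that reproduces the under-counting of
  aggregating samples at high density; it is a modelling choice, not a
  fitted aggregation model.
* **Rendering.** Bright-field: bright background (0.85), darker well fluid
  (0.75), dark rim annuli (0.35), dark particles (0.12). Fluorescence: dark
  background (0.05), faint rims (0.22), bright particles (0.85). The
  constants are package defaults (real acquisition adjusts illumination per
  device) and are overridable via `contrast`. Particles sit at random
  sub-well positions with the offset capped so at least about half of each
  particle stays inside the sampled interior — a lone rim-hugging particle
  still moves its well's mean intensity.
* **Noise.** Additive Gaussian noise (sigma 0.02 by default) and a linear
  illumination gradient (5% tilt) are applied last; intensities are clipped
  to [0, 1]. Everything is bit-reproducible given the seeds.
* **Not modelled:** point-spread functions, depth effects, motion blur,
  vignetting beyond the linear tilt, sensor fixed-pattern noise. Passing
  tests therefore demonstrate correctness of the algorithmic chain under a
  controlled image model, not performance on any particular microscope.

## Well detection

`denoise()` is a plain kernel average (box mean, default 3 × 3, reflected
edges) — the smallest kernel that suppresses pixel noise without eroding
10 px wells.

`find_wells()` is a circular Hough transform restricted to radii within
1 um of the nominal well radius. Gradient-magnitude edge pixels (central
differences, threshold 0.08 intensity units) vote for centers one radius
away; the accumulator is normalised by ring perimeter so a fully edged rim
scores about 1. Restricting the radius band is what rejects particles,
aggregates and structured boundaries, none of which present a rim-sized
circle. Several numerical details matter:

* Arcs of two facing rims vote weakly at the mid-point between wells,
  exactly half a pitch from both true centers. Peak merging therefore uses
  an exclusion radius of 0.7 × pitch — above pitch/2, below the pitch — so
  these ghosts collapse onto the stronger true peaks and no two returned
  centers are closer than half a pitch.
* Each surviving peak is validated against the image: edge pixels in the
  radius band whose gradients point radially (in either polarity — the
  fluid side of a rim and a particle pressed against it face opposite
  ways) must cover at least 8 of 12 angular sectors. Arcs of wrong-sized
  or neighbouring circles fail this and are discarded.
* The sub-pixel center comes from a fixed-radius Gauss–Newton circle fit
  on the rim's inner transition, selected by gradient polarity (inward in
  bright-field, outward in fluorescence) and by gradient magnitude (the
  weak pixel-phase-dependent skirt of a thick thresholded edge, and the
  much stronger particle boundaries, are both excluded). The radius is
  re-estimated jointly but clamped to the Hough band.
* Wells whose rims are largely occluded by several particles can still
  shift a raw detection by a few pixels; the lattice fit below reduces
  the error of every *fitted* center to well under a pixel, which is what
  the downstream analysis uses.

`fit_grid()` reconstructs the full lattice from whatever subset of wells
was detected. Centers are clustered into rows and columns with a gap
threshold of half a pitch (median coordinate per cluster), clusters are
mapped to integer lattice indices through the nominal pitch, and an affine
lattice model ($x$ and $y$ each linear in row and column index) is fitted
by least squares. The affine form absorbs small rotation and shear in one
pass, rather than fitting axis-aligned first and estimating rotation only
on failure; the result is the same where images are near-axis-aligned and
strictly more robust otherwise. Every well receives a fitted center whether
or not it was detected — occupancy can never change the number of analysed
wells, which is the core robustness property of counting wells instead of
particles. Fits whose RMS residual exceeds a quarter pitch, or whose
fitted pitch deviates more than 25% from nominal, are rejected as "not one
consistent lattice".

## Classification

`well_intensities()` averages pixels inside a disk of 0.8 × the fitted
radius at each fitted center; the shrunken disk excludes rim pixels, which
are dark in bright-field and would bias empty-well means.

`auto_threshold()` separates the two histogram peaks. Early versions used
the minimum of a kernel density estimate between the two largest modes;
that rule fails in both tails of the operating range — at high occupancy,
multi-particle wells fragment the occupied mass into sub-modes that can
both out-rank the empty-well peak, and inside a genuinely empty valley the
KDE minimum is a numerical tie decided by grid order. The implemented rule
works directly on the sorted intensities: grow the empty-well cluster from
the extreme value on the empty side (brightest in bright-field, darkest in
fluorescence) and split at the first gap exceeding
$\max(0.5 \times \text{span so far},\ 5 \times \text{local median spacing},\ 10^{-3})$.
The threshold is the midpoint of that gap. If no qualifying gap exists the
distribution carries no evidence of occupancy and a sentinel threshold
classifies every well as empty — so an empty device reports a density of
exactly 0 rather than a noise floor. Ties at the threshold classify as
unoccupied, the conservative direction for density.

Thresholding is per device by default (all panels pooled into one
histogram), matching how a single stained sample is imaged across panels;
`pool = "panel"` thresholds each panel separately for samples with
panel-to-panel intensity drift. A manual `threshold` bypasses the automatic
rule entirely.

## Design-space simulators

`ci_vs_well_count()` evaluates counting precision against the number of
wells, analytically (expected count $k = np$ plugged into the estimator) or
by Monte Carlo (mean CI% over binomial draws); precision scales as
$1/\sqrt n$ — quadrupling from 900 to 14,400 wells halves the CI% twice
over. The two methods are strictly speaking different estimands — the
value at the expected count versus the expectation of the value — and
differ by a Jensen curvature term of order $1/n$; over the device-relevant
range ($n \ge 900$) that term is far inside the Monte-Carlo error, which
is where the self-consistency check is run. `density_vs_volume()`
is the exact closed form $-\ln(1-f)/V$: each fixed-$f$ curve is a line of
slope $-1$ in log–log axes, spanning $10^6$ particles/uL for femtoliter
wells down to tens per uL for nanoliter wells. `end_to_end_recovery()`
composes generator and pipeline so bias, coverage and the aggregation
failure mode can be measured.

## Problem sizes used in the test suite

Statistical checks run at the device's native scales: binomial coverage at
$n = 900$ with 2,000 replicates per $\lambda$; goodness-of-fit at
$n = 14{,}400$; image-pipeline recovery on single 900-well panels with 100
seeded runs per $\lambda \in \{0.1, 0.7, 2\}$ and 20 runs for the
aggregation-bias check; one full 16-panel device run verifies the 14,400
well total. Single panels (rather than full devices) are used for the
replicated recovery studies because the estimator sees only pooled $(k, n)$
— panel count multiplies runtime without changing what is being tested
beyond the value of $n$.

## Known limitations

* Saturated devices ($k = n$) yield only a lower bound; in the near-regime
  $p \gtrsim 0.99$ the estimate is extremely sensitive to single
  misclassified wells.
* The lattice fit anchors row/column indices at the topmost/leftmost
  *detected* line; if an entire edge row of wells is absent from the image
  the fitted grid is translated by one pitch. Random missing wells make
  this vanishingly unlikely; structurally missing edge rows would not be
  caught.
* The aggregation model reproduces the direction and rough magnitude of
  clumping bias, not any measured clump-size distribution; no correction
  for aggregation is attempted, matching the method's documented behaviour.
* Rotation beyond a few degrees defeats the row/column gap clustering; the
  affine fit only absorbs small misalignment.
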