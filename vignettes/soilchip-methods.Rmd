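---
title: "soilchip: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{soilchip: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilchip)
```

## Scientific setting

Matrix-producing (wild-type) *Pseudomonas aeruginosa* and matrix-deficient
mutants (for example a ΔpelA strain that cannot make the Pel
polysaccharide) compete very differently depending on the flow environment.
In a planar chamber with a simple parabolic flow profile, producers win at
every starting frequency.  In a porous, soil-like chamber filled with
column obstacles, producer biofilms locally clog pores; clogged, near-zero
shear regions become refuges in which the shear-sensitive mutant can
accumulate, and the two strains can coexist.  `soilchip` implements the
computational side of such experiments end to end: chamber design,
tessellation-based image quantification, flow mapping from bead streaks,
area-normalized co-occurrence statistics, and frequency-dependent-selection
analysis, together with a synthetic-data generator that provides
region-level ground truth for validating every step.

## Chamber design

The porous arena is derived from a three-dimensional granular model: unit
spheres on a face-centered cubic (FCC) lattice, the canonical close
packing.  `packSpheres(n)` enumerates the lattice as all integer triples
with even coordinate sum, scaled so touching neighbors are two radii
apart.  Grain-size heterogeneity is introduced by redrawing each radius
i.i.d. uniform on [0.4, 1.0] (`perturbRadii()`); because radii never exceed
1, perturbed spheres remain disjoint, and so do their plane sections.

`crossSection()` cuts the bed with an oblique plane.  Obliquity is
enforced (default minimum angle 5° against the {100}, {110} and {111}
symmetry families) because a symmetry-plane cut produces a crystalline,
periodic pattern rather than the irregular arrangement of a granular
medium.  The default normal, (1, 0.37, 0.22), is 23° or more away from all
families.  Sphere sections become circles of radius $\sqrt{r^2 - d^2}$.

`scaleToPhysical()` maps the section to micrometers with a single linear
factor anchored so the largest circle has radius 200 µm, then discards
circles below 80 µm (fine sand) and circles not fully inside the chamber.
Since the anchor/cutoff mapping was an open choice, it is implemented
explicitly rather than by clipping or redrawing; a defensive
overlap-resolution step (shrink the smaller of an overlapping pair to
tangency minus a 5 µm clearance) also guards user-supplied circle sets.
Columns additionally keep a 10 µm clearance from the chamber walls, as
fabricated pillars do.  Default chamber dimensions are 4500 × 3000 × 75 µm.
The paper-scale experiments do not pin these down; 75 µm matches the
channel-height scale used for shear estimates, and the 1.5:1 footprint
keeps a compact 40% clog from severing the whole arena (see below).  A
typical layout holds 50–100 columns.

Wall shear stress uses the standard surface-shear expression
$\tau = \alpha\,\partial u/\partial y|_{y=0} = (\Delta p / L)(H/2)$ for a
rectangular channel.  Two routes are provided:

* `method = "plate"` (default): the parallel-plate (plane Poiseuille)
  limit, $\tau = 6 \alpha U / H$.  At the experimental operating point
  (U = 175 µm/s, α = 10⁻³ Pa·s, H = 75 µm) this gives τ = 0.014 Pa.
* `method = "duct"`: Δp/L from the exact rectangular-duct Fourier series
  (20 terms by default), which matters at moderate aspect ratios.  The two
  routes agree within 1% only for aspect ratios W/H of roughly 65 and
  above (the discrepancy is ≈6.7% at W/H = 10); the test suite asserts the
  1% agreement at W/H = 100 and monotone convergence.

## Region analysis

The quantification scheme follows the network-structure procedure: column
centers are nodes, straight segments between centers are edges, and the
triangles partition the imaged chamber into sampling regions.

* **Column detection.** Columns are near-zero-intensity disks on a
  fluorescent background.  `detectColumns()` thresholds pixels darker than
  half the image median, labels connected components, and reports each
  component's centroid and area-equivalent radius.  On synthetic scenes
  this recovers centers within 2 px and radii within 5%.  When a layout
  file is available, `columnsFromLayout()` registers it instead.
* **Triangulation.** The "network structure" is realized as the Delaunay
  triangulation (via `deldir`), which is unique in general position and
  maximizes minimum angles; the empty-circumcircle property is asserted in
  tests.  Triangles outside the node convex hull (wall regions) are not
  analyzed.
* **Rasterization.** A pixel belongs to the triangle containing its
  center; pixels on shared edges go to the lowest-id triangle, a
  deterministic tie-break.  Column-covered pixels are removed from each
  triangle's effective mask.  Raster areas conserve the hull area within
  0.5%.  Node ordering is canonicalized (by y, then x), so a tessellation
  built from detected columns and one built from the registered layout
  assign identical region ids.
* **Occupancy calls.** Mean intensity is computed over each effective
  mask.  Two threshold rules are available.  `"otsu"` maximizes
  between-class variance over the region means (computed by exhaustive
  sweep over midpoints, no binning).  `"k_sigma"` thresholds at background
  + k·MAD (k = 5).  The pipeline default is `"k_sigma"` anchored on the
  image background (the minimum of the pixel median over effective masks
  and the Otsu lower-class median — each estimator alone is biased upward
  in a different regime), because biofilm clusters vary widely in size:
  occupied regions form a long-tailed intensity class that a
  variance-based split cuts through, while a background-anchored rule
  detects weak but real occupancy.  A noise floor of 4× the expected
  standard error of a region mean guards against noise-driven positives;
  ties at the threshold are negative.
* **Flow calls.** Bead-streak frames are integrated by pixelwise maximum
  (a union of sampled corridors; a sum would weight repeatedly-sampled
  paths).  Streak pixels are segmented at background median + 5 MAD, and a
  region is `open` when streak coverage of its effective mask reaches
  `minCoverage` (default 0.001, boundary inclusive), else `blocked`.

## Co-occurrence statistics

For each strain and flow class, the occurrence frequency is the occupied
effective area divided by the class's total effective area, i.e.
normalized to the total area of blocked versus open flow.  Area weighting
(rather than region counting) makes frequencies comparable across unequal
triangles; a count-weighted mode is provided for sensitivity analysis.
Replicate-level frequencies are compared between classes with a pooled
two-sample t-test — pooled, not Welch, because with n replicates per class
the customary df is $n_1 + n_2 - 2$ (three replicate chambers per class
give df = 4) — and the two per-strain comparisons are Bonferroni
corrected at a family-wise 0.05.

## Frequency-dependent selection

Competition records are (f0, f72) pairs of initial and final wild-type
frequencies.  The frequency change Δf = f72 − f0 is fitted by least
squares on the basis {f0(1−f0), f0²(1−f0)}, which forces Δf → 0 at the
absorbing states f0 ∈ {0, 1}.  The fitted curve is classified by its sign
on a fine grid over (0, 1); a single positive-to-negative crossing is the
negative frequency-dependent regime, and the crossing — the critical
coexistence frequency — is located by bisection, with a percentile
bootstrap over records for its confidence interval.  The underlying
experiments read the crossover (≈0.6) directly off replicate data; the
parametric fit formalizes that readout and is validated on synthetic data
only.  With the default validation conditions (n = 30 records, replicate
noise sd 0.03) a single experiment estimates the critical frequency with
sampling standard deviation ≈0.033, so point-recovery checks use the
median over 11 replicate experiments, while CI coverage is checked per
experiment.

Growth rates are the maximum over contiguous windows (default 5 points,
2 h at 30-minute sampling) of the least-squares slope of OD against time,
i.e. the maximum slope of the growth curve on the raw OD scale; a log-OD
mode gives the exponential rate instead.  On a noise-free logistic curve
the windowed estimate matches the analytic grid maximum within 2% when
the window spans well under a doubling time.

## The synthetic-data generator

The generator emulates every pipeline input with known region-level truth:

* **Clogging truth.** A blocked set grows region by region from a random
  clog site, preferring regions nearest the site (clogs spread locally).
  A candidate joins only if every remaining open region stays connected —
  through open neighbors — to both the inlet and the outlet side
  (leftmost/rightmost 20% of the arena).  This rejection rule encodes two
  physical facts: clogs grow where flow still delivers cells, and a
  stagnant pocket is by definition not an open-flow region.  It also keeps
  the truth self-consistent with bead streaks, which can only trace
  corridors reachable from the inlet.  The default blocked fraction is
  0.4.
* **Occupancy truth.** The wild type occupies regions with probability
  0.5 independently of flow; the shear-sensitive mutant occupies blocked
  regions with probability 0.75 and open regions with probability 0.15 —
  a 5:1 ratio.
* **Scenes.** Two 16-bit-scale channels: uniform background (100 counts),
  column disks at 2 counts, and 1–4 Gaussian biofilm blobs per occupied
  region with peak amplitude 6× the background noise scale
  $\sqrt{\mathrm{bg} + \sigma_\mathrm{read}^2}$ and scale 25 µm (typical
  of 72 h microcolonies), truncated at 3σ and placed so they cannot cross
  into a neighboring region (overlap with columns is harmless because
  column pixels are excluded from means).  Blob footprints are capped at
  40% of the region so background pixels always dominate.  Noise is
  Poisson photon noise plus Gaussian read noise (sd 3); `noise = FALSE`
  renders the exact expectation.
* **Bead stacks.** Streak paths are depth-first walks over the adjacency
  graph of open regions, split into sub-walks spanning several regions,
  drawn as 1 px anti-aliased polylines through pore anchor points (the
  deepest pixel of each region's effective mask) and shared-edge
  midpoints, distributed over 12 frames (within the typical 10–15
  integration range).  Any streak pixel landing in a blocked region's
  effective mask is cleared, so the stack never contradicts the truth.
* **Competition and growth tables.** Δf = a·f0(1−f0) (uniform positive)
  or a·f0(1−f0)(f_c−f0) (negative frequency-dependent, default f_c = 0.6)
  plus Gaussian noise, clipped so f72 ∈ [0, 1]; logistic OD600 curves
  sampled every 30 minutes by default (a 10-minute preset is
  `dtMin = 10`; both sampling conventions appear in practice) with
  additive Gaussian noise.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: biofilm growth dynamics and streamer
mechanics (truth states are sampled, not emergent), uneven illumination
and photobleaching, cell-scale texture, bead depletion and out-of-focus
streaks, chamber drift, or segmentation artifacts at real PDMS/glass
interfaces.  Validation on these synthetic scenes demonstrates the
internal consistency and statistical calibration of the pipeline, not
instrument-level robustness.

## Numerical choices and degenerate inputs

Coordinates are (x right, y down) with pixel (i, j) centered at
(j−0.5, i−0.5); physical scaling is a single µm-per-pixel factor.
Barycentric containment uses a 10⁻⁹ tolerance.  Collinear column sets,
empty bead stacks, all-identical region means (warned, all-negative),
zero-variance t-test inputs (t = 0/p = 1 on equal means, infinite t
otherwise) and classes with zero area (flagged undefined, dropped from
tests) are all handled explicitly.  One integer seed drives any stochastic
step through a scoped RNG wrapper that restores the caller's RNG state,
making every artifact bit-reproducible.

Problem sizes used in the shipped validation: scenes are rendered at
5 µm/px (600 × 900 px, ~100 regions each, pooling ≥200 regions for
sensitivity/specificity), calibration uses 100 three-replicate
co-occurrence experiments and 1000 null experiments, and selection fits
use 30-record experiments with 200–1000 bootstrap resamples.

## Known limitations

* The estimator of the critical frequency assumes the cubic logistic-type
  basis; selection functions outside its span are classified by sign
  pattern but their crossing estimate inherits model bias.
* Occupancy calling assumes a spatially uniform background; strong
  illumination gradients would require flat-field correction upstream.
* In a fully clogged chamber the open class is empty: occurrence
  frequencies are flagged undefined and the replicate is unusable for the
  blocked-vs-open comparison, mirroring the practice of discarding failed
  chambers.
* Column detection assumes dark, roughly circular, non-touching pillars;
  heavily fouled columns whose rims brighten would need the layout-file
  registration path.
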