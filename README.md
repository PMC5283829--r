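# soilchip

Spatial competition analysis for bacterial biofilms growing in
soil-mimicking (obstacle-containing) microfluidic chambers.

Matrix-producing wild-type *Pseudomonas aeruginosa* and matrix-deficient
mutants (e.g. ΔpelA, unable to make the Pel polysaccharide) compete very
differently depending on hydrodynamics.  Under simple parabolic flow the
producer wins at any starting frequency; in porous arenas, producer
biofilms clog pores, the clogged near-zero-shear regions shelter the
shear-sensitive mutant, and the strains coexist through negative
frequency-dependent selection.  `soilchip` implements the computational
workflow behind such experiments:

* **Chamber design** — soil-mimicking column layouts cut as oblique
  cross-sections through a perturbed close-packed (FCC) sphere bed, with
  column radii spanning 80–200 µm (fine-to-medium sand), plus wall shear
  stress τ = (Δp/L)(H/2) for rectangular channels (parallel-plate limit
  τ = 6αU/H, or the exact duct series).
* **Region analysis** — column detection, Delaunay tessellation with
  column centers as nodes and column area removed from each triangular
  sampling region, per-region mean intensities, biofilm occupancy calls,
  and open/blocked flow calls from integrated bead-streak images.
* **Co-occurrence statistics** — strain occurrence frequencies normalized
  to the total effective area of blocked vs open flow, compared across
  replicate chambers with pooled two-sample t-tests (df = n₁+n₂−2) and
  Bonferroni correction.
* **Selection analysis** — Δf = f72 − f0 fitted on the basis
  {f0(1−f0), f0²(1−f0)}, regime classification, critical coexistence
  frequency by bisection with a bootstrap CI, and maximum growth rates as
  windowed slopes of OD600 curves.
* **Synthetic data** — two-channel chamber scenes, bead-streak stacks,
  competition tables and logistic growth curves, all with region-level
  ground truth for end-to-end validation.

## Worked example

```r
library(soilchip)

# design a porous chamber and estimate shear at the operating point
layout <- makeSoilLayout(seed = 13)
layout
#> ChamberLayout: 4500 x 3000 x 75 um, 55 columns (r 81.0-185.7 um)
wallShearStress(175, 1e-3, height = 75)
#> [1] 0.014      # Pa, at 175 um/s mean flow in a 75 um channel

# simulate a full experiment (images + bead stack + truth), then analyze it
sim <- simulateChamberExperiment(seed = 13, umPerPx = 5)
res <- runPipeline(sim$gfp, sim$mcherry, sim$beads, layout = sim$layout,
                   config = runConfig(seed = 13, umPerPx = 5))
res$occurrence
#>   strain flow_class area_occupied_um2 area_total_um2 frequency
#> 1     wt       open           1903000        4001725 0.4755449
#> 2 mutant       open            580525        4001725 0.1450687
#> 3     wt    blocked           1331350        2954100 0.4506787
#> 4 mutant    blocked           2312100        2954100 0.7826749

# replicate-level test: is each strain enriched where flow is blocked?
s <- simulateOccurrenceExperiment(sim$tessellation, nReplicates = 3,
                                  seed = 13)
cooccurrenceTest(s)
#>   strain         t df            p significant mean_blocked mean_open
#> 1     wt  1.007828  4 3.705534e-01       FALSE    0.4739234 0.4337750
#> 2 mutant 22.443834  4 2.333657e-05        TRUE    0.7380146 0.1342867

# frequency-dependent selection from competition records
rec <- sampleCompetition(seq(0.1, 0.9, length.out = 30), a = 1, fc = 0.6,
                         noiseSd = 0.03, seed = 13)
fitSelectionFunction(rec, seed = 13)
#> SelectionFit: regime = negative_freq_dependent
#>   critical frequency f_c = 0.586 (95% CI 0.534-0.639)
#>   coefficients: b1 = 0.72, b2 = -1.229; n = 30 records
```

The mutant occupies blocked regions about five times as often as open
ones, the replicate t-test flags that enrichment (with df = 4 for three
replicates per class, Bonferroni-corrected over the two strains) while
wild-type occupancy shows no flow association, and the fitted selection
function recovers a critical coexistence frequency near 0.6: below it the
wild type gains, above it the mutant does.

A small demo layout and pipeline configuration are bundled under
`inst/extdata/` (`demo_layout.csv` + sidecar JSON, `demo_config.json`);
`readLayout()` and `runPipeline()` accept them directly.

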