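# orgaKinetics

Image-based quantification of *delayed* drug responses in scaffold-embedded
organoid cultures.

Organoid drug testing happens inside a physical context that classical
readouts ignore: a gel scaffold (Matrigel or a synthetic hydrogel) sits
between the medium and the cells, an organoid's position inside the
hemispherical scaffold dome sets its diffusion path length, and within a
single large organoid the drug reaches the rim before the core. All three
effects show up as *delays* in time-resolved readouts of drug action —
and the delay, not just the endpoint, is the measurement.

`orgaKinetics` is an R implementation of the complete quantification
chain for two live-cell imaging readouts in prostate-cancer models, plus
the endpoint viability analysis around them:

* **Nuclear androgen-receptor (AR) translocation.** From two-channel
  (Hoechst + EGFP-AR) time-lapse frames: nucleus segmentation (Otsu +
  distance-transform watershed), perinuclear cytoplasmic rings
  (nearest-nucleus Voronoi partition), and the per-cell ratio
  `nuc / (nuc + cyt)` of background-corrected mean intensities — 0 for
  complete cytoplasmic, 1 for complete nuclear localization.
* **Taxane-induced tubulin stabilization.** From an EYFP-tubulin channel:
  cell-area segmentation and the Haralick contrast
  `sum_ij P(i,j) (i-j)^2` of a symmetric, normalized gray-level
  co-occurrence matrix (32 levels, 4 direction-1 offsets, fixed
  quantization range per time series), with an optional
  bleaching correction from an untreated control.
* **Spatial structure.** Radial distance of each organoid from the dome
  centre, grouping into nine 250 µm bins; core/periphery allocation of
  nuclei by a 100-pixel rim rule on the Euclidean distance transform of
  the organoid mask; organoid size classes at 8000 µm².
* **Kinetics and statistics.** Half-transition times t½ from 4-parameter
  logistic fits in time (with an explicit "plateau not attained" status
  for curves that never saturate), Welch t tests with Bonferroni
  correction across conditions, 4PL dose-response fits (IRLS for
  constant-CV luminescence noise, bootstrap EC50 CIs) and an
  extra-sum-of-squares F test for potency shifts between curves.
* **Synthetic data with exact ground truth.** Renders monolayer and dome
  time-lapses, tubulin texture ramps and viability plates under
  programmed kinetics, so that every stage above is validated by
  parameter recovery — no external data needed.

The package is S4/Bioconductor-flavoured (EBImage for image primitives,
`minpack.lm` for nonlinear fits) with classes `ImagingConfig`,
`KineticModel`, `LabelImage`, `GLCMatrix`, `SigmoidFit`, `FourPLFit`,
`DomeLayout` and `BinningScheme`.

## A worked example

Simulate and analyse the scaffold-delay design end to end — three
monolayer conditions (no gel / synthetic hydrogel / Matrigel) with
programmed translocation lags of 0, 1 and 3 h, three independent
simulated experiments each:

```r
library(orgaKinetics)

report <- runScenario("monolayer_scaffold", seed = 7)
report$delta_t50_vs_control_h
#>  noviogel  matrigel
#> 0.9787531 2.9343904
report$comparisons[, c("group1", "group2", "adjusted_p")]
#>     group1   group2   adjusted_p
#> 1   no_gel noviogel 1.152001e-04
#> 2   no_gel matrigel 1.291914e-07
#> 3 noviogel matrigel 7.911702e-06
```

The pipeline recovers the programmed 1 h and 3 h delays from the rendered
images (segmentation → per-cell ratios → mean curves → sigmoid fits), and
the Bonferroni-corrected Welch tests call both delays significant.

Dose-response, single cells versus assembled organoids (a programmed
10-fold EC50 shift at 5% well-to-well CV):

```r
dr <- runScenario("dose_response", seed = 7)
ec50(dr$fits$single_cells)
#> [1] 0.1009
ec50(dr$fits$organoids)
#> [1] 1.0222
dr$shift_test$p
#> [1] 6.66e-20
```

Other scenarios: `"dome_binning"` (recovers a linear 0→2 h lag gradient
across nine radial dome bins as strictly increasing per-bin t½) and
`"core_periphery"` (recovers a programmed 1 h core delay inside large
organoids as a t½ difference between the normalized zone curves).
`runScenario(..., out_dir = )` writes per-cell CSVs, curve CSVs, fit JSON
and a provenance record; see `defaultRunConfig()` for every knob. A thin
command-line wrapper ships in `inst/scripts/orgakinetics.R`, and
simulated stacks round-trip to multi-page 16-bit TIFF via
`writeSimulation()` / `readImageStack()`.

The methods vignette
(`vignettes/quantifying-delayed-drug-responses.Rmd`) documents the
models, the ground-truth definitions, every tunable parameter and the
design decisions in detail.

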