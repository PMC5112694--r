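# decayflux

Genome-wide mRNA decay kinetics, transcription-vs-degradation regulatory
control, and expression-constrained metabolic flux prediction — an
integrated, tested R/Bioconductor-style pipeline for prokaryotes grown on
different substrates (the motivating system is the methanogenic archaeon
*Methanosarcina acetivorans* on methanol, trimethylamine and acetate).

## The scientific problem

When a microbe switches growth substrate, transcript abundances shift.
Each shift can come from transcription, from degradation, or both — and the
regulated genes reshape metabolic fluxes in ways a stoichiometric model can
predict.  `decayflux` covers that chain of analysis:

1. **Half-lives from transcription-arrest time courses.**  After arrest,
   each transcript decays as

   ```
   R_i(t) = R_{i,0} e^{-k_i t},        tau_i = ln(2) / k_i
   ```

   `fitDecay()` estimates `k_i` by Levenberg–Marquardt least squares on
   RPKM-normalized counts (`rpkmNormalize()`, operon-averaged
   `orpkmNormalize()`), after `referenceScale()` removes global
   per-timepoint drift by anchoring a designated ultra-stable reference
   gene (e.g. *sodB*/MA1574) to a 2-hour half-life.  QC keeps fits with
   `k > 0` and `se_k/k < 0.5`.  Distribution tools: cell-cycle scaling
   (`scaleByDoubling()`), per-gene shift calls (`classifyShift()`),
   Mann–Whitney distribution comparison, per-category summaries.

2. **Control coefficients.**  At steady state `k_trn = gamma * m`, so a
   condition pair defines

   ```
   rho_D = -d ln(gamma) / d ln(m)      rho_T = d ln(k_trn) / d ln(m)
   rho_T + rho_D = 1
   ```

   with `rho_D >= 1` meaning degradation-controlled abundance change,
   `rho_D <= 0` transcription-controlled, and shared control in between
   (`controlCoefficients()`, `classifyRegime()`, `controlAnalysis()`).
   Consensus differential-expression calling across method tables,
   operon-level pooling and a bootstrap on the DEG count round out the
   regulation module.

3. **Expression-constrained biomass fitting.**  With a genome-scale
   metabolic model, `fitBiomassCoefficients()` refits the biomass
   coefficients `b_j` of the alternative condition so that flux ratios
   match expression ratios of DE genes, minimizing

   ```
   sum_i sum_{r: i in r} | v_1r/v_2r  -  m_1i/m_2i |
   ```

   over random coordinate-sweep orderings (default 96), with substrate
   uptake re-matched to the measured growth rate `mu = ln(2)/T_d` at every
   candidate; metabolites are then classified as higher/lower/unchanged
   demand by a t-test across orderings.  FBA itself (`fbaSolve()`,
   `matchGrowth()`, parsimonious optima, JSON/SBML model import) runs on a
   compiled dense simplex kernel.

A synthetic-data module (`simulateDecayExperiment()`,
`simulateCountExperiment()`, `makeToyModel()`) generates inputs with known
ground truth for every stage.

## Worked example

```r
library(decayflux)

## -- half-lives from a drifting, noisy arrest time course ----------------
sim     <- simulateDecayExperiment(nGenes = 300, noiseCV = 0.1,
                                   driftAmplitude = 0.2, seed = 11)
scaled  <- referenceScale(sim$experiment, "MA1574", referenceHalflife = 120)
records <- qcFilter(fitDecay(scaled))
head(records[, c("gene_id", "k_per_min", "tau_min", "se_k", "cv")], 3)
#>    gene_id k_per_min tau_min     se_k     cv
#> 1   MA1574   0.00578   120.0 0.000340 0.0588
#> 2 gene0001   0.01474    47.0 0.000976 0.0662
#> 3 gene0002   0.01230    56.4 0.000951 0.0773
```

All 300 genes pass QC; the reference gene lands exactly on its 120-min
anchor, and the median half-life recovery error against the generator's
truth table is 9.7%.

```r
## -- which force moved this transcript? ----------------------------------
cc <- controlCoefficients(m1 = 10, m2 = 40,
                          gamma1 = log(2) / 60, gamma2 = log(2) / 180)
cc
#>       rho_T     rho_D determinate
#> 1 0.2075187 0.7924813        TRUE
classifyRegime(cc$rho_D)
#> [1] "shared"
```

A 4-fold abundance increase accompanied by a 3-fold stabilization is
mostly (79%) a degradation effect, but not purely — shared control.

```r
## -- recover a planted 2x biomass demand from expression ratios ----------
toy <- makeToyModel(plantedShift = c(P2 = 2))
fit <- fitBiomassCoefficients(toy$model, toy$ref, toy$alt, toy$deg,
                              nOrderings = 96, seed = 1)
fit[, c("metabolite", "b_orig", "b_mean", "b_sd", "pvalue", "class")]
#>   metabolite b_orig b_mean b_sd pvalue     class
#> 1         P1    0.5    0.5    0      1 unchanged
#> 2         P2    1.0    2.0    0      0    higher
#> 3         P3    1.5    1.5    0      1 unchanged
#> 4         P4    0.8    0.8    0      1 unchanged
#> 5         P5    1.2    1.2    0      1 unchanged
#> 6         P6    2.0    2.0    0      1 unchanged
```

The planted doubling of metabolite P2's demand is recovered exactly; every
unperturbed coefficient stays put.

`runPipeline()` chains all stages from TSV/JSON inputs to result tables
plus a checksummed run manifest, and `inst/scripts/decayflux` exposes the
same steps as shell subcommands (`simulate`, `halflife`, `control`,
`deg-consensus`, `operon-pool`, `fluxfit`, `run`).

## Method documentation

The methods vignette (`vignettes/decayflux-methods.Rmd`) describes the
models and their assumptions, every tunable parameter with units and
defaults, the numerical choices (zero-flux floors, regime boundary
handling, grid design, parsimonious-FBA equivalence used in the fitting
loop), what the synthetic generators do and do not emulate, and known
limitations.
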