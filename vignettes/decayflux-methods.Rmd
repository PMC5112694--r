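---
title: "Methods: decay kinetics, regulatory control and expression-constrained flux fitting"
author: "decayflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decay kinetics, regulatory control and expression-constrained flux fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decayflux)
```

# Scope

`decayflux` implements three linked analyses for comparing a prokaryote
(typically a methanogen or other archaeon/bacterium) across growth
conditions:

1. **mRNA half-life estimation** from transcription-arrest RNA-seq time
   courses,
2. **regulatory control coefficients** that attribute changes in
   steady-state transcript abundance to transcription or degradation, and
3. **expression-constrained flux balance analysis (FBA)** in which the
   biomass composition of a metabolic model is refit so that predicted flux
   ratios between conditions track measured expression ratios.

A synthetic-data generator with ground truth backs the test suite; it is a
first-class module, not a fixture.

# Half-life estimation

## Model and assumptions

After transcription is blocked (e.g. with actinomycin D), the abundance of
each transcript decays by degradation alone.  We model this as first-order
decay,
$$R_i(t) = R_{i,0}\, e^{-k_i t}, \qquad \tau_i = \ln 2 / k_i,$$
with $k_i$ the per-minute decay rate and $\tau_i$ the half-life.  The
assumptions are the standard ones: arrest is complete and instantaneous at
the level of resolution of the sampling grid, degradation is memoryless,
and the normalized expression measure (RPKM) is proportional to abundance.

Counts are normalized to RPKM (`rpkmNormalize()`); an operon-averaged
variant (`orpkmNormalize()`) first averages per-kilobase values across
operon members, since genes in one polycistronic message share a fate.

## Reference-gene drift correction

Genome-wide time courses carry a shared per-timepoint distortion: residual
transcription, library-size normalization artifacts, and arrest-response
programs move all genes together.  `referenceScale()` removes it by
anchoring a designated highly stable gene (for *Methanosarcina
acetivorans*, the superoxide dismutase *sodB*/MA1574) to a known half-life,
2 hours by default.  Each timepoint is multiplied by the factor that puts
the reference gene's replicate-mean trajectory exactly on its assigned
exponential.  The correction is anchored at the first measured timepoint,
which we treat as the decay origin.  Two properties follow by construction
and are asserted in the tests: the operation is idempotent, and a
subsequent fit of the reference gene returns the assigned half-life
exactly.

A nominal offset between arrest and the first sample has no effect on the
correction factors (it cancels algebraically) and, with $R_0$ anchored at
the first-sample mean, none on the fitted rate either; we therefore do not
expose an origin-offset parameter.

## Fitting

`fitDecay()` fixes $R_{i,0}$ to the replicate-mean expression at the first
timepoint and estimates $k_i$ by Levenberg--Marquardt nonlinear least
squares on the *untransformed* scale (log-linear regression would require
discarding zeros and reweights the noise).  Replicates enter as pooled
points rather than being averaged, so the standard error of $k$ reflects
replicate scatter.  Standard errors come from the analytic Jacobian at the
optimum; a two-parameter fit with $R_0$ free is available behind
`freeR0 = TRUE` but off by default.

Quality control follows the usual convention for this assay:
`qc_pass` requires $k > 0$ (a positive half-life) and a coefficient of
variation $\mathrm{cv} = se_k/k < 0.5$.  Because $\tau = \ln2/k$, the
relative uncertainty of $\tau$ is the same number, so the filter can be
read on either scale.  Genes with zero counts at some timepoints are fit
as-is; all-zero genes are reported as unfittable (`NA`) rather than
silently dropped.

## Downstream distribution analyses

* `scaleByDoubling()` expresses half-lives as fractions of the cell cycle
  ($\tau / (60\,T_d)$ for doubling time $T_d$ in hours), with an
  inverse-variance weighted SD.
* `classifyShift()` calls per-gene half-life changes between two
  conditions ("longer" / "shorter" / "no_change") by a two-sided t-test on
  $\tau_b - \tau_a$ with propagated errors
  ($se_\tau = \ln2\, se_k / k^2$) and Welch--Satterthwaite degrees of
  freedom; `coreUnregulated()` intersects the no-change sets across
  comparisons.
* `compareDistributions()` is the two-sided Mann--Whitney rank-sum test,
  exact for samples of at most 8 without ties, mid-rank/normal
  approximation otherwise.
* `summarizeByCategory()` reports the median half-life per functional
  category (e.g. COG class) with inverse-variance weighted SD; the weights
  $1/se_\tau^2$ are our choice where a "weighted standard deviation" is
  otherwise underspecified.

# Control coefficients

At steady state, synthesis balances removal, $k_{trn} = \gamma m$ (with
dilution negligible against degradation whenever doubling times are hours
and half-lives minutes; an optional `mu` argument adds $\ln2/T_d$ for slow
decayers).  For a condition pair, the finite-difference control
coefficients are
$$\rho_D = -\frac{\ln(\gamma_2/\gamma_1)}{\ln(m_2/m_1)}, \qquad
  \rho_T = \frac{\ln(k_{trn,2}/k_{trn,1})}{\ln(m_2/m_1)},$$
which satisfy $\rho_T + \rho_D = 1$ identically.  The sign convention on
$\rho_D$ is fixed by that identity.  Regimes are
classified with closed thresholds: degradational control for
$\rho_D \ge 1$, transcriptional for $\rho_D \le 0$, shared in between.

Numerical choices: genes with $|\ln(m_2/m_1)| < 10^{-6}$ are marked
indeterminate instead of producing exploding coefficients, as are genes
whose half-life fit failed QC in either condition; and $\rho_D$ values
within $10^{-9}$ of the boundaries 0 and 1 are snapped onto them before
thresholding, because the finite-difference logs carry floating-point
error of a few ulp and a gene constructed exactly on a boundary must not
drift across it.  Because only ratios enter, the coefficients are invariant
to any proportional expression scale (RPKM vs copies per cell); this is
asserted in the tests.  `copiesPerCell()` distributes a user-supplied
total mRNA count per cell proportionally to RPKM — the total is a required
input, as it cannot be derived from sequencing alone.

# Differential expression plumbing

The consensus-set logic (`consensusDEG()`) intersects per-method DEG calls
at $p \le 0.01$: a gene is differentially expressed only if every supplied
method calls it.  The per-method p-value tables are *inputs* — this package
deliberately does not re-implement count-model DE tools.  For running the
pipeline end to end without external tables, `simpleDETest()` provides a
two-sided moderated t-test (limma `lmFit`/`eBayes`) on
$\log_2(\text{library-normalized counts} + 0.5)$; it is documented as
plumbing, not as a substitute for edgeR/DESeq2/PoissonSeq.
`poolOperons()` sums member-gene counts (and lengths) per operon so the
same tests can run at operon level; per-sample totals are conserved.
`bootstrapDEGUncertainty()` resamples replicates with replacement within
condition and reports the relative SD of the DEG count; replicates (not
reads) are the resampling unit, a choice the function documents.

# Flux balance analysis and biomass-coefficient fitting

## FBA

`fbaSolve()` maximizes a reaction flux (the biomass reaction by default)
subject to $S v = 0$ and bounds.  Exchange reactions follow the standard
orientation (`met ->`), so uptake is a negative flux bounded below by the
uptake capacity.  Because LP optima are degenerate in general, the
returned vector is made deterministic by parsimonious selection —
among all optima, minimize $\sum_r |v_r|$ — so that downstream ratio
computations are well defined.  The LP kernel is a dense two-phase primal
simplex with Bland's rule, written in C++ (`src/simplex.cpp`) because the
fitting procedure below solves on the order of $10^4$–$10^5$ LPs; its
optima are verified in the tests against exhaustive vertex enumeration.
Infinite bounds are clamped at $10^4$ mmol/gDW/h, far above any active
flux in these models.

`matchGrowth()` tunes the substrate uptake bound by bisection until the
maximal growth rate equals the measured $\mu = \ln2/T_d$ (tolerance
$10^{-6}$), returning the bound from the upper bracket so that the
reported solution, with biomass capped at $\mu$, reproduces the target
exactly.

## Fitting biomass coefficients to expression ratios

The central fitting procedure treats the biomass coefficients $b_j$
(mmol of precursor per gram dry weight) of the *alternative* condition as
free parameters and scores a candidate composition by
$$\sum_{i \in \mathrm{DE}} \; \sum_{r \,:\, i \in r}
  \left| \frac{v_{1,r}}{v_{2,r}} - \frac{m_{1,i}}{m_{2,i}} \right|,$$
the deviation of predicted flux ratios from measured expression ratios
over differentially expressed genes and their GPR-associated reactions
(association is set membership in the GPR string; no and/or semantics).
Condition 1 is the reference and keeps the original biomass.

`fitBiomassCoefficients()` sweeps the coefficients in random order; each
coefficient is optimized over a log2-spaced multiplicative grid
($b_j \times 2^{-3} \ldots 2^{3}$, 25 points — a one-dimensional search,
since nothing in the score couples coefficients once growth is re-matched),
re-tuning uptake to the measured growth rate at every candidate.  Ties are
broken toward the smallest change from the original coefficient, so a
coefficient the score cannot see stays put.  The sweep is repeated for 96
random orderings (the default); per-metabolite mean and SD over the
orderings feed a two-sided one-sample t-test against the original
coefficient at $\alpha = 0.01$, and metabolites are classified
higher / lower / unchanged by the sign of the shift.  Orderings whose
candidates are all infeasible leave the coefficient at its original value
and are flagged.  When every ordering lands on the same grid point the SD
is zero and the t-test degenerates; we then call the shift significant iff
the fitted value differs from the original.

Two numerical points deserve note.  First, inside the candidate loop we
do not literally re-bisect the uptake bound: capping the biomass flux at
the target growth rate and solving parsimoniously yields *exactly* the
growth-matched parsimonious solution (the minimum-total-flux optimum takes
up precisely the substrate the target growth requires), so one feasibility
LP plus one parsimonious LP replace the bisection, cutting solver calls
~15-fold without changing any result.  Second, fluxes with magnitude below
$10^{-9}$ are floored at $10^{-9}$ (sign preserved) when ratios are
formed, and gene–reaction pairs whose fluxes are below the floor in *both*
conditions are skipped: their ratio is undefined, and counting them would
reward degenerate solutions that switch pathways off.

`classifyFluxChanges()` applies the conventional two-fold rule
($|v_2|/|v_1| > 2$ or the inverse) with the same zero-flux floor, and
`fluxExpressionCorrelation()` emits paired flux/expression log-ratios per
gene–reaction mapping with their Pearson correlation.

# Synthetic data generator

`simulateDecayExperiment()` emulates the statistical structure the
half-life analysis assumes: exponential decay per gene, lognormal
half-life and initial-abundance distributions, multiplicative lognormal
noise per replicate and timepoint (mean 1, coefficient of variation
`noiseCV`), and a shared per-timepoint lognormal drift factor that exists
precisely to exercise the reference-gene correction.  Defaults follow the
assay design the package targets: timepoints 5, 10, 20, 30, 60, 120 and
240 minutes, three biological replicates, a reference gene with a 120-min
half-life, and a half-life distribution with median 60 min.  The noise
level of real RPKM time series is not well characterized, so
`noiseCV = 0.1` is a deliberate, realistic choice rather than a measured
value — recovery results at other noise levels can be generated by
changing one argument.

`simulateCountExperiment()` draws gamma--Poisson (negative binomial)
counts, the standard overdispersed RNA-seq surrogate, with planted log2
fold changes.  `makeToyModel()` builds a small metabolic network — one
substrate exchange, a hub metabolite, six independent two-step branches
with one-gene GPRs, and a biomass reaction over the branch end products —
in which branch fluxes at matched growth are uniquely $b_j\mu$.  That
identifiability is the point: the emitted expression ratios equal the
exact flux ratios under the planted demand shifts, so the fitting
procedure has a known right answer, and an exhaustive single-coefficient
search is a valid independent oracle (branches decouple).

What the generators do *not* emulate: sequencing-depth heteroskedasticity
and gene-length biases, correlated noise across neighbouring genes,
partial transcription arrest, multi-gene GPR logic, and alternate optima
in the toy network (its optimum is unique by construction).  Passing
recovery tests on these inputs therefore demonstrates correctness of the
estimators under their own assumptions, not robustness to every artifact
of real sequencing data.

# Problem sizes and runtime choices

The test and acceptance workloads use sizes chosen to exercise every code
path at desk scale: 500 genes for decay-recovery checks, 10,000 random
inputs for the control-coefficient identity, a 10,000-gene null for test
calibration, and the full 96 orderings for the biomass fit on the
6-branch toy model.  The grid-search decay oracle evaluates 2,000
log-spaced rates, then refines by golden-section search, making it
independent of the Levenberg--Marquardt path it checks.

# Known limitations

* Degradation is strictly first-order; biphasic decay or delayed arrest
  onset will bias $\tau$ for affected genes.
* The control-coefficient analysis compares exactly two conditions by
  finite differences; it does not regress across many conditions.
* The simplex kernel is dense; it is intended for toy-to-genome-scale
  models (hundreds of reactions), not for community-scale models with
  tens of thousands of reactions.
* The biomass-coefficient search is a per-coefficient grid; coefficients
  outside $2^{\pm 3}$ of the original, or optima requiring coordinated
  moves of several coefficients, are out of reach by design.
* SBML import covers Level 3 + FBC stoichiometry, bounds, gene products
  and the active objective — the subset needed to map a reconstruction
  onto the JSON schema — not the full SBML feature set.
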