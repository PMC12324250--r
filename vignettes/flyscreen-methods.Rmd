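---
title: "Methods: hit calling, modifier analysis and oligogenic risk scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hit calling, modifier analysis and oligogenic risk scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyscreen)
library(dplyr)
```

# What this package computes

flyscreen implements the statistical machinery of a loss-of-function screen
of Alzheimer's-disease (AD) risk-gene homologs in *Drosophila*. Candidate
genes from human genetics are knocked out (or knocked down, for essential
genes) in the fly and scored in four central-nervous-system assays:

* **Brain structure** — vacuole counts on head histology sections;
* **Neuronal function** — electroretinogram (ERG) recordings of the
  retina's response to a light pulse;
* **Stress resilience** — recovery from acute heat (42 °C water bath) and
  mechanical ("bang", vortexing) stress;
* **Disease-modifier status** — change in the progressive climbing-speed
  decline of flies pan-neuronally expressing human amyloid-β42 or tau.

Gene-level calls from these assays are integrated into phenotype clusters,
each cluster is mapped to the AD risk alleles (lead GWAS SNPs) of its member
genes, and each individual in a human cohort receives one *oligogenic risk
score per cluster*: the count of risk alleles they carry across that
cluster's SNPs. Standardizing these scores and running a PCA yields a
low-dimensional stratification of the cohort by phenotype-cluster burden.

Because the screen's raw measurements and the sequenced cohort are not
distributable, the package ships a seeded synthetic-data module that
generates every input with the statistical structure the analyses assume,
plus a fully synthetic 100-gene summary table whose marginal counts match
the screen's published arithmetic.

# Hit-calling rules

## Histology

Wildtype brains can show up to ~10 vacuoles, so a genotype is called
structurally degenerating when it *consistently* has ≥ 15 vacuoles per
brain (`call_structure()`, `threshold = 15`). "Consistently" is read
strictly: **every** examined head (at least two per genotype) must reach
the threshold. A mean-across-heads alternative is available
(`rule = "mean"`); the strict reading is the default because it parallels
the both-RNAi requirement for essential genes and is the most conservative
interpretation. For essential genes assayed with two RNAi lines, both
genotypes must satisfy the criterion.

## Electroretinograms

Each trace decomposes into three components (`extract_erg_features()`):
the light-coincident receptor potential (LCRP; the sustained depolarization
plateau), and the on and off transients (postsynaptic responses at light
onset/offset). Traces are stored corneal-negative (depolarization is
negative voltage); features are reported as non-negative magnitudes, which
fixes a polarity convention the assay literature leaves implicit. Five
traces per fly are averaged (`average_fly_traces()`) and the average is one
biological replicate; five flies per genotype is the default design.

The protocol does not state measurement windows, so they are explicit
configuration (`erg_windows()`): baseline = 200 ms before onset, on window
= 100 ms after onset, plateau = last 50 % of the stimulus, off window =
200 ms after offset. LCRP amplitude defaults to the plateau-window mean
(|mean − baseline|); a peak-based option exists because the choice is not
documented in the source protocol. All features are invariant to adding a
constant voltage offset, and to time shifts that move the whole stimulus
window consistently.

Mutants are compared only to controls with matching eye color — the
comparison is keyed structurally on `eye_color`, since the *white* gene
both changes eye pigment and sensitizes photoreceptors. Statistics follow
the screen's design: Kruskal–Wallis across the genotypes of a batch, then
Dunn's z tests of each mutant against the control. The Dunn variant is not
specified by the original analysis software, so the package uses
Holm-adjusted Dunn p-values (order-preserving and conservative), with
Bonferroni as an option. Mid-ranks and the tie-corrected rank variance are
used throughout; an all-tied comparison is flagged degenerate and reported
with p = 1 rather than propagating a 0/0.

A gene's class is `decreased`, `increased`, `mixed` (significant components
in both directions), or `none`; for essential genes a component only counts
when significant in both RNAi strains with the same direction.

## Stress resilience

The design is screen-then-replicate. In the primary screen a genotype with
≥ 60 % impaired flies after the recovery period is a candidate (the cutoff
is more than double the control averages of 26 % heat / 19 % bang
impairment); essential genes need both RNAi lines above the cutoff.
Candidates are re-assayed with 5–10 flies per biological replicate and
confirmed by Kruskal–Wallis + Dunn against control replicate fractions at
adjusted P < 0.05. Candidates with fewer than three replicates are reported
as *unconfirmable*, never silently dropped. The replicate-stage omnibus
test pools the candidates of one assay batch; whether the original analysis
batched per day or per experiment is unknowable from the protocol, so the
batch is whatever is passed in one call (configurable by splitting calls).

# Longitudinal modifier analysis

Climbing speed (mean of the ~10 females per vial) is assessed from day 5 to
day 18 post-eclosion — 6 timepoints for the tau model, which declines
earlier, 9 for amyloid-β — with 4 vials per genotype. `fit_longitudinal()`
models speed as a quadratic polynomial in age, a genotype indicator (curve
shift, the *additive* effect), genotype × age interactions (slope change,
the *interactive* effect) and a random intercept per vial. The quadratic
basis is this package's concrete choice for the "nonlinear" decline —
it captures the curvature of a progressive decline with few timepoints
without risking the instability of richer nonlinear forms; linear and
log-age bases are options. Random slopes are deliberately omitted: four
vials per genotype cannot support them. When the mixed fit degenerates
(zero residual variance, as in noiseless oracle tests) the model falls back
to ordinary least squares and records that in the result.

`test_effects()` produces three p-values — overall genotype, additive,
interactive — as joint F tests with Kenward–Roger denominator degrees of
freedom (default). Kenward–Roger was chosen over Satterthwaite because in
simulation the 3-degree-of-freedom joint test with eight vials is slightly
liberal under Satterthwaite (~6.9 % at nominal 5 %) and well calibrated
under Kenward–Roger (~4.4 %); Satterthwaite remains available where speed
matters, e.g. large Monte-Carlo sweeps. The three p-values within one
strain are the Holm family (`holm_adjust()`), matching per-strain adjusted
p-values on volcano plots.

The effect-size statistic is the **area between curves**: the trapezoidal
integral of (test − disease-control) fitted mean speed over the shared age
span, in mm/s·day. Negative area = worse climbing = enhancer; positive =
suppressor. The original workflow gates calls on a visual plausibility
check of the plots; `classify_strain()` codifies that as a minimum |area|
floor, defaulting to 10 % of the disease-control curve's own area, because
a reproducible pipeline needs an explicit rule. A strain is a modifier when
any of the three Holm-adjusted p-values clears α = 0.05 (configurable to
interaction-only; the source protocol does not say which p-value gates when
they disagree) *and* the area clears the floor. A gene is a
*high-confidence* modifier with ≥ 2 strains called in the same direction;
conflicting directions block the call and set a flag. Gain- vs
loss-of-function allele class is metadata only — consistency is judged on
phenotype direction.

# Oligogenic risk scores and stratification

`count_risk_alleles()` tabulates, per individual and phenotype cluster, the
dosage (0/1/2) of the risk allele at each cluster SNP. Design decisions,
each exposed as configuration:

* The ERG ("function") cluster defaults to decreased-depolarization genes
  only, matching the functional-defect definition used for risk scoring;
  an include-all option covers increased/mixed classes.
* A SNP shared by two cluster genes at one locus is counted once
  (deduplicated) to avoid double-weighting one variant; per-gene counting
  is a flag.
* Dosage counting is the default; carrier (0/1) counting is a flag — the
  source methods do not distinguish them.
* Missing genotypes are imputed with the per-SNP mean dosage (preserving
  column means) with a per-SNP missingness report attached; strict mode
  refuses missingness.

Counts are standardized per cluster with the sample SD (n − 1; the
convention is configurable since unstated). PCA runs on the covariance of
the standardized matrix; components are ordered by eigenvalue and the
eigensign is fixed so each component's ERG loading is ≥ 0 (ties broken by
the next cluster), making outputs comparable across runs. Individuals are
sorted by their projection onto component 2 by default — in the study this
models, the second component was *observed* to separate phenotype-class
burden profiles; because that was a data-driven observation rather than a
rule, `component_separation()` also reports which component best separates
any supplied subgroup labels. For rendering, each individual's row is
centered on its own mean (`center_rows()`), so heatmap rows sum to zero.

The study's reported loadings (ERG .35, Structure .16, Bang −.69, Heat
−.61, 32 % of variance) depend on its unavailable cohort; the package's
recovery experiment checks only the qualitative pattern — ERG/Structure
loadings sharing a sign opposite to Bang/Heat, with strong subgroup
separation — on simulated two-subgroup cohorts.

# The synthetic-data generator

The generator's defaults are the study conditions: 26 %/19 % control
impairment, 60 % primary cutoff, 2 heads per genotype, 5 × 5 ERG design,
climbing days 5–18 with 6 (tau) or 9 (amyloid-β) timepoints and 4 vials,
phenotype prevalences equal to the screen's observed rates (18 % structure,
35 % ERG, 7 % heat, 3 % bang, 22 %/9 % tau/amyloid-β modifiers, 32 %
lethal with 9 % unrescuable). Where the source reports no value the
defaults are documented stand-ins, not estimates:

* vacuole counts are Poisson with mean 5 (normal) vs 25 (degenerating),
  giving clean separation around the ≥ 15 rule so that sensitivity and
  specificity are testable;
* ERG noise is Gaussian, SD 0.5 mV on a 10 mV plateau;
* climbing declines from 10 mm/s at day 5 by 0.5 mm/s/day, with a 0.3 mm/s
  vial random intercept and 0.5 mm/s residual; the default modifier effect
  is a −1.5 mm/s shift;
* cohort dosages are Binomial(2, f) with baseline f = 0.3 and subgroup
  enrichment to f = 0.5 at enriched clusters.

All randomness flows from one root seed through named substreams, one per
table, so any single table can be regenerated in isolation and identical
configurations are byte-identical.

What the generator does **not** emulate: trace drift and electrode
artifacts, non-Poisson overdispersion of vacuole counts, batch effects
beyond the vial intercept, age-dependent variance changes, linkage
disequilibrium between cohort SNPs, relatedness, or ancestry
structure. Passing recovery tests therefore demonstrates that the
*machinery* is correct and well calibrated under the assumed data model,
not that real screen data would behave this well.

# Numerical choices and degenerate inputs

* Holm adjustment caps at 1 and enforces monotone non-decreasing adjusted
  values; it matches a brute-force step-down enumeration on all
  permutations of up to six p-values.
* Dunn z uses mid-ranks and the Σ(t³−t) tie correction; degenerate
  (all-tied) batches return z = 0, p = 1 with a flag.
* Perfect-separation fits (zero residual variance) report p = 0 for
  non-zero effects and p = 1 for null effects instead of NaN.
* PCA on rank-deficient input reports zero eigenvalues rather than
  failing; reconstruction from all components is exact to < 1e−8.
* Projection sort order breaks ties by individual id, making the heatmap
  row order fully deterministic.

# Problem sizes used in the shipped experiments

The package's own simulation experiments use: 1,000 replicates for the
null-calibration check of the effect tests; 500 genotypes for the null
stress screen; 200 + 200 genotypes for histology operating
characteristics; 500 genes × 2 strains (10 % true enhancers) for modifier
recovery; 1,000 null and 200 effect genotypes for ERG calibration and
power; and 50 seeded replicates of the 100-individual, 40-SNP two-subgroup
cohort. These sizes give Monte-Carlo standard errors comfortably inside
the margins being tested while keeping a full run of the suite and the
acceptance script in the minutes range on a single core.

# Known limitations

* The histology sensitivity margin is intrinsically tight: under the
  Poisson(25), two-head, all-heads-≥15 design the true per-gene
  sensitivity is (1 − F(14; 25))² ≈ 0.957, so finite simulations estimate
  it with visible noise.
* The Dunn test's normal approximation is coarse for very small groups
  (n < 4); the package reports it faithfully but exact permutation tests
  are the better tool at those sizes (they serve as the test oracle here).
* Batch composition affects Dunn families: comparing many strong mutants
  against one shared control in a single batch dilutes rank separation.
  The package analyzes whatever batch it is handed; batching policy is the
  caller's scientific decision.
* The modifier pipeline assumes vial means as the observational unit and
  ignores within-vial fly-to-fly variance, as does the assay it models.
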