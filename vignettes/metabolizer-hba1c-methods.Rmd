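---
title: "Metabolizer phenotyping and HbA1c association: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolizer phenotyping and HbA1c association: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypmeta)
```

This vignette is the package's own account of the science it implements:
the classification model, the regression model, the simulator that stands
in for restricted biobank data, and the design decisions taken where the
underlying methodology left room.

## 1. Star-allele calling

A *star allele* is a named haplotype of a pharmacogene defined by a set of
variants and carrying a functional annotation. The matcher treats a phased
haplotype as a vector of alternate-allele indicators over the definition
table's variant sites and calls the allele whose defining variants are all
present. Three rules close the gaps the nomenclature itself leaves open:

* **Wild-type default.** A haplotype matching no non-reference allele is
  called \*1. This is the standard convention for finite SNP panels, and it
  has a known cost: variants the panel does not type inflate the wild-type
  share. The matcher therefore counts missing genotypes at defining sites
  (`missing_defining_sites`) so the misclassification risk is visible.
* **Most-specific match.** When several alleles fully match, the allele
  with the most defining variants wins. This resolves genuine subset
  relations in the nomenclature — the bundled CYP2D6 panel defines \*4 by
  rs1065852 + rs3892097 and \*10 by rs1065852 alone, so a \*4 haplotype
  always also "matches" \*10; specificity picks \*4, which is how reference
  callers in this field behave.
* **Conservative tie-break.** Among equally specific full matches the
  lowest-activity allele is chosen (biasing toward detecting impaired
  metabolism, the clinically actionable direction), then the lowest allele
  name so calls are invariant to table row order. Every such tie is
  flagged in the call.

Missing genotypes are treated as reference: an unobserved site cannot
support a match. The alternative (dropping the haplotype) would discard
samples for sites that are mostly irrelevant to any given allele.

The bundled definition tables are a deliberately minimal reconstruction —
real rsIDs, GRCh37 coordinates, CPIC-style function classes — covering
CYP2D6 \*1/\*3/\*4/\*6/\*9/\*10/\*17/\*41 and CYP2C19 \*1/\*2/\*3/\*17.
They are shipped as editable TSVs with a JSON sidecar (gene, build,
extraction region: gene ± 1 Mb) and validated on load (exactly one \*1 with
no defining variants; unique allele names; activity consistent with
function class; variants inside the region). Copy-number and hybrid
alleles (\*5, duplications) are out of scope: without CNV input they
cannot be detected, and consequently no CYP2D6 ultra-rapid calls are made —
the phenotyper refuses increased-function CYP2D6 alleles rather than
binning them silently.

## 2. Phenotype translation

**CYP2D6** uses the Gaedigk activity score: each allele contributes 0 (no
function), 0.5 (decreased) or 1 (normal), and the diplotype score is the
sum, giving \{0, 0.5, 1, 1.5, 2\} without CNV alleles. The default bins
are 0 → PM, 0.5–1 → IM, 1.5–2 → NM. An alternative `"legacy"` scheme
(score 1 → NM) is selectable because guidance has shifted over time on
whether a single functional allele is "intermediate" or "normal"; the
choice moves a large group (\*1/\*4 heterozygotes and similar), so it is a
configuration option rather than a constant.

**CYP2C19** is classified from the pair of function classes directly:
none/none → PM, none/normal → IM, normal/normal → NM, normal/increased →
RM, increased/increased → UM. The none/increased combination (e.g.
\*2/\*17) is not determined by first principles; the package follows the
CPIC convention of IM and exposes `none_increased = "RM"` for sensitivity
analyses.

## 3. Variant and sample QC

Common variants must pass MAF ≥ 0.01 and imputation information ≥ 0.3.
Because the variants defining impaired-function star alleles are mostly
rare, a blanket MAF filter would delete the signal of interest; rare
star-allele-defining imputed variants are therefore rescued at the
stricter information threshold of 0.6, and rare genotyped variants pass
only with an upstream intensity-cluster review flag (the review itself is
a manual step outside the package).

Sample exclusions apply one primary reason per sample in a fixed order:
missingness > 0.10, reported/genetic sex mismatch, excess relatedness,
then pairwise kinship pruning at kinship > 0.083. Kinship pruning is
greedy: repeatedly remove the sample in the most surviving over-threshold
pairs (ties by sample id) until none remains. "Remove one of each pair"
underdetermines the result; greedy highest-degree removal is the standard
max-retention choice and, on chains like A–B, B–C, keeps two of three
where naive pair-wise removal could keep one. Pruning runs on the full
input sample set by default (before any medication-based restriction);
this is configurable, since the order is not dictated by the design.

## 4. Cohort construction

Medication strings are harmonized case-insensitively through a synonym
table (proprietary → generic); unmatched names pass through and are
logged, never dropped. Participants reporting antidiabetic medication
while denying diabetes are excluded (diagnostic uncertainty), as are
records without HbA1c. Cohorts are then: one cohort per antidepressant
with ≥ 1800 takers (count and comparator configurable, and the drug list
can be pinned to reproduce a given grouping exactly); a grouped tricyclic
cohort excluding amitriptyline, whose frequency would otherwise dominate;
and one grouped cohort of CYP2D6-substrate antipsychotics. Tricyclic
models include both genes' phenotypes simultaneously because tertiary
amine TCAs are metabolized sequentially by CYP2C19 then CYP2D6; no
gene-by-gene interaction is fitted. A participant taking several study
drugs joins every matching cohort.

The shipped substrate and inhibitor lists are editable fixtures assembled
from standard prescribing references. The inhibitor lists deliberately
omit index study drugs that are themselves inhibitors (paroxetine,
fluoxetine): flagging a cohort's own drug would make the inhibitor
covariate constant within that cohort; `flag_inhibitors(exclude = ...)`
generalizes this.

## 5. The association model

For each cohort, ordinary least squares:

$$\mathrm{HbA1c}_i = \beta_0 + \beta_D D_i + \sum_k \beta_k P_{ik}
 + \sum_k \gamma_k D_i P_{ik} + \mathbf{x}_i^\top \boldsymbol\delta + \varepsilon_i$$

with $D$ diabetes status, $P_{ik}$ indicator contrasts of metabolizer
phenotype against the NM reference, and $\mathbf{x}$ the covariates
(antidiabetic treatment, inhibitor exposure, BMI, age, sex, ancestry
group with the largest group as reference). Inference is classical OLS
with Wald 95% intervals and two-sided p-values, consistent with the
symmetric intervals reported in this literature; heteroskedasticity-robust
(HC1) standard errors are available via `robust = TRUE` but off by
default. If any phenotype-by-diabetes interaction has p < 0.05 (strict),
the model is refit separately in the diabetic and non-diabetic strata
without the diabetes main effect or interactions. Missing covariates are
handled complete-case within cohort, with counts recorded on the fit.

Degenerate inputs are explicit errors, not silent repairs: phenotype
levels with no members are dropped with a warning, covariates constant
within a cohort are removed from the design (recorded on the object),
remaining aliased coefficients raise an error naming the collinear
columns, and strata smaller than the parameter count fail with the
stratum's name. The significance machinery keeps two analysis families:
grouped analyses at 0.025 (suggestive 0.05) and single-drug analyses at
0.05/6 (suggestive 0.1/6). Exact fractions are used rather than the
rounded 0.0083/0.017, so the label of a p-value printed as exactly 0.017
depends on digits not shown; raw p-values are always reported alongside.

## 6. The synthetic-data generator

The simulator emulates a biobank extract end to end. Haplotypes are two
independent draws per gene from configured star-allele frequencies
(Hardy–Weinberg equilibrium, i.e. random mating, no LD structure beyond
each allele's defining variants, no genotyping error); they are rendered
into a phased plain-text VCF and can be round-tripped through the standard
reader with exact diplotype agreement. Covariates follow the cohort
description the package targets: age uniform on 40–70 years, BMI normal
with mean 28.8 and SD 5.66 kg/m², 68.9% female, an ancestry mix dominated
by the European group. Medications are independent per-drug Bernoulli
draws, with 10% of recorded names replaced by proprietary synonyms to
exercise normalization, and an exact configurable count of
antidiabetic-without-diabetes records to exercise the exclusion rule.
HbA1c is $y = X\beta + \varepsilon$ with normal errors, clipped to the
assay's analytical range of 15–184 mmol/mol; clip events are counted
because clipping biases extreme settings. Default generative effects put
the diabetes shift at 6.85 and the PM shift at 2.43 mmol/mol with an
intercept placed so the mean lands near 37.1 mmol/mol.

What passing tests on simulated data do **not** show: robustness to LD
between defining variants, to phasing or imputation error, to
phenoconversion (inhibitor-induced phenocopying is modelled only as a
covariate, not as a phenotype reassignment), or to the self-report noise
of real medication data. The simulator validates the machinery, not the
epidemiology.

## 7. Parameter-recovery references

The headline coefficients this package re-implements come from
restricted-access data, so correctness is checked by parameter recovery:
`recovery_reference()` stores four published cohort designs (sizes,
phenotype-level counts, diabetic counts, reported coefficients, reported
adjusted R²); `simulate_recovery_cohort()` regenerates a cohort with
those exact counts, unreported nuisance coefficients fixed at plausible
values (BMI 0.35 mmol/mol per kg/m², age 0.08 per year, sex −0.3,
antidiabetic 8.0, inhibitor 0.3, small ancestry offsets), and residual SD
derived per replicate from the reported adjusted R² as
$\sigma = \sqrt{\operatorname{var}(X\beta)(1-R^2)/R^2}$; `run_recovery()`
averages fitted coefficients over replicates. Because OLS is unbiased
under correct specification, recovery does not depend on the nuisance
choices — they only set realistic signal-to-noise. For interaction
designs, diabetes assignment is redrawn until every phenotype-by-diabetes
cell has at least two members so the interaction is always estimable
(the expected smallest cell has ≈ 10 members; redraws are rare).

Problem sizes used by the packaged checks: 500 replicates for the two
pooled designs (n = 1930 and n = 1887) and 1000 replicates for the two
diabetic strata (n = 182 and n = 426); the coverage property uses 2000
replicates of the n = 182 design and requires the empirical 95% CI
coverage to sit within ±2% of nominal. These sizes give Monte-Carlo SEs
an order of magnitude below the coefficients being recovered while
keeping a full run in well under a minute on one CPU.

## 8. Known limitations

* No CNV/hybrid alleles, hence no CYP2D6 UM group and no \*5 deletions;
  suballeles (\*4.001 vs \*4.013) are not distinguished.
* The wild-type default overcalls \*1 when panels are sparse; the count of
  missing defining sites is the honest signal to watch.
* Inhibitor exposure is a binary covariate; dose, duration and inhibitor
  potency are absent, so phenoconversion is not modelled.
* Ancestry enters as a label; the package neither infers it nor models
  within-label structure, and per-ancestry allele frequencies are the
  user's responsibility in simulation.
* The association stage is cross-sectional OLS; no longitudinal or
  dose–response structure.
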