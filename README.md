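# cypmeta

Pharmacogenomic metabolizer phenotyping and HbA1c association modelling for
CYP2D6 and CYP2C19.

Antidepressants and antipsychotics are cleared mainly by the cytochrome P450
enzymes CYP2D6 and CYP2C19, and both genes are highly polymorphic. People
whose diplotypes predict impaired enzyme function ("poor" or "intermediate"
metabolizers) reach higher drug exposures at standard doses, which may
translate into adverse metabolic effects such as impaired glycemic control.
`cypmeta` implements the full analysis pipeline needed to test that question
in a biobank-style cohort:

1. **Star-allele diplotype calling** — phased haplotypes are matched against
   a star-allele definition table (variant → allele → function class);
   haplotypes carrying no allele-defining variant default to wild-type
   (\*1). When several alleles fully match, the most specific (most
   defining variants) wins, then the least functional.
2. **Metabolizer phenotyping** — CYP2D6 phenotypes come from the Gaedigk
   activity score, the sum of the two alleles' activity values
   (0 = no function, 0.5 = decreased, 1 = normal): score 0 → PM,
   0.5–1 → IM, 1.5–2 → NM. CYP2C19 phenotypes come from the pair of
   function classes: PM (none/none), IM (none/normal), NM (normal/normal),
   RM (normal/increased), UM (increased/increased). Without copy-number
   data, CYP2D6 ultra-rapid metabolizers cannot be assigned and
   increased-function CYP2D6 input is refused rather than mis-binned.
3. **Post-imputation QC** — common variants kept at MAF ≥ 1% and
   imputation information ≥ 0.3; rare star-allele-defining imputed variants
   rescued at information ≥ 0.6; sample exclusion on missingness > 10%,
   sex mismatch, excess relatedness, and greedy kinship pruning at
   kinship > 0.083 (third-degree relatives).
4. **Cohort building** — free-text medication names harmonized to generics,
   enzyme-inhibitor exposure flagged, participants on antidiabetic
   medication without a diabetes diagnosis excluded, and drug-defined
   cohorts assembled (single-drug cohorts above a 1800-participant
   threshold, a grouped tricyclic cohort excluding amitriptyline, a grouped
   CYP2D6-substrate antipsychotic cohort).
5. **Association modelling** — for each cohort, OLS of HbA1c (mmol/mol) on
   metabolizer phenotype (NM reference) and diabetes status with their
   interaction, adjusted for antidiabetic treatment, inhibitor exposure,
   BMI, age, sex and ancestry:

   `HbA1c ~ phenotype * diabetes + antidiabetic + inhibitor + BMI + age + sex + ancestry`

   A significant interaction (p < 0.05) triggers diabetes-stratified
   refits. Verdicts use nested multiple-testing thresholds: 0.05/2
   (grouped analyses) and 0.05/6 (single-drug analyses), with suggestive
   thresholds 0.1/2 and 0.1/6.
6. **Synthetic cohorts** — a fully deterministic simulator draws phased
   haplotypes from star-allele frequencies under Hardy–Weinberg
   equilibrium, writes them as phased VCF, assigns medications and
   covariates, and generates HbA1c from the linear model above, so the
   whole pipeline is testable without restricted biobank data.

The package is aimed at pharmacogenetics/biostatistics analysts who want a
tested, reusable implementation of this design rather than one-off scripts.

## Worked example

```r
library(cypmeta)

# star-allele matching: a haplotype carrying rs1065852 + rs3892097 is *4,
# not the less specific *10 (defined by rs1065852 alone)
d6 <- load_allele_definitions(cyp_fixture_path("CYP2D6"))
hap <- setNames(rep(0L, nrow(d6$sites)), d6$sites$id)
hap[c("rs1065852", "rs3892097")] <- 1L
match_haplotype(hap, d6)
#> Haplotype call: *4 (2 defining variants matched)

# simulate a cohort and fit the association model
cfg <- sim_config(n_participants = 5000, seed = 2026)
sim <- simulate_cohort(cfg)
fit <- fit_hba1c_model(sim$participants, genes = "CYP2D6",
                       interaction = FALSE, cohort_label = "simulated cohort")
fit
#> HbA1c metabolizer-phenotype model (simulated cohort)
#>   genes:CYP2D6
#>                     term    n estimate           CI        p
#>              (Intercept)   NA   20.486 19.15, 21.82  < 1e-16
#>                 Diabetes  481    6.488   5.54, 7.43  < 1e-16
#>                CYP2D6 IM 1703    0.481   0.14, 0.82  0.00585
#>                CYP2D6 PM  202    2.879   2.05, 3.70 8.43e-12
#>       Takes antidiabetic  332    9.007  7.89, 10.13  < 1e-16
#>                      bmi   NA    0.370   0.34, 0.40  < 1e-16
#>                      age   NA    0.084   0.07, 0.10  < 1e-16
#>                  sexMale   NA   -0.446 -0.79, -0.10  0.01126
#>  ...
#> Observations: 5000   R2/R2 adjusted: 0.388/0.387
```

The simulator's default generative truth puts the poor-metabolizer shift at
2.43 mmol/mol and the diabetes shift at 6.85 mmol/mol; the fitted PM
estimate above (2.88, 95% CI 2.05–3.70) recovers it within sampling error,
and `apply_thresholds(fit, family = "single_drug")` labels the PM term
significant at the 0.05/6 threshold.

An end-to-end run (simulate → QC → phenotype → cohorts → association, with
per-stage logs and a reproducibility manifest) is one call:

```r
run_pipeline(list(out_dir = "run1", seed = 11,
                  simulate = list(n_participants = 2000),
                  cohorts = list(single_drug_min = 200)))
```

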