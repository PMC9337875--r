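# fhscreen

Population screening for familial hypercholesterolemia (FH) from biobank
genotypes and phenotypes.

FH is an autosomal disorder of LDL-cholesterol clearance: carriers of a
pathogenic variant in an FH gene (most often `LDLR`, also `APOB`, `PCSK9`
and a longer candidate panel) run untreated LDL-C several mmol/L above the
population mean and face premature coronary disease. It is common — on the
order of 1 in 250 heterozygous carriers in European populations, more in
consanguineous populations — and heavily underdiagnosed. Given a cohort
with both a multi-sample VCF over an 11-gene FH panel and per-subject
questionnaire/lipid phenotypes, `fhscreen` runs the full screen:

* **QC** — variant filters (call rate ≥ 0.98, Hardy-Weinberg χ² p ≥ 1e-10,
  mean depth ≥ 10×, MAF < 0.005), sample filters (call rate ≥ 0.95,
  heterozygosity within ±3 sd), and analysis-cohort assembly (drop missing
  LDL-C, then hypothyroid subjects).
* **Untreated LDL-C** — back-correction for lipid-lowering therapy,
  `LDL_untreated = LDL_measured / (1 − r)`, with `r` from an editable
  drug/dose factor table and a minimum-dose fallback when the dose is
  unrecorded.
* **Pathogenicity** — *known pathogenic* = asserted pathogenic/likely
  pathogenic (ClinVar, LOVD) or `DM`/`DM?` (HGMD) by **≥ 2 of the 3
  databases**; *possibly pathogenic* = CADD > 20 **and** HC-penetrance
  ≥ 50% among the remainder.
* **Penetrance** — per variant, the percentage of carriers with untreated
  LDL-C > 3.3 mmol/L, on medication, or self-reporting hypercholesterolemia
  (HC-penetrance), and the percentage with a phenotype-only DLCN score ≥ 3
  (DLCN-penetrance).
* **DLCN scoring** — Dutch Lipid Clinic Network points from questionnaire
  fields: family history (1), premature MI/angina (2), untreated LDL-C
  bands (0/1/3/5/8 at edges 4.0/5.0/6.5/8.5 mmol/L), DNA evidence (8);
  categories unlikely (< 3), possible (3–5), probable (6–8), definite
  (> 8), scored with and without genetics so reclassification is explicit.
* **Prevalence & burden** — percentage and "1 in N" prevalence, distinct-
  carrier prevalence per variant class, characteristics tables
  (Welch t / Fisher exact vs the unlikely group), and gene-collapsed
  carrier burden tests by logistic regression with automatic
  Firth-penalized fitting under separation.

A synthetic-cohort generator (`sim_config()` / `generate_cohort()`)
reproduces the statistical structure of such a biobank — rare heterozygous
carriers, carrier LDL shifts, a treatment model the correction inverts
exactly, noisy self-report — so every stage is testable against known
ground truth. See the methods vignette
(`vignettes/fh-screening-methods.Rmd`) for the model, the questionnaire →
DLCN mapping, and the design decisions.

## Worked example

```r
library(fhscreen)
library(dplyr)

cfg    <- sim_config(n_subjects = 8000, seed = 42)
cohort <- generate_cohort(cfg)

phen <- build_analysis_cohort(cohort$phenotypes)   # 7,932 of 8,000 retained
phen <- correct_ldl(phen, cfg$correction_table)

assess <- assess_variants(cohort$variants, cohort$genotypes,
                          cohort$annotations, phen)
assess |> select(gene, rsid, class, n_het, maf, dlcn_penetrance, hc_penetrance)
#>   gene  rsid         class               n_het     maf dlcn_penetrance hc_penetrance
#> 1 LDLR  rs1064793799 known_pathogenic        9 5.67e-4            88.9         100
#> 2 LDLR  rs771019366  known_pathogenic        3 1.89e-4            66.7         100
#> 3 PCSK9 rs891322948  known_pathogenic        1 6.30e-5           100           100
#> 4 APOB  rs775231207  possibly_pathogenic     3 1.89e-4             0           100
#> 5 LDLR  <NA>         other                   0 0                  NA            NA
#> 6 APOE  <NA>         other                   3 1.89e-4             0            66.7
```

Three variants meet the two-database rule; all their carriers show the
high-cholesterol phenotype (HC-penetrance 100%), while 67–100% already
reach DLCN ≥ 3 on phenotype alone. Scoring the cohort twice shows what
genetic testing adds:

```r
path_ids <- assess |> filter(class == "known_pathogenic") |> pull(variant_id)
carriers <- rownames(cohort$genotypes)[
  rowSums(cohort$genotypes[, path_ids, drop = FALSE] >= 1) > 0]

dlcn <- dlcn_score(phen, carriers = carriers)
table(phenotype_only = dlcn$category_phenotype, with_genetics = dlcn$category)
#>               with_genetics
#> phenotype_only unlikely possible probable definite
#>       unlikely     7851        0        0        2
#>       possible        0       68        0        7
#>       probable        0        0        0        4
#>       definite        0        0        0        0

estimate_prevalence(dlcn)   # definite or probable FH
#>   n_cases n_cohort percent one_in_n
#> 1      13     7932   0.164      610
```

Thirteen carriers are reclassified upward by DNA evidence — the screen's
central point: none of them were definite on phenotype alone. The
definite/probable prevalence in this small synthetic cohort is 0.16%
(1 in 610); the generator's default variant panel carries fewer pathogenic
variants than a real population would. Finally, the gene-collapsed burden
test recovers the carrier–hypercholesterolemia association:

```r
phen$hc <- (!is.na(phen$selfreport_hc) & phen$selfreport_hc) |
  phen$on_lipid_med | phen$ldl_untreated > 3.3
burden_scan(assess, cohort$genotypes, phen) |> select(-fit)
#>   gene  n_variants n_carriers  beta    se         p method
#> 1 LDLR           2         12  3.46  1.50 0.0000240 firth
#> 2 PCSK9          1          1  1.28  2.31 1         firth
#> 3 APOB           1          3  2.21  1.75 0.0795    firth
```

`LDLR` carriers are strongly associated (log-odds 3.5, p = 2.4e-5, Firth
fit because every carrier is affected); single-carrier genes are reported
but carry no power.

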