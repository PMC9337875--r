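---
title: "Population screening for familial hypercholesterolemia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population screening for familial hypercholesterolemia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhscreen)
library(dplyr)
```

## The problem

Familial hypercholesterolemia (FH) is an autosomal disorder of LDL
cholesterol clearance. Carriers of a pathogenic variant in an FH gene —
most often `LDLR`, less often `APOB` or `PCSK9` — run untreated LDL-C
several mmol/L above the population mean and face premature coronary
disease; heterozygous FH affects on the order of 1 in 250 people in
European populations, more in consanguineous or founder populations, and
it is heavily underdiagnosed. A population biobank that has both
whole-genome genotypes and questionnaire/lipid phenotypes allows FH to be
screened in both directions at once: clinically, by scoring each subject
with the Dutch Lipid Clinic Network (DLCN) criteria, and genetically, by
scanning a panel of FH genes for rare pathogenic variants and measuring
how penetrant they are in unselected carriers.

`fhscreen` implements that screen as a set of composable, data-frame-first
steps:

1. **synthetic cohort** (`sim_config()`, `generate_cohort()`) — a generative
   model of the cohort, used for testing and power exploration;
2. **I/O** (`read_phenotypes()`, `read_vcf_genotypes()`,
   `read_annotations()`) — the three tabular inputs;
3. **QC** (`filter_variants()`, `filter_samples()`,
   `build_analysis_cohort()`);
4. **LDL correction** (`correct_ldl()`);
5. **pathogenicity and penetrance** (`is_known_pathogenic()`,
   `is_possibly_pathogenic()`, `hc_penetrance()`, `dlcn_penetrance()`,
   `assess_variants()`);
6. **DLCN scoring** (`dlcn_score()`, `classify_dlcn()`);
7. **prevalence and burden** (`estimate_prevalence()`,
   `carrier_prevalence()`, `characteristics_table()`, `burden_test()`,
   `burden_scan()`).

## Variant and sample QC

Variant-level filters are a conjunction with the conventional thresholds of
biobank sequencing QC: call rate at least 98%, Hardy-Weinberg equilibrium
chi-square p at least 1e-10, mean depth of coverage at least 10x, and minor
allele frequency below 0.005 — a screen for a roughly 1-in-200 condition
should not be looking at common variation. The HWE test is the plain 1-df
chi-square of observed genotype counts against expectations from the allele
frequencies; monomorphic sites pass by definition (`chi2 = 0`, `p = 1`),
since a site with no variation carries no evidence of genotyping error.
Because the filters are a conjunction, their order cannot change the
retained set; the exclusion log reports the *first* failing filter per
variant in the fixed order call rate, HWE, depth, MAF.

Sample-level filters drop call rate below 95% and heterozygosity beyond 3
standard deviations of the cohort mean (a conventional excess-heterozygosity
cutoff; the multiplier is configurable). When the cohort heterozygosity is
constant the standard deviation is zero and nobody is excluded — the guard
matters for small or degenerate panels. Sex-ambiguity exclusions are
consumed as a precomputed flag: inferring sex needs X-chromosome data that
an autosomal FH panel does not carry.

`build_analysis_cohort()` then applies the phenotype exclusions in a fixed,
logged order: subjects without an LDL-C measurement first, then subjects
with hypothyroidism (which raises LDL-C secondarily and would contaminate
an FH screen). A subject failing both is logged once, under the first
reason. Genotype QC is applied before these phenotype exclusions, so
penetrance denominators and prevalence denominators always refer to the
same analysis cohort.

## Untreated LDL-C

DLCN LDL bands and the high-cholesterol penetrance criterion are defined on
*untreated* LDL-C. For subjects on lipid-lowering therapy the measured value
is back-corrected by dividing by `1 - r`, where `r` is the proportional
reduction expected for their drug and dose — the standard inversion of a
correction-factor table. The shipped table covers common statins and
statin+ezetimibe combinations with reductions between 0.18 and 0.58 and is
an editable configuration file, not ground truth. Two fallbacks are built
in and flagged per row: a missing dose uses the drug's *minimum* listed dose
(deliberately conservative — it under-corrects rather than inflating the
phenotype), and a missing or unlisted drug can use a configurable default
reduction; with no default configured it is an error, because silently
skipping correction would bias every downstream score. Combination
preparations are handled as their own table rows rather than by modelling
interactions.

## Pathogenicity classes

A variant is **known pathogenic** when at least two of the three assertion
databases support it — ClinVar or LOVD with a pathogenic/likely-pathogenic
label, HGMD with `DM` or `DM?`. Composite labels such as `P/LP/VUS`
(several submitters, several interpretations) count as support, because at
least one qualifying assertion exists. The two-database quorum trades
sensitivity for robustness against a single database's misclassification.

A variant that fails that rule is **possibly pathogenic** when its CADD
PHRED score is above 20 (the top 1% most deleterious substitutions
genome-wide) *and* its high-cholesterol penetrance among carriers is at
least 50%. The penetrance boundary is inclusive: with the very small
carrier counts typical of rare variants, half-affected (1 of 2, 2 of 4) is
a common and informative configuration, and an exclusive boundary would
discard exactly those rows. The CADD boundary is exclusive (a score of
20.0 does not qualify). Variants absent from every database — novel,
population-specific variants are expected in underrepresented populations —
remain eligible for this class whenever a CADD score is available.
Known-pathogenic status is evaluated first and wins: the classes partition
the variant set.

Two penetrance statistics are computed per variant, both as percentages of
carriers, reported to one decimal:

* **HC-penetrance**: untreated LDL-C > 3.3 mmol/L, OR on lipid-lowering
  medication, OR self-reported hypercholesterolemia. Missing components
  count as not met. The LDL threshold is applied to the medication-corrected
  value; for treated subjects the medication branch makes the choice
  immaterial.
* **DLCN-penetrance**: phenotype-only DLCN score of at least 3. The 8
  genetic-evidence points are excluded on purpose — every carrier would
  otherwise score at least 8 and the statistic would be identically 100%.

Zero-carrier variants have *undefined* penetrance (`NA`), which is not the
same thing as 0%: the first says "no data", the second says "carriers are
unaffected".

## DLCN scoring from questionnaire phenotypes

The DLCN criteria were designed for lipid clinics; mapping them onto
biobank questionnaire fields is the screen's central unstated step, and
every mapping here is explicit and overridable:

* **Family history (1 point)**: father or mother with heart disease,
  regardless of onset age (the questionnaire does not record it). The
  2-point family item needs relatives' examinations and lipid values, which
  population questionnaires do not collect; it is always 0. Within the
  group the score is the maximum eligible item, not a sum.
* **Clinical history (2 points)**: myocardial infarction or angina before
  the sex-specific premature-CHD age (55 for males, 60 for females, the
  standard DLCN convention). An event without a recorded age uses the
  subject's current age as a conservative upper bound. The 1-point
  peripheral/cerebral vascular disease item is not collected; always 0.
* **Untreated LDL-C band**: below 4.0 mmol/L scores 0; 4.0–4.9 scores 1;
  5.0–6.4 scores 3; 6.5–8.4 scores 5; 8.5 and above scores 8. Bands are
  left-closed (4.0 scores 1), consistent with treating 4.0 mmol/L as the
  threshold *below* which no LDL points accrue.
* **Physical signs** (tendinous xanthomas, arcus cornealis) are not
  recorded in questionnaire cohorts and are never scored.
* **DNA evidence (8 points)**: carrying a known pathogenic FH variant.

The maximum attainable total is therefore 1 + 2 + 8 + 8 = 19. Categories
follow the standard cuts: below 3 unlikely, 3–5 possible, 6–8 probable,
above 8 definite. Scoring is run twice — phenotype-only and with genetics —
and both categories are kept per subject, so reclassification is an
explicit, auditable report (`reclassification_report()`) rather than a
diff between two runs. Adding 8 points can only raise a category, which is
asserted as an invariant. A carrier with no phenotypic evidence lands at
exactly 8: probable FH on genetics alone; one additional phenotype point
(an LDL of 4.0, or a parent with heart disease) crosses into definite.

Missing answers contribute 0 points for their component — an unanswered
question is absence of evidence, and the DLCN score is a sum of positive
evidence.

## Prevalence and burden

Prevalence is reported as a percentage and in the conventional "1 in N"
form, with N rounded half away from zero (13,677 / 109 = 125.5 reports
1 in 125). Carrier prevalence counts *distinct* subjects carrying at least
one variant of a class, so a double carrier is not double-counted.
Characteristic tables report continuous traits as mean ± sd with a Welch
t-test against the unlikely-FH reference group (the pooled-variance test is
available by flag) and binary traits as count (%) with Fisher's exact test;
raw p-values are starred at 0.05 with no multiple-testing correction, and
the table notes as much.

The gene-based burden test collapses all pathogenic and possibly-pathogenic
variants in a gene into one carrier indicator and fits a logistic
regression of hypercholesterolemia status on it, adjusting for age, sex and
the first four genetic principal components (taken as given covariates).
Relatedness is not modelled: a mixed-model machinery with a genomic
relationship matrix is out of scope here, so the test assumes approximately
unrelated subjects and its p-values should be read accordingly in strongly
consanguineous cohorts. Rare-variant burdens routinely separate the data —
a handful of carriers, all affected — where maximum-likelihood estimates
diverge; on detected separation (or on request) the fit switches to
Firth-penalized logistic regression (Jeffreys-prior penalty, Newton
iterations on the modified score with step-halving), whose estimates stay
finite. The reported p-value is a (penalized) likelihood-ratio test of the
carrier term, which is better calibrated than the Wald test in the
rare-carrier regime; the permutation-null calibration of its type-I error
is part of the test suite.

## The synthetic cohort: what it does and does not emulate

The generator draws, per subject: untreated LDL-C from a Gaussian
(mean 3.02, sd 0.82 mmol/L, truncated at 0.5) plus an additive per-variant
carrier shift; heterozygous carrier status per variant as Bernoulli(2·MAF)
(a Hardy-Weinberg mode draws Binomial(2, MAF) genotypes to exercise the
homozygote path — the default is heterozygous-only, matching what rare-FH
screens actually find); lipid-lowering therapy from a logistic model on
untreated LDL-C, with drug and dose drawn from the correction table and the
observed LDL-C set to `untreated × (1 − r)` so that `correct_ldl()` inverts
the treatment model *exactly*; self-reported hypercholesterolemia as a
noisy report (configurable sensitivity 0.80 / specificity 0.95) of the
latent indicator `untreated LDL > 3.3 mmol/L`; plus family-history,
MI/angina, comorbidity, missingness and covariate fields at rates typical
of an adult population biobank (missing LDL 0.77%, hypothyroidism 0.17%,
smoking 17%, male fraction 0.44, age 40 ± 13 truncated to 18–85).

Defaults describe a 13,808-subject cohort; tests run the same model at
hundreds to tens of thousands of subjects, which is enough to exercise
every code path and to check Monte-Carlo expectations while keeping the
default suite fast.

Per-variant LDL effect sizes are not published as mmol/L anywhere usable,
so the defaults (3.0–3.5 mmol/L for pathogenic, 1.5–1.8 for possibly
pathogenic variants) were chosen once to reproduce the kind of group
separation seen between definite-FH and unlikely-FH lipid profiles, and are
not fitted to any cohort.

Deliberate non-goals of the generator: sequencing reads, linkage
disequilibrium between panel variants, kinship and population structure
(the PCs it emits are pure noise), and a heavy-tailed LDL distribution.
The last one matters for interpretation: with a truncated-Gaussian
baseline, phenotype-only definite-FH cases (untreated LDL ≥ 8.5 mmol/L
without a variant) are much rarer than in real cohorts, where the LDL
distribution has a heavier right tail and secondary hypercholesterolemia
abounds. Passing tests on synthetic cohorts therefore demonstrate the
*rules and arithmetic* of the pipeline — carrier detection, correction,
scoring, class assignment, penetrance and prevalence bookkeeping — not the
empirical prevalence structure of any real population.

## Numerical choices and degenerate inputs

* Penetrances and prevalence percentages round half away from zero (so
  11/13 is 84.6, and "1 in N" matches the convention used when such
  numbers are reported); all internal computation is full precision.
* `hwe_chisq` is vectorized, exact on the boundary cases, and agrees with
  an independent closed-form identity to 1e-8 relative tolerance over
  randomized genotype counts.
* The Firth fit declares convergence at a step norm below 1e-8 and guards
  the Newton step with halving against decreases of the penalized
  log-likelihood.
* Burden tests with zero carriers (or all carriers) return a typed
  "no test" result rather than an estimate; zero-variance covariates are
  dropped, which provably cannot change the fit.
* Empty cohorts score to empty tables; missing LDL contributes 0 DLCN
  points; multi-allelic VCF sites are decomposed into biallelic records
  with per-alternate allele counts (a `1/2` call carries one copy of each).

## Known limitations

* The kinship-free burden test overstates significance under strong cryptic
  relatedness.
* The DLCN mapping cannot score the physical-sign and relative-lipid items;
  phenotype-only totals are bounded at 11 rather than the clinic maximum,
  which makes the screen conservative for the definite-by-phenotype
  category.
* Assertion databases disagree; the two-database rule inherits their biases
  and their coverage gaps for non-European populations.
* MAFs are computed over the analysis cohort at hand and are not expected
  to reproduce externally published MAF columns computed on different
  denominators.
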