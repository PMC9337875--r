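# ---- synthetic cohort generator -------------------------------------------
# Emulates a deeply phenotyped adult biobank cohort with rare FH variant
# carriers, so that every downstream stage (QC, LDL correction, pathogenicity
# aggregation, DLCN scoring, prevalence, burden tests) has inputs with known
# ground truth. It does NOT simulate reads, linkage disequilibrium, kinship
# or population stratification.

#' Describe one simulated panel variant
#'
#' Builds a single row of the variant design used by [sim_config()]. Each
#' simulated variant has a truth class (what the generator "knows" it is), a
#' carrier LDL-C effect, and the database assertions that the annotation table
#' will carry for it.
#'
#' @param gene One of the 11 FH panel genes (see `fh_panel()`).
#' @param chrom,pos,ref,alt Site coordinates (GRCh38 convention, 1-based).
#' @param maf Simulated minor allele frequency; must be below 0.005 because
#'   the screen targets rare variants only.
#' @param truth_class `"pathogenic"`, `"possibly_pathogenic"` or `"benign"`.
#' @param ldl_shift Additive shift (mmol/L) on carrier untreated LDL-C;
#'   must be non-negative.
#' @param hgmd,lovd,clinvar Database assertion labels written to the
#'   annotation table (slash-composites such as `"P/LP"` allowed; `"NR"` =
#'   not reported).
#' @param cadd CADD PHRED score written to the annotation table.
#' @param rsid Optional variant identifier; `NA` marks a novel variant.
#' @return A one-row tibble.
#' @export
#' @examples
#' sim_variant("LDLR", pos = 11102789, maf = 4.4e-4, truth_class = "pathogenic",
#'             ldl_shift = 3.5, hgmd = "DM", clinvar = "P", cadd = 25)
sim_variant <- function(gene, chrom = NULL, pos, ref = "A", alt = "C",
                        maf, truth_class = c("pathogenic", "possibly_pathogenic", "benign"),
                        ldl_shift = 0, hgmd = "NR", lovd = "NR", clinvar = "NR",
                        cadd = NA_real_, rsid = NA_character_) {
  truth_class <- match.arg(truth_class)
  panel <- fh_panel()
  if (!gene %in% panel$gene) {
    abort(paste0("Gene '", gene, "' is not in the 11-gene FH panel."))
  }
  if (is.null(chrom)) chrom <- panel$chrom[match(gene, panel$gene)]
  stopifnot(maf > 0 || maf == 0, maf < 0.005, ldl_shift >= 0)
  tibble(
    gene = gene, chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    rsid = rsid, maf = maf, truth_class = truth_class, ldl_shift = ldl_shift,
    hgmd = hgmd, lovd = lovd, clinvar = clinvar, cadd = cadd
  )
}

default_sim_variants <- function() {
  bind_rows(
    # highly penetrant pathogenic splice variant, the most frequent in the screen
    sim_variant("LDLR", pos = 11102789, ref = "A", alt = "C", maf = 4.43e-4,
                truth_class = "pathogenic", ldl_shift = 3.5,
                hgmd = "DM", lovd = "NR", clinvar = "P", cadd = 26,
                rsid = "rs1064793799"),
    # pathogenic missense, moderate effect
    sim_variant("LDLR", pos = 11102742, ref = "A", alt = "G", maf = 2.05e-4,
                truth_class = "pathogenic", ldl_shift = 3.0,
                hgmd = "DM", lovd = "LP", clinvar = "P/LP", cadd = 28,
                rsid = "rs771019366"),
    # pathogenic PCSK9 missense
    sim_variant("PCSK9", pos = 55059529, ref = "G", alt = "T", maf = 6.8e-5,
                truth_class = "pathogenic", ldl_shift = 3.2,
                hgmd = "DM?", lovd = "LP", clinvar = "NR", cadd = 24,
                rsid = "rs891322948"),
    # possibly pathogenic: single-database VUS, deleterious in silico
    sim_variant("APOB", pos = 21012456, ref = "A", alt = "C", maf = 2.3e-4,
                truth_class = "possibly_pathogenic", ldl_shift = 1.5,
                hgmd = "NR", lovd = "NR", clinvar = "VUS", cadd = 21.8,
                rsid = "rs775231207"),
    # novel possibly pathogenic (no rsid, absent from all databases)
    sim_variant("LDLR", pos = 11089574, ref = "G", alt = "A", maf = 1e-4,
                truth_class = "possibly_pathogenic", ldl_shift = 1.8,
                cadd = 22.8),
    # benign rare variant, no lipid effect
    sim_variant("APOE", pos = 44909000, ref = "C", alt = "T", maf = 3e-4,
                truth_class = "benign", ldl_shift = 0,
                hgmd = "NR", lovd = "LB", clinvar = "B", cadd = 3.1)
  )
}

#' Configuration for the synthetic biobank cohort
#'
#' Returns the full parameter set of the cohort generator. The defaults
#' describe an adult population biobank of 13,808 genotyped subjects with
#' questionnaire, medication and fasting-lipid data: baseline untreated LDL-C
#' around 3.0 +/- 0.8 mmol/L, roughly 44% males, low rates of missing lipid
#' profiling (0.77%) and of hypothyroidism (0.17%), and rare heterozygous FH
#' variant carriers at per-variant minor allele frequencies below 0.005.
#'
#' Lipid-lowering therapy is assigned by a logistic model on untreated LDL-C,
#' the drug/dose is drawn from the correction-factor table, and the observed
#' (treated) LDL-C is `untreated * (1 - r)` with `r` the drug/dose reduction
#' fraction, so [correct_ldl()] inverts the treatment model exactly.
#' Self-reported hypercholesterolemia is a noisy report of the indicator
#' `untreated LDL-C > hc_ldl_threshold` with configurable sensitivity and
#' specificity.
#'
#' @param n_subjects Cohort size.
#' @param variants Variant design tibble (rows from [sim_variant()]).
#' @param baseline_ldl_mean,baseline_ldl_sd Untreated LDL-C distribution
#'   (mmol/L), Gaussian truncated below at 0.5 mmol/L.
#' @param hc_ldl_threshold LDL-C (mmol/L) above which a subject "really" has
#'   hypercholesterolemia for the self-report model.
#' @param medication_model Named vector `c(intercept, slope)` for
#'   `P(on therapy) = plogis(intercept + slope * untreated LDL)`.
#' @param selfreport_sensitivity,selfreport_specificity Self-report accuracy.
#' @param selfreport_missing_rate Fraction of subjects with no self-report.
#' @param paternal_hd_rate,maternal_hd_rate Background family-history rates.
#' @param mi_model Named vector `c(intercept, slope)` for the logistic
#'   probability of a myocardial infarction history given untreated LDL.
#' @param angina_rate Background angina rate.
#' @param missing_ldl_rate Fraction of subjects with no LDL-C measurement.
#' @param hypothyroid_rate Fraction flagged hypothyroid (excluded from the
#'   analysis cohort because hypothyroidism secondarily raises LDL-C).
#' @param missing_dose_rate Fraction of treated subjects with a missing dose
#'   (exercises the minimum-dose fallback of [correct_ldl()]).
#' @param male_fraction Fraction of males.
#' @param age_mean,age_sd Age distribution (years), truncated to [18, 85].
#' @param smoker_rate,hypertension_rate,diabetes_rate Background comorbidity
#'   rates.
#' @param hardy_weinberg Draw genotypes as Binomial(2, maf) instead of
#'   heterozygous-only carriers, to exercise the homozygote path. Default
#'   `FALSE`: population screens of this kind find carriers in the
#'   heterozygous state only.
#' @param correction_table Drug/dose reduction-fraction table (see
#'   [fh_correction_table()]).
#' @param mean_dp_range Range of simulated per-variant mean depth of coverage.
#' @param seed Integer seed; the generator is fully reproducible given it.
#' @return A list of class `fh_sim_config`.
#' @export
sim_config <- function(n_subjects = 13808,
                       variants = default_sim_variants(),
                       baseline_ldl_mean = 3.02,
                       baseline_ldl_sd = 0.82,
                       hc_ldl_threshold = 3.3,
                       medication_model = c(intercept = -7.0, slope = 1.5),
                       selfreport_sensitivity = 0.80,
                       selfreport_specificity = 0.95,
                       selfreport_missing_rate = 0.019,
                       paternal_hd_rate = 0.212,
                       maternal_hd_rate = 0.125,
                       mi_model = c(intercept = -7.5, slope = 0.45),
                       angina_rate = 0.002,
                       missing_ldl_rate = 107 / 13808,
                       hypothyroid_rate = 24 / 13808,
                       missing_dose_rate = 0.20,
                       male_fraction = 0.438,
                       age_mean = 39.7, age_sd = 13.1,
                       smoker_rate = 0.168,
                       hypertension_rate = 0.153,
                       diabetes_rate = 0.198,
                       hardy_weinberg = FALSE,
                       correction_table = fh_correction_table(),
                       mean_dp_range = c(28, 42),
                       seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 || n_subjects < 1) {
    abort("n_subjects must be a positive integer.")
  }
  variants <- as_tibble(variants)
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
  if (anyDuplicated(key)) {
    abort("Duplicate variant positions in the simulation design.")
  }
  fracs <- c(selfreport_sensitivity, selfreport_specificity,
             selfreport_missing_rate, paternal_hd_rate, maternal_hd_rate,
             angina_rate, missing_ldl_rate, hypothyroid_rate,
             missing_dose_rate, male_fraction, smoker_rate,
             hypertension_rate, diabetes_rate)
  if (any(fracs < 0 | fracs > 1)) abort("All rate parameters must lie in [0, 1].")
  if (any(variants$maf >= 0.005)) abort("Simulated MAFs must be below 0.005.")
  structure(as.list(environment()), class = "fh_sim_config")
}

#' @export
print.fh_sim_config <- function(x, ...) {
  cat("<fh_sim_config>\n")
  cat("  subjects:", x$n_subjects, " variants:", nrow(x$variants),
      " seed:", x$seed, "\n")
  cat("  baseline LDL-C:", x$baseline_ldl_mean, "+/-", x$baseline_ldl_sd,
      "mmol/L;", if (x$hardy_weinberg) "HWE genotypes" else "heterozygous-only carriers", "\n")
  invisible(x)
}

truncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort under the model described in [sim_config()]: per-variant
#' heterozygous carriers at `2 * maf` (or Hardy-Weinberg genotypes when
#' configured), carrier untreated LDL-C shifted by the variant's effect,
#' treatment assignment and observed LDL-C under the configured medication
#' model, and noisy self-report/family-history/comorbidity fields.
#'
#' @param config An [sim_config()] object.
#' @return A list of class `fh_cohort` with elements `phenotypes` (tibble, one
#'   row per subject), `genotypes` (integer matrix, subjects x variants, allele
#'   counts 0/1/2 with `NA` for missing), `variants` (tibble of site records
#'   incl. per-variant `mean_dp`), `annotations` (assertion table as consumed
#'   by [read_annotations()]), and `truth` (per-subject latent values: untreated
#'   LDL-C before missingness, true HC status and carried effect).
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_subjects = 500, seed = 42))
#' dplyr::glimpse(cohort$phenotypes)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "fh_sim_config"))
  set.seed(config$seed)
  n <- as.integer(config$n_subjects)
  v <- config$variants
  nv <- nrow(v)
  vkey <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

  subject_id <- sprintf("S%05d", seq_len(n))

  # genotypes: heterozygous carriers at 2*maf, or full HWE draws on request
  geno <- matrix(0L, nrow = n, ncol = nv, dimnames = list(subject_id, vkey))
  for (j in seq_len(nv)) {
    geno[, j] <- if (config$hardy_weinberg) {
      rbinom(n, 2L, v$maf[j])
    } else {
      rbinom(n, 1L, 2 * v$maf[j])
    }
  }

  # untreated LDL-C: truncated-Gaussian baseline plus additive carrier shifts
  ldl_untreated <- truncnorm(n, config$baseline_ldl_mean, config$baseline_ldl_sd,
                             lower = 0.5)
  shift <- as.numeric(geno %*% v$ldl_shift)
  ldl_untreated <- ldl_untreated + shift

  # medication: logistic in untreated LDL-C; drug/dose from the correction table
  mm <- config$medication_model
  p_med <- plogis(mm[["intercept"]] + mm[["slope"]] * ldl_untreated)
  on_med <- rbinom(n, 1L, p_med) == 1L
  tab <- config$correction_table
  drugs <- unique(tab$drug)
  med_drug <- rep(NA_character_, n)
  med_dose <- rep(NA_real_, n)
  reduction <- rep(0, n)
  idx <- which(on_med)
  if (length(idx)) {
    pick <- sample(nrow(tab), length(idx), replace = TRUE)
    med_drug[idx] <- tab$drug[pick]
    med_dose[idx] <- tab$dose[pick]
    reduction[idx] <- tab$reduction[pick]
    hide <- idx[runif(length(idx)) < config$missing_dose_rate]
    med_dose[hide] <- NA_real_
  }
  ldl_observed <- ldl_untreated * (1 - reduction)

  # self-report of hypercholesterolemia: noisy report of the latent indicator
  true_hc <- ldl_untreated > config$hc_ldl_threshold
  p_report <- ifelse(true_hc, config$selfreport_sensitivity,
                     1 - config$selfreport_specificity)
  selfreport_hc <- rbinom(n, 1L, p_report) == 1L
  selfreport_hc[runif(n) < config$selfreport_missing_rate] <- NA
  age <- round(truncnorm(n, config$age_mean, config$age_sd, 18, 85))
  age_at_hc_dx <- ifelse(!is.na(selfreport_hc) & selfreport_hc,
                         pmin(age, round(truncnorm(n, 40, 10, 18, 85))),
                         NA_real_)

  # events and comorbidities
  mim <- config$mi_model
  mi_history <- rbinom(n, 1L, plogis(mim[["intercept"]] + mim[["slope"]] * ldl_untreated)) == 1L
  age_at_mi <- ifelse(mi_history, pmax(25, round(age - rexp(n, 1 / 8))), NA_real_)
  angina <- rbinom(n, 1L, config$angina_rate) == 1L

  sex <- ifelse(runif(n) < config$male_fraction, "male", "female")
  phen <- tibble(
    subject_id = subject_id,
    sex = sex,
    age = age,
    bmi = round(truncnorm(n, 29.5, 6.1, 15, 60), 1),
    smoker = rbinom(n, 1L, config$smoker_rate) == 1L,
    hypertension = rbinom(n, 1L, config$hypertension_rate) == 1L,
    diabetes = rbinom(n, 1L, config$diabetes_rate) == 1L,
    hypothyroidism = rbinom(n, 1L, config$hypothyroid_rate) == 1L,
    selfreport_hc = selfreport_hc,
    age_at_hc_dx = age_at_hc_dx,
    on_lipid_med = on_med,
    med_drug = med_drug,
    med_dose = med_dose,
    mi_history = mi_history,
    age_at_mi = age_at_mi,
    angina = angina,
    paternal_heart_disease = rbinom(n, 1L, config$paternal_hd_rate) == 1L,
    maternal_heart_disease = rbinom(n, 1L, config$maternal_hd_rate) == 1L,
    tc = ldl_observed + truncnorm(n, 1.8, 0.4, 0.5),
    hdl = truncnorm(n, 1.4, 0.39, 0.4),
    ldl_measured = ldl_observed,
    tg = truncnorm(n, 1.3, 0.73, 0.2),
    pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n), pc4 = rnorm(n)
  )
  phen$ldl_measured[runif(n) < config$missing_ldl_rate] <- NA_real_

  variants <- tibble(
    variant_id = vkey, chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    gene = v$gene, rsid = v$rsid,
    mean_dp = round(runif(nv, config$mean_dp_range[1], config$mean_dp_range[2]), 1)
  )
  annotations <- tibble(
    variant_id = vkey, gene = v$gene, rsid = v$rsid,
    clinvar = v$clinvar, hgmd = v$hgmd, lovd = v$lovd, cadd = v$cadd
  )
  truth <- tibble(
    subject_id = subject_id,
    ldl_untreated = ldl_untreated,
    ldl_shift = shift,
    true_hc = true_hc,
    reduction = reduction
  )
  structure(
    list(phenotypes = phen, genotypes = geno, variants = variants,
         annotations = annotations, truth = truth, config = config),
    class = "fh_cohort"
  )
}

#' @export
print.fh_cohort <- function(x, ...) {
  cat("<fh_cohort> ", nrow(x$phenotypes), " subjects x ",
      nrow(x$variants), " panel variants\n", sep = "")
  carriers <- sum(rowSums(x$genotypes > 0, na.rm = TRUE) > 0)
  cat("  carriers of >=1 panel variant: ", carriers, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Writes the three standard inputs consumed by the readers in this package:
#' a VCF v4.2 with per-sample GT calls, tab-delimited phenotype and annotation
#' tables, and the generator configuration as a YAML file.
#'
#' @param cohort An [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fh_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    phenotypes = file.path(dir, "phenotypes.tsv"),
    genotypes = file.path(dir, "genotypes.vcf"),
    annotations = file.path(dir, "annotations.tsv"),
    config = file.path(dir, "sim_config.yaml")
  )
  readr::write_tsv(cohort$phenotypes, paths$phenotypes)
  write_vcf_genotypes(cohort$variants, cohort$genotypes, paths$genotypes)
  ann <- cohort$annotations
  ann$cadd[is.na(ann$cadd)] <- NA
  readr::write_tsv(ann, paths$annotations, na = "NR")
  cfg <- cohort$config
  cfg_list <- cfg[setdiff(names(cfg), c("variants", "correction_table"))]
  cfg_list$variants <- purrr::transpose(as.list(cfg$variants))
  yaml::write_yaml(cfg_list, paths$config)
  invisible(paths)
}
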