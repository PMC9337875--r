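# fixtures built in code: minimal subjects, tiny VCFs, toy genotype matrices

# one phenotype row with sensible defaults, any field overridable
make_subject <- function(subject_id = "s1", sex = "female", age = 40,
                         bmi = 28, smoker = FALSE, hypertension = FALSE,
                         diabetes = FALSE, hypothyroidism = FALSE,
                         selfreport_hc = FALSE, age_at_hc_dx = NA_real_,
                         on_lipid_med = FALSE, med_drug = NA_character_,
                         med_dose = NA_real_, mi_history = FALSE,
                         age_at_mi = NA_real_, angina = FALSE,
                         paternal_heart_disease = FALSE,
                         maternal_heart_disease = FALSE,
                         tc = 4.8, hdl = 1.4, ldl_measured = 3.0, tg = 1.3,
                         pc1 = 0, pc2 = 0, pc3 = 0, pc4 = 0,
                         ldl_untreated = NULL) {
  row <- tibble::tibble(
    subject_id = subject_id, sex = sex, age = age, bmi = bmi,
    smoker = smoker, hypertension = hypertension, diabetes = diabetes,
    hypothyroidism = hypothyroidism, selfreport_hc = selfreport_hc,
    age_at_hc_dx = age_at_hc_dx, on_lipid_med = on_lipid_med,
    med_drug = med_drug, med_dose = med_dose, mi_history = mi_history,
    age_at_mi = age_at_mi, angina = angina,
    paternal_heart_disease = paternal_heart_disease,
    maternal_heart_disease = maternal_heart_disease,
    tc = tc, hdl = hdl, ldl_measured = ldl_measured, tg = tg,
    pc1 = pc1, pc2 = pc2, pc3 = pc3, pc4 = pc4
  )
  if (!is.null(ldl_untreated)) row$ldl_untreated <- ldl_untreated
  row
}

make_subjects <- function(n, ...) {
  out <- make_subject(...)[rep(1L, n), ]
  out$subject_id <- sprintf("s%03d", seq_len(n))
  out
}

# write a small VCF from explicit body lines (header supplied)
write_tiny_vcf <- function(body, samples, path = tempfile(fileext = ".vcf")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(hdr, body), path)
  path
}

# independent closed-form HWE 1-df chi-square (algebraic identity, distinct
# from the observed-vs-expected sum used by the package)
hwe_chi2_closed_form <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  denom <- (2 * n_AA + n_Aa)^2 * (2 * n_aa + n_Aa)^2
  if (denom == 0) return(0)
  n * (n_Aa^2 - 4 * n_AA * n_aa)^2 / denom
}

# genotype column helper: counts of 0/1/2/NA expanded to a shuffled vector
geno_vec <- function(n0, n1, n2 = 0, n_na = 0, seed = 1) {
  withr::with_seed(seed, sample(rep(c(0L, 1L, 2L, NA_integer_),
                                    c(n0, n1, n2, n_na))))
}
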