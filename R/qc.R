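# ---- variant & sample QC --------------------------------------------------

#' QC thresholds for a rare-variant panel screen
#'
#' Default thresholds: variants need a call rate of at least 98%, a
#' Hardy-Weinberg equilibrium chi-square p-value of at least 1e-10 and a mean
#' depth of coverage of at least 10x, and only rare variants (MAF < 0.005)
#' are kept — a screen for a condition of roughly 1-in-200 prevalence has no
#' business in common variation. Samples need a call rate of at least 95%
#' and a heterozygosity rate within `het_excess_sd` standard deviations of
#' the cohort mean.
#'
#' @param min_variant_call_rate,hwe_p_min,min_depth,max_maf Variant-level
#'   thresholds.
#' @param min_sample_call_rate,het_excess_sd Sample-level thresholds.
#' @return A list of class `fh_qc_thresholds`.
#' @export
qc_thresholds <- function(min_variant_call_rate = 0.98,
                          hwe_p_min = 1e-10,
                          min_depth = 10,
                          max_maf = 0.005,
                          min_sample_call_rate = 0.95,
                          het_excess_sd = 3) {
  stopifnot(min_variant_call_rate >= 0, min_variant_call_rate <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1, min_depth >= 0,
            max_maf >= 0, max_maf <= 0.5,
            min_sample_call_rate >= 0, min_sample_call_rate <= 1,
            het_excess_sd > 0)
  structure(as.list(environment()), class = "fh_qc_thresholds")
}

#' Genotype call rate
#'
#' Fraction of non-missing genotype calls. Invariant to subject order.
#'
#' @param g Vector (or matrix column) of allele counts with `NA` for missing.
#' @return A fraction in [0, 1].
#' @export
#' @examples
#' call_rate(c(0, 1, NA, 0))
call_rate <- function(g) {
  if (length(g) < 1) abort("call_rate needs at least one genotype.")
  mean(!is.na(g))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Plain 1-df chi-square of observed genotype counts against the counts
#' expected from the allele frequencies. Monomorphic sites (allele frequency
#' 0 or 1) are defined to pass: `chi2 = 0`, `p = 1`.
#'
#' @param n_AA,n_Aa,n_aa Observed genotype counts (vectorized).
#' @return A tibble with columns `chi2` and `p`.
#' @export
#' @examples
#' hwe_chisq(25, 50, 25)   # exact HWE proportions: chi2 = 0
#' hwe_chisq(50, 0, 50)    # no hets at p = 0.5: chi2 = n
hwe_chisq <- function(n_AA, n_Aa, n_aa) {
  stopifnot(all(n_AA >= 0), all(n_Aa >= 0), all(n_aa >= 0))
  n <- n_AA + n_Aa + n_aa
  if (any(n < 1)) abort("hwe_chisq needs a total genotype count of at least 1.")
  p_a <- (2 * n_aa + n_Aa) / (2 * n)
  e_AA <- n * (1 - p_a)^2
  e_Aa <- n * 2 * p_a * (1 - p_a)
  e_aa <- n * p_a^2
  chi2 <- ifelse(
    p_a == 0 | p_a == 1, 0,
    (n_AA - e_AA)^2 / e_AA + (n_Aa - e_Aa)^2 / e_Aa + (n_aa - e_aa)^2 / e_aa
  )
  tibble(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Minor allele frequency from allele counts
#'
#' Computed over called alleles only (missing genotypes drop out of the
#' denominator).
#'
#' @param g Vector of per-subject allele counts (0/1/2, `NA` missing).
#' @return The minor allele frequency, `min(f, 1 - f)`.
#' @export
#' @examples
#' minor_allele_frequency(c(0, 1, 0, 0))  # 1/8
minor_allele_frequency <- function(g) {
  g <- g[!is.na(g)]
  if (!length(g)) return(NA_real_)
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

geno_counts <- function(g) {
  g <- g[!is.na(g)]
  c(n_AA = sum(g == 0), n_Aa = sum(g == 1), n_aa = sum(g == 2))
}

#' Variant-level QC filter
#'
#' Applies the four variant filters as a conjunction: a variant is retained
#' iff call rate >= `min_variant_call_rate` AND HWE p >= `hwe_p_min` AND mean
#' depth >= `min_depth` AND MAF < `max_maf`. The exclusion log records the
#' first failing filter per variant, in that order; the retained set does not
#' depend on the order.
#'
#' @param variants Tibble with `variant_id` and `mean_dp`.
#' @param genotypes Allele-count matrix (subjects x variants).
#' @param thresholds A [qc_thresholds()] object.
#' @return A tibble per variant: QC metrics, `keep`, and `fail_reason`
#'   (`NA` for retained variants).
#' @export
filter_variants <- function(variants, genotypes, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "fh_qc_thresholds"),
            nrow(variants) == ncol(genotypes))
  metrics <- purrr::map_dfr(seq_len(nrow(variants)), function(j) {
    g <- genotypes[, j]
    cc <- geno_counts(g)
    hw <- if (sum(cc) >= 1) hwe_chisq(cc[1], cc[2], cc[3]) else tibble(chi2 = NA_real_, p = NA_real_)
    tibble(
      variant_id = variants$variant_id[j],
      call_rate = call_rate(g),
      hwe_p = hw$p,
      mean_dp = variants$mean_dp[j],
      maf = minor_allele_frequency(g)
    )
  })
  metrics |>
    mutate(
      fail_reason = dplyr::case_when(
        call_rate < thresholds$min_variant_call_rate ~ "call_rate",
        hwe_p < thresholds$hwe_p_min ~ "hwe",
        is.na(mean_dp) | mean_dp < thresholds$min_depth ~ "depth",
        maf >= thresholds$max_maf ~ "maf",
        TRUE ~ NA_character_
      ),
      keep = is.na(fail_reason)
    )
}

#' Sample-level QC filter
#'
#' Excludes samples with genotype call rate below `min_sample_call_rate`,
#' heterozygosity rate beyond `het_excess_sd` standard deviations of the
#' cohort mean (guarded: no exclusion when the cohort sd is 0), and samples
#' flagged sex-ambiguous upstream (X-chromosome intensity/heterozygosity
#' checks are outside this panel's scope, so the flag is consumed as given).
#'
#' @param genotypes Allele-count matrix (subjects x variants).
#' @param thresholds A [qc_thresholds()] object.
#' @param sex_ambiguous Optional character vector of subject ids flagged
#'   sex-ambiguous by an upstream check.
#' @return A tibble per sample: `call_rate`, `het_rate`, `keep`,
#'   `fail_reason`.
#' @export
filter_samples <- function(genotypes, thresholds = qc_thresholds(),
                           sex_ambiguous = NULL) {
  stopifnot(inherits(thresholds, "fh_qc_thresholds"))
  cr <- apply(genotypes, 1, call_rate)
  het <- apply(genotypes, 1, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    mean(g == 1)
  })
  het_sd <- sd(het, na.rm = TRUE)
  het_mu <- mean(het, na.rm = TRUE)
  het_out <- if (is.na(het_sd) || het_sd == 0) {
    rep(FALSE, length(het))
  } else {
    abs(het - het_mu) > thresholds$het_excess_sd * het_sd
  }
  tibble(
    subject_id = rownames(genotypes),
    call_rate = cr,
    het_rate = het
  ) |>
    mutate(
      fail_reason = dplyr::case_when(
        .data$subject_id %in% sex_ambiguous ~ "sex_ambiguity",
        call_rate < thresholds$min_sample_call_rate ~ "call_rate",
        het_out ~ "het_excess",
        TRUE ~ NA_character_
      ),
      keep = is.na(fail_reason)
    )
}

#' Assemble the analysis cohort from genotyped subjects
#'
#' Drops subjects with a missing LDL-C measurement first, then subjects
#' flagged hypothyroid (hypothyroidism raises LDL-C secondarily and would
#' confound an FH screen). A subject failing both is logged once, under the
#' missing-LDL reason.
#'
#' @param phenotypes Phenotype tibble (needs `ldl_measured` and
#'   `hypothyroidism`).
#' @return The retained subjects, with an `exclusions` attribute logging
#'   `subject_id` and `reason` (`"ldl_missing"` or `"hypothyroid"`) in
#'   application order.
#' @export
#' @examples
#' phen <- tibble::tibble(subject_id = c("a", "b", "c"),
#'                        ldl_measured = c(3, NA, 4),
#'                        hypothyroidism = c(FALSE, FALSE, TRUE))
#' nrow(build_analysis_cohort(phen))
build_analysis_cohort <- function(phenotypes) {
  stopifnot(all(c("ldl_measured", "hypothyroidism") %in% names(phenotypes)))
  ldl_missing <- is.na(phenotypes$ldl_measured)
  hypo <- !ldl_missing & !is.na(phenotypes$hypothyroidism) & phenotypes$hypothyroidism
  exclusions <- bind_rows(
    tibble(subject_id = phenotypes$subject_id[ldl_missing], reason = "ldl_missing"),
    tibble(subject_id = phenotypes$subject_id[hypo], reason = "hypothyroid")
  )
  out <- phenotypes[!ldl_missing & !hypo, , drop = FALSE]
  attr(out, "exclusions") <- exclusions
  out
}
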