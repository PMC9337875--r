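# ---- Dutch Lipid Clinic Network scoring -----------------------------------
# DLCN items available from questionnaire-style biobank phenotypes:
#   family history (parent with heart disease)        -> 1 point
#   clinical history (premature MI/angina)            -> 2 points
#   untreated LDL-C band                              -> 0/1/3/5/8 points
#   DNA evidence (known pathogenic FH mutation)       -> 8 points
# Physical-sign items (tendinous xanthomas, arcus cornealis) are not
# collected by such questionnaires and are never scored here; the maximum
# attainable total is therefore 1 + 2 + 8 + 8 = 19.

#' DLCN points for the untreated LDL-C band
#'
#' Standard DLCN bands on untreated LDL-C (mmol/L), left-closed:
#' below 4.0 scores 0, 4.0-4.9 scores 1, 5.0-6.4 scores 3, 6.5-8.4 scores 5
#' and 8.5 or above scores 8.
#'
#' @param ldl_untreated Untreated LDL-C in mmol/L (vectorized).
#' @param bands Band edges (lower bounds of the scoring bands).
#' @param points Points for each band, aligned with `bands`.
#' @return Integer points.
#' @export
#' @examples
#' score_ldl_band(c(3.9, 4.0, 5.2, 9.83))
score_ldl_band <- function(ldl_untreated,
                           bands = c(4.0, 5.0, 6.5, 8.5),
                           points = c(1L, 3L, 5L, 8L)) {
  stopifnot(length(bands) == length(points), !is.unsorted(bands))
  if (any(!is.na(ldl_untreated) & ldl_untreated <= 0)) {
    abort("Untreated LDL-C must be positive.")
  }
  idx <- findInterval(ldl_untreated, bands)  # left-closed: x >= band edge
  out <- c(0L, points)[idx + 1L]
  out[is.na(ldl_untreated)] <- NA_integer_
  out
}

#' DLCN family-history points
#'
#' One point for a first-degree relative with heart disease (either parent;
#' the item is a category maximum, not a sum). The 2-point family item
#' (relative with xanthoma/arcus, or an affected child) requires relative
#' examinations that questionnaire cohorts do not collect, so it is always 0.
#' Missing answers contribute 0 points.
#'
#' @param data Phenotype tibble with `paternal_heart_disease` and
#'   `maternal_heart_disease`.
#' @return Integer points (0 or 1) per subject.
#' @export
score_family_history <- function(data) {
  pat <- !is.na(data$paternal_heart_disease) & data$paternal_heart_disease
  mat <- !is.na(data$maternal_heart_disease) & data$maternal_heart_disease
  as.integer(pat | mat)
}

#' DLCN clinical-history points
#'
#' Two points for premature coronary disease: a myocardial infarction or
#' angina before the sex-specific premature age (default 55 for males, 60
#' for females, the standard DLCN convention). An event with no recorded
#' age uses the subject's current age as a conservative upper bound. The
#' 1-point item (premature peripheral/cerebral vascular disease) is not
#' collected and is always 0. Missing answers contribute 0 points.
#'
#' @param data Phenotype tibble with `sex`, `age`, `mi_history`,
#'   `age_at_mi`, `angina`.
#' @param premature_age_male,premature_age_female Premature-CHD age cutoffs
#'   in years.
#' @return Integer points (0 or 2) per subject.
#' @export
score_clinical_history <- function(data, premature_age_male = 55,
                                   premature_age_female = 60) {
  cutoff <- ifelse(!is.na(data$sex) & data$sex == "male",
                   premature_age_male, premature_age_female)
  mi_age <- ifelse(is.na(data$age_at_mi), data$age, data$age_at_mi)
  mi_prem <- !is.na(data$mi_history) & data$mi_history & mi_age < cutoff
  ang_prem <- !is.na(data$angina) & data$angina & data$age < cutoff
  as.integer(mi_prem | ang_prem) * 2L
}

#' DLCN genetic-evidence points
#'
#' Eight points for carrying a known pathogenic mutation in an FH gene; a
#' carrier with no phenotypic evidence therefore lands at a total of exactly
#' 8 (probable FH).
#'
#' @param carrier Logical vector: carries a known pathogenic FH variant.
#' @return Integer points (0 or 8) per subject.
#' @export
score_genetic <- function(carrier) {
  as.integer(!is.na(carrier) & carrier) * 8L
}

#' Four-way DLCN category from the total score
#'
#' Below 3 is unlikely FH, 3-5 possible, 6-8 probable, above 8 definite.
#'
#' @param total Integer DLCN totals.
#' @return An ordered factor `unlikely < possible < probable < definite`.
#' @export
#' @examples
#' classify_dlcn(c(0, 3, 5, 6, 8, 9))
classify_dlcn <- function(total) {
  lev <- c("unlikely", "possible", "probable", "definite")
  cut(total, breaks = c(-Inf, 2, 5, 8, Inf), labels = lev,
      ordered_result = TRUE)
}

#' Score a cohort with the DLCN criteria
#'
#' Computes the per-subject component points, the phenotype-only total, and
#' (when carrier status is supplied) the genotype-integrated total that adds
#' 8 points of DNA evidence. Both categories are reported so reclassification
#' under genetic testing is explicit; adding genetic evidence can never
#' lower a category.
#'
#' @param data Phenotype tibble carrying an `ldl_untreated` column (from
#'   [correct_ldl()]).
#' @param carriers Character vector of subject ids carrying a known
#'   pathogenic variant, or a logical vector aligned with `data`. `NULL`
#'   scores the phenotype-only pass.
#' @param premature_age_male,premature_age_female Passed to
#'   [score_clinical_history()].
#' @return A tibble per subject: `points_family_history`, `points_clinical`,
#'   `points_ldl`, `points_genetic`, `phenotype_only_total`, `total`,
#'   `category_phenotype`, `category`, `reclassified`.
#' @export
#' @examples
#' phen <- tibble::tibble(
#'   subject_id = "s1", sex = "male", age = 45, ldl_untreated = 3.0,
#'   mi_history = FALSE, age_at_mi = NA_real_, angina = FALSE,
#'   paternal_heart_disease = FALSE, maternal_heart_disease = FALSE)
#' dlcn_score(phen, carriers = "s1")   # mutation alone: total 8, probable
dlcn_score <- function(data, carriers = NULL,
                       premature_age_male = 55, premature_age_female = 60) {
  if (!"ldl_untreated" %in% names(data)) {
    abort("dlcn_score needs an 'ldl_untreated' column; run correct_ldl() first.")
  }
  carrier <- if (is.null(carriers)) {
    rep(FALSE, nrow(data))
  } else if (is.logical(carriers)) {
    stopifnot(length(carriers) == nrow(data))
    carriers
  } else {
    data$subject_id %in% carriers
  }
  pts_ldl <- score_ldl_band(data$ldl_untreated)
  pts_ldl[is.na(pts_ldl)] <- 0L  # unmeasured LDL contributes no points
  res <- tibble(
    subject_id = data$subject_id,
    points_family_history = score_family_history(data),
    points_clinical = score_clinical_history(data, premature_age_male,
                                             premature_age_female),
    points_ldl = pts_ldl,
    points_genetic = score_genetic(carrier)
  ) |>
    mutate(
      phenotype_only_total = .data$points_family_history +
        .data$points_clinical + .data$points_ldl,
      total = .data$phenotype_only_total + .data$points_genetic,
      category_phenotype = classify_dlcn(.data$phenotype_only_total),
      category = classify_dlcn(.data$total),
      reclassified = .data$category != .data$category_phenotype
    )
  res
}

#' Reclassification report between the phenotype-only and genetic passes
#'
#' @param dlcn A [dlcn_score()] result.
#' @return The subjects whose category changed when DNA evidence was added,
#'   with both categories and the reason.
#' @export
reclassification_report <- function(dlcn) {
  dlcn |>
    filter(.data$reclassified) |>
    mutate(reason = "carries a known pathogenic FH variant (+8 DLCN points)") |>
    select("subject_id", "category_phenotype", "category",
           "phenotype_only_total", "total", "reason")
}
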