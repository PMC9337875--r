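# ---- prevalence & group characteristics -----------------------------------

new_prevalence <- function(n_cases, n_cohort) {
  stopifnot(n_cases >= 0, n_cohort >= 1, n_cases <= n_cohort)
  tibble(
    n_cases = as.integer(n_cases),
    n_cohort = as.integer(n_cohort),
    percent = 100 * n_cases / n_cohort,
    one_in_n = if (n_cases > 0) round_half_up(n_cohort / n_cases) else NA_real_
  )
}

#' Prevalence of an FH category set
#'
#' Prevalence as a percentage of the analysis cohort, plus the conventional
#' "1 in N" form with N rounded half away from zero. With zero cases the
#' ratio form is undefined (`NA`).
#'
#' @param categories Vector (or [dlcn_score()] result) of per-subject DLCN
#'   categories.
#' @param which Categories that count as cases (default: the usual
#'   definite-or-probable FH case definition).
#' @return A one-row tibble: `n_cases`, `n_cohort`, `percent`, `one_in_n`.
#' @export
#' @examples
#' estimate_prevalence(rep(c("definite", "unlikely"), c(2, 248)))
estimate_prevalence <- function(categories, which = c("definite", "probable")) {
  if (is.data.frame(categories)) categories <- categories$category
  categories <- as.character(categories)
  new_prevalence(sum(categories %in% which), length(categories))
}

#' Carrier prevalence of a pathogenicity class
#'
#' Counts distinct subjects carrying at least one variant of the class — a
#' subject with two qualifying variants counts once — over the analysis
#' cohort.
#'
#' @param assessments An [assess_variants()] result.
#' @param genotypes Allele-count matrix (subjects x variants).
#' @param class Pathogenicity class to count carriers of.
#' @param n_cohort Cohort size for the denominator; defaults to the number
#'   of rows of `genotypes`.
#' @return A one-row tibble: `n_cases`, `n_cohort`, `percent`, `one_in_n`.
#' @export
carrier_prevalence <- function(assessments, genotypes,
                               class = "known_pathogenic",
                               n_cohort = nrow(genotypes)) {
  ids <- assessments$variant_id[assessments$class %in% class]
  ids <- intersect(ids, colnames(genotypes))
  carriers <- if (length(ids)) {
    rowSums(genotypes[, ids, drop = FALSE] >= 1, na.rm = TRUE) > 0
  } else {
    rep(FALSE, nrow(genotypes))
  }
  new_prevalence(sum(carriers), n_cohort)
}

#' Per-category characteristics table with tests against the reference group
#'
#' Summarises each DLCN category the way cohort papers report them:
#' continuous traits as mean +/- sd compared with a t-test against the
#' reference (unlikely FH) group, binary traits as count (%) compared with
#' Fisher's exact test. Raw p-values are starred at p < 0.05; no
#' multiple-testing correction is applied.
#'
#' @param data Phenotype tibble.
#' @param categories Per-subject categories aligned with `data` (vector or
#'   [dlcn_score()] result).
#' @param continuous,binary Trait columns to summarise.
#' @param reference Reference category.
#' @param welch Use the Welch (unequal-variance) t-test; `FALSE` gives the
#'   pooled-variance test.
#' @return A tidy tibble: one row per trait x category with `n`, `mean`,
#'   `sd`, `count`, `pct`, `p_value`, `signif`.
#' @export
characteristics_table <- function(data, categories,
                                  continuous = intersect(
                                    c("age", "bmi", "age_at_hc_dx", "age_at_mi",
                                      "tc", "hdl", "ldl_measured", "tg"),
                                    names(data)),
                                  binary = intersect(
                                    c("smoker", "hypertension", "diabetes",
                                      "selfreport_hc", "on_lipid_med",
                                      "mi_history", "angina",
                                      "paternal_heart_disease",
                                      "maternal_heart_disease"),
                                    names(data)),
                                  reference = "unlikely",
                                  welch = TRUE) {
  if (is.data.frame(categories)) categories <- categories$category
  categories <- as.character(categories)
  stopifnot(length(categories) == nrow(data))
  cats <- unique(categories)
  if (!reference %in% cats) {
    abort(paste0("Reference category '", reference, "' not present."))
  }
  ref_rows <- categories == reference

  summarise_one <- function(cat) {
    rows <- categories == cat
    cont <- purrr::map_dfr(continuous, function(tr) {
      x <- data[[tr]][rows]
      y <- data[[tr]][ref_rows]
      p <- if (cat == reference || sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) {
        NA_real_
      } else {
        tryCatch(t.test(x, y, var.equal = !welch)$p.value,
                 error = function(e) NA_real_)
      }
      tibble(trait = tr, type = "continuous",
             n = sum(!is.na(x)), mean = mean(x, na.rm = TRUE),
             sd = sd(x, na.rm = TRUE),
             count = NA_integer_, pct = NA_real_, p_value = p)
    })
    bin <- purrr::map_dfr(binary, function(tr) {
      x <- data[[tr]][rows]
      y <- data[[tr]][ref_rows]
      cnt <- sum(x, na.rm = TRUE)
      p <- if (cat == reference) NA_real_ else {
        tab <- matrix(c(cnt, sum(!x, na.rm = TRUE),
                        sum(y, na.rm = TRUE), sum(!y, na.rm = TRUE)),
                      nrow = 2)
        tryCatch(fisher.test(tab)$p.value, error = function(e) NA_real_)
      }
      tibble(trait = tr, type = "binary",
             n = sum(!is.na(x)), mean = NA_real_, sd = NA_real_,
             count = as.integer(cnt),
             pct = 100 * cnt / max(sum(!is.na(x)), 1), p_value = p)
    })
    mutate(bind_rows(cont, bin), category = cat, .before = 1)
  }
  order_cats <- intersect(c("definite", "probable", "possible", "unlikely"), cats)
  purrr::map_dfr(c(order_cats, setdiff(cats, order_cats)), summarise_one) |>
    mutate(signif = !is.na(.data$p_value) & .data$p_value < 0.05)
}
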