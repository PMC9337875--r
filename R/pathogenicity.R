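# ---- pathogenicity aggregation & penetrance -------------------------------

supporting_labels <- list(
  clinvar = c("P", "LP"),
  lovd = c("P", "LP"),
  hgmd = c("DM", "DM?")
)

db_supports <- function(labels, qualifying) {
  map_lgl(labels, function(set) any(set %in% qualifying))
}

#' Two-or-more-database rule for known pathogenic variants
#'
#' A database "supports" pathogenicity when any of its assertions for the
#' variant is pathogenic/likely pathogenic (ClinVar, LOVD) or
#' disease-causing/likely disease-causing (`DM`/`DM?`, HGMD). A variant is
#' *known pathogenic* when at least two of the three databases support it;
#' composite labels such as `"P/LP/VUS"` count as supporting because at
#' least one submitted interpretation qualifies.
#'
#' @param annotations Annotation tibble with `clinvar`, `hgmd`, `lovd`
#'   columns (slash-composite strings, `"NR"` = no assertion), as read by
#'   [read_annotations()].
#' @return `annotations` with added `known_pathogenic` (logical) and
#'   `supporting_databases` (comma-separated string, `""` when none).
#' @export
#' @examples
#' ann <- tibble::tibble(variant_id = "v1", clinvar = "VUS",
#'                       hgmd = "DM", lovd = "LP")
#' is_known_pathogenic(ann)$known_pathogenic   # TRUE: HGMD + LOVD
is_known_pathogenic <- function(annotations) {
  cv <- db_supports(parse_label_set(annotations$clinvar, clinvar_tokens),
                    supporting_labels$clinvar)
  lv <- db_supports(parse_label_set(annotations$lovd, clinvar_tokens),
                    supporting_labels$lovd)
  hg <- annotations$hgmd %in% supporting_labels$hgmd
  support <- cbind(ClinVar = cv, HGMD = hg, LOVD = lv)
  annotations$supporting_databases <- apply(support, 1, function(s) {
    paste(colnames(support)[s], collapse = ",")
  })
  annotations$known_pathogenic <- rowSums(support) >= 2
  annotations
}

resolve_carriers <- function(data, carriers) {
  if (is.logical(carriers)) {
    stopifnot(length(carriers) == nrow(data))
    carriers
  } else {
    data$subject_id %in% carriers
  }
}

#' High-cholesterol penetrance of a variant
#'
#' Percentage of carriers who show the high-cholesterol phenotype: untreated
#' LDL-C above the threshold (3.3 mmol/L by default), OR on
#' cholesterol-lowering medication, OR self-reported hypercholesterolemia.
#' Missing components count as not met. Undefined (NA) when there are no
#' carriers — a variant nobody carries has no penetrance, which is not the
#' same as 0%.
#'
#' @param data Phenotype tibble with `ldl_untreated` (see [correct_ldl()]),
#'   `on_lipid_med` and `selfreport_hc`.
#' @param carriers Subject ids, or a logical vector aligned with `data`.
#' @param ldl_threshold Untreated LDL-C threshold in mmol/L.
#' @return Percentage in [0, 100], rounded to one decimal; `NA` for zero
#'   carriers.
#' @export
hc_penetrance <- function(data, carriers, ldl_threshold = 3.3) {
  keep <- resolve_carriers(data, carriers)
  if (!any(keep)) return(NA_real_)
  d <- data[keep, , drop = FALSE]
  met <- (!is.na(d$ldl_untreated) & d$ldl_untreated > ldl_threshold) |
    (!is.na(d$on_lipid_med) & d$on_lipid_med) |
    (!is.na(d$selfreport_hc) & d$selfreport_hc)
  round_half_up(100 * mean(met), 1)
}

#' DLCN penetrance of a variant
#'
#' Percentage of carriers whose *phenotype-only* DLCN score is at least 3
#' (i.e. at least possible FH before DNA evidence). The 8 genetic-evidence
#' points are excluded on purpose: including them would make every carrier
#' score at least 8 and the statistic trivially 100%.
#'
#' @param dlcn A [dlcn_score()] result (any pass; the phenotype-only total is
#'   used).
#' @param carriers Subject ids, or a logical vector aligned with `dlcn`.
#' @param min_score Phenotype-only DLCN score that counts as penetrant.
#' @return Percentage in [0, 100], rounded to one decimal; `NA` for zero
#'   carriers.
#' @export
dlcn_penetrance <- function(dlcn, carriers, min_score = 3) {
  keep <- resolve_carriers(dlcn, carriers)
  if (!any(keep)) return(NA_real_)
  round_half_up(100 * mean(dlcn$phenotype_only_total[keep] >= min_score), 1)
}

#' In-silico rule for possibly pathogenic variants
#'
#' Applied to variants that are not already known pathogenic: a variant is
#' *possibly pathogenic* when its CADD PHRED score exceeds 20 (top 1% most
#' deleterious substitutions genome-wide) AND its high-cholesterol penetrance
#' is at least 50%. The penetrance boundary is inclusive, so variants whose
#' carriers split evenly qualify.
#'
#' @param cadd CADD PHRED scores (vectorized; `NA` never qualifies).
#' @param hc_penetrance HC-penetrance percentages.
#' @param cadd_min Exclusive CADD threshold.
#' @param penetrance_min Inclusive penetrance threshold (percent).
#' @return Logical vector.
#' @export
#' @examples
#' is_possibly_pathogenic(c(20.5, 24.9, 19.9, 34), c(100, 50, 100, 49))
is_possibly_pathogenic <- function(cadd, hc_penetrance,
                                   cadd_min = 20, penetrance_min = 50) {
  !is.na(cadd) & cadd > cadd_min &
    !is.na(hc_penetrance) & hc_penetrance >= penetrance_min
}

#' Assess every panel variant: class, carriers, penetrance
#'
#' Joins genotypes, annotations and phenotypes into one assessment row per
#' variant. Known-pathogenic status (two-database rule) is evaluated first;
#' the possibly-pathogenic rule (CADD and HC-penetrance) is applied only to
#' the remainder with at least one carrier. Variants absent from the
#' annotation table are treated as unasserted (`NR` everywhere) but remain
#' eligible for the possibly-pathogenic class when a CADD score is supplied —
#' novel variants are expected in underrepresented populations.
#'
#' @param variants Variant tibble (`variant_id`, `gene`, ...).
#' @param genotypes Allele-count matrix (subjects x variants).
#' @param annotations Annotation tibble from [read_annotations()].
#' @param phenotypes Phenotype tibble with `ldl_untreated` (run
#'   [correct_ldl()] first), restricted to the analysis cohort.
#' @param ldl_threshold HC-penetrance LDL-C threshold (mmol/L).
#' @return A tibble per variant: `class` (`known_pathogenic`,
#'   `possibly_pathogenic`, `other`), `supporting_databases`, `n_het`,
#'   `n_hom_alt`, `n_carriers`, `maf`, `dlcn_penetrance`, `hc_penetrance`,
#'   `cadd`.
#' @export
assess_variants <- function(variants, genotypes, annotations, phenotypes,
                            ldl_threshold = 3.3) {
  stopifnot(nrow(variants) == ncol(genotypes))
  ann <- annotations
  for (col in c("clinvar", "hgmd", "lovd")) {
    if (!col %in% names(ann)) ann[[col]] <- "NR"
  }
  if (!"cadd" %in% names(ann)) ann$cadd <- NA_real_
  ann <- is_known_pathogenic(ann)
  ann <- select(ann, "variant_id", "clinvar", "hgmd", "lovd", "cadd",
                "known_pathogenic", "supporting_databases")

  # genotype matrix restricted to the phenotyped (analysis) subjects
  keep <- rownames(genotypes) %in% phenotypes$subject_id
  gsub_ <- genotypes[keep, , drop = FALSE]
  phen <- phenotypes[match(rownames(gsub_), phenotypes$subject_id), , drop = FALSE]
  dlcn <- dlcn_score(phen)

  out <- variants |>
    left_join(ann, by = "variant_id") |>
    mutate(
      clinvar = dplyr::coalesce(.data$clinvar, "NR"),
      hgmd = dplyr::coalesce(.data$hgmd, "NR"),
      lovd = dplyr::coalesce(.data$lovd, "NR"),
      known_pathogenic = dplyr::coalesce(.data$known_pathogenic, FALSE),
      supporting_databases = dplyr::coalesce(.data$supporting_databases, "")
    )
  per_variant <- purrr::map_dfr(seq_len(nrow(out)), function(j) {
    g <- gsub_[, out$variant_id[j]]
    carrier <- !is.na(g) & g >= 1
    tibble(
      n_het = sum(g == 1, na.rm = TRUE),
      n_hom_alt = sum(g == 2, na.rm = TRUE),
      n_carriers = sum(carrier),
      maf = minor_allele_frequency(g),
      dlcn_penetrance = dlcn_penetrance(dlcn, carrier),
      hc_penetrance = hc_penetrance(phen, carrier, ldl_threshold)
    )
  })
  out <- bind_cols(out, per_variant)
  res <- out |>
    mutate(
      class = dplyr::case_when(
        .data$known_pathogenic ~ "known_pathogenic",
        is_possibly_pathogenic(.data$cadd, .data$hc_penetrance) ~ "possibly_pathogenic",
        TRUE ~ "other"
      )
    ) |>
    select("variant_id", dplyr::any_of(c("chrom", "pos", "ref", "alt", "gene", "rsid")),
           "class", "supporting_databases", "clinvar", "hgmd", "lovd", "cadd",
           "n_het", "n_hom_alt", "n_carriers", "maf",
           "dlcn_penetrance", "hc_penetrance")
  class(res) <- c("fh_assessment", class(res))
  res
}
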