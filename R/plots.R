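# ---- figures ---------------------------------------------------------------

#' Category counts before and after adding genetic evidence
#'
#' Side-by-side bars of the four DLCN categories under the phenotype-only
#' pass and the genotype-integrated pass, making reclassification visible.
#'
#' @param dlcn A [dlcn_score()] result.
#' @return A ggplot.
#' @export
plot_dlcn_categories <- function(dlcn) {
  long <- bind_rows(
    tibble(pass = "phenotype only", category = dlcn$category_phenotype),
    tibble(pass = "with genetics", category = dlcn$category)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, fill = .data$pass)) +
    ggplot2::geom_bar(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "DLCN category", y = "subjects (log scale)",
                  fill = NULL,
                  title = "FH classification with and without DNA evidence") +
    ggplot2::theme_minimal()
}

#' CADD score against HC-penetrance for assessed variants
#'
#' Scatter of the two axes of the possibly-pathogenic rule, with the CADD>20
#' and penetrance>=50% thresholds drawn; points colored by assigned class.
#'
#' @param assessments An [assess_variants()] result.
#' @param cadd_min,penetrance_min Thresholds to draw.
#' @return A ggplot.
#' @export
plot_variant_assessment <- function(assessments, cadd_min = 20,
                                    penetrance_min = 50) {
  d <- filter(assessments, !is.na(.data$cadd), !is.na(.data$hc_penetrance))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cadd, y = .data$hc_penetrance,
                                  colour = .data$class)) +
    ggplot2::geom_vline(xintercept = cadd_min, linetype = 2, colour = "grey40") +
    ggplot2::geom_hline(yintercept = penetrance_min, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_point(size = 2, alpha = 0.85) +
    ggplot2::labs(x = "CADD (PHRED)", y = "HC-penetrance (%)", colour = NULL,
                  title = "Variant deleteriousness vs carrier penetrance") +
    ggplot2::theme_minimal()
}

#' Lipid profiles across FH categories
#'
#' Boxplots of a lipid trait per DLCN category.
#'
#' @param data Phenotype tibble.
#' @param categories Per-subject categories aligned with `data` (vector or
#'   [dlcn_score()] result).
#' @param trait Lipid column to plot.
#' @return A ggplot.
#' @export
plot_lipids_by_category <- function(data, categories, trait = "ldl_untreated") {
  if (is.data.frame(categories)) categories <- categories$category
  d <- tibble(category = factor(as.character(categories),
                                levels = c("unlikely", "possible",
                                           "probable", "definite")),
              value = data[[trait]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3, fill = "steelblue", alpha = 0.6) +
    ggplot2::labs(x = "DLCN category", y = paste0(trait, " (mmol/L)")) +
    ggplot2::theme_minimal()
}

#' @rdname plot_variant_assessment
#' @param object An [assess_variants()] result (`autoplot` interface).
#' @param ... Passed to [plot_variant_assessment()].
#' @export
autoplot.fh_assessment <- function(object, ...) {
  plot_variant_assessment(object, ...)
}

#' Forest-style coefficient plot for a burden fit
#'
#' @param object An `fh_burden` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fh_burden <- function(object, ...) {
  td <- tidy(object)
  td$lo <- td$estimate - 1.96 * td$std.error
  td$hi <- td$estimate + 1.96 * td$std.error
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "log-odds estimate (95% CI)", y = NULL,
                  title = if (!is.na(object$gene)) {
                    paste0("Carrier burden model: ", object$gene)
                  } else "Carrier burden model") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
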