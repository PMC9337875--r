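# ---- LDL-C medication correction ------------------------------------------

#' Drug/dose LDL-C reduction factor table
#'
#' Loads the correction-factor table mapping a cholesterol-lowering drug and
#' daily dose (mg) to the expected proportional LDL-C reduction `r`, plus a
#' per-drug minimum-dose flag used as the fallback when the dose was not
#' recorded. The shipped defaults cover common statins and statin+ezetimibe
#' combinations with reduction fractions in the range reported by clinical
#' audit studies of FH cohorts; the file is an editable config, not ground
#' truth.
#'
#' @param path Optional path to an alternative TSV (`drug`, `dose`,
#'   `reduction`, `is_min_dose`).
#' @return A tibble of class `fh_correction_table`.
#' @export
fh_correction_table <- function(path = fh_extdata("ldl_correction_factors.tsv")) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    drug = "c", dose = "d", reduction = "d", is_min_dose = "l"
  ))
  if (any(tab$reduction < 0 | tab$reduction >= 1)) {
    abort("Reduction fractions must lie in [0, 1).")
  }
  no_min <- setdiff(unique(tab$drug), tab$drug[tab$is_min_dose])
  if (length(no_min)) {
    abort(paste0("Drug(s) without a minimum-dose entry: ",
                 paste(no_min, collapse = ", ")))
  }
  class(tab) <- c("fh_correction_table", class(tab))
  tab
}

lookup_reduction <- function(drug, dose, table, default_reduction = NULL) {
  out <- numeric(length(drug))
  flag <- character(length(drug))
  for (i in seq_along(drug)) {
    d <- drug[i]
    if (is.na(d)) {
      if (is.null(default_reduction)) {
        abort("Subject on lipid-lowering medication with no drug recorded and no default_reduction configured.")
      }
      out[i] <- default_reduction
      flag[i] <- "default_reduction"
      next
    }
    rows <- table[table$drug == d, , drop = FALSE]
    if (nrow(rows) == 0) {
      if (is.null(default_reduction)) {
        abort(paste0("Drug '", d, "' is not in the correction table and no default_reduction is configured."))
      }
      out[i] <- default_reduction
      flag[i] <- "default_reduction"
      next
    }
    if (is.na(dose[i])) {
      out[i] <- rows$reduction[rows$is_min_dose][1]
      flag[i] <- "dose_fallback"
    } else {
      hit <- which(rows$dose == dose[i])
      if (length(hit)) {
        out[i] <- rows$reduction[hit[1]]
        flag[i] <- "exact"
      } else {
        # unlisted dose: nearest listed dose below, else the minimum dose
        below <- which(rows$dose < dose[i])
        j <- if (length(below)) below[which.max(rows$dose[below])] else which(rows$is_min_dose)[1]
        out[i] <- rows$reduction[j]
        flag[i] <- "nearest_dose"
      }
    }
  }
  list(reduction = out, flag = flag)
}

#' Back-correct measured LDL-C for lipid-lowering therapy
#'
#' DLCN LDL-C bands and the high-cholesterol penetrance threshold are defined
#' on *untreated* LDL-C, so measured values of treated subjects are divided
#' by `1 - r`, inverting the proportional reduction `r` expected for their
#' drug and dose. When the dose is missing the drug's minimum dose is used
#' (a deliberately conservative fallback); when the drug itself is missing a
#' configurable `default_reduction` applies and the row is flagged.
#'
#' @param data Phenotype tibble with `ldl_measured`, `on_lipid_med`,
#'   `med_drug`, `med_dose`.
#' @param table A [fh_correction_table()].
#' @param default_reduction Reduction fraction applied when a treated
#'   subject's drug is unknown; `NULL` (default) makes that an error.
#' @return `data` with two added columns: `ldl_untreated` (mmol/L; equal to
#'   `ldl_measured` for untreated subjects) and `ldl_correction`
#'   (`"none"`, `"exact"`, `"dose_fallback"`, `"nearest_dose"` or
#'   `"default_reduction"`).
#' @export
#' @examples
#' tab <- fh_correction_table()
#' phen <- tibble::tibble(subject_id = "s1", ldl_measured = 3.0,
#'                        on_lipid_med = TRUE, med_drug = "atorvastatin",
#'                        med_dose = NA_real_)
#' correct_ldl(phen, tab)$ldl_untreated  # 3.0 / (1 - 0.37)
correct_ldl <- function(data, table = fh_correction_table(),
                        default_reduction = NULL) {
  need <- c("ldl_measured", "on_lipid_med", "med_drug", "med_dose")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("correct_ldl needs column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.na(data$ldl_measured) & data$ldl_measured <= 0)) {
    abort("Measured LDL-C must be positive.")
  }
  treated <- !is.na(data$on_lipid_med) & data$on_lipid_med & !is.na(data$ldl_measured)
  reduction <- rep(0, nrow(data))
  flag <- ifelse(treated, "", "none")
  if (any(treated)) {
    res <- lookup_reduction(data$med_drug[treated], data$med_dose[treated],
                            table, default_reduction)
    reduction[treated] <- res$reduction
    flag[treated] <- res$flag
  }
  data$ldl_untreated <- data$ldl_measured / (1 - reduction)
  data$ldl_correction <- flag
  data
}
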