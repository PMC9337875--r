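# ---- cohort I/O -----------------------------------------------------------

#' The 11-gene FH panel and its genomic regions
#'
#' Reads the panel configuration mapping each FH-related gene to a genomic
#' region (GRCh38, 1-based inclusive). The panel covers `LDLR`, `APOB`,
#' `PCSK9`, `APOE`, `LDLRAP1`, `CYP7A1`, `STAP1`, `ITIH4`, `EPHX2`, `GHR`
#' and `PPP1R17`. The regions ship as an editable config file rather than
#' hard-coded constants.
#'
#' @param path Optional path to an alternative panel file (TSV with columns
#'   `gene`, `chrom`, `start`, `end`).
#' @return A tibble with one row per panel gene.
#' @export
#' @examples
#' fh_panel()
fh_panel <- function(path = fh_extdata("fh_panel_grch38.tsv")) {
  readr::read_tsv(path, col_types = readr::cols(
    gene = "c", chrom = "c", start = "i", end = "i"
  ))
}

# canonical phenotype schema: required and optional columns with types
phenotype_schema <- function() {
  list(
    required = c("subject_id", "sex", "age", "on_lipid_med", "ldl_measured"),
    lipid = c("tc", "hdl", "ldl_measured", "tg"),
    logical = c("smoker", "hypertension", "diabetes", "hypothyroidism",
                "selfreport_hc", "on_lipid_med", "mi_history", "angina",
                "paternal_heart_disease", "maternal_heart_disease"),
    numeric = c("age", "bmi", "age_at_hc_dx", "med_dose", "age_at_mi",
                "tc", "hdl", "ldl_measured", "tg", "pc1", "pc2", "pc3", "pc4"),
    character = c("subject_id", "sex", "med_drug")
  )
}

as_logical_col <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "n", "0")] <- FALSE
  out
}

#' Read a subject phenotype table
#'
#' Reads the tab-delimited per-subject questionnaire/clinical/lipid table.
#' Column names can be remapped through `aliases` (e.g. a file using
#' `gender` instead of `sex`). Booleans accept TRUE/FALSE, 0/1 or yes/no;
#' empty fields and `NA` are treated as missing. Missing phenotype booleans
#' are kept missing, not imputed false: a subject who did not answer
#' contributes no points for that DLCN component downstream.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param aliases Named character vector mapping file column names to schema
#'   names, e.g. `c(gender = "sex")`.
#' @return A typed tibble of subjects. The number of rows with a missing
#'   LDL-C measurement is reported in a message and stored in the
#'   `n_missing_ldl` attribute.
#' @export
read_phenotypes <- function(path, aliases = NULL) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"))
  if (!is.null(aliases)) {
    hit <- names(aliases)[names(aliases) %in% names(raw)]
    names(raw)[match(hit, names(raw))] <- unname(aliases[hit])
  }
  sch <- phenotype_schema()
  missing_cols <- setdiff(sch$required, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Phenotype file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- raw
  for (col in intersect(sch$numeric, names(out))) {
    val <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(!is.na(out[[col]]) & is.na(val))
    if (length(bad)) {
      abort(paste0("Non-numeric value in column '", col, "' at data line(s) ",
                   paste(head(bad, 5), collapse = ", "),
                   " (e.g. '", out[[col]][bad[1]], "')."))
    }
    out[[col]] <- val
  }
  for (col in intersect(sch$logical, names(out))) {
    out[[col]] <- as_logical_col(out[[col]])
  }
  out$sex <- tolower(out$sex)
  bad_sex <- which(!out$sex %in% c("male", "female", "unknown") & !is.na(out$sex))
  if (length(bad_sex)) {
    abort(paste0("Unrecognized sex value(s): ",
                 paste(unique(out$sex[bad_sex]), collapse = ", ")))
  }
  if (anyDuplicated(out$subject_id)) abort("Duplicate subject_id values.")
  n_missing_ldl <- sum(is.na(out$ldl_measured))
  message(nrow(out), " subjects read; ", n_missing_ldl, " with missing LDL-C.")
  attr(out, "n_missing_ldl") <- n_missing_ldl
  out
}

#' Write a phenotype table
#'
#' @param phenotypes Tibble as returned by [read_phenotypes()].
#' @param path Output path (tab-delimited with header).
#' @return Invisibly, `path`.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_tsv(phenotypes, path)
  invisible(path)
}

# ---- VCF ------------------------------------------------------------------

strip_chr <- function(x) sub("^chr", "", x)

#' Read panel genotypes from a multi-sample VCF
#'
#' Reads a VCF (v4.2) with a GT FORMAT field, keeps only sites inside the
#' panel gene regions, decomposes multi-allelic sites into biallelic records,
#' and returns per-subject alternate-allele counts. Contig naming is
#' normalized so that `chr19` and `19` match regardless of which convention
#' the file or the panel uses.
#'
#' @param path Path to a VCF file.
#' @param panel Panel regions, as from [fh_panel()].
#' @return A list with `variants` (tibble: `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `rsid`, `mean_dp`) and `genotypes` (integer matrix
#'   subjects x variants of allele counts in 0/1/2, `NA` = missing call).
#' @export
read_vcf_genotypes <- function(path, panel = fh_panel()) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no variant records.")
  if (!"GT" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID &&
      !grepl("GT", vcf@gt[1, "FORMAT"])) {
    abort("VCF has no GT FORMAT field.")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)

  pos <- as.integer(fix$POS)
  chrom_n <- strip_chr(fix$CHROM)
  panel$chrom_n <- strip_chr(panel$chrom)

  # panel membership and gene assignment
  gene <- rep(NA_character_, nrow(fix))
  for (k in seq_len(nrow(panel))) {
    inside <- chrom_n == panel$chrom_n[k] & pos >= panel$start[k] & pos <= panel$end[k]
    gene[inside] <- panel$gene[k]
  }
  keep <- which(!is.na(gene))
  if (!length(keep)) {
    return(list(
      variants = tibble(variant_id = character(), chrom = character(),
                        pos = integer(), ref = character(), alt = character(),
                        gene = character(), rsid = character(),
                        mean_dp = double()),
      genotypes = matrix(integer(), nrow = length(samples), ncol = 0,
                         dimnames = list(samples, NULL))
    ))
  }

  # mean depth per site: INFO MDP if present, else mean of FORMAT DP
  info_mdp <- suppressWarnings(
    as.numeric(sub(".*MDP=([0-9.eE+-]+).*", "\\1", fix$INFO))
  )
  info_mdp[!grepl("MDP=", fix$INFO %||% "")] <- NA
  dp_mat <- tryCatch(
    suppressWarnings(apply(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE),
                           1, mean, na.rm = TRUE)),
    error = function(e) rep(NA_real_, nrow(fix))
  )
  mean_dp <- ifelse(is.na(info_mdp), dp_mat, info_mdp)

  rows <- list()
  counts <- list()
  for (i in keep) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    calls <- gt[i, ]
    alleles <- strsplit(calls, "[/|]")
    for (a in seq_along(alts)) {
      cnt <- vapply(alleles, function(al) {
        if (length(al) == 0 || any(al == ".") || all(is.na(al))) return(NA_integer_)
        sum(al == as.character(a))
      }, integer(1))
      cnt[is.na(calls)] <- NA_integer_
      rows[[length(rows) + 1L]] <- tibble(
        chrom = fix$CHROM[i], pos = pos[i], ref = fix$REF[i], alt = alts[a],
        gene = gene[i],
        rsid = if (is.na(fix$ID[i]) || fix$ID[i] == ".") NA_character_ else fix$ID[i],
        mean_dp = mean_dp[i]
      )
      counts[[length(counts) + 1L]] <- cnt
    }
  }
  variants <- bind_rows(rows)
  variants <- mutate(variants,
                     variant_id = paste(.data$chrom, .data$pos, .data$ref,
                                        .data$alt, sep = ":"),
                     .before = 1)
  geno <- do.call(cbind, counts)
  dimnames(geno) <- list(samples, variants$variant_id)
  list(variants = variants, genotypes = geno)
}

#' Write a genotype matrix as a VCF v4.2
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt`, `rsid` and
#'   optionally `mean_dp` (written to the INFO field as `MDP`).
#' @param genotypes Integer matrix subjects x variants of allele counts
#'   (0/1/2, `NA` = missing).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf_genotypes <- function(variants, genotypes, path) {
  stopifnot(nrow(variants) == ncol(genotypes))
  samples <- rownames(genotypes)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MDP,Number=1,Type=Float,Description=\"Mean depth of coverage across samples\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(nrow(variants)), function(i) {
    g <- genotypes[, i]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    info <- if ("mean_dp" %in% names(variants) && !is.na(variants$mean_dp[i])) {
      paste0("MDP=", variants$mean_dp[i])
    } else "."
    rsid <- variants$rsid[i]
    paste(c(variants$chrom[i], variants$pos[i],
            if (is.na(rsid)) "." else rsid,
            variants$ref[i], variants$alt[i], ".", "PASS", info, "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- annotations ----------------------------------------------------------

clinvar_tokens <- c("P", "LP", "VUS", "LB", "B", "NR")
hgmd_tokens <- c("DM", "DM?", "NR", "other")

#' Split a slash-delimited assertion label into a label set
#'
#' Composite ClinVar/LOVD-style labels such as `"P/LP/VUS"` record multiple
#' submitted interpretations for one variant; `"NR"` (not reported) maps to
#' the empty set.
#'
#' @param x Character vector of composite labels.
#' @param valid Allowed tokens.
#' @return A list of character vectors (one set per input label).
#' @export
#' @examples
#' parse_label_set("P/LP/VUS")
#' parse_label_set("NR")
parse_label_set <- function(x, valid = clinvar_tokens) {
  map(x, function(lab) {
    if (is.na(lab) || lab == "NR" || lab == "") return(character(0))
    toks <- strsplit(lab, "/", fixed = TRUE)[[1]]
    bad <- setdiff(toks, valid)
    if (length(bad)) {
      abort(paste0("Unknown assertion label token(s): ",
                   paste(bad, collapse = ", ")))
    }
    toks
  })
}

#' Read a variant annotation table
#'
#' Reads the tab-delimited per-variant table of database assertions
#' (ClinVar / HGMD / LOVD) and CADD PHRED scores. Composite slash-delimited
#' labels are validated and kept as strings; use [parse_label_set()] or
#' [is_known_pathogenic()] to work with the label sets. `NR` means the
#' database carries no assertion for the variant.
#'
#' @param path Path to a tab-delimited file with columns `clinvar`, `hgmd`,
#'   `lovd`, `cadd` and either `variant_id` or `chrom`/`pos`/`ref`/`alt`.
#' @return A tibble, one row per variant.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"))
  need <- c("clinvar", "hgmd", "lovd")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols)) {
    abort(paste0("Annotation file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"cadd" %in% names(ann)) ann$cadd <- NA_character_
  if (!"variant_id" %in% names(ann)) {
    if (!all(c("chrom", "pos", "ref", "alt") %in% names(ann))) {
      abort("Annotation file needs 'variant_id' or chrom/pos/ref/alt columns.")
    }
    ann$variant_id <- paste(ann$chrom, ann$pos, ann$ref, ann$alt, sep = ":")
  }
  ann$clinvar[is.na(ann$clinvar)] <- "NR"
  ann$hgmd[is.na(ann$hgmd)] <- "NR"
  ann$lovd[is.na(ann$lovd)] <- "NR"
  # validate label tokens eagerly so bad files fail at read time
  invisible(parse_label_set(ann$clinvar, clinvar_tokens))
  invisible(parse_label_set(ann$lovd, clinvar_tokens))
  bad_hgmd <- setdiff(unique(ann$hgmd), hgmd_tokens)
  if (length(bad_hgmd)) {
    abort(paste0("Unknown HGMD label token(s): ", paste(bad_hgmd, collapse = ", ")))
  }
  ann$cadd <- suppressWarnings(as.numeric(ann$cadd))
  if ("pos" %in% names(ann)) ann$pos <- as.integer(ann$pos)
  for (col in intersect(c("n_het", "dlcn_penetrance", "hc_penetrance", "maf"),
                        names(ann))) {
    ann[[col]] <- suppressWarnings(as.numeric(ann[[col]]))
  }
  ann
}
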