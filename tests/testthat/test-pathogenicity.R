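# build a tiny cohort in which each variant has a prescribed number of
# carriers and of carriers meeting the high-cholesterol criterion
build_penetrance_cohort <- function(design, n_extra = 20) {
  design$n_meet <- pmin(design$n_meet, design$n_het)
  total <- sum(design$n_het) + n_extra
  ids <- sprintf("p%03d", seq_len(total))
  phen_rows <- list()
  geno <- matrix(0L, nrow = total, ncol = nrow(design),
                 dimnames = list(ids, design$variant_id))
  at <- 1
  for (i in seq_len(nrow(design))) {
    nh <- design$n_het[i]
    if (nh == 0) next
    meets <- c(rep(TRUE, design$n_meet[i]), rep(FALSE, nh - design$n_meet[i]))
    for (m in meets) {
      phen_rows[[at]] <- make_subject(ids[at], selfreport_hc = m,
                                      ldl_untreated = 3.0)
      geno[at, i] <- 1L
      at <- at + 1
    }
  }
  while (at <= total) {
    phen_rows[[at]] <- make_subject(ids[at], ldl_untreated = 3.0)
    at <- at + 1
  }
  phen <- dplyr::bind_rows(phen_rows)
  variants <- tibble::tibble(variant_id = design$variant_id,
                             gene = design$gene, mean_dp = 35)
  annotations <- tibble::tibble(
    variant_id = design$variant_id, clinvar = design$clinvar,
    hgmd = design$hgmd, lovd = design$lovd, cadd = design$cadd
  )
  list(variants = variants, genotypes = geno, annotations = annotations,
       phenotypes = phen)
}

test_that("two-database rule: qualifying labels, quorum, composites", {
  ann <- tibble::tibble(
    variant_id = paste0("v", 1:5),
    clinvar = c("VUS", "P", "NR", "P/LP/VUS", "B"),
    hgmd    = c("DM",  "NR", "NR", "NR",      "DM"),
    lovd    = c("LP",  "NR", "NR", "LP",      "NR")
  )
  res <- is_known_pathogenic(ann)
  expect_identical(res$known_pathogenic, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_identical(res$supporting_databases[1], "HGMD,LOVD")
  expect_identical(res$supporting_databases[4], "ClinVar,LOVD")
  expect_identical(res$supporting_databases[3], "")
})

test_that("every assertion triple in the shipped known-pathogenic table qualifies", {
  ann <- read_annotations(fh_extdata("known_pathogenic_fh_variants.tsv"))
  res <- is_known_pathogenic(ann)
  expect_equal(nrow(res), 17)
  expect_true(all(res$known_pathogenic))
})

test_that("HC-penetrance reproduces carrier-fraction arithmetic", {
  phen <- dplyr::bind_rows(
    make_subject("c1", selfreport_hc = TRUE, ldl_untreated = 3.0),
    make_subject("c2", ldl_untreated = 3.0),
    make_subject("c3", ldl_untreated = 3.2),
    make_subject("c4", on_lipid_med = TRUE, ldl_untreated = 2.5)
  )
  expect_equal(hc_penetrance(phen, c("c1", "c2", "c3")), 33.3)
  expect_equal(hc_penetrance(phen, c("c1", "c2")), 50.0)
  expect_equal(hc_penetrance(phen, c("c1", "c4")), 100.0)  # meds branch
  expect_equal(hc_penetrance(phen, character(0)), NA_real_)
  # LDL branch is strict: 3.3 exactly does not qualify
  phen2 <- make_subject("b", ldl_untreated = 3.3)
  expect_equal(hc_penetrance(phen2, "b"), 0)
  expect_equal(hc_penetrance(dplyr::mutate(phen2, ldl_untreated = 3.31), "b"),
               100)
})

test_that("HC-penetrance is monotone in criterion-meeting carriers", {
  n <- 12
  for (k in 0:n) {
    phen <- make_subjects(n, ldl_untreated = 3.0)
    phen$selfreport_hc <- seq_len(n) <= k
    expect_equal(hc_penetrance(phen, phen$subject_id),
                 round(100 * k / n, 1))
  }
})

test_that("DLCN-penetrance counts phenotype-only scores of 3+", {
  mk <- function(n, n_pen) {
    phen <- make_subjects(n, ldl_untreated = 3.0)
    phen$ldl_untreated[seq_len(n_pen)] <- 5.5   # 3 LDL points
    dlcn_score(phen)
  }
  expect_equal(dlcn_penetrance(mk(13, 11), sprintf("s%03d", 1:13)), 84.6)
  expect_equal(dlcn_penetrance(mk(6, 5), sprintf("s%03d", 1:6)), 83.3)
  expect_equal(dlcn_penetrance(mk(4, 0), sprintf("s%03d", 1:4)), 0)
  expect_equal(dlcn_penetrance(mk(4, 0), character(0)), NA_real_)
})

test_that("possibly-pathogenic rule: CADD strictly above 20, penetrance at least 50", {
  expect_identical(
    is_possibly_pathogenic(c(20.5, 24.9, 19.9, 34, 20, NA),
                           c(100, 50, 100, 49, 100, 100)),
    c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  shipped <- read_annotations(fh_extdata("possibly_pathogenic_fh_variants.tsv"))
  expect_equal(nrow(shipped), 18)
  expect_true(all(is_possibly_pathogenic(shipped$cadd, shipped$hc_penetrance)))
})

test_that("assessment keeps exactly the qualifying variants among distractors", {
  known <- read_annotations(fh_extdata("known_pathogenic_fh_variants.tsv"))
  design_known <- tibble::tibble(
    variant_id = known$variant_id, gene = known$gene,
    clinvar = known$clinvar, hgmd = known$hgmd, lovd = known$lovd,
    cadd = NA_real_, n_het = known$n_het, n_meet = known$n_het
  )
  distract <- tibble::tibble(
    variant_id = paste0("d", 1:5), gene = "LDLR",
    clinvar = c("P", "NR", "VUS", "NR", "B"),
    hgmd = c("NR", "DM", "NR", "NR", "NR"),
    lovd = c("NR", "NR", "LP", "NR", "LB"),
    cadd = NA_real_, n_het = 2, n_meet = 2
  )
  fx <- build_penetrance_cohort(dplyr::bind_rows(design_known, distract))
  res <- assess_variants(fx$variants, fx$genotypes, fx$annotations,
                         fx$phenotypes)
  expect_equal(sum(res$class == "known_pathogenic"), 17)
  expect_identical(sort(res$variant_id[res$class == "known_pathogenic"]),
                   sort(known$variant_id))
})

test_that("assessment applies the in-silico rule only beyond the known class", {
  poss <- read_annotations(fh_extdata("possibly_pathogenic_fh_variants.tsv"))
  design <- tibble::tibble(
    variant_id = poss$variant_id, gene = poss$gene,
    clinvar = "NR", hgmd = "NR", lovd = "NR",
    cadd = poss$cadd, n_het = poss$n_het,
    n_meet = round(poss$hc_penetrance / 100 * poss$n_het)
  )
  distract <- tibble::tibble(
    variant_id = paste0("d", 1:4), gene = "APOB",
    clinvar = "NR", hgmd = "NR", lovd = "NR",
    cadd = c(19.9, 34, NA, 30),
    n_het = c(3, 4, 3, 0),         # last one: zero carriers
    n_meet = c(3, 1, 3, 0)         # CADD fail / penetrance fail / no CADD
  )
  fx <- build_penetrance_cohort(dplyr::bind_rows(design, distract))
  res <- assess_variants(fx$variants, fx$genotypes, fx$annotations,
                         fx$phenotypes)
  expect_equal(sum(res$class == "possibly_pathogenic"), 18)
  expect_identical(sort(res$variant_id[res$class == "possibly_pathogenic"]),
                   sort(poss$variant_id))
  # zero-carrier distractor has undefined penetrance, never "possibly"
  expect_identical(res$class[res$variant_id == "d4"], "other")
  expect_true(is.na(res$hc_penetrance[res$variant_id == "d4"]))
})

test_that("classes partition the variant set", {
  co <- generate_cohort(sim_config(n_subjects = 1500, seed = 13))
  phen <- correct_ldl(build_analysis_cohort(co$phenotypes),
                      fh_correction_table())
  res <- assess_variants(co$variants, co$genotypes, co$annotations, phen)
  expect_equal(nrow(res), nrow(co$variants))
  expect_true(all(res$class %in%
                    c("known_pathogenic", "possibly_pathogenic", "other")))
})

test_that("an empty annotation table with no carriers yields only 'other'", {
  variants <- tibble::tibble(variant_id = c("v1", "v2"), gene = "LDLR",
                             mean_dp = 30)
  geno <- matrix(0L, 5, 2, dimnames = list(sprintf("s%03d", 1:5),
                                           c("v1", "v2")))
  phen <- make_subjects(5, ldl_untreated = 3.0)
  ann <- tibble::tibble(variant_id = character(), clinvar = character(),
                        hgmd = character(), lovd = character(),
                        cadd = double())
  res <- assess_variants(variants, geno, ann, phen)
  expect_identical(res$class, c("other", "other"))
})

test_that("fully expressive synthetic pathogenic variants reach 100% exactly", {
  v <- sim_variant("LDLR", pos = 11102789, maf = 2e-4,
                   truth_class = "pathogenic", ldl_shift = 3.5,
                   hgmd = "DM", lovd = "LP", clinvar = "P", cadd = 26)
  cfg <- sim_config(n_subjects = 20000, variants = v, seed = 77,
                    selfreport_sensitivity = 1, selfreport_specificity = 1,
                    selfreport_missing_rate = 0, missing_ldl_rate = 0)
  co <- generate_cohort(cfg)
  phen <- correct_ldl(build_analysis_cohort(co$phenotypes),
                      cfg$correction_table)
  res <- assess_variants(co$variants, co$genotypes, co$annotations, phen)
  expect_gt(res$n_carriers, 0)
  # baseline is truncated at 0.5 mmol/L, so every carrier exceeds
  # 0.5 + 3.5 = 4.0 > 3.3: penetrance is exactly 100
  expect_identical(res$hc_penetrance, 100)
})
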