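test_that("call rate is the called fraction and ignores subject order", {
  g <- geno_vec(97, 0, 0, 3)
  expect_equal(call_rate(rep(0L, 100)), 1.0)
  expect_equal(call_rate(g), 0.97)
  expect_equal(call_rate(sample(g)), 0.97)
})

test_that("HWE chi-square matches hand-checkable cases", {
  expect_equal(hwe_chisq(25, 50, 25), tibble::tibble(chi2 = 0, p = 1))
  res <- hwe_chisq(50, 0, 50)              # total het deficit at p = 0.5
  expect_equal(res$chi2, 100)
  expect_lt(res$p, 1e-20)
  expect_gt(hwe_chisq(999, 1, 0)$p, 0.95)  # singleton het is ~exact HWE
  mono <- hwe_chisq(100, 0, 0)             # monomorphic passes by definition
  expect_equal(mono$chi2, 0)
  expect_equal(mono$p, 1)
})

test_that("HWE chi-square agrees with the closed-form identity", {
  set.seed(42)
  for (i in 1:200) {
    cc <- as.integer(rmultinom(1, sample(10:5000, 1), runif(3)))
    expect_equal(hwe_chisq(cc[1], cc[2], cc[3])$chi2,
                 hwe_chi2_closed_form(cc[1], cc[2], cc[3]),
                 tolerance = 1e-8)
  }
})

test_that("minor allele frequency uses called alleles only", {
  g <- geno_vec(14656, 13, 0, 0)
  expect_equal(minor_allele_frequency(g), 13 / (2 * 14669), tolerance = 1e-12)
  expect_equal(round(minor_allele_frequency(g), 7), 4.431e-4)
  expect_equal(minor_allele_frequency(rep(0L, 50)), 0)
  expect_equal(minor_allele_frequency(c(rep(0L, 99), 1L)), 1 / 200)
  # missing calls shrink the denominator
  expect_equal(minor_allele_frequency(c(0, 1, NA, NA)), 1 / 4)
  # folded at 0.5
  expect_equal(minor_allele_frequency(rep(2L, 10)), 0)
})

make_qc_fixture <- function() {
  n <- 10000
  cols <- list(
    pass      = geno_vec(n - 10, 10, 0, 0, seed = 1),
    call_rate = geno_vec(n - 310, 10, 0, 300, seed = 2),    # 97% < 98%
    hwe       = geno_vec(n - 40, 0, 40, 0, seed = 3),       # homs, no hets
    depth     = geno_vec(n - 10, 10, 0, 0, seed = 4),
    maf       = geno_vec(n - 200, 200, 0, 0, seed = 5),     # maf 0.01
    maf2      = geno_vec(n - 150, 150, 0, 0, seed = 6)      # maf 0.0075
  )
  geno <- do.call(cbind, cols)
  rownames(geno) <- sprintf("s%05d", seq_len(n))
  variants <- tibble::tibble(
    variant_id = names(cols),
    mean_dp = c(35, 35, 35, 5, 35, 35)
  )
  list(variants = variants, genotypes = geno)
}

test_that("variant filter is the conjunction, with a first-fail log", {
  fx <- make_qc_fixture()
  res <- filter_variants(fx$variants, fx$genotypes)
  expect_identical(res$variant_id[res$keep], "pass")
  fails <- setNames(res$fail_reason, res$variant_id)
  expect_identical(unname(fails[c("call_rate", "hwe", "depth", "maf", "maf2")]),
                   c("call_rate", "hwe", "depth", "maf", "maf"))
  expect_setequal(unique(na.omit(res$fail_reason)),
                  c("call_rate", "hwe", "depth", "maf"))
})

test_that("relaxed thresholds retain everything; retained set matches brute force", {
  fx <- make_qc_fixture()
  lax <- qc_thresholds(min_variant_call_rate = 0, hwe_p_min = 0,
                       min_depth = 0, max_maf = 0.5)
  expect_true(all(filter_variants(fx$variants, fx$genotypes, lax)$keep))

  th <- qc_thresholds()
  res <- filter_variants(fx$variants, fx$genotypes, th)
  brute <- vapply(seq_len(ncol(fx$genotypes)), function(j) {
    g <- fx$genotypes[, j]
    cr <- mean(!is.na(g))
    hw <- hwe_chisq(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                    sum(g == 2, na.rm = TRUE))$p
    maf <- minor_allele_frequency(g)
    cr >= th$min_variant_call_rate && hw >= th$hwe_p_min &&
      fx$variants$mean_dp[j] >= th$min_depth && maf < th$max_maf
  }, logical(1))
  expect_identical(res$keep, brute)
})

test_that("sample filter: low call rate out, sd-0 guard, het outlier out", {
  set.seed(31)
  n <- 200; m <- 60
  geno <- matrix(rbinom(n * m, 1L, 0.1), n, m,
                 dimnames = list(sprintf("s%03d", 1:n), NULL))
  geno[1, 1:10] <- NA           # call rate 50/60 = 83% < 95%
  geno[2, ] <- 1L               # heterozygosity far above the cohort mean
  res <- filter_samples(geno)
  expect_identical(res$fail_reason[1], "call_rate")
  expect_identical(res$fail_reason[2], "het_excess")
  expect_true(all(res$keep[-(1:2)]))

  # all-identical samples: het sd is 0, nobody excluded for heterozygosity
  same <- matrix(1L, 50, 10, dimnames = list(sprintf("t%02d", 1:50), NULL))
  expect_true(all(filter_samples(same)$keep))

  # precomputed sex-ambiguity flags are honoured
  res2 <- filter_samples(geno, sex_ambiguous = "s005")
  expect_identical(res2$fail_reason[res2$subject_id == "s005"], "sex_ambiguity")
})

test_that("analysis cohort drops missing-LDL then hypothyroid, counting once", {
  phen <- tibble::tibble(
    subject_id = c("a", "b", "c", "d"),
    ldl_measured = c(3, NA, 4, NA),
    hypothyroidism = c(FALSE, FALSE, TRUE, TRUE)
  )
  out <- build_analysis_cohort(phen)
  expect_identical(out$subject_id, "a")
  exc <- attr(out, "exclusions")
  expect_identical(exc$reason[exc$subject_id == "d"], "ldl_missing")
  expect_equal(sum(exc$reason == "ldl_missing"), 2)
  expect_equal(sum(exc$reason == "hypothyroid"), 1)

  none <- tibble::tibble(subject_id = "a", ldl_measured = 3,
                         hypothyroidism = FALSE)
  expect_identical(build_analysis_cohort(none)$subject_id, "a")
})
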