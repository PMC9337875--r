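sim_burden_data <- function(n, carrier_rate, beta, base_rate = 0.2,
                            seed = 1) {
  withr::with_seed(seed, {
    carrier <- rbinom(n, 1, carrier_rate) == 1
    age <- rnorm(n, 40, 12)
    sex <- sample(c("male", "female"), n, replace = TRUE)
    eta <- qlogis(base_rate) + 0.02 * (age - 40) + beta * carrier
    tibble::tibble(hc = rbinom(n, 1, plogis(eta)) == 1, carrier = carrier,
                   age = age, sex = sex,
                   pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n),
                   pc4 = rnorm(n))
  })
}

test_that("a fully penetrant rare burden is detected with positive beta", {
  set.seed(2)
  d <- sim_burden_data(4000, 0, beta = 0, base_rate = 0.02)
  d$carrier[1:20] <- TRUE
  d$hc[1:20] <- TRUE                 # all 20 carriers affected: separation
  fit <- burden_test(d)
  expect_s3_class(fit, "fh_burden")
  expect_identical(fit$method, "firth")   # separation forces the penalized fit
  expect_gt(fit$beta, 0)
  expect_true(is.finite(fit$beta) && is.finite(fit$se))
  expect_lt(fit$p, 1e-4)
})

test_that("degenerate carrier sets give a no-test result, not an estimate", {
  d <- sim_burden_data(200, 0, beta = 0)
  fit <- burden_test(d)
  expect_identical(fit$method, "none")
  expect_true(is.na(fit$beta) && is.na(fit$p))
  d$carrier <- TRUE
  expect_identical(burden_test(d)$method, "none")
})

test_that("zero-variance covariates do not move the estimate", {
  d <- sim_burden_data(1500, 0.05, beta = 1.2, seed = 4)
  fit <- burden_test(d, covariates = c("age", "sex"))
  d$flat <- 3.7
  fit2 <- burden_test(d, covariates = c("age", "sex", "flat"))
  expect_equal(fit2$beta, fit$beta)
  expect_equal(fit2$se, fit$se)
  expect_equal(fit2$p, fit$p)
})

test_that("Firth and ML agree on well-separated-free data", {
  d <- sim_burden_data(3000, 0.10, beta = 0.8, base_rate = 0.3, seed = 6)
  ml <- burden_test(d, method = "glm")
  firth <- burden_test(d, method = "firth")
  expect_identical(ml$method, "glm")
  expect_lt(abs(ml$beta - firth$beta), 0.05)
  expect_lt(abs(ml$se - firth$se) / ml$se, 0.05)
})

test_that("effect recovery improves with sample size", {
  beta_true <- 1.5
  small <- burden_test(sim_burden_data(4000, 0.05, beta_true, seed = 8))
  big <- burden_test(sim_burden_data(24000, 0.05, beta_true, seed = 9))
  expect_lt(abs(big$beta - beta_true), 3 * big$se)
  expect_lt(big$se, small$se)
  expect_lt(abs(big$beta - beta_true), 0.2)
})

test_that("tidy and glance expose the fit in broom form", {
  d <- sim_burden_data(1200, 0.08, beta = 1.0, seed = 10)
  fit <- burden_test(d, gene = "LDLR")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in% names(td)))
  expect_true("carrier" %in% td$term)
  expect_equal(td$estimate[td$term == "carrier"], fit$beta)
  expect_equal(td$p.value[td$term == "carrier"], fit$p)
  gl <- glance(fit)
  expect_equal(gl$gene, "LDLR")
  expect_equal(gl$beta, fit$beta)
  # no-test objects tidy to zero rows
  d0 <- d; d0$carrier <- FALSE
  expect_equal(nrow(tidy(burden_test(d0))), 0)
})

test_that("burden_scan collapses per-gene variants against the cohort", {
  v <- dplyr::bind_rows(
    sim_variant("LDLR", pos = 11102789, maf = 2e-3 / 2, truth_class = "pathogenic",
                ldl_shift = 3.5, hgmd = "DM", lovd = "LP", clinvar = "P",
                cadd = 26),
    sim_variant("LDLR", pos = 11102800, maf = 1e-3, truth_class = "pathogenic",
                ldl_shift = 3.5, hgmd = "DM", lovd = "LP", clinvar = "P",
                cadd = 25),
    sim_variant("APOE", pos = 44909000, maf = 1e-3, truth_class = "benign",
                ldl_shift = 0, lovd = "LB", clinvar = "B", cadd = 2)
  )
  cfg <- sim_config(n_subjects = 6000, variants = v, seed = 33)
  co <- generate_cohort(cfg)
  phen <- correct_ldl(build_analysis_cohort(co$phenotypes),
                      cfg$correction_table)
  ass <- assess_variants(co$variants, co$genotypes, co$annotations, phen)
  phen$hc <- (!is.na(phen$selfreport_hc) & phen$selfreport_hc) |
    phen$on_lipid_med | phen$ldl_untreated > 3.3
  res <- burden_scan(ass, co$genotypes, phen)
  expect_identical(res$gene, "LDLR")            # APOE variant is not qualifying
  expect_equal(res$n_variants, 2)
  expect_gt(res$beta, 0)
  expect_lt(res$p, 0.01)
  expect_s3_class(res$fit[[1]], "fh_burden")
})
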