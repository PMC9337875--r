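# ---- gene-collapsed carrier burden test -----------------------------------

# Firth-penalized logistic regression (Jeffreys-prior penalty), fitted by
# Newton iterations on the modified score U* = X'(y - mu + h (1/2 - mu)).
# Rare-variant burden indicators routinely separate the data (every carrier
# affected), where plain ML estimates diverge; the penalized estimates stay
# finite.
firth_logit <- function(X, y, maxit = 100, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen_loglik <- function(beta) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    I <- crossprod(X, X * (mu * (1 - mu)))
    sum(y * eta - log1p(exp(eta))) +
      0.5 * as.numeric(determinant(I, logarithm = TRUE)$modulus)
  }
  pl <- pen_loglik(beta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    mu <- plogis(drop(X %*% beta))
    w <- mu * (1 - mu)
    I <- crossprod(X, X * w)
    Iinv <- solve(I)
    h <- rowSums((X %*% Iinv) * X) * w
    U <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    delta <- drop(Iinv %*% U)
    # step-halving to keep the penalized log-likelihood increasing
    step <- 1
    repeat {
      cand <- beta + step * delta
      pl_new <- pen_loglik(cand)
      if (is.finite(pl_new) && pl_new >= pl - 1e-12) break
      step <- step / 2
      if (step < 1e-10) break
    }
    beta <- beta + step * delta
    pl <- pen_loglik(beta)
    if (max(abs(step * delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  mu <- plogis(drop(X %*% beta))
  I <- crossprod(X, X * (mu * (1 - mu)))
  list(coefficients = setNames(beta, colnames(X)),
       vcov = solve(I), pen_loglik = pl, converged = converged)
}

detect_separation <- function(fit) {
  eps <- 1e-6
  probs <- fitted(fit)
  co <- coef(fit)[-1]
  se <- sqrt(diag(vcov(fit)))[-1]
  any(probs < eps | probs > 1 - eps) || !fit$converged ||
    any(abs(co) > 10, na.rm = TRUE) || any(se > 50, na.rm = TRUE)
}

#' Gene-collapsed carrier burden test
#'
#' Collapses all qualifying (pathogenic / possibly pathogenic) variants in a
#' gene into a single carrier indicator and regresses case status on it with
#' covariate adjustment, by logistic regression. When the data are separated
#' — the expected regime when a handful of carriers are all affected — the
#' fit switches to Firth-penalized logistic regression, whose estimates stay
#' finite. The p-value is a (penalized) likelihood-ratio test of the carrier
#' term. Adjustment uses fixed covariates only; relatedness is assumed
#' negligible or handled upstream.
#'
#' @param data Tibble with the outcome, carrier indicator and covariates.
#' @param carrier Name of the logical/0-1 carrier indicator column.
#' @param outcome Name of the binary case-status column (e.g. affected by
#'   hypercholesterolemia).
#' @param covariates Covariate column names; zero-variance covariates are
#'   dropped (they cannot affect the fit).
#' @param gene Optional gene label carried into the result.
#' @param method `"auto"` (default: plain logistic, Firth on separation),
#'   `"glm"` or `"firth"`.
#' @return An object of class `fh_burden` with the carrier log-odds `beta`,
#'   its `se`, the likelihood-ratio `p`, carrier counts and the method used.
#'   `tidy()` and `glance()` methods are provided. Zero carriers (or zero
#'   non-carriers) give a no-test result with `NA` estimates.
#' @export
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(
#'   hc = rbinom(500, 1, 0.2) == 1, carrier = rbinom(500, 1, 0.05) == 1,
#'   age = rnorm(500, 40, 10), sex = sample(c("male", "female"), 500, TRUE))
#' burden_test(d, gene = "LDLR")
burden_test <- function(data, carrier = "carrier", outcome = "hc",
                        covariates = intersect(c("age", "sex", "pc1", "pc2",
                                                 "pc3", "pc4"), names(data)),
                        gene = NA_character_,
                        method = c("auto", "glm", "firth")) {
  method <- match.arg(method)
  need <- c(carrier, outcome, covariates)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("burden_test needs column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  d <- data[stats::complete.cases(data[need]), need, drop = FALSE]
  y <- as.integer(as.logical(d[[outcome]]))
  if (any(is.na(y))) abort("Outcome must be binary (logical or 0/1).")
  carr <- as.integer(as.logical(d[[carrier]]))
  n_carriers <- sum(carr)
  no_test <- function(note) {
    structure(list(gene = gene, n = nrow(d), n_carriers = n_carriers,
                   beta = NA_real_, se = NA_real_, p = NA_real_,
                   method = "none", converged = NA, covariates = covariates,
                   note = note),
              class = "fh_burden")
  }
  if (n_carriers == 0) return(no_test("no carriers: burden not testable"))
  if (n_carriers == nrow(d)) return(no_test("no non-carriers: burden not testable"))

  # zero-variance covariates cannot affect the fit; drop them
  keep_cov <- covariates[vapply(covariates, function(cv) {
    x <- d[[cv]]
    length(unique(x[!is.na(x)])) > 1
  }, logical(1))]
  rhs <- paste(c(carrier, keep_cov), collapse = " + ")
  f_full <- stats::as.formula(paste(outcome, "~", rhs))
  d[[outcome]] <- y
  d[[carrier]] <- carr

  mm <- stats::model.matrix(f_full, data = d)
  carrier_col <- which(colnames(mm) == carrier)

  use_firth <- method == "firth"
  glm_fit <- NULL
  if (!use_firth) {
    glm_fit <- suppressWarnings(glm(f_full, data = d, family = binomial()))
    if (method == "auto" && detect_separation(glm_fit)) use_firth <- TRUE
  }

  if (use_firth) {
    full <- firth_logit(mm, y)
    red <- firth_logit(mm[, -carrier_col, drop = FALSE], y)
    beta <- full$coefficients[[carrier]]
    se <- sqrt(diag(full$vcov))[carrier_col]
    lr <- 2 * (full$pen_loglik - red$pen_loglik)
    p <- pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
    out <- list(gene = gene, n = nrow(d), n_carriers = n_carriers,
                beta = beta, se = se, p = p, method = "firth",
                converged = full$converged, covariates = keep_cov,
                coefficients = full$coefficients, vcov = full$vcov,
                note = NULL)
  } else {
    f_red <- stats::as.formula(paste(outcome, "~",
                                     paste(c("1", keep_cov), collapse = " + ")))
    red <- glm(f_red, data = d, family = binomial())
    lr <- as.numeric(2 * (logLik(glm_fit) - logLik(red)))
    p <- pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
    beta <- coef(glm_fit)[[carrier]]
    se <- sqrt(diag(vcov(glm_fit)))[[carrier]]
    out <- list(gene = gene, n = nrow(d), n_carriers = n_carriers,
                beta = beta, se = se, p = p, method = "glm",
                converged = glm_fit$converged, covariates = keep_cov,
                coefficients = coef(glm_fit), vcov = vcov(glm_fit),
                note = NULL)
  }
  structure(out, class = "fh_burden")
}

#' @export
print.fh_burden <- function(x, ...) {
  cat("<fh_burden>", if (!is.na(x$gene)) paste0(" gene: ", x$gene), "\n", sep = "")
  if (x$method == "none") {
    cat("  ", x$note, "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("  n = %d (%d carriers); beta = %.3f, SE = %.3f, p = %.3g [%s]\n",
              x$n, x$n_carriers, x$beta, x$se, x$p, x$method))
  invisible(x)
}

#' Burden tests for a set of genes
#'
#' Runs [burden_test()] once per gene, collapsing all variants of the given
#' pathogenicity classes in that gene into one carrier indicator.
#'
#' @param assessments An [assess_variants()] result.
#' @param genotypes Allele-count matrix (subjects x variants).
#' @param phenotypes Phenotype tibble for the analysis cohort; must contain
#'   the outcome and covariates.
#' @param genes Genes to test; default, every gene with at least one
#'   qualifying variant.
#' @param classes Variant classes collapsed into the burden indicator.
#' @param outcome,covariates,method Passed to [burden_test()].
#' @return A tibble, one row per gene, with the `fh_burden` fits in a list
#'   column.
#' @export
burden_scan <- function(assessments, genotypes, phenotypes,
                        genes = NULL,
                        classes = c("known_pathogenic", "possibly_pathogenic"),
                        outcome = "hc",
                        covariates = intersect(c("age", "sex", "pc1", "pc2",
                                                 "pc3", "pc4"),
                                               names(phenotypes)),
                        method = "auto") {
  qual <- assessments[assessments$class %in% classes, , drop = FALSE]
  if (is.null(genes)) genes <- unique(qual$gene)
  geno <- genotypes[match(phenotypes$subject_id, rownames(genotypes)), ,
                    drop = FALSE]
  purrr::map_dfr(genes, function(gn) {
    ids <- intersect(qual$variant_id[qual$gene == gn], colnames(geno))
    carrier <- if (length(ids)) {
      rowSums(geno[, ids, drop = FALSE] >= 1, na.rm = TRUE) > 0
    } else {
      rep(FALSE, nrow(geno))
    }
    d <- phenotypes
    d$carrier <- carrier
    fit <- burden_test(d, carrier = "carrier", outcome = outcome,
                       covariates = covariates, gene = gn, method = method)
    tibble(gene = gn, n_variants = length(ids), n_carriers = fit$n_carriers,
           beta = fit$beta, se = fit$se, p = fit$p, method = fit$method,
           fit = list(fit))
  })
}
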