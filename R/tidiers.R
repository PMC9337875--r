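# broom-style accessors for burden fits

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a burden-test fit
#'
#' @param x An `fh_burden` object.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`,
#'   `std.error`, `statistic` (Wald z), `p.value` (likelihood-ratio for the
#'   carrier term, Wald otherwise).
#' @export
tidy.fh_burden <- function(x, ...) {
  if (x$method == "none") {
    return(tibble(term = character(), estimate = double(),
                  std.error = double(), statistic = double(),
                  p.value = double()))
  }
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  z <- est / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  out <- tibble(term = names(est), estimate = unname(est),
                std.error = unname(se), statistic = unname(z),
                p.value = unname(p))
  carrier_term <- setdiff(names(est), c("(Intercept)", x$covariates))
  # report the LRT p for the carrier term (matches the headline p of the fit)
  out$p.value[match(carrier_term[1], out$term)] <- x$p
  out
}

#' One-line summary of a burden-test fit
#'
#' @param x An `fh_burden` object.
#' @param ... Unused.
#' @return A one-row tibble: `gene`, `n`, `n_carriers`, `beta`, `se`, `p`,
#'   `method`, `converged`.
#' @export
glance.fh_burden <- function(x, ...) {
  tibble(gene = x$gene, n = x$n, n_carriers = x$n_carriers,
         beta = x$beta, se = x$se, p = x$p,
         method = x$method, converged = isTRUE(x$converged))
}
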