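#' Tidy a haplotype regression fit
#'
#' @param x A `haplo_fit` from [haplotype_regression()] or
#'   [dosage_regression()].
#' @param ... Unused.
#' @return The per-haplotype association tibble: `label`, `alleles`,
#'   `n`, `beta`, `se`, `z`, `or`, `ci_lo`, `ci_hi`, `p`, `neglog10p`,
#'   `class` (the reference row carries `class = "reference"`).
#' @method tidy haplo_fit
#' @export
tidy.haplo_fit <- function(x, ...) {
  x$table
}

#' One-row summary of a haplotype regression fit
#'
#' @inheritParams tidy.haplo_fit
#' @return A one-row tibble: `model` (`"counts"` or `"dosages"`),
#'   `n_haplotypes`, `reference`, `alpha`, `n_used`, `n_excluded`,
#'   `loglik`, `converged`.
#' @method glance haplo_fit
#' @export
glance.haplo_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_haplotypes = nrow(x$table) - 1L,
    reference = x$reference,
    alpha = x$alpha,
    n_used = x$n_used,
    n_excluded = x$n_excluded,
    loglik = x$loglik,
    converged = x$converged
  )
}
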