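#' Enumerate best-guess haplotypes over the candidate variants
#'
#' Collapses the phased matrix (restricted to the candidate variants) to
#' the distinct haplotypes actually observed, with chromosome counts and
#' per-group frequencies. Labels are deterministic: haplotypes are sorted
#' by ascending risk-allele count, ties by the binary allele string, and
#' labelled `H0`, `H1`, ... — so the all-nonrisk haplotype, when observed,
#' is always `H0`.
#'
#' @param hm Phased 0/1 haplotype matrix (2 rows per individual), columns
#'   named by variant id.
#' @param pheno Optional phenotype tibble with `y` aligned to the
#'   individuals of `hm`; enables case/control frequencies.
#' @param candidates Optional character vector of variant ids (subset of
#'   the columns) defining the haplotypes; default all columns.
#' @return Tibble with columns `label`, `alleles` (0/1 string in variant
#'   order), `n_risk`, `n`, `freq`, and (when `pheno` is given)
#'   `freq_cases`, `freq_controls`.
#' @export
enumerate_haplotypes <- function(hm, pheno = NULL, candidates = NULL) {
  assert_binary_matrix(hm)
  if (!is.null(candidates)) {
    miss <- setdiff(candidates, colnames(hm))
    if (length(miss)) {
      abort(sprintf("candidate variant(s) not in matrix: %s", paste(miss, collapse = ", ")))
    }
    hm <- hm[, candidates, drop = FALSE]
  }
  if (!ncol(hm)) abort("candidate set must be non-empty.")
  strs <- apply(hm, 1L, hap_to_string)
  tab <- table(strs)
  out <- tibble::tibble(
    alleles = names(tab),
    n = as.integer(tab)
  )
  out$n_risk <- vapply(out$alleles, function(s) sum(string_to_hap(s)), integer(1))
  out <- out[order(out$n_risk, out$alleles), , drop = FALSE]
  out$label <- paste0("H", seq_len(nrow(out)) - 1L)
  out$freq <- out$n / nrow(hm)
  if (!is.null(pheno)) {
    y_chrom <- rep(pheno$y, each = 2L)
    case_tab <- table(factor(strs[y_chrom == 1L], levels = out$alleles))
    ctrl_tab <- table(factor(strs[y_chrom == 0L], levels = out$alleles))
    out$freq_cases <- as.integer(case_tab) / max(sum(y_chrom == 1L), 1L)
    out$freq_controls <- as.integer(ctrl_tab) / max(sum(y_chrom == 0L), 1L)
  }
  out[, c("label", "alleles", "n_risk", "n", "freq",
          intersect(c("freq_cases", "freq_controls"), names(out)))]
}

#' Minimum haplotype count for a frequency floor
#'
#' The smallest chromosome count `c` with `c / (2 n) >= f_min`, i.e.
#' `ceiling(2 * n_individuals * f_min)`. With the study's 16,144 cases and
#' 17,832 controls and a 0.05% floor this is 34.
#'
#' @param n_individuals Number of individuals.
#' @param f_min Haplotype frequency floor in (0, 1).
#' @return Integer count threshold.
#' @export
#' @examples
#' min_count_threshold(16144 + 17832, 0.0005)
min_count_threshold <- function(n_individuals, f_min = 5e-4) {
  if (n_individuals <= 0) abort("`n_individuals` must be positive.")
  if (f_min <= 0 || f_min >= 1) abort("`f_min` must lie strictly between 0 and 1.")
  as.integer(ceiling(2 * n_individuals * f_min))
}

#' Filter haplotypes by minimum count
#'
#' Splits a haplotype table into haplotypes with reasonable counts
#' (`n >= min_count`) and dropped rare haplotypes. The all-nonrisk
#' reference must itself survive the filter (it anchors the regression),
#' otherwise an error is raised.
#'
#' @param tbl Haplotype table from [enumerate_haplotypes()].
#' @param min_count Minimum chromosome count (>= 1).
#' @return List with `retained` and `dropped` tibbles.
#' @export
filter_haplotypes <- function(tbl, min_count) {
  if (min_count < 1) abort("`min_count` must be at least 1.")
  keep <- tbl$n >= min_count
  ref_row <- tbl$n_risk == 0L
  if (any(ref_row) && !all(keep[ref_row])) {
    abort("the all-nonrisk reference haplotype falls below `min_count`; it must be estimable.")
  }
  list(retained = tbl[keep, , drop = FALSE], dropped = tbl[!keep, , drop = FALSE])
}

# Per-individual copy counts of each haplotype; individuals carrying any
# haplotype outside `labels_keep` are marked NA (to be excluded or pooled).
hap_count_matrix <- function(hm, tbl, candidates = NULL) {
  if (!is.null(candidates)) hm <- hm[, candidates, drop = FALSE]
  strs <- apply(hm, 1L, hap_to_string)
  idx <- match(strs, tbl$alleles)
  n <- nrow(hm) / 2L
  counts <- matrix(0L, nrow = n, ncol = nrow(tbl),
                   dimnames = list(NULL, tbl$label))
  carrier_of_other <- logical(n)
  for (i in seq_len(n)) {
    for (chrom in c(2L * i - 1L, 2L * i)) {
      h <- idx[chrom]
      if (is.na(h)) carrier_of_other[i] <- TRUE else counts[i, h] <- counts[i, h] + 1L
    }
  }
  list(counts = counts, carrier_of_other = carrier_of_other)
}

# Shared engine for the count- and dosage-based haplotype models.
haplo_glm_fit <- function(design, y, covs, tbl, reference, alpha, model, n_excluded) {
  keep_cols <- setdiff(colnames(design), reference)
  X <- cbind(`(Intercept)` = 1, design[, keep_cols, drop = FALSE], covs)
  fit <- tryCatch(
    fit_logistic(X, y),
    haplofine_rank_deficient = function(e) {
      abort(paste0(
        "haplotype design is collinear (complementary coding); ",
        "remove the reference haplotype column before fitting: ",
        conditionMessage(e)
      ))
    }
  )
  rows <- purrr::map_dfr(keep_cols, function(h) {
    b <- fit$beta[[h]]; s <- fit$se[[h]]; z <- b / s
    p <- exp(log_p_two_sided(z))
    tibble::tibble(
      label = h, beta = b, se = s, z = z, or = exp(b),
      ci_lo = exp(b - 1.96 * s), ci_hi = exp(b + 1.96 * s),
      p = p, neglog10p = neglog10p_from_z(z),
      class = dplyr::case_when(
        p > alpha ~ "null",
        exp(b) > 1 ~ "risk",
        TRUE ~ "protective"
      )
    )
  })
  ref_row <- tibble::tibble(
    label = reference, beta = 0, se = NA_real_, z = NA_real_, or = 1,
    ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_, neglog10p = NA_real_,
    class = "reference"
  )
  table <- dplyr::left_join(
    dplyr::bind_rows(ref_row, rows),
    tbl[, intersect(c("label", "alleles", "n", "freq", "freq_cases", "freq_controls"),
                    names(tbl))],
    by = "label"
  )
  table <- table[order(match(table$label, tbl$label)), , drop = FALSE]
  structure(
    list(
      table = table, reference = reference, alpha = alpha,
      model = model, n_used = length(y), n_excluded = n_excluded,
      loglik = fit$loglik, converged = fit$converged
    ),
    class = "haplo_fit"
  )
}

#' Multivariable haplotype logistic regression
#'
#' Jointly regresses case-control status on per-individual copy counts
#' (0/1/2) of every retained haplotype except the reference — by
#' convention `H0`, the haplotype carrying exclusively nonrisk alleles —
#' plus the standard covariates. Each non-reference haplotype's odds ratio
#' is therefore measured against the all-nonrisk background. Haplotypes
#' are classified at level `alpha`: `risk` (OR > 1, p <= alpha),
#' `protective` (OR < 1, p <= alpha), or `null` (p > alpha).
#'
#' Individuals carrying a haplotype outside the retained table are
#' excluded from the fit by default (a dropped rare haplotype must not
#' masquerade as reference dosage); set `pool_rare = TRUE` to keep them
#' with their rare chromosomes pooled into an `Hrare` column instead.
#'
#' @param hm Phased haplotype matrix (2 rows per individual).
#' @param tbl Retained haplotype table (see [filter_haplotypes()]).
#' @param pheno Phenotype tibble with `y` and covariates.
#' @param reference Reference haplotype label (default `"H0"`).
#' @param covariates Covariate columns to adjust for.
#' @param alpha Classification significance level (default 0.05).
#' @param candidates Optional candidate variant ids (columns of `hm`)
#'   defining the haplotypes; must match how `tbl` was built.
#' @param pool_rare Pool non-retained chromosomes into an `Hrare` class
#'   instead of excluding their carriers.
#' @return An object of class `haplo_fit`; see [tidy.haplo_fit()].
#' @export
haplotype_regression <- function(hm, tbl, pheno, reference = "H0",
                                 covariates = c("WGA", "PC1", "PC2"),
                                 alpha = 0.05, candidates = NULL,
                                 pool_rare = FALSE) {
  assert_binary_matrix(hm)
  if (!reference %in% tbl$label) {
    abort(sprintf("reference haplotype '%s' is not in the table.", reference))
  }
  hc <- hap_count_matrix(hm, tbl, candidates)
  counts <- hc$counts
  covs <- covariate_matrix(pheno, covariates)
  y <- pheno$y
  n_excluded <- 0L
  if (any(hc$carrier_of_other)) {
    if (pool_rare) {
      rare <- integer(nrow(counts))
      rare[hc$carrier_of_other] <- 2L - rowSums(counts[hc$carrier_of_other, , drop = FALSE])
      counts <- cbind(counts, Hrare = rare)
    } else {
      keep <- !hc$carrier_of_other
      n_excluded <- sum(!keep)
      inform(sprintf(
        "haplotype_regression: excluding %d carrier(s) of non-retained haplotypes.",
        n_excluded
      ))
      counts <- counts[keep, , drop = FALSE]
      covs <- covs[keep, , drop = FALSE]
      y <- y[keep]
    }
  }
  haplo_glm_fit(counts, y, covs, tbl, reference, alpha, "counts", n_excluded)
}

#' Haplotype dosage regression under phase uncertainty
#'
#' Same model as [haplotype_regression()] with the integer copy counts
#' replaced by fractional haplotype dosages aggregated over phasing
#' replicates; the reference haplotype's dosage column is omitted from the
#' design (unmapped replicate mass is likewise not entered as a
#' predictor). With unambiguous phasing the dosages are integers and the
#' fit reproduces the count-based model exactly.
#'
#' @param dm A `dosage_matrix` from [haplotype_dosages()].
#' @param tbl Retained haplotype table whose labels match `colnames(dm$d)`.
#' @param pheno Phenotype tibble with `y` and covariates.
#' @inheritParams haplotype_regression
#' @return An object of class `haplo_fit`.
#' @export
dosage_regression <- function(dm, tbl, pheno, reference = "H0",
                              covariates = c("WGA", "PC1", "PC2"),
                              alpha = 0.05) {
  if (!inherits(dm, "dosage_matrix")) abort("`dm` must come from haplotype_dosages().")
  if (any(dm$d < 0 | dm$d > 2)) abort("dosages must lie in [0, 2].")
  tot <- rowSums(dm$d) + dm$unmapped
  if (any(abs(tot - 2) > 1e-8)) abort("dosage conservation violated: rows must sum to 2.")
  if (!reference %in% colnames(dm$d)) {
    abort(sprintf("reference haplotype '%s' is not a dosage column.", reference))
  }
  covs <- covariate_matrix(pheno, covariates)
  haplo_glm_fit(dm$d, pheno$y, covs, tbl, reference, alpha, "dosages", 0L)
}

#' @export
print.haplo_fit <- function(x, ...) {
  cat(sprintf(
    "<haplo_fit> %s-based haplotype model: %d haplotypes vs reference %s (alpha = %g)\n",
    x$model, nrow(x$table) - 1L, x$reference, x$alpha
  ))
  cat(sprintf("  %d individuals used", x$n_used))
  if (x$n_excluded > 0L) cat(sprintf(" (%d excluded as rare-haplotype carriers)", x$n_excluded))
  cat("\n")
  print(x$table)
  invisible(x)
}
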