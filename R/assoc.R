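#' Per-variant case-control association scan
#'
#' Fits one covariate-adjusted additive logistic regression per variant:
#' risk-allele dosage (0-2, fractional dosages allowed) plus the standard
#' covariates (`WGA`, `PC1`, `PC2` where present in the phenotype table).
#' Inference is Wald throughout: `z = beta/se`, 95% CI
#' `exp(beta +/- 1.96 se)`, and the two-sided P handled in log space so
#' `neglog10p` stays finite at signal strengths where the P-value itself
#' underflows double precision.
#'
#' @param geno N x M genotype/dosage matrix (columns follow `vm`).
#' @param pheno Phenotype tibble with `y` and covariate columns, one row
#'   per individual, aligned to `geno`.
#' @param vm Variant map.
#' @param covariates Covariate column names to adjust for.
#' @return A tibble with one row per polymorphic variant: `id`, `pos`,
#'   `beta`, `se`, `z`, `or`, `ci_lo`, `ci_hi`, `p`, `neglog10p`,
#'   `converged`. Monomorphic variants are skipped with a message.
#' @export
scan_variants <- function(geno, pheno, vm, covariates = c("WGA", "PC1", "PC2")) {
  vm <- validate_variant_map(vm)
  geno <- as.matrix(geno)
  if (ncol(geno) != nrow(vm)) abort("`geno` must have one column per variant map row.")
  if (nrow(geno) != nrow(pheno)) abort("`geno` and `pheno` must describe the same individuals.")
  covs <- covariate_matrix(pheno, covariates)
  y <- pheno$y
  rows <- purrr::map(seq_len(nrow(vm)), function(k) {
    g <- geno[, k]
    if (length(unique(g)) < 2L) {
      inform(sprintf("scan_variants: skipping monomorphic variant %s", vm$id[k]))
      return(NULL)
    }
    X <- cbind(`(Intercept)` = 1, dosage = g, covs)
    fit <- fit_logistic(X, y)
    b <- fit$beta[["dosage"]]
    s <- fit$se[["dosage"]]
    z <- b / s
    tibble::tibble(
      id = vm$id[k], pos = vm$pos[k], beta = b, se = s, z = z,
      or = exp(b), ci_lo = exp(b - 1.96 * s), ci_hi = exp(b + 1.96 * s),
      p = exp(log_p_two_sided(z)), neglog10p = neglog10p_from_z(z),
      converged = fit$converged
    )
  })
  dplyr::bind_rows(rows)
}

#' Posterior probabilities of association from Wald Z-scores
#'
#' Computes the Wakefield approximate Bayes factor for each variant from
#' its Wald statistic and standard error, with a normal prior of variance
#' `W` on the log odds ratio, and normalizes over the locus:
#' \deqn{ABF_i = \sqrt{V_i/(V_i+W)}\,\exp\!\big(Z_i^2 W / (2 (V_i+W))\big),
#'   \qquad PPA_i = ABF_i / \sum_j ABF_j}
#' with \eqn{V_i = se_i^2}. Everything is evaluated in log space so the
#' normalization is stable at locus-scale Z statistics.
#'
#' @param assoc Tibble from [scan_variants()] (needs `z` and `se`; rows
#'   with `converged = FALSE` are rejected).
#' @param W Prior variance of the log odds ratio (default 0.04, i.e. a
#'   prior sd of 0.2 — the conventional case-control fine-mapping choice).
#' @return `assoc` with columns `log_abf` and `ppa` appended;
#'   `sum(ppa) == 1`.
#' @export
compute_ppa <- function(assoc, W = 0.04) {
  if (W <= 0) abort("prior variance `W` must be positive.")
  if (!all(is.finite(assoc$se)) || any(assoc$se <= 0)) {
    abort("all standard errors must be finite and positive.")
  }
  V <- assoc$se^2
  log_abf <- 0.5 * (log(V) - log(V + W)) + assoc$z^2 * W / (2 * (V + W))
  log_norm <- max(log_abf) + log(sum(exp(log_abf - max(log_abf))))
  assoc$log_abf <- log_abf
  assoc$ppa <- exp(log_abf - log_norm)
  assoc
}

#' Credible set of associated variants
#'
#' Greedily accumulates variants in decreasing posterior probability of
#' association until the cumulative probability reaches `level`; ties in
#' `ppa` are broken by ascending genomic position so the set is
#' deterministic. The returned set is minimal: removing its last member
#' drops the cumulative probability below `level`.
#'
#' @param ppa_tbl Tibble with columns `id`, `pos`, `ppa` (e.g. from
#'   [compute_ppa()]).
#' @param level Credible level in (0, 1); default 0.99.
#' @return Tibble of member variants sorted by decreasing `ppa`, with a
#'   `cum_ppa` column giving the cumulative probability at inclusion.
#' @export
credible_set <- function(ppa_tbl, level = 0.99) {
  if (level <= 0 || level >= 1) abort("`level` must lie strictly between 0 and 1.")
  ord <- ppa_tbl[order(-ppa_tbl$ppa, ppa_tbl$pos), , drop = FALSE]
  cum <- cumsum(ord$ppa)
  k <- which(cum >= level)
  k <- if (length(k)) k[1] else nrow(ord)
  out <- ord[seq_len(k), , drop = FALSE]
  out$cum_ppa <- cum[seq_len(k)]
  out
}

#' Stepwise conditional association scan for secondary signals
#'
#' Starting from the lead variant as a fixed covariate, refits every other
#' variant conditional on the current set of detected signals; the most
#' significant variant with conditional P below `p_threshold` is added and
#' the scan repeats until no variant qualifies. Variants collinear with
#' the conditioning set are skipped with a message.
#'
#' @param geno Genotype/dosage matrix (columns follow `vm`).
#' @param pheno Phenotype tibble with `y` and covariates.
#' @param vm Variant map.
#' @param lead Lead variant id; defaults to the map's flagged lead.
#' @param p_threshold Conditional significance threshold (default 5e-8).
#' @param covariates Covariate columns to adjust for.
#' @return Tibble of detected secondary signals (`id`, `pos`, `round`,
#'   `beta`, `se`, `p`, `neglog10p`); zero rows when the locus carries a
#'   single signal.
#' @export
conditional_scan <- function(geno, pheno, vm, lead = NULL,
                             p_threshold = 5e-8,
                             covariates = c("WGA", "PC1", "PC2")) {
  vm <- validate_variant_map(vm)
  geno <- as.matrix(geno)
  lead <- lead %||% lead_variant(vm)
  if (!lead %in% vm$id) abort(sprintf("lead variant '%s' not in variant map.", lead))
  covs <- covariate_matrix(pheno, covariates)
  y <- pheno$y
  conditioning <- lead
  detected <- list()
  round <- 0L
  if (p_threshold <= 0) return(tibble::tibble(
    id = character(), pos = integer(), round = integer(),
    beta = numeric(), se = numeric(), p = numeric(), neglog10p = numeric()
  ))
  repeat {
    round <- round + 1L
    cond_idx <- match(conditioning, vm$id)
    cond_mat <- geno[, cond_idx, drop = FALSE]
    colnames(cond_mat) <- conditioning
    candidates <- setdiff(vm$id, conditioning)
    res <- purrr::map(candidates, function(v) {
      k <- match(v, vm$id)
      g <- geno[, k]
      if (length(unique(g)) < 2L) return(NULL)
      X <- cbind(`(Intercept)` = 1, dosage = g, cond_mat, covs)
      fit <- tryCatch(
        fit_logistic(X, y),
        haplofine_rank_deficient = function(e) {
          inform(sprintf(
            "conditional_scan: %s collinear with conditioning set; skipped.", v
          ))
          NULL
        }
      )
      if (is.null(fit) || !fit$converged) return(NULL)
      z <- fit$beta[["dosage"]] / fit$se[["dosage"]]
      tibble::tibble(
        id = v, pos = vm$pos[k], round = round,
        beta = fit$beta[["dosage"]], se = fit$se[["dosage"]],
        p = exp(log_p_two_sided(z)), neglog10p = neglog10p_from_z(z)
      )
    })
    res <- dplyr::bind_rows(res)
    if (!nrow(res)) break
    hit <- res[res$p < p_threshold, , drop = FALSE]
    if (!nrow(hit)) break
    best <- hit[which.max(hit$neglog10p), , drop = FALSE]
    detected[[round]] <- best
    conditioning <- c(conditioning, best$id)
  }
  out <- dplyr::bind_rows(detected)
  if (!nrow(out)) {
    out <- tibble::tibble(
      id = character(), pos = integer(), round = integer(),
      beta = numeric(), se = numeric(), p = numeric(), neglog10p = numeric()
    )
  }
  out
}
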