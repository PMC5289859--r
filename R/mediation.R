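#' Candidate variant pairs for the mediation screen
#'
#' Extracts the variants in strong LD with the lead (|D'| strictly above
#' `dprime_threshold`, computed by haplotype counting) and returns every
#' unordered pair of distinct non-lead variants among them. These are the
#' pairs that could plausibly represent two causal variants jointly tagged
#' by the lead.
#'
#' @param hm Phased haplotype matrix (columns follow `vm`).
#' @param vm Variant map.
#' @param dprime_threshold Strict |D'| threshold (default 0.8).
#' @return Tibble with columns `var1`, `var2`.
#' @export
prefilter_pairs <- function(hm, vm, dprime_threshold = 0.8) {
  vm <- validate_variant_map(vm)
  linked <- ld_to_lead(hm, vm, threshold = dprime_threshold, stat = "dprime")
  ids <- setdiff(linked$id, lead_variant(vm))
  if (length(ids) < 2L) {
    return(tibble::tibble(var1 = character(), var2 = character()))
  }
  cmb <- utils::combn(ids, 2L)
  tibble::tibble(var1 = cmb[1L, ], var2 = cmb[2L, ])
}

#' Mediation test for a pair of variants against the lead signal
#'
#' Operationalizes the question "does this pair of variants jointly
#' explain the lead variant's effect?" as a coefficient-attenuation test:
#' the lead's log odds ratio is estimated without (`beta_unadj`) and with
#' (`beta_adj`) the pair as additional covariates, and
#' `delta = beta_unadj - beta_adj` is tested against zero with a
#' case-status-stratified nonparametric bootstrap (resampling individuals
#' with replacement within cases and within controls, preserving the
#' design margins). The bootstrap P is +1-corrected,
#' `p = (1 + #{|delta_b - delta| >= |delta|}) / (n_boot + 1)`, so it is
#' never exactly zero.
#'
#' Pairs that jointly determine the lead dosage (adjusted design
#' collinear) are returned flagged `"full-collinearity"` with `NA`
#' statistics; such rows must be excluded from FDR adjustment.
#'
#' @param geno Genotype/dosage matrix (columns follow `vm`).
#' @param pheno Phenotype tibble with `y` and covariates.
#' @param vm Variant map.
#' @param pair Character vector of two variant ids (distinct from the lead).
#' @param lead Lead variant id; defaults to the map's flagged lead.
#' @param covariates Covariate columns to adjust for.
#' @param n_boot Bootstrap replicates (default 1000; minimum 100).
#' @param seed Seed for the bootstrap resampling.
#' @return One-row tibble: `var1`, `var2`, `beta_unadj`, `beta_adj`,
#'   `delta`, `rel_drop`, `p_boot`, `n_boot`, `flag`.
#' @export
mediation_test <- function(geno, pheno, vm, pair, lead = NULL,
                           covariates = c("WGA", "PC1", "PC2"),
                           n_boot = 1000, seed = 1L) {
  vm <- validate_variant_map(vm)
  lead <- lead %||% lead_variant(vm)
  if (length(pair) != 2L || anyDuplicated(pair)) abort("`pair` must be two distinct variant ids.")
  if (lead %in% pair) abort("pair members must be distinct from the lead variant.")
  if (n_boot < 100) abort("`n_boot` must be at least 100.")
  geno <- as.matrix(geno)
  covs <- covariate_matrix(pheno, covariates)
  y <- pheno$y
  g_lead <- geno[, match(lead, vm$id)]
  g_pair <- geno[, match(pair, vm$id), drop = FALSE]
  colnames(g_pair) <- pair

  X0_all <- cbind(`(Intercept)` = 1, lead = g_lead, covs)
  X1_all <- cbind(X0_all[, 1:2, drop = FALSE], g_pair, covs)
  # rank is checked once on the full design; the bootstrap refits reuse
  # the raw IRLS engine for speed
  fast_beta <- function(X, yy) {
    fit <- suppressWarnings(glm.fit(
      x = X, y = yy, family = binomial(),
      control = glm.control(epsilon = 1e-10, maxit = 100)
    ))
    coef(fit)[["lead"]]
  }
  delta_fn <- function(idx) {
    c(fast_beta(X0_all[idx, , drop = FALSE], y[idx]),
      fast_beta(X1_all[idx, , drop = FALSE], y[idx]))
  }

  full <- tryCatch(
    {
      fit_logistic(X0_all, y)
      fit_logistic(X1_all, y)
      delta_fn(seq_along(y))
    },
    haplofine_rank_deficient = function(e) NULL
  )
  if (is.null(full)) {
    return(tibble::tibble(
      var1 = pair[1], var2 = pair[2], beta_unadj = NA_real_,
      beta_adj = NA_real_, delta = NA_real_, rel_drop = NA_real_,
      p_boot = NA_real_, n_boot = as.integer(n_boot),
      flag = "full-collinearity"
    ))
  }
  delta_hat <- full[1] - full[2]

  set.seed(derive_seed(seed, "mediation"))
  # canonical within-stratum order (by data values) makes the bootstrap
  # invariant to the order individuals arrive in
  key <- cbind(g_lead, g_pair, covs)
  canon <- function(idx) idx[do.call(order, asplit(key[idx, , drop = FALSE], 2L))]
  case_idx <- canon(which(y == 1L))
  ctrl_idx <- canon(which(y == 0L))
  deltas <- vapply(seq_len(n_boot), function(b) {
    idx <- c(
      case_idx[sample.int(length(case_idx), replace = TRUE)],
      ctrl_idx[sample.int(length(ctrl_idx), replace = TRUE)]
    )
    d <- tryCatch(delta_fn(idx), error = function(e) c(NA_real_, NA_real_))
    d[1] - d[2]
  }, numeric(1))
  ok <- is.finite(deltas)
  p_boot <- (1 + sum(abs(deltas[ok] - delta_hat) >= abs(delta_hat))) / (sum(ok) + 1)
  tibble::tibble(
    var1 = pair[1], var2 = pair[2],
    beta_unadj = full[1], beta_adj = full[2], delta = delta_hat,
    rel_drop = delta_hat / full[1],
    p_boot = p_boot, n_boot = as.integer(n_boot), flag = NA_character_
  )
}

#' Mediation screen over all prefiltered pairs
#'
#' Runs [mediation_test()] for every pair from [prefilter_pairs()] and
#' adjusts the bootstrap P-values with the Benjamini-Hochberg false
#' discovery rate. A pair is declared a significant mediator when
#' `q < q_threshold` and the relative drop `delta / beta_unadj` exceeds
#' `drop_threshold` (the lead's effect must fall strongly, not merely
#' detectably). Collinearity-flagged pairs are excluded from FDR with a
#' warning.
#'
#' @inheritParams mediation_test
#' @param hm Phased haplotype matrix used for the D' prefilter.
#' @param dprime_threshold |D'|-to-lead prefilter threshold.
#' @param q_threshold,drop_threshold Significance and relative-drop
#'   thresholds for declaring mediation (defaults 0.05 and 0.5).
#' @return Tibble of per-pair results with `q` and `significant` columns.
#' @export
mediation_screen <- function(hm, geno, pheno, vm, lead = NULL,
                             dprime_threshold = 0.8,
                             covariates = c("WGA", "PC1", "PC2"),
                             n_boot = 1000, seed = 1L,
                             q_threshold = 0.05, drop_threshold = 0.5) {
  pairs <- prefilter_pairs(hm, vm, dprime_threshold)
  if (!nrow(pairs)) {
    return(tibble::tibble(
      var1 = character(), var2 = character(), beta_unadj = numeric(),
      beta_adj = numeric(), delta = numeric(), rel_drop = numeric(),
      p_boot = numeric(), n_boot = integer(), flag = character(),
      q = numeric(), significant = logical()
    ))
  }
  res <- purrr::pmap_dfr(pairs, function(var1, var2) {
    mediation_test(
      geno, pheno, vm, c(var1, var2), lead = lead,
      covariates = covariates, n_boot = n_boot, seed = seed
    )
  })
  flagged <- !is.na(res$flag)
  if (any(flagged)) {
    warn(sprintf("%d pair(s) flagged collinear and excluded from FDR.", sum(flagged)))
  }
  res$q <- NA_real_
  res$q[!flagged] <- fdr_adjust(res$p_boot[!flagged])
  res$significant <- !flagged & res$q < q_threshold & res$rel_drop > drop_threshold
  res
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up q-values (`min` over the tail of `p * m / rank`) with
#' monotonicity enforced, delegated to [stats::p.adjust()].
#'
#' @param p Vector of P-values in (0, 1].
#' @return q-values of the same length; empty input gives empty output.
#' @export
fdr_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("P-values must lie in (0, 1].")
  }
  p.adjust(p, method = "BH")
}
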