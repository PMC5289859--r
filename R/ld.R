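#' Pairwise linkage disequilibrium from phased haplotypes
#'
#' Computes D, D' and r-squared between two variants by direct haplotype
#' counting on the phased matrix (no EM from genotypes). With `pA`, `pB`
#' the allele-1 frequencies and `pAB` the joint haplotype frequency:
#' `D = pAB - pA*pB`;
#' `D' = D / Dmax` with `Dmax = min(pA(1-pB), (1-pA)pB)` when `D > 0` and
#' `min(pA*pB, (1-pA)(1-pB))` otherwise; `r2 = D^2 / (pA(1-pA)pB(1-pB))`.
#' `dprime` is reported as |D'|; the sign is carried on `d` only.
#'
#' @param hm Phased 0/1 haplotype matrix (chromosomes x variants).
#' @param i,j Variant column indices or column names.
#' @return A one-row tibble with columns `i`, `j`, `d`, `dprime`, `r2`.
#' @export
#' @examples
#' hm <- rbind(c(1L, 1L), c(0L, 0L), c(1L, 0L), c(0L, 0L))
#' pairwise_ld(hm, 1, 2)
pairwise_ld <- function(hm, i, j) {
  assert_binary_matrix(hm, paired = FALSE)
  ii <- resolve_variant(i, hm)
  jj <- resolve_variant(j, hm)
  a <- hm[, ii]
  b <- hm[, jj]
  if (length(unique(a)) < 2L || length(unique(b)) < 2L) {
    abort(
      "LD undefined: monomorphic variant column.",
      class = "haplofine_monomorphic"
    )
  }
  pA <- mean(a)
  pB <- mean(b)
  pAB <- mean(a == 1L & b == 1L)
  D <- pAB - pA * pB
  dmax <- if (D > 0) {
    min(pA * (1 - pB), (1 - pA) * pB)
  } else {
    min(pA * pB, (1 - pA) * (1 - pB))
  }
  dprime <- if (D == 0) 0 else abs(D / dmax)
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  tibble::tibble(
    i = colnames(hm)[ii] %||% ii, j = colnames(hm)[jj] %||% jj,
    d = D, dprime = dprime, r2 = r2
  )
}

#' Variants in strong LD with the lead variant
#'
#' Computes `r2` (or |D'|) of every variant against the lead and returns
#' those strictly exceeding the threshold. The lead itself is included
#' (its r-squared to itself is 1). Monomorphic variants cannot have
#' defined LD and are dropped with a warning.
#'
#' @param hm Phased haplotype matrix with columns following `vm`.
#' @param vm Variant map (defines the lead).
#' @param threshold Strict lower bound on the statistic (default 0.8).
#' @param stat `"r2"` (candidate filter) or `"dprime"` (mediation
#'   prefilter).
#' @return A tibble `id`, `pos`, and the chosen statistic, in genomic
#'   order, restricted to variants with statistic > threshold.
#' @export
ld_to_lead <- function(hm, vm, threshold = 0.8, stat = c("r2", "dprime")) {
  stat <- match.arg(stat)
  vm <- validate_variant_map(vm)
  assert_binary_matrix(hm, paired = FALSE)
  lead <- lead_variant(vm)
  lead_idx <- match(lead, vm$id)
  vals <- vapply(seq_len(nrow(vm)), function(k) {
    if (k == lead_idx) return(1)
    out <- tryCatch(
      pairwise_ld(hm, k, lead_idx)[[stat]],
      haplofine_monomorphic = function(e) NA_real_
    )
    out
  }, numeric(1))
  if (anyNA(vals)) {
    warn(sprintf(
      "LD to lead undefined (monomorphic) for: %s; excluded from selection.",
      paste(vm$id[is.na(vals)], collapse = ", ")
    ))
  }
  out <- tibble::tibble(id = vm$id, pos = vm$pos, value = vals)
  names(out)[3] <- stat
  out[!is.na(vals) & vals > threshold, , drop = FALSE]
}
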