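# Small in-code fixtures shared across the suite.

# A minimal variant map of m equally spaced variants; lead = last by default.
toy_vm <- function(m = 5, lead = m) {
  tibble::tibble(
    chrom = "10",
    pos = seq(100L, by = 100L, length.out = m),
    id = paste0("v", seq_len(m)),
    nonrisk_allele = "A",
    risk_allele = "G",
    annotation = NA_character_,
    lead = as.integer(seq_len(m) == lead)
  )
}

# Phased matrix from a vector of haplotype strings (one chromosome each).
hm_from_strings <- function(strs, ids = NULL) {
  hm <- do.call(rbind, lapply(strs, function(s) {
    as.integer(strsplit(s, "")[[1]])
  }))
  if (!is.null(ids)) colnames(hm) <- ids
  hm
}

# A deterministic phenotype table with null covariates.
toy_pheno <- function(y) {
  n <- length(y)
  tibble::tibble(
    iid = sprintf("ind%05d", seq_len(n)),
    y = as.integer(y), WGA = rep(0L, n), PC1 = rep(0, n), PC2 = rep(0, n)
  )
}

# Simulate a small case-control locus; returns haplotypes + phenotypes.
toy_dataset <- function(m = 5, n_cases = 200, n_controls = 200, seed = 1,
                        recomb_rate = 0.05, beta_causal = log(2.787),
                        lead = m, causal = NULL, ...) {
  vm <- toy_vm(m, lead)
  cfg <- generator_config(
    vm,
    causal_variant = causal %||% vm$id[lead],
    n_cases = n_cases, n_controls = n_controls,
    recomb_rate = recomb_rate, beta_causal = beta_causal, seed = seed, ...
  )
  pool <- generate_haplotype_pool(vm, cfg)
  d <- suppressMessages(sample_case_control(pool, vm, cfg))
  c(d, list(vm = vm, cfg = cfg, pool = pool))
}

`%||%` <- rlang::`%||%`
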