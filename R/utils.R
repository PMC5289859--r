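# Internal helpers shared across modules.

# Two-sided normal tail in log space; safe for |z| far beyond double
# underflow (-log10 p stays finite).
log_p_two_sided <- function(z) {
  pnorm(-abs(z), log.p = TRUE) + log(2)
}

neglog10p_from_z <- function(z) {
  -log_p_two_sided(z) / log(10)
}

# Derive a per-stage seed from a root seed; stays within 32-bit range.
derive_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 11L, phase = 23L, replicates = 37L,
    mediation = 53L, pipeline = 71L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 1009 + off) %% .Machine$integer.max)
}

# Collapse a 0/1 integer vector to a compact haplotype string ("0110...").
hap_to_string <- function(x) paste(as.integer(x), collapse = "")

string_to_hap <- function(s) as.integer(strsplit(s, "", fixed = TRUE)[[1]])

assert_binary_matrix <- function(hm, arg = "hm", paired = TRUE) {
  if (!is.matrix(hm) || !all(hm %in% c(0L, 1L))) {
    abort(sprintf("`%s` must be a matrix with entries in {0, 1}.", arg))
  }
  if (paired && nrow(hm) %% 2L != 0L) {
    abort(sprintf("`%s` must have an even number of rows (2 per individual).", arg))
  }
  invisible(hm)
}

# Resolve a variant reference (id string or column index) against a matrix
# whose columns follow the variant map.
resolve_variant <- function(ref, hm) {
  if (is.character(ref)) {
    idx <- match(ref, colnames(hm))
    if (is.na(idx)) abort(sprintf("variant '%s' not found among columns.", ref))
    return(idx)
  }
  idx <- as.integer(ref)
  if (idx < 1L || idx > ncol(hm)) abort("variant index out of range.")
  idx
}
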