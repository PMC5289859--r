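#' Load a variant map
#'
#' A variant map fixes the coordinate frame for the whole analysis: the
#' ordered locus variants, their risk-allele orientation (allele coding 1
#' always means the risk allele), and which variant is the lead. The
#' packaged fixture `"table1"` holds the 25 candidate variants of the
#' ARMS2/HTRA1 locus on chromosome 10q26 with the lead variant rs3750846,
#' together with the published per-variant summary statistics
#' (`neglog10p`, `ppa`, `r2`, `dprime`, `or` with CI, and the published
#' `excluded` flag) as auxiliary columns.
#'
#' @param source Either the fixture name `"table1"` or a path to a
#'   tab-separated file with columns `chrom`, `pos`, `id`,
#'   `nonrisk_allele`, `risk_allele`, `annotation`, `lead` (0/1, exactly
#'   one 1). Extra columns are kept as-is.
#'
#' @return A tibble with one row per variant, ordered by position,
#'   validated so that positions are strictly increasing, alleles are
#'   non-empty and distinct, and exactly one variant carries `lead = 1`.
#' @export
#' @examples
#' vm <- load_variant_map("table1")
#' vm[vm$lead == 1, c("id", "pos")]
load_variant_map <- function(source) {
  path <- if (identical(source, "table1")) {
    system.file("extdata", "table1.tsv", package = "haplofine", mustWork = TRUE)
  } else {
    if (!file.exists(source)) abort(sprintf("variant map file not found: '%s'", source))
    source
  }
  vm <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_variant_map(vm)
}

#' Validate a variant map
#'
#' Checks the structural invariants of a variant map tibble and returns it
#' (with `pos` and `lead` coerced to integer) or aborts with an
#' informative message.
#'
#' @param vm A data frame with the columns described in
#'   [load_variant_map()].
#' @return The validated variant map tibble.
#' @export
validate_variant_map <- function(vm) {
  required <- c("chrom", "pos", "id", "nonrisk_allele", "risk_allele", "lead")
  missing <- setdiff(required, names(vm))
  if (length(missing)) {
    abort(sprintf("variant map is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  vm <- tibble::as_tibble(vm)
  vm$pos <- as.integer(vm$pos)
  vm$lead <- as.integer(vm$lead)
  if (!"annotation" %in% names(vm)) vm$annotation <- NA_character_
  if (anyDuplicated(vm$pos)) abort("variant map has duplicate positions.")
  if (is.unsorted(vm$pos, strictly = TRUE)) {
    abort("variant map positions must be strictly increasing.")
  }
  if (anyDuplicated(vm$id)) abort("variant map has duplicate variant ids.")
  bad_allele <- !nzchar(vm$nonrisk_allele) | !nzchar(vm$risk_allele) |
    vm$nonrisk_allele == vm$risk_allele
  if (any(bad_allele)) {
    abort(sprintf(
      "invalid alleles (empty or identical) for variant(s): %s",
      paste(vm$id[bad_allele], collapse = ", ")
    ))
  }
  if (sum(vm$lead == 1L) != 1L) {
    abort("variant map must flag exactly one lead variant (lead = 1).")
  }
  vm
}

#' @rdname load_variant_map
#' @param vm A validated variant map.
#' @return `lead_variant()`: the id of the lead variant.
#' @export
lead_variant <- function(vm) {
  vm$id[vm$lead == 1L]
}
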