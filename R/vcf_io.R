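#' Write a phased haplotype matrix as VCF
#'
#' Serializes the phased matrix with one sample per individual, FORMAT
#' `GT` only, phased separators (`a|b`). REF is the nonrisk allele and ALT
#' the risk allele of the variant map, so the 0/1 coding round-trips.
#'
#' @param hm Phased 0/1 matrix (2 consecutive rows per individual),
#'   columns following `vm`.
#' @param vm Variant map.
#' @param path Output file path (plain-text `.vcf`).
#' @param iid Individual ids; inferred from row names when present.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(hm, vm, path, iid = NULL) {
  assert_binary_matrix(hm)
  vm <- validate_variant_map(vm)
  if (ncol(hm) != nrow(vm)) abort("`hm` must have one column per variant map row.")
  n <- nrow(hm) / 2L
  if (is.null(iid)) {
    iid <- if (!is.null(rownames(hm))) {
      sub("_a$", "", rownames(hm)[seq(1L, nrow(hm), by = 2L)])
    } else {
      sprintf("ind%05d", seq_len(n))
    }
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=haplofine",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", iid), collapse = "\t")
  )
  odd <- seq(1L, nrow(hm), by = 2L)
  body <- vapply(seq_len(nrow(vm)), function(k) {
    gt <- paste0(hm[odd, k], "|", hm[odd + 1L, k])
    paste(c(vm$chrom[k], vm$pos[k], vm$id[k], vm$nonrisk_allele[k],
            vm$risk_allele[k], ".", ".", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased VCF into risk-oriented haplotypes
#'
#' Parses a VCF (via the vcfR package), matches records to the variant
#' map by id (falling back to position), and maps REF/ALT onto the
#' nonrisk/risk orientation: when REF/ALT are swapped relative to the map
#' the coding is flipped and the flip is logged; any other allele
#' mismatch, a missing variant, or an unphased genotype (`/` separator)
#' aborts loudly.
#'
#' @param path Path to a VCF with phased `GT` for every sample at every
#'   map variant.
#' @param vm Variant map.
#' @return A phased 0/1 matrix (2N x M), rows named `<iid>_a`/`<iid>_b`,
#'   columns named by variant id.
#' @export
read_phased_vcf <- function(path, vm) {
  vm <- validate_variant_map(vm)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  pos <- as.integer(fix[, "POS"])
  rows <- match(vm$id, ids)
  if (anyNA(rows)) rows[is.na(rows)] <- match(vm$pos[is.na(rows)], pos)
  if (anyNA(rows)) {
    abort(sprintf(
      "variant(s) missing from VCF: %s",
      paste(vm$id[is.na(rows)], collapse = ", ")
    ))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  n <- length(samples)
  hm <- matrix(0L, nrow = 2L * n, ncol = nrow(vm),
               dimnames = list(paste0(rep(samples, each = 2L), c("_a", "_b")), vm$id))
  for (k in seq_len(nrow(vm))) {
    r <- rows[k]
    ref <- fix[r, "REF"]; alt <- fix[r, "ALT"]
    if (ref == vm$nonrisk_allele[k] && alt == vm$risk_allele[k]) {
      flip <- FALSE
    } else if (ref == vm$risk_allele[k] && alt == vm$nonrisk_allele[k]) {
      flip <- TRUE
      inform(sprintf(
        "read_phased_vcf: REF/ALT swapped for %s relative to the variant map; coding flipped.",
        vm$id[k]
      ))
    } else {
      abort(sprintf(
        "allele mismatch for %s: VCF %s/%s vs map %s/%s",
        vm$id[k], ref, alt, vm$nonrisk_allele[k], vm$risk_allele[k]
      ))
    }
    g <- gt[r, ]
    if (anyNA(g)) abort(sprintf("missing GT for %s.", vm$id[k]))
    if (any(grepl("/", g, fixed = TRUE))) {
      abort(sprintf(
        "unphased genotype ('/') at %s; phase the data (e.g. em_phase()) first.",
        vm$id[k]
      ))
    }
    parts <- strsplit(g, "|", fixed = TRUE)
    if (any(lengths(parts) != 2L)) abort(sprintf("malformed GT at %s.", vm$id[k]))
    a <- as.integer(vapply(parts, `[[`, character(1), 1L))
    b <- as.integer(vapply(parts, `[[`, character(1), 2L))
    if (flip) { a <- 1L - a; b <- 1L - b }
    hm[seq(1L, 2L * n, by = 2L), k] <- a
    hm[seq(2L, 2L * n, by = 2L), k] <- b
  }
  hm
}

#' Read and write phenotype tables
#'
#' Tab-separated phenotype/covariate files with columns `iid`, `y`,
#' `WGA`, `PC1`, `PC2`.
#'
#' @param path File path.
#' @return `read_phenotypes()`: a validated tibble.
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("iid", "y")
  miss <- setdiff(required, names(ph))
  if (length(miss)) abort(sprintf("phenotype file missing column(s): %s", paste(miss, collapse = ", ")))
  if (!all(ph$y %in% c(0L, 1L))) abort("`y` must be binary 0/1.")
  ph
}

#' @rdname read_phenotypes
#' @param pheno Phenotype tibble.
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_tsv(pheno, path, progress = FALSE)
  invisible(path)
}
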