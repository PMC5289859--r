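#' Allele-on-haplotype exclusion of candidate variants
#'
#' The core recombinant-haplotype inference: a candidate variant cannot be
#' driving the disease association if its alleles are discordant with the
#' haplotype-level association pattern. Concretely, a variant is excluded
#' when some classified non-reference haplotype either
#' \itemize{
#'   \item carries the variant's \emph{nonrisk} allele while the haplotype
#'     itself is a \emph{risk} haplotype (`"nonrisk-on-risk"`), or
#'   \item carries the variant's \emph{risk} allele while the haplotype is
#'     \emph{protective or not associated} (`"risk-on-nonassociated"`).
#' }
#' The reference haplotype never contributes evidence (classes are defined
#' relative to it). "Not associated" means p > alpha regardless of the
#' direction of the odds ratio. Every triggering haplotype is recorded,
#' together with its chromosome count, so underpowered null haplotypes can
#' be audited.
#'
#' @param tbl Haplotype table with columns `label` and `alleles` (and
#'   optionally `n`), e.g. from [enumerate_haplotypes()].
#' @param classes Either a `haplo_fit` or a tibble with columns `label`
#'   and `class` (`"risk"`, `"protective"`, `"null"`, `"reference"`).
#'   Every haplotype in `tbl` must be classified.
#' @param vm Optional variant map giving ids/positions for the candidate
#'   columns (in order); defaults to index-based naming.
#' @return An `exclusion_report` tibble: one row per candidate variant
#'   with `id`, `pos`, `excluded`, `rules` (comma-collapsed unique rule
#'   names), and `evidence` (list column of per-haplotype evidence
#'   tibbles). The retained variants are the rows with `excluded ==
#'   FALSE`.
#' @export
exclude_variants <- function(tbl, classes, vm = NULL) {
  if (inherits(classes, "haplo_fit")) classes <- classes$table
  if (!all(c("label", "class") %in% names(classes))) {
    abort("`classes` must have columns `label` and `class`.")
  }
  unclassified <- setdiff(tbl$label, classes$label)
  if (length(unclassified)) {
    abort(sprintf(
      "haplotype(s) present but unclassified: %s",
      paste(unclassified, collapse = ", ")
    ))
  }
  cls <- classes$class[match(tbl$label, classes$label)]
  bad <- !cls %in% c("risk", "protective", "null", "reference")
  if (any(bad)) {
    abort(sprintf("invalid class value(s): %s", paste(unique(cls[bad]), collapse = ", ")))
  }
  alleles <- do.call(rbind, lapply(tbl$alleles, string_to_hap))
  m <- ncol(alleles)
  if (!is.null(vm)) {
    vm <- validate_variant_map(vm)
    if (nrow(vm) != m) abort("`vm` must have one row per haplotype allele position.")
    ids <- vm$id; pos <- vm$pos
  } else {
    ids <- paste0("v", seq_len(m)); pos <- seq_len(m)
  }
  counts <- if ("n" %in% names(tbl)) tbl$n else rep(NA_integer_, nrow(tbl))
  informative <- which(cls != "reference")
  out <- purrr::map_dfr(seq_len(m), function(v) {
    ev <- purrr::map_dfr(informative, function(h) {
      a <- alleles[h, v]
      rule <- if (a == 0L && cls[h] == "risk") {
        "nonrisk-on-risk"
      } else if (a == 1L && cls[h] %in% c("null", "protective")) {
        "risk-on-nonassociated"
      } else {
        NA_character_
      }
      if (is.na(rule)) return(NULL)
      tibble::tibble(
        label = tbl$label[h], class = cls[h],
        allele = if (a == 1L) "risk" else "nonrisk",
        rule = rule, n = counts[h]
      )
    })
    tibble::tibble(
      id = ids[v], pos = pos[v],
      excluded = nrow(ev) > 0L,
      rules = if (nrow(ev)) paste(sort(unique(ev$rule)), collapse = ",") else "",
      evidence = list(ev)
    )
  })
  class(out) <- c("exclusion_report", class(out))
  out
}

#' Minimal set of risk-associated variants
#'
#' The complement of the exclusion report: the variants not excluded by
#' any haplotype evidence, in genomic order, together with the base-pair
#' interval they span.
#'
#' @param report An `exclusion_report` from [exclude_variants()].
#' @param vm Optional variant map (used to re-attach annotation columns).
#' @return A list with `variants` (tibble `id`, `pos` in genomic order)
#'   and `interval` (`c(start, end)` in base pairs; `NA` with a warning
#'   when everything was excluded).
#' @export
minimal_risk_set <- function(report, vm = NULL) {
  retained <- report[!report$excluded, c("id", "pos"), drop = FALSE]
  retained <- retained[order(retained$pos), , drop = FALSE]
  if (!nrow(retained)) {
    warn("all candidate variants were excluded; the minimal risk set is empty.")
    return(list(variants = retained, interval = c(NA_integer_, NA_integer_)))
  }
  if (!is.null(vm)) {
    keep <- intersect(c("id", "annotation"), names(vm))
    retained <- dplyr::left_join(retained, vm[, keep, drop = FALSE], by = "id")
  }
  list(variants = tibble::as_tibble(retained), interval = range(retained$pos))
}
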