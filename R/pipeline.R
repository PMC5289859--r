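#' Pipeline configuration
#'
#' Bundles every threshold and replicate count of the end-to-end analysis
#' with its default: candidate-filter r-squared 0.8, mediation-prefilter
#' D' 0.8, credible level 0.99, haplotype frequency floor 0.05%, haplotype
#' classification alpha 0.05, conditional-scan threshold 5e-8, Wakefield
#' prior variance 0.04, 1000 mediation bootstraps, 100 phasing
#' replicates. Thresholds are validated up front; the seed drives every
#' stage through derived per-stage streams.
#'
#' @param vm Variant map (object or `"table1"` or a path).
#' @param generator Optional [generator_config()] used when no input VCF
#'   is given (the simulate-or-load switch).
#' @param vcf,phenotype Paths to a phased VCF and phenotype TSV (used when
#'   `generator` is `NULL`).
#' @param r2_candidate,dprime_mediation,credible_level,min_hap_freq,alpha,condscan_p,W
#'   Analysis thresholds (see Description).
#' @param n_boot,phase_replicates Replicate counts.
#' @param run_mediation Whether to run the (costly) pair screen.
#' @param out_dir Optional directory for stage TSV outputs + manifest.
#' @param seed Root seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vm, generator = NULL, vcf = NULL, phenotype = NULL,
                            r2_candidate = 0.8, dprime_mediation = 0.8,
                            credible_level = 0.99, min_hap_freq = 5e-4,
                            alpha = 0.05, condscan_p = 5e-8, W = 0.04,
                            n_boot = 1000, phase_replicates = 100,
                            run_mediation = TRUE, out_dir = NULL, seed = 1L) {
  if (is.character(vm)) vm <- load_variant_map(vm)
  vm <- validate_variant_map(vm)
  stopifnot(
    r2_candidate >= 0, r2_candidate <= 1,
    dprime_mediation >= 0, dprime_mediation <= 1,
    credible_level > 0, credible_level < 1,
    min_hap_freq > 0, min_hap_freq < 1,
    alpha > 0, alpha < 1, W > 0, n_boot >= 100, phase_replicates >= 1
  )
  if (is.null(generator) && (is.null(vcf) || is.null(phenotype))) {
    abort("provide either a `generator` config or both `vcf` and `phenotype` paths.")
  }
  structure(
    list(
      vm = vm, generator = generator, vcf = vcf, phenotype = phenotype,
      r2_candidate = r2_candidate, dprime_mediation = dprime_mediation,
      credible_level = credible_level, min_hap_freq = min_hap_freq,
      alpha = alpha, condscan_p = condscan_p, W = W,
      n_boot = n_boot, phase_replicates = phase_replicates,
      run_mediation = run_mediation, out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full fine-mapping pipeline
#'
#' Executes the stages in analysis order: simulate (or load) phased
#' case-control data; per-variant association scan; Wakefield PPA and
#' credible set; candidate selection as the union of variants with
#' r-squared to the lead above `r2_candidate` and the credible-set
#' members; stepwise conditional scan; optional mediation screen;
#' haplotype enumeration, count filter and multivariable regression
#' against the all-nonrisk reference; allele-on-haplotype exclusion; and
#' the minimal risk set. Per-stage counts are logged and a manifest
#' (config hash, seed, package version, timestamp) accompanies the
#' results; when `out_dir` is set every stage table is also written as
#' TSV.
#'
#' @param cfg A [pipeline_config()].
#' @return A list (class `haplofine_result`) with elements `data`,
#'   `assoc`, `credible`, `candidates`, `conditional`, `mediation`,
#'   `haplotypes`, `fit`, `exclusion`, `minimal_set`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  vm <- cfg$vm
  if (!is.null(cfg$generator)) {
    inform("stage simulate: drawing synthetic case-control data")
    pool <- generate_haplotype_pool(vm, cfg$generator)
    data <- sample_case_control(pool, vm, cfg$generator)
  } else {
    inform("stage load: reading phased VCF and phenotypes")
    hm <- read_phased_vcf(cfg$vcf, vm)
    ph <- read_phenotypes(cfg$phenotype)
    data <- list(haplotypes = hm, phenotypes = ph)
  }
  hm <- data$haplotypes
  pheno <- data$phenotypes
  geno <- unphase(hm)

  inform(sprintf("stage assoc: scanning %d variants", nrow(vm)))
  assoc <- scan_variants(geno, pheno, vm)
  assoc <- compute_ppa(assoc, W = cfg$W)
  cred <- credible_set(assoc, level = cfg$credible_level)

  ld_sel <- ld_to_lead(hm, vm, threshold = cfg$r2_candidate, stat = "r2")
  candidates <- vm$id[vm$id %in% union(ld_sel$id, cred$id)]
  inform(sprintf(
    "stage candidates: %d by r2 > %g, %d in %g credible set, %d in union",
    nrow(ld_sel), cfg$r2_candidate, nrow(cred), cfg$credible_level,
    length(candidates)
  ))

  cond <- conditional_scan(geno, pheno, vm, p_threshold = cfg$condscan_p)
  inform(sprintf("stage conditional: %d secondary signal(s)", nrow(cond)))

  med <- NULL
  if (cfg$run_mediation) {
    med <- mediation_screen(
      hm, geno, pheno, vm,
      dprime_threshold = cfg$dprime_mediation,
      n_boot = cfg$n_boot, seed = cfg$seed
    )
    inform(sprintf(
      "stage mediation: %d pair(s) tested, %d significant",
      nrow(med), sum(med$significant, na.rm = TRUE)
    ))
  }

  haps <- enumerate_haplotypes(hm, pheno, candidates)
  min_count <- min_count_threshold(nrow(pheno), cfg$min_hap_freq)
  filt <- filter_haplotypes(haps, min_count)
  inform(sprintf(
    "stage haplotypes: %d observed, %d retained at count >= %d, %d dropped",
    nrow(haps), nrow(filt$retained), min_count, nrow(filt$dropped)
  ))
  fit <- haplotype_regression(
    hm, filt$retained, pheno,
    alpha = cfg$alpha, candidates = candidates
  )

  cand_vm <- vm[vm$id %in% candidates, , drop = FALSE]
  report <- exclude_variants(filt$retained, fit, cand_vm)
  minimal <- minimal_risk_set(report, cand_vm)
  inform(sprintf(
    "stage exclusion: %d candidate(s), %d excluded, %d retained",
    nrow(report), sum(report$excluded), nrow(minimal$variants)
  ))

  manifest <- list(
    package = "haplofine",
    version = as.character(utils::packageVersion("haplofine")),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    thresholds = cfg[c(
      "r2_candidate", "dprime_mediation", "credible_level", "min_hap_freq",
      "alpha", "condscan_p", "W", "n_boot", "phase_replicates"
    )]
  )
  manifest$result_hash <- rlang::hash(list(assoc, cred, candidates, cond,
                                           haps, fit$table, report))

  result <- structure(
    list(
      data = data, assoc = assoc, credible = cred, candidates = candidates,
      conditional = cond, mediation = med, haplotypes = filt,
      fit = fit, exclusion = report, minimal_set = minimal,
      manifest = manifest
    ),
    class = "haplofine_result"
  )
  if (!is.null(cfg$out_dir)) write_result_bundle(result, cfg$out_dir)
  result
}

# Stage tables as TSV plus a JSON manifest carrying config hash and seed.
write_result_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_tsv(x, file.path(out_dir, paste0(name, ".tsv")), progress = FALSE)
  }
  w(result$assoc, "assoc")
  w(result$credible, "credible_set")
  w(tibble::tibble(id = result$candidates), "candidates")
  w(result$conditional, "conditional_scan")
  if (!is.null(result$mediation)) w(result$mediation, "mediation")
  w(result$haplotypes$retained, "haplotypes_retained")
  w(result$haplotypes$dropped, "haplotypes_dropped")
  w(result$fit$table, "haplotype_association")
  excl <- result$exclusion
  excl$evidence_haplotypes <- vapply(excl$evidence, function(e) {
    paste(e$label, collapse = ",")
  }, character(1))
  excl$evidence_counts <- vapply(excl$evidence, function(e) {
    paste(e$n, collapse = ",")
  }, character(1))
  w(excl[, c("id", "pos", "excluded", "rules", "evidence_haplotypes", "evidence_counts")],
    "exclusion")
  w(result$minimal_set$variants, "minimal_risk_set")
  jsonlite::write_json(
    result$manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(out_dir)
}

#' @export
print.haplofine_result <- function(x, ...) {
  cat("<haplofine_result>\n")
  cat(sprintf("  candidates: %d variants\n", length(x$candidates)))
  cat(sprintf("  conditional secondary signals: %d\n", nrow(x$conditional)))
  cat(sprintf(
    "  haplotypes retained: %d (dropped %d)\n",
    nrow(x$haplotypes$retained), nrow(x$haplotypes$dropped)
  ))
  cat(sprintf(
    "  minimal risk set: %d variants spanning %s-%s bp\n",
    nrow(x$minimal_set$variants),
    format(x$minimal_set$interval[1], big.mark = ","),
    format(x$minimal_set$interval[2], big.mark = ",")
  ))
  invisible(x)
}
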