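Package: haplofine
Title: Recombinant-Haplotype Fine-Mapping of Case-Control Association Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fine-maps a strong-LD disease-association locus using rare
    recombinant haplotypes, following the strategy used to dissect the
    ARMS2/HTRA1 region in age-related macular degeneration. From phased
    case-control haplotypes the package computes per-variant logistic
    association with covariates, Wakefield approximate Bayes factors and
    99% credible sets, linkage-disequilibrium (D', r-squared) candidate
    filters, a stepwise conditional scan, a bootstrap mediation screen
    with false-discovery-rate control, EM haplotype phasing with
    phase-uncertainty dosages, multivariable haplotype regression against
    an all-nonrisk reference haplotype, and an allele-on-haplotype
    exclusion rule that yields the minimal set of risk-associated
    variants. A synthetic-data generator emulates a locus with two
    founder haplotypes, rare single-crossover recombinants, and a
    logistic disease model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
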