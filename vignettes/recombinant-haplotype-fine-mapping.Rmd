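---
title: "Fine-mapping a strong-LD locus with recombinant haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-mapping a strong-LD locus with recombinant haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplofine)
```

## The problem

Some disease-association loci are statistically easy to find and almost
impossible to dissect. The ARMS2/HTRA1 region on chromosome 10q26 — the
strongest genetic signal for age-related macular degeneration (AMD) after
CFH — is the canonical example: two adjacent genes, dozens of variants in
near-perfect linkage disequilibrium (LD), and per-allele odds ratios near
2.8 at many of them. Conditional regression cannot separate variants whose
genotypes are correlated at $r^2 > 0.95$, so the question "ARMS2 or HTRA1?"
stays open by purely single-variant means.

What can separate them are **rare recombinant haplotypes**. Even in a
strong-LD interval a little historical recombination survives, producing
chromosomes that carry risk alleles over only part of the locus. If a
haplotype carries the risk alleles of variants A–F but not G–Z and is still
fully disease-associated, then G–Z were never necessary; if a haplotype
carries the risk alleles of G–Z alone and shows no association, G–Z are not
sufficient either. This package turns that logic into a reusable, tested
pipeline, with a synthetic-data generator standing in for consortium-scale
genotypes.

## The pipeline

Given phased case-control haplotypes, a risk-oriented variant map (allele 1
is always the risk allele), and a phenotype table with the standard
covariates (a whole-genome-amplification batch flag `WGA` and two ancestry
principal components), the stages are:

1. **Single-variant scan** (`scan_variants()`): per-variant additive
   logistic regression adjusted for `WGA`, `PC1`, `PC2`; Wald inference
   with all tail probabilities handled in log space (at this locus
   $-\log_{10} p$ runs into the hundreds, far below double-precision
   underflow of $p$ itself).
2. **Credible set** (`compute_ppa()`, `credible_set()`): Wakefield
   approximate Bayes factors from the Wald statistics,
   $\mathrm{ABF}_i = \sqrt{V_i/(V_i+W)}\;
   \exp\!\big(Z_i^2 W/(2(V_i+W))\big)$ with $V_i = se_i^2$, normalized to
   posterior probabilities of association (PPA), then the smallest variant
   set whose cumulative PPA reaches 99%.
3. **Candidate selection**: the union of variants with $r^2 > 0.8$ to the
   lead (haplotype-counting LD, `ld_to_lead()`) and the 99% credible set.
4. **Secondary-signal checks**: stepwise conditional regression
   (`conditional_scan()`) and a bootstrap mediation screen over variant
   pairs in $|D'| > 0.8$ with the lead (`mediation_screen()`).
5. **Haplotype analysis** (`enumerate_haplotypes()`,
   `haplotype_regression()`): best-guess haplotypes over the candidates,
   a minimum-count filter, and one multivariable logistic model with the
   all-nonrisk haplotype H0 as reference.
6. **Exclusion** (`exclude_variants()`): a variant is removed from the
   candidate set if its *nonrisk* allele rides on a *risk* haplotype, or
   its *risk* allele rides on a *protective or non-associated* haplotype.
   The complement is the minimal set of risk-associated variants
   (`minimal_risk_set()`).
7. **Phase uncertainty** (`em_phase()`, `sample_phasing_replicates()`,
   `haplotype_dosages()`, `dosage_regression()`): the haplotype model
   refitted on dosages aggregated over repeated phasings.

`run_pipeline()` composes the stages and records a manifest (seed, config
hash, versions) so a run is exactly reproducible.

## The synthetic-data generator

The generator (`generator_config()`, `generate_haplotype_pool()`,
`sample_case_control()`) emulates the locus structure the analysis
exploits, not a population-genetic history:

* **Two founder haplotypes** — all-nonrisk and all-risk — with default
  frequencies 0.7 / 0.3. A risk-haplotype frequency of 0.3 is typical of
  common strong-effect AMD haplotypes and makes both homozygote classes
  well populated at desk-scale sample sizes.
* **Single-crossover recombinants**: a chromosome is recombinant with
  probability 0.02 (total), the breakpoint uniform over the $M-1$
  intervals. One breakpoint per chromosome suffices because the observed
  haplotype mosaics at loci like this are step-like; it also keeps the
  pool enumerable and the ground truth of every test legible. Pool
  frequencies are analytic (founders keep $(1-\rho)f$, recombinant mass
  $\rho$ splits over ordered founder pairs by frequency product and
  uniformly over breakpoints), so the pool itself involves no randomness.
* **A logistic disease model with one causal variant**: default per-allele
  log odds ratio $\ln 2.787$ at the ARMS2 coding variant, baseline
  log-odds $\mathrm{logit}(0.05)$ (a plausible late-AMD prevalence scale),
  and covariates with configurable effects (null by default).
* **Quota sampling by rejection** from the population model until the case
  and control counts are met. The per-allele odds ratio is invariant to
  outcome-dependent sampling under the logistic model, so effect-size
  recovery targets remain valid while the sampler stays simple.

What it deliberately does **not** model: genotyping error, imputation
quality, coalescent ancestry, double crossovers, and linkage to variants
outside the map. Passing tests on this generator therefore demonstrate
that the *inference machinery* is correct under the structural assumptions
the method itself makes — not that those assumptions hold in any given
real cohort.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `r2_candidate` | 0.8 | strict $r^2$ filter to the lead for candidate variants |
| `credible_level` | 0.99 | credible-set mass |
| `W` | 0.04 | prior variance of the log-OR in the Wakefield ABF (prior sd 0.2, the conventional case-control fine-mapping choice); the published PPA column's prior is not stated, so PPAs are comparable in ranking, not digit-for-digit |
| `min_hap_freq` | 5e-4 | haplotype frequency floor; the count threshold is `ceiling(2 * n * f)` — 34 chromosomes at the 33,976-individual study scale |
| `alpha` | 0.05 | haplotype classification level: `risk`/`protective` need $p \le \alpha$, otherwise `null` |
| `dprime_mediation` | 0.8 | strict $|D'|$ prefilter for mediation pairs |
| `condscan_p` | 5e-8 | conditional-scan significance (genome-wide convention; the source analysis does not print its threshold) |
| `n_boot` | 1000 | mediation bootstrap replicates |
| `phase_replicates` | 100 | phasing replicates for dosage aggregation |

## Numerical and design choices

* **Log-space tails everywhere.** `neglog10p` is computed from the Wald
  $Z$ via `pnorm(log.p = TRUE)`, never from $p$; the raw `p` column is
  also reported but underflows to 0 beyond $|Z| \approx 38$ and should
  not be used for arithmetic.
* **Wakefield ABF in log space**, normalized with the max-shift trick, so
  $\sum \mathrm{PPA} = 1$ to machine precision at locus-scale $Z$.
* **Credible-set ties** are broken by ascending genomic position, making
  the set deterministic.
* **LD by direct haplotype counting** on the phased matrix; $|D'|$ is
  reported with the sign retained only on $D$. Threshold comparisons are
  strict (`>`). Monomorphic variants have undefined LD and are excluded
  with a warning rather than silently scored 0.
* **Logistic fits** go through iteratively reweighted least squares
  (`stats::glm.fit`) with the deviance tolerance tightened to 1e-10 and a
  100-iteration cap; designs are rank-checked up front with the collinear
  columns named, and fits showing separation (exploding coefficients or
  standard errors) are flagged rather than reported. Constant covariate
  columns (e.g. a batch flag absent from a subsample) are dropped rather
  than allowed to break the rank check.
* **Mediation** is operationalized as the attenuation of the lead's
  coefficient when the pair is added, tested with a case/control-stratified
  nonparametric bootstrap and the +1-corrected percentile P, then
  Benjamini–Hochberg adjusted. Within each stratum individuals are put
  into a canonical data-sorted order before resampling, which makes the
  bootstrap exactly invariant to input row order. "Significant mediation"
  additionally requires a relative coefficient drop above 0.5 — "drops
  strongly" needs an explicit operationalization and this is ours, exposed
  as a configurable threshold. The bootstrap is well calibrated under the
  scientifically relevant null (pair in LD with a truly causal lead but
  with no effect of its own, where the attenuation statistic is
  asymptotically normal); under the fully degenerate null in which the
  pair is independent of everything, the statistic is $O_p(1/n)$ and the
  percentile bootstrap is conservative — it under-rejects, never the
  reverse.
* **EM phasing** restricts the haplotype space to haplotypes compatible
  with at least one observed genotype (an individual with $h$ heterozygous
  sites contributes $2^{h-1}$ unordered diplotypes, refused above 14 het
  sites), uses uniform initial frequencies, and stops at
  $\max|\Delta f| < 10^{-8}$ or 500 iterations. Phasing replicates are
  posterior draws from the single converged EM, not independent EM
  restarts: the replicates are meant to carry *phase* uncertainty, which
  the diplotype posterior encodes, whereas restarts would conflate it with
  frequency-estimation instability.
* **Dosage mapping** is exact-match only; replicate haplotypes matching no
  best-guess haplotype accumulate in an explicit `unmapped` mass (so
  dosages + unmapped always sum to 2) instead of being forced onto a
  nearest match.
* **Carriers of sub-threshold haplotypes** are excluded from the count
  model by default — fitting "all haplotypes with reasonable counts" while
  silently crediting rare chromosomes to the reference would bias the
  baseline; a pooled `Hrare` mode is available behind `pool_rare = TRUE`.
* **The reference haplotype never contributes exclusion evidence**: the
  risk/protective/null classes are defined relative to it. "Not
  associated" means $p > \alpha$ regardless of the direction of the odds
  ratio, and each evidence haplotype's chromosome count is carried in the
  report so that underpowered null classifications can be audited.

## A worked example

```{r example, eval = FALSE}
vm <- load_variant_map("table1")
gen <- generator_config(vm, n_cases = 2000, n_controls = 2000,
                        recomb_rate = 0.05, seed = 1)
cfg <- pipeline_config(vm, generator = gen, run_mediation = FALSE,
                       min_hap_freq = 0.002, seed = 1)
res <- run_pipeline(cfg)
res$minimal_set$variants
autoplot(res$fit)
```

## Problem sizes used in the test suite

The package's own checks run the generator at 300–10,000 individuals per
dataset, 25 replicate seeds for effect-size recovery, 199–1000 bootstrap
replicates, and 100–2000 phasing replicates — sizes at which every
stochastic assertion has explicit binomial or Monte-Carlo error bounds.
Exhaustive oracles (all two-variant haplotype tables up to 8 chromosomes;
all class assignments over enumerated haplotype sets up to 4 variants)
back the LD and exclusion rules.

## Known limitations

* The exclusion rule is deterministic, not probabilistic: a haplotype
  classified `null` purely from low power will exclude variants exactly as
  a well-powered one would. The per-haplotype counts in the report are the
  audit trail; a posterior over causal configurations is out of scope.
* Reference-panel imputation and external phasing tools are out of scope;
  the pipeline consumes variants already present and phases internally by
  EM when given unphased genotypes.
* The generator's two-founder, single-crossover structure is an idealized
  strong-LD locus; multi-founder or mutation-on-haplotype scenarios are
  not modeled.
* The published per-variant PPA values depend on an unstated prior
  variance; this package's PPAs use `W = 0.04` and agree in ordering, not
  to printed digits.
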