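#' Configuration for the synthetic locus generator
#'
#' Describes the population model the generator draws from: two founder
#' haplotypes (by default the all-nonrisk and all-risk vectors, emulating
#' the two common haplotypes of a strong-LD locus), rare single-crossover
#' recombinants between them, a logistic disease model with one causal
#' variant, and the covariates carried through every regression (a
#' DNA-preparation batch flag `WGA` and two ancestry principal
#' components).
#'
#' Defaults follow the study design the package emulates: risk-haplotype
#' frequency 0.3, total recombinant frequency 0.02, per-allele odds ratio
#' 2.787 at the causal variant (the ARMS2 coding variant rs10490924 when
#' present in `vm`, otherwise the lead), and a baseline log-odds giving
#' roughly 5% disease prevalence on the nonrisk background.
#'
#' @param vm Variant map defining the locus (see [load_variant_map()]).
#' @param founders List of two or more 0/1 integer vectors of length
#'   `nrow(vm)`; default all-0 and all-1.
#' @param founder_freqs Founder haplotype frequencies, summing to 1.
#' @param recomb_rate Per-chromosome probability that the drawn haplotype
#'   is a single-crossover recombinant of two founders.
#' @param causal_variant Variant id carrying the disease effect.
#' @param beta_causal Log odds ratio per risk allele at the causal variant.
#' @param beta0 Baseline log-odds of disease.
#' @param wga_prop,beta_wga Bernoulli probability and log-odds effect of
#'   the WGA batch covariate.
#' @param pc_sd,beta_pc1,beta_pc2 Standard deviation of the two principal
#'   components and their log-odds effects.
#' @param n_cases,n_controls Case and control quotas.
#' @param max_draws Cap on population draws during quota sampling; the
#'   sampler aborts with a diagnostic when the quotas cannot be filled.
#' @param seed Integer seed controlling every random draw.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(vm,
                             founders = NULL,
                             founder_freqs = c(0.7, 0.3),
                             recomb_rate = 0.02,
                             causal_variant = NULL,
                             beta_causal = log(2.787),
                             beta0 = qlogis(0.05),
                             wga_prop = 0.5,
                             beta_wga = 0,
                             pc_sd = 1,
                             beta_pc1 = 0,
                             beta_pc2 = 0,
                             n_cases = 5000,
                             n_controls = 5000,
                             max_draws = 2e6,
                             seed = 1L) {
  vm <- validate_variant_map(vm)
  m <- nrow(vm)
  if (is.null(founders)) {
    founders <- list(rep(0L, m), rep(1L, m))
  }
  founders <- lapply(founders, as.integer)
  if (any(vapply(founders, length, 1L) != m)) {
    abort("every founder haplotype must have one allele per variant map row.")
  }
  if (any(!unlist(founders) %in% c(0L, 1L))) abort("founder alleles must be 0/1.")
  if (length(founder_freqs) != length(founders)) {
    abort("`founder_freqs` must have one entry per founder.")
  }
  if (abs(sum(founder_freqs) - 1) > 1e-8) abort("`founder_freqs` must sum to 1.")
  if (recomb_rate < 0 || recomb_rate > 1) abort("`recomb_rate` must lie in [0, 1].")
  if (n_cases <= 0 || n_controls <= 0) abort("case/control quotas must be positive.")
  if (!is.finite(beta_causal)) abort("`beta_causal` must be finite.")
  if (is.null(causal_variant)) {
    causal_variant <- if ("rs10490924" %in% vm$id) "rs10490924" else lead_variant(vm)
  }
  if (!causal_variant %in% vm$id) {
    abort(sprintf("causal variant '%s' is not in the variant map.", causal_variant))
  }
  structure(
    list(
      founders = founders, founder_freqs = founder_freqs,
      recomb_rate = recomb_rate, causal_variant = causal_variant,
      beta_causal = beta_causal, beta0 = beta0,
      wga_prop = wga_prop, beta_wga = beta_wga,
      pc_sd = pc_sd, beta_pc1 = beta_pc1, beta_pc2 = beta_pc2,
      n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
      max_draws = max_draws, seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' Enumerate the haplotype pool implied by a generator configuration
#'
#' The pool holds the founder haplotypes plus every single-crossover
#' recombinant between an ordered pair of distinct founders: a crossover
#' after variant `k` yields a haplotype equal to one founder up to `k` and
#' to the other founder beyond it (a "step" vector when the founders are
#' all-0 and all-1). Frequencies are analytic, not sampled: founders keep
#' `founder_freqs * (1 - recomb_rate)`; the total recombinant mass
#' `recomb_rate` is split across ordered founder pairs in proportion to
#' their frequency product and uniformly across breakpoints. Recombinants
#' identical to a founder (possible when founders agree over a flank) have
#' their mass folded back into that founder.
#'
#' @param vm Variant map.
#' @param cfg A [generator_config()].
#' @return A tibble with columns `hap` (haplotype string), `freq`,
#'   `origin` (`"founder"` or `"recombinant"`) and `breakpoint` (last
#'   variant of the prefix; `NA` for founders).
#' @export
generate_haplotype_pool <- function(vm, cfg) {
  vm <- validate_variant_map(vm)
  if (cfg$recomb_rate < 0 || cfg$recomb_rate > 1) abort("`recomb_rate` must lie in [0, 1].")
  m <- nrow(vm)
  founders <- cfg$founders
  f_str <- vapply(founders, hap_to_string, character(1))
  pool <- tibble::tibble(
    hap = f_str,
    freq = cfg$founder_freqs * (1 - cfg$recomb_rate),
    origin = "founder",
    breakpoint = NA_integer_
  )
  if (cfg$recomb_rate > 0 && length(founders) >= 2 && m >= 2) {
    pairs <- expand.grid(a = seq_along(founders), b = seq_along(founders))
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    w <- cfg$founder_freqs[pairs$a] * cfg$founder_freqs[pairs$b]
    w <- w / sum(w)
    rec <- purrr::pmap_dfr(
      list(pairs$a, pairs$b, w),
      function(a, b, wt) {
        tibble::tibble(
          hap = vapply(seq_len(m - 1L), function(k) {
            hap_to_string(c(founders[[a]][seq_len(k)], founders[[b]][(k + 1L):m]))
          }, character(1)),
          freq = cfg$recomb_rate * wt / (m - 1L),
          origin = "recombinant",
          breakpoint = seq_len(m - 1L)
        )
      }
    )
    # fold recombinants indistinguishable from a founder back into it
    dup <- rec$hap %in% pool$hap
    if (any(dup)) {
      for (h in unique(rec$hap[dup])) {
        pool$freq[pool$hap == h] <- pool$freq[pool$hap == h] + sum(rec$freq[dup & rec$hap == h])
      }
      rec <- rec[!dup, , drop = FALSE]
    }
    rec <- dplyr::summarise(
      dplyr::group_by(rec, .data$hap, .data$origin, .data$breakpoint),
      freq = sum(.data$freq), .groups = "drop"
    )[, c("hap", "freq", "origin", "breakpoint")]
    pool <- dplyr::bind_rows(pool, rec)
  }
  stopifnot(abs(sum(pool$freq) - 1) < 1e-12)
  pool
}

#' Draw chromosomes from a haplotype pool
#'
#' @param pool Tibble from [generate_haplotype_pool()].
#' @param n Number of chromosomes to draw.
#' @return An `n` x M 0/1 matrix (one row per chromosome).
#' @export
sample_chromosomes <- function(pool, n) {
  idx <- sample.int(nrow(pool), n, replace = TRUE, prob = pool$freq)
  mat <- do.call(rbind, lapply(pool$hap, string_to_hap))
  mat[idx, , drop = FALSE]
}

#' Simulate a phased case-control sample
#'
#' Draws individuals as two independent pool haplotypes, assigns disease
#' status from the logistic model
#' \eqn{P(y=1) = \mathrm{logit}^{-1}(\beta_0 + \beta_c x_c + \beta_{WGA} WGA
#' + \beta_1 PC1 + \beta_2 PC2)} where \eqn{x_c} is the risk-allele count
#' at the causal variant, and rejection-samples from the population until
#' the case and control quotas are met. Given the same seed the output is
#' bit-identical.
#'
#' @param pool Haplotype pool from [generate_haplotype_pool()].
#' @param vm Variant map.
#' @param cfg A [generator_config()].
#' @return A list with `haplotypes` (2N x M 0/1 matrix, two consecutive
#'   rows per individual, columns named by variant id) and `phenotypes`
#'   (tibble `iid`, `y`, `WGA`, `PC1`, `PC2`; cases first).
#' @export
sample_case_control <- function(pool, vm, cfg) {
  vm <- validate_variant_map(vm)
  set.seed(derive_seed(cfg$seed, "simulate"))
  causal_idx <- match(cfg$causal_variant, vm$id)
  hap_mat <- do.call(rbind, lapply(pool$hap, string_to_hap))
  need_cases <- cfg$n_cases
  need_controls <- cfg$n_controls
  got_cases <- list(); got_controls <- list()
  n_case_rows <- 0L; n_control_rows <- 0L
  drawn <- 0
  batch <- max(1000L, need_cases + need_controls)
  while ((n_case_rows < need_cases || n_control_rows < need_controls)) {
    if (drawn >= cfg$max_draws) {
      abort(sprintf(
        paste0(
          "quota sampling failed: after %d population draws only %d/%d cases ",
          "and %d/%d controls were obtained; check beta0/effect sizes."
        ),
        drawn, n_case_rows, need_cases, n_control_rows, need_controls
      ))
    }
    nb <- as.integer(min(batch, cfg$max_draws - drawn))
    drawn <- drawn + nb
    i1 <- sample.int(nrow(pool), nb, replace = TRUE, prob = pool$freq)
    i2 <- sample.int(nrow(pool), nb, replace = TRUE, prob = pool$freq)
    wga <- rbinom(nb, 1L, cfg$wga_prop)
    pc1 <- rnorm(nb, 0, cfg$pc_sd)
    pc2 <- rnorm(nb, 0, cfg$pc_sd)
    x_causal <- hap_mat[i1, causal_idx] + hap_mat[i2, causal_idx]
    eta <- cfg$beta0 + cfg$beta_causal * x_causal +
      cfg$beta_wga * wga + cfg$beta_pc1 * pc1 + cfg$beta_pc2 * pc2
    y <- rbinom(nb, 1L, plogis(eta))
    d <- tibble::tibble(i1 = i1, i2 = i2, y = y, WGA = wga, PC1 = pc1, PC2 = pc2)
    ca <- d[d$y == 1L, , drop = FALSE]
    co <- d[d$y == 0L, , drop = FALSE]
    if (n_case_rows < need_cases && nrow(ca)) {
      take <- head(ca, need_cases - n_case_rows)
      got_cases[[length(got_cases) + 1L]] <- take
      n_case_rows <- n_case_rows + nrow(take)
    }
    if (n_control_rows < need_controls && nrow(co)) {
      take <- head(co, need_controls - n_control_rows)
      got_controls[[length(got_controls) + 1L]] <- take
      n_control_rows <- n_control_rows + nrow(take)
    }
  }
  d <- dplyr::bind_rows(dplyr::bind_rows(got_cases), dplyr::bind_rows(got_controls))
  n <- nrow(d)
  iid <- sprintf("ind%05d", seq_len(n))
  rows <- integer(2L * n)
  rows[seq(1L, 2L * n, by = 2L)] <- d$i1
  rows[seq(2L, 2L * n, by = 2L)] <- d$i2
  hm <- hap_mat[rows, , drop = FALSE]
  colnames(hm) <- vm$id
  rownames(hm) <- paste0(rep(iid, each = 2L), c("_a", "_b"))
  list(
    haplotypes = hm,
    phenotypes = tibble::tibble(
      iid = iid, y = d$y, WGA = d$WGA, PC1 = d$PC1, PC2 = d$PC2
    )
  )
}

#' Collapse a phased haplotype matrix to unphased genotypes
#'
#' @param hm 2N x M phased 0/1 matrix (two consecutive rows per
#'   individual).
#' @return N x M genotype matrix with entries 0/1/2 (risk-allele counts);
#'   row names are the individual ids when the haplotype rows are named
#'   `<iid>_a` / `<iid>_b`.
#' @export
unphase <- function(hm) {
  assert_binary_matrix(hm)
  odd <- seq(1L, nrow(hm), by = 2L)
  g <- hm[odd, , drop = FALSE] + hm[odd + 1L, , drop = FALSE]
  if (!is.null(rownames(hm))) {
    rownames(g) <- sub("_a$", "", rownames(hm)[odd])
  }
  g
}
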