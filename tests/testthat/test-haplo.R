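test_that("haplotype enumeration conserves counts and labels deterministically", {
  d <- toy_dataset(m = 4, n_cases = 150, n_controls = 150, seed = 33,
                   recomb_rate = 0.1)
  tbl <- enumerate_haplotypes(d$haplotypes, d$phenotypes)
  expect_equal(sum(tbl$n), 2L * 300L)
  expect_equal(tbl$label, paste0("H", seq_len(nrow(tbl)) - 1L))
  # sorted by risk-allele count, ties by binary string
  expect_true(!is.unsorted(tbl$n_risk))
  expect_equal(tbl$alleles[1], "0000")   # all-nonrisk observed => H0
  # injected recombinants are recovered as step vectors
  steps <- vapply(tbl$alleles, function(s) {
    x <- as.integer(strsplit(s, "")[[1]]); sum(diff(x) != 0) <= 1
  }, logical(1))
  expect_true(all(steps))

  # two founders only
  d0 <- toy_dataset(m = 4, n_cases = 50, n_controls = 50, seed = 2, recomb_rate = 0)
  tbl0 <- enumerate_haplotypes(d0$haplotypes)
  expect_equal(nrow(tbl0), 2L)
  expect_equal(sum(tbl0$n), 200L)
})

test_that("the count threshold is exact ceiling arithmetic", {
  expect_identical(min_count_threshold(16144 + 17832, 0.0005), 34L)
  expect_identical(min_count_threshold(1000, 0.05), 100L)
  expect_identical(min_count_threshold(10, 0.0005), 1L)
  expect_error(min_count_threshold(0, 0.05), "positive")
  expect_error(min_count_threshold(10, 1), "between")
})

test_that("haplotype filtering splits at the threshold and protects the reference", {
  tbl <- tibble::tibble(
    label = c("H0", "H1", "H2"),
    alleles = c("000", "001", "111"),
    n_risk = c(0L, 1L, 3L),
    n = c(1000L, 33L, 500L),
    freq = c(1000, 33, 500) / 1533
  )
  f <- filter_haplotypes(tbl, 34)
  expect_equal(f$retained$label, c("H0", "H2"))
  expect_equal(f$dropped$label, "H1")
  expect_equal(nrow(filter_haplotypes(tbl, 1)$dropped), 0L)

  ref_low <- tbl; ref_low$n[1] <- 10L
  expect_error(filter_haplotypes(ref_low, 34), "reference")
})

test_that("the two-homozygote haplotype model matches the collapsed 2x2 odds ratio", {
  # 50 H1/H1 individuals (30 cases), 50 H0/H0 (15 cases)
  hm <- hm_from_strings(c(rep("11", 100), rep("00", 100)))
  y <- c(rep(1, 30), rep(0, 20), rep(1, 15), rep(0, 35))
  ph <- toy_pheno(y)
  tbl <- enumerate_haplotypes(hm, ph)
  fit <- haplotype_regression(hm, tbl, ph, covariates = character(0))
  b <- tidy(fit)$beta[tidy(fit)$label == "H1"]
  or_2x2 <- (30 / 20) / (15 / 35)
  expect_equal(exp(2 * b), or_2x2, tolerance = 1e-6)
})

test_that("with two haplotypes the model equals the single-variant allelic model", {
  d <- toy_dataset(m = 3, n_cases = 250, n_controls = 250, seed = 44, recomb_rate = 0)
  tbl <- enumerate_haplotypes(d$haplotypes, d$phenotypes)
  fit_h <- haplotype_regression(d$haplotypes, tbl, d$phenotypes,
                                covariates = character(0))
  b_h <- tidy(fit_h)$beta[tidy(fit_h)$class != "reference"]
  g <- unphase(d$haplotypes)
  fit_v <- fit_logistic(cbind(`(Intercept)` = 1, g = g[, 1]), d$phenotypes$y)
  expect_equal(b_h, fit_v$beta[["g"]], tolerance = 1e-8)
})

test_that("haplotype effect sizes are recovered from generated data", {
  # risk haplotype with log-OR 1 at 20,000 chromosomes
  d <- toy_dataset(m = 4, n_cases = 5000, n_controls = 5000, seed = 55,
                   recomb_rate = 0, beta_causal = 1)
  tbl <- enumerate_haplotypes(d$haplotypes, d$phenotypes)
  fit <- haplotype_regression(d$haplotypes, tbl, d$phenotypes)
  row <- tidy(fit)[tidy(fit)$label == "H1", ]
  expect_equal(row$class, "risk")
  # within 3 Wald standard errors of the truth
  expect_lt(abs(row$beta - 1), 3 * row$se)
})

test_that("null haplotypes are classified null at roughly rate 1 - alpha", {
  set.seed(66)
  null_rate <- mean(vapply(1:20, function(s) {
    d <- toy_dataset(m = 3, n_cases = 150, n_controls = 150, seed = 100 + s,
                     recomb_rate = 0, beta_causal = 0)
    tbl <- enumerate_haplotypes(d$haplotypes, d$phenotypes)
    fit <- haplotype_regression(d$haplotypes, tbl, d$phenotypes)
    tidy(fit)$class[tidy(fit)$label == "H1"] == "null"
  }, logical(1)))
  expect_gte(null_rate, 0.7)   # 99% binomial lower bound at p = 0.95, n = 20
})

test_that("carriers of dropped haplotypes are excluded unless pooling is requested", {
  hm <- hm_from_strings(c(rep("00", 40), rep("11", 38), "01", "01"))
  y <- rep(c(0, 1), 20)
  ph <- toy_pheno(y)
  tbl <- enumerate_haplotypes(hm, ph)
  filt <- filter_haplotypes(tbl, 3)
  expect_equal(filt$dropped$alleles, "01")
  expect_message(
    fit <- haplotype_regression(hm, filt$retained, ph, covariates = character(0)),
    "excluding"
  )
  expect_equal(glance(fit)$n_excluded, 1L)  # both rare chromosomes sit in one individual
  fit_pool <- suppressMessages(haplotype_regression(
    hm, filt$retained, ph, covariates = character(0), pool_rare = TRUE
  ))
  expect_equal(glance(fit_pool)$n_excluded, 0L)
  expect_true("Hrare" %in% tidy(fit_pool)$label)
})

test_that("dosage regression reproduces the count model when phase is certain", {
  d <- toy_dataset(m = 3, n_cases = 100, n_controls = 100, seed = 77,
                   recomb_rate = 0.05)
  tbl <- enumerate_haplotypes(d$haplotypes, d$phenotypes)
  post <- em_phase(unphase(d$haplotypes))
  # fabricate perfectly certain replicates from the true phase
  reps <- list(d$haplotypes, d$haplotypes)
  bg <- setNames(tbl$alleles, tbl$label)
  dm <- haplotype_dosages(reps, bg)
  fit_d <- dosage_regression(dm, tbl, d$phenotypes)
  fit_c <- haplotype_regression(d$haplotypes, tbl, d$phenotypes)
  expect_equal(tidy(fit_d)$beta, tidy(fit_c)$beta, tolerance = 1e-8)
  expect_equal(tidy(fit_d)$class, tidy(fit_c)$class)
})

test_that("dosage fits vary continuously under conservation-preserving noise", {
  d <- toy_dataset(m = 3, n_cases = 200, n_controls = 200, seed = 88,
                   recomb_rate = 0.05)
  tbl <- enumerate_haplotypes(d$haplotypes, d$phenotypes)
  bg <- setNames(tbl$alleles, tbl$label)
  dm <- haplotype_dosages(list(d$haplotypes), bg)
  base_beta <- tidy(dosage_regression(dm, tbl, d$phenotypes))$beta
  set.seed(1)
  betas <- sapply(c(1e-4, 1e-3, 1e-2), function(eps) {
    dm2 <- dm
    # move eps of mass between two haplotype columns, preserving row sums
    shift <- pmin(dm2$d[, 1], eps)
    dm2$d[, 1] <- dm2$d[, 1] - shift
    dm2$d[, 2] <- dm2$d[, 2] + shift
    tidy(dosage_regression(dm2, tbl, d$phenotypes))$beta
  })
  dev <- apply(betas, 2, function(b) max(abs(b - base_beta), na.rm = TRUE))
  expect_true(all(diff(dev) >= -1e-8))   # deviation shrinks with eps
  expect_lt(dev[1], 0.05)                # no jumps at tiny eps
})
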