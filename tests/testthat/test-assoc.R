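test_that("logistic MLE reproduces the closed form of a saturated 2x2 design", {
  y <- c(rep(1, 100), rep(0, 100))
  x <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  fit <- fit_logistic(cbind(`(Intercept)` = 1, exposure = x), y)
  expect_equal(exp(fit$beta[["exposure"]]), 30 * 90 / (70 * 10), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("degenerate designs are rejected with named columns", {
  y <- rep(c(0, 1), 20)
  X <- cbind(`(Intercept)` = 1, flat = rep(2, 40))
  expect_error(fit_logistic(X, y), "flat", class = "haplofine_rank_deficient")
  expect_error(fit_logistic(cbind(1, rnorm(10)), rep(1, 10)), "both classes")
})

test_that("null phenotypes give near-zero betas and uniform p-values", {
  set.seed(31)
  reject <- 0; total <- 0; betas <- numeric(0)
  for (s in 1:30) {
    n <- 400
    x <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, 0.5)
    fit <- fit_logistic(cbind(`(Intercept)` = 1, g = x), y)
    z <- fit$beta[["g"]] / fit$se[["g"]]
    p <- 2 * pnorm(-abs(z))
    reject <- reject + (p < 0.05); total <- total + 1
    betas <- c(betas, fit$beta[["g"]])
  }
  expect_lt(abs(mean(betas)), 0.05)
  # rejection rate within 99% binomial bounds of 0.05 at 30 trials
  expect_lte(reject, qbinom(0.995, total, 0.05))
})

test_that("scan_variants is covariate-adjusted, additive and sign-symmetric", {
  d <- toy_dataset(m = 4, n_cases = 300, n_controls = 300, seed = 13)
  g <- unphase(d$haplotypes)
  res <- scan_variants(g, d$phenotypes, d$vm)
  expect_equal(nrow(res), 4L)
  expect_true(all(res$or > 0))
  expect_true(all(res$ci_lo < res$or & res$or < res$ci_hi))
  # recoding the phenotype flips the sign of beta only
  flipped <- d$phenotypes; flipped$y <- 1L - flipped$y
  res_f <- scan_variants(g, flipped, d$vm)
  expect_equal(res_f$beta, -res$beta, tolerance = 1e-6)

  # monomorphic variants are skipped
  g2 <- cbind(g, v5 = 0L)
  vm5 <- toy_vm(5, lead = 4)
  expect_message(res5 <- scan_variants(g2, d$phenotypes, vm5), "monomorphic")
  expect_equal(nrow(res5), 4L)
})

test_that("PPA follows the Wakefield formula and normalizes to one", {
  # single variant: normalization forces ppa = 1
  one <- tibble::tibble(id = "v1", pos = 1L, z = 3, se = 0.2)
  expect_equal(compute_ppa(one)$ppa, 1)

  # equal evidence: equal split
  two <- tibble::tibble(id = c("a", "b"), pos = 1:2, z = c(4, 4), se = c(0.1, 0.1))
  expect_equal(compute_ppa(two)$ppa, c(0.5, 0.5))

  # direct high-precision evaluation of the formula
  tb <- tibble::tibble(id = c("a", "b"), pos = 1:2, z = c(5, 0), se = c(0.1, 0.1))
  W <- 0.04; V <- 0.01
  abf <- sqrt(V / (V + W)) * exp(tb$z^2 * W / (2 * (V + W)))
  expect_equal(compute_ppa(tb, W)$ppa, abf / sum(abf), tolerance = 1e-12)

  expect_error(compute_ppa(tb, W = 0), "positive")

  # sum-to-one and monotonicity in |Z| on random inputs
  set.seed(41)
  for (r in 1:10) {
    n <- 20
    tbl <- tibble::tibble(
      id = paste0("v", 1:n), pos = 1:n,
      z = rnorm(n, 0, 20), se = runif(n, 0.05, 0.3)
    )
    pp <- compute_ppa(tbl)
    expect_equal(sum(pp$ppa), 1, tolerance = 1e-12)
    tbl2 <- tbl; tbl2$z[1] <- tbl2$z[1] + sign(tbl2$z[1] + 0.1) * 1
    # strict monotonicity in |Z| holds on the Bayes-factor (log) scale even
    # where the normalized ppa has saturated at 1
    expect_gt(compute_ppa(tbl2)$log_abf[1], pp$log_abf[1])
    expect_gte(compute_ppa(tbl2)$ppa[1], pp$ppa[1])
  }
})

test_that("credible sets are greedy, minimal and position-tie-broken", {
  tb <- tibble::tibble(id = paste0("v", 1:4), pos = 1:4,
                       ppa = c(0.6, 0.3, 0.08, 0.02))
  cs <- credible_set(tb, 0.99)
  expect_equal(nrow(cs), 4L)       # cumulative 0.98 < 0.99 after three
  expect_equal(cs$cum_ppa[3], 0.98)

  expect_equal(nrow(credible_set(tibble::tibble(id = "v", pos = 1L, ppa = 1), 0.99)), 1L)
  expect_equal(nrow(credible_set(
    tibble::tibble(id = c("a", "b"), pos = 1:2, ppa = c(0.995, 0.005)), 0.99
  )), 1L)

  # ties broken by ascending position
  tie <- tibble::tibble(id = c("far", "near"), pos = c(200L, 100L), ppa = c(0.5, 0.5))
  expect_equal(credible_set(tie, 0.5)$id, "near")

  # minimality on random normalized vectors
  set.seed(51)
  for (r in 1:25) {
    n <- sample(3:15, 1)
    p <- rexp(n); p <- p / sum(p)
    tbl <- tibble::tibble(id = paste0("v", 1:n), pos = 1:n, ppa = p)
    cs <- credible_set(tbl, 0.99)
    expect_gte(sum(cs$ppa), 0.99 - 1e-12)
    if (nrow(cs) > 1) expect_lt(sum(cs$ppa[-nrow(cs)]), 0.99)
  }
})

test_that("-log10 P from Z agrees with the Mills-ratio oracle far into the tail", {
  neglog10p <- haplofine:::neglog10p_from_z
  # moderate Z: direct comparison
  for (z in c(0.5, 1, 2, 5, 8)) {
    expect_equal(neglog10p(z), -log10(2 * pnorm(-z)), tolerance = 1e-10)
  }
  # large Z: asymptotic expansion of the normal tail (independent route)
  mills <- function(z) {
    lq <- -z^2 / 2 - log(z) - 0.5 * log(2 * pi) +
      log1p(-1 / z^2 + 3 / z^4 - 15 / z^6)
    -(lq + log(2)) / log(10)
  }
  for (z in c(10, 20, 40, 60)) {
    expect_equal(neglog10p(z), mills(z), tolerance = 1e-6 * mills(z))
  }
  # the scale of the strongest locus signals (-log10 p ~ 782) stays finite
  expect_gt(neglog10p(59.85), 700)
  d <- toy_dataset(m = 3, n_cases = 100, n_controls = 100, seed = 6)
  res <- scan_variants(unphase(d$haplotypes), d$phenotypes, toy_vm(3))
  expect_true(all(is.finite(res$neglog10p)))
})

test_that("the conditional scan finds secondary signals only when they exist", {
  # single causal variant: no secondary signal
  d <- toy_dataset(m = 4, n_cases = 400, n_controls = 400, seed = 17,
                   recomb_rate = 0.05)
  g <- unphase(d$haplotypes)
  sec <- conditional_scan(g, d$phenotypes, d$vm, p_threshold = 1e-4)
  expect_equal(nrow(sec), 0L)

  # p_threshold = 0: empty by construction
  expect_equal(nrow(conditional_scan(g, d$phenotypes, d$vm, p_threshold = 0)), 0L)

  # two independent causal variants in linkage equilibrium
  set.seed(61)
  n <- 3000
  g1 <- rbinom(n, 2, 0.4); g2 <- rbinom(n, 2, 0.4); g3 <- rbinom(n, 2, 0.4)
  eta <- -1 + 0.8 * g1 + 0.8 * g2
  y <- rbinom(n, 1, plogis(eta))
  geno <- cbind(v1 = g1, v2 = g2, v3 = g3)
  vm <- toy_vm(3, lead = 1)
  ph <- toy_pheno(y)
  sec2 <- conditional_scan(geno, ph, vm, p_threshold = 1e-6)
  expect_true("v2" %in% sec2$id)
  expect_false("v3" %in% sec2$id)
})
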