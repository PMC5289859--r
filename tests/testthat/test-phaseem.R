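test_that("EM is exact and immediate on fully homozygous samples", {
  homo <- hm_from_strings(c(rep("0000", 6), rep("1111", 4)))
  g <- unphase(homo)
  post <- em_phase(g)
  expect_true(post$converged)
  f <- setNames(post$f$freq, post$f$hap)
  expect_equal(unname(f["0000"]), 0.6)
  expect_equal(unname(f["1111"]), 0.4)
  # one ambiguity-free E/M pass reaches the fixed point
  expect_lte(post$n_iter, 2L)
})

test_that("diplotype posteriors concentrate as homozygote evidence accumulates", {
  post_prob_cis <- function(n_homo) {
    # one double heterozygote on a background of AB/AB and ab/ab homozygotes
    g <- rbind(
      matrix(2, n_homo, 2), matrix(0, n_homo, 2), c(1, 1)
    )
    post <- em_phase(g)
    het <- post$individuals[[2 * n_homo + 1]]
    hap_of <- function(i) post$haplotypes[i]
    cis <- vapply(seq_len(nrow(het$pairs)), function(p) {
      all(sort(hap_of(het$pairs[p, ])) == c("00", "11"))
    }, logical(1))
    sum(het$prob[cis])
  }
  p10 <- post_prob_cis(10)
  p100 <- post_prob_cis(100)
  expect_gte(p100, p10)
  expect_gt(p100, 0.98)
})

test_that("EM log-likelihood is nondecreasing and matches an independent maximizer", {
  set.seed(81)
  for (rep in 1:5) {
    n <- 60
    # random 2-variant genotypes with ambiguity
    f_true <- rexp(4); f_true <- f_true / sum(f_true)
    haps <- c("00", "01", "10", "11")
    draw <- matrix(sample(4, 2 * n, TRUE, prob = f_true), ncol = 2)
    hm <- hm_from_strings(haps[as.vector(t(draw))])
    g <- unphase(hm)
    post <- em_phase(g, tol = 1e-10)
    expect_true(all(diff(post$loglik) >= -1e-9))

    # independent maximizer: multi-start Nelder-Mead on the softmax simplex
    counts <- table(factor(paste0(g[, 1], g[, 2]),
                           levels = as.vector(outer(0:2, 0:2, paste0))))
    loglik_fn <- function(theta) {
      f <- exp(c(0, theta)); f <- f / sum(f)   # f over 00,01,10,11
      names(f) <- haps
      ll <- 0
      for (g1 in 0:2) for (g2 in 0:2) {
        nobs <- counts[[paste0(g1, g2)]]
        if (nobs == 0) next
        pr <- 0
        for (a in 1:4) for (b in 1:4) {
          ha <- as.integer(strsplit(haps[a], "")[[1]])
          hb <- as.integer(strsplit(haps[b], "")[[1]])
          if (ha[1] + hb[1] == g1 && ha[2] + hb[2] == g2) pr <- pr + f[a] * f[b]
        }
        ll <- ll + nobs * log(pr)
      }
      -ll
    }
    best <- NULL
    for (s in 1:8) {
      o <- optim(rnorm(3), loglik_fn, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
      if (is.null(best) || o$value < best$value) best <- o
    }
    f_opt <- exp(c(0, best$par)); f_opt <- f_opt / sum(f_opt)
    f_em <- setNames(rep(0, 4), haps)
    f_em[post$f$hap] <- post$f$freq
    expect_equal(unname(f_em), unname(f_opt), tolerance = 1e-4)
  }
})

test_that("corrupt genotypes are rejected naming the individual", {
  g <- rbind(a = c(0, 1), b = c(3, 0))
  expect_error(em_phase(g), "b")
})

test_that("phasing replicates respect posteriors and determinism", {
  # unambiguous individuals phase identically in every replicate
  homo <- hm_from_strings(c(rep("000", 4), rep("111", 4)))
  post <- em_phase(unphase(homo))
  reps <- sample_phasing_replicates(post, R = 5, seed = 3)
  expect_true(all(vapply(reps[-1], identical, logical(1), reps[[1]])))

  # draw frequencies match the posterior within binomial bounds
  strs <- c(rep("11", 30), rep("00", 30), "10", "01")
  hm <- hm_from_strings(strs)
  hm <- rbind(hm[1:60, ], hm[61:62, ])  # 31 individuals, last one ambiguous
  post2 <- em_phase(unphase(hm))
  het <- post2$individuals[[31]]
  p_top <- max(het$prob)
  R <- 400
  reps2 <- sample_phasing_replicates(post2, R = R, seed = 9)
  top_pair <- which.max(het$prob)
  hap_a <- haplofine:::string_to_hap(post2$haplotypes[het$pairs[top_pair, 1]])
  drawn <- vapply(reps2, function(m) all(m[61, ] == hap_a) || all(m[62, ] == hap_a),
                  logical(1))
  bounds <- qbinom(c(0.005, 0.995), R, p_top)
  expect_gte(sum(drawn), bounds[1])
  expect_lte(sum(drawn), bounds[2])

  # same seed, same draws; R = 1 is a single best-guess-style phasing
  expect_identical(
    sample_phasing_replicates(post2, R = 3, seed = 7),
    sample_phasing_replicates(post2, R = 3, seed = 7)
  )
  expect_length(sample_phasing_replicates(post2, R = 1, seed = 1), 1L)
})

test_that("dosages count exact matches and conserve total mass 2", {
  # homozygous carrier in every replicate: dosage 2
  homo <- hm_from_strings(c("11", "11", "00", "00"))
  reps <- list(homo, homo, homo)
  dm <- haplotype_dosages(reps, c(H0 = "00", H1 = "11"))
  expect_equal(unname(dm$d[1, "H1"]), 2)
  expect_equal(unname(dm$d[2, "H0"]), 2)
  expect_equal(rowSums(dm$d) + dm$unmapped, rep(2, 2))

  # counting oracle: (h1,h2) in 60% of replicates, (h3,h4) in 40%
  pair_a <- hm_from_strings(c("10", "01"))
  pair_b <- hm_from_strings(c("11", "00"))
  reps2 <- c(rep(list(pair_a), 60), rep(list(pair_b), 40))
  dm2 <- haplotype_dosages(reps2, c(H0 = "00", H1 = "01", H2 = "10", H3 = "11"))
  expect_equal(unname(dm2$d[1, ]), c(0.4, 0.6, 0.6, 0.4),
               ignore_attr = TRUE)

  # unmapped mass tracked, never force-matched
  dm3 <- haplotype_dosages(list(pair_a), c(H0 = "00"))
  expect_equal(dm3$unmapped, 2)
  expect_equal(rowSums(dm3$d) + dm3$unmapped, 2)
})

test_that("long-run dosages converge to twice the posterior marginal", {
  strs <- c(rep("11", 20), rep("00", 20))
  hm <- rbind(hm_from_strings(strs), hm_from_strings(c("10", "01")))
  post <- em_phase(unphase(hm))
  het <- post$individuals[[21]]
  marg <- setNames(numeric(length(post$haplotypes)), post$haplotypes)
  for (p in seq_len(nrow(het$pairs))) {
    marg[het$pairs[p, 1]] <- marg[het$pairs[p, 1]] + het$prob[p]
    marg[het$pairs[p, 2]] <- marg[het$pairs[p, 2]] + het$prob[p]
  }
  R <- 2000
  reps <- sample_phasing_replicates(post, R = R, seed = 11)
  bg <- setNames(post$haplotypes, paste0("H", seq_along(post$haplotypes) - 1))
  dm <- haplotype_dosages(reps, bg)
  d_het <- dm$d[21, ]
  for (h in seq_along(bg)) {
    expect_equal(unname(d_het[h]), unname(marg[bg[h]]),
                 tolerance = 4 * sqrt(0.5 / R) + 1e-9)
  }
})
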