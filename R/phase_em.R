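#' EM haplotype-frequency estimation and diplotype posteriors
#'
#' Excoffier-Slatkin EM on unphased genotypes over the candidate variant
#' set. The haplotype space is restricted to haplotypes compatible with at
#' least one individual's genotype (each individual with `h` heterozygous
#' sites contributes its `2^(h-1)` compatible unordered diplotypes), so
#' the full `2^M` enumeration never materializes. The E-step weights each
#' compatible diplotype `(a, b)` by `f_a f_b` (doubled for heterozygous
#' pairs, `a != b`); the M-step re-estimates the frequency vector `f` from
#' the expected haplotype counts. Iteration stops when
#' `max |f_new - f| < tol` or after `max_iter` iterations; the
#' log-likelihood trace is retained and is nondecreasing by construction.
#'
#' @param geno N x M genotype matrix with entries 0/1/2.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence tolerance on the frequency update (default 1e-8).
#' @param het_limit Maximum heterozygous sites per individual before the
#'   diplotype expansion is refused (default 14, i.e. at most 8192
#'   compatible pairs per individual).
#' @return An object of class `diplotype_posterior`: a list with
#'   `haplotypes` (string vector), `f` (tibble `hap`, `freq`),
#'   `individuals` (per individual, matrix of compatible hap-index pairs
#'   and posterior probabilities summing to 1), `loglik` (trace),
#'   `converged`, `n_iter`.
#' @export
em_phase <- function(geno, max_iter = 500, tol = 1e-8, het_limit = 14L) {
  geno <- as.matrix(geno)
  if (!all(geno %in% c(0L, 1L, 2L))) {
    bad <- which(rowSums(!matrix(geno %in% c(0L, 1L, 2L), nrow(geno))) > 0)[1]
    abort(sprintf(
      "genotypes must be 0/1/2; individual %s has an invalid entry.",
      rownames(geno)[bad] %||% bad
    ))
  }
  n <- nrow(geno); m <- ncol(geno)
  # enumerate compatible diplotypes per individual as haplotype strings
  indiv_pairs <- vector("list", n)
  hap_strings <- character(0)
  hap_index <- new.env(parent = emptyenv())
  get_idx <- function(s) {
    i <- hap_index[[s]]
    if (is.null(i)) {
      hap_strings[[length(hap_strings) + 1L]] <<- s
      i <- length(hap_strings)
      hap_index[[s]] <- i
    }
    i
  }
  for (i in seq_len(n)) {
    g <- geno[i, ]
    het <- which(g == 1L)
    base <- integer(m)
    base[g == 2L] <- 1L
    h <- length(het)
    if (h > het_limit) {
      abort(sprintf(
        "individual %s has %d heterozygous sites (limit %d); reduce the candidate set.",
        rownames(geno)[i] %||% i, h, het_limit
      ))
    }
    if (h == 0L) {
      idx <- get_idx(hap_to_string(base))
      indiv_pairs[[i]] <- matrix(c(idx, idx), ncol = 2L)
      next
    }
    # fix the first het site to chromosome a: 2^(h-1) unordered pairs
    n_pairs <- 2L^(h - 1L)
    pairs <- matrix(0L, nrow = n_pairs, ncol = 2L)
    for (p in seq_len(n_pairs)) {
      bits <- as.integer(intToBits(p - 1L))[seq_len(max(h - 1L, 1L))]
      a <- base; b <- base
      a[het[1L]] <- 1L; b[het[1L]] <- 0L
      if (h > 1L) {
        rest <- het[-1L]
        a[rest] <- bits[seq_len(h - 1L)]
        b[rest] <- 1L - bits[seq_len(h - 1L)]
      }
      pairs[p, ] <- c(get_idx(hap_to_string(a)), get_idx(hap_to_string(b)))
    }
    indiv_pairs[[i]] <- pairs
  }
  H <- length(hap_strings)
  f <- rep(1 / H, H)
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  post <- vector("list", n)
  repeat {
    iter <- iter + 1L
    counts <- numeric(H)
    ll <- 0
    for (i in seq_len(n)) {
      pr <- indiv_pairs[[i]]
      wt <- f[pr[, 1L]] * f[pr[, 2L]] * ifelse(pr[, 1L] == pr[, 2L], 1, 2)
      s <- sum(wt)
      if (s <= 0) {
        abort(sprintf(
          "individual %s is incompatible with all current haplotypes.",
          rownames(geno)[i] %||% i
        ))
      }
      ll <- ll + log(s)
      w <- wt / s
      post[[i]] <- w
      for (p in seq_len(nrow(pr))) {
        counts[pr[p, 1L]] <- counts[pr[p, 1L]] + w[p]
        counts[pr[p, 2L]] <- counts[pr[p, 2L]] + w[p]
      }
    }
    loglik <- c(loglik, ll)
    f_new <- counts / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  structure(
    list(
      haplotypes = hap_strings,
      f = tibble::tibble(hap = hap_strings, freq = f),
      individuals = purrr::map2(indiv_pairs, post, function(pr, w) {
        list(pairs = pr, prob = w)
      }),
      loglik = loglik, converged = converged, n_iter = iter,
      n_individuals = n, iid = rownames(geno)
    ),
    class = "diplotype_posterior"
  )
}

#' @export
print.diplotype_posterior <- function(x, ...) {
  cat(sprintf(
    "<diplotype_posterior> %d individuals, %d haplotypes, %s in %d EM iterations\n",
    x$n_individuals, length(x$haplotypes),
    if (x$converged) "converged" else "NOT converged", x$n_iter
  ))
  invisible(x)
}

#' Draw phasing replicates from diplotype posteriors
#'
#' Each replicate draws one compatible diplotype per individual from its
#' posterior, independently across individuals and replicates. Unambiguous
#' individuals are phased identically in every replicate.
#'
#' @param posterior A [em_phase()] result.
#' @param R Number of replicates (default 100).
#' @param seed Seed for the draws.
#' @return A list of `R` phased 0/1 matrices (2N x M, two consecutive rows
#'   per individual).
#' @export
sample_phasing_replicates <- function(posterior, R = 100, seed = 1L) {
  if (R < 1) abort("`R` must be at least 1.")
  set.seed(derive_seed(seed, "replicates"))
  n <- posterior$n_individuals
  hap_mat <- do.call(rbind, lapply(posterior$haplotypes, string_to_hap))
  lapply(seq_len(R), function(r) {
    rows <- matrix(0L, nrow = 2L * n, ncol = ncol(hap_mat))
    for (i in seq_len(n)) {
      ind <- posterior$individuals[[i]]
      p <- if (nrow(ind$pairs) == 1L) 1L else {
        sample.int(nrow(ind$pairs), 1L, prob = ind$prob)
      }
      rows[2L * i - 1L, ] <- hap_mat[ind$pairs[p, 1L], ]
      rows[2L * i, ] <- hap_mat[ind$pairs[p, 2L], ]
    }
    if (!is.null(posterior$iid)) {
      rownames(rows) <- paste0(rep(posterior$iid, each = 2L), c("_a", "_b"))
    }
    rows
  })
}

#' Haplotype dosages over phasing replicates
#'
#' Maps every replicate chromosome onto the best-guess haplotypes by
#' exact match and averages over replicates: `d[i, h]` is the mean number
#' of copies (0-2) of best-guess haplotype `h` carried by individual `i`.
#' Replicate haplotypes matching no best-guess haplotype are not forced
#' onto a nearest match; their mass is tracked in `unmapped`, so
#' `rowSums(d) + unmapped == 2` for every individual.
#'
#' @param replicates List of phased matrices from
#'   [sample_phasing_replicates()].
#' @param best_guess Character vector of haplotype strings (optionally
#'   named with labels, e.g. `H0`...`H12`; unnamed vectors are labelled in
#'   order).
#' @return A list of class `dosage_matrix`: `d` (N x H matrix),
#'   `unmapped` (length-N vector), `R`.
#' @export
haplotype_dosages <- function(replicates, best_guess) {
  R <- length(replicates)
  if (!R) abort("`replicates` must be a non-empty list.")
  labels <- names(best_guess) %||% paste0("H", seq_along(best_guess) - 1L)
  if (is.null(names(best_guess))) names(best_guess) <- labels
  n <- nrow(replicates[[1L]]) / 2L
  d <- matrix(0, nrow = n, ncol = length(best_guess),
              dimnames = list(NULL, names(best_guess)))
  unmapped <- numeric(n)
  for (rep_mat in replicates) {
    strs <- apply(rep_mat, 1L, hap_to_string)
    idx <- match(strs, unname(best_guess))
    for (i in seq_len(n)) {
      for (chrom in c(2L * i - 1L, 2L * i)) {
        h <- idx[chrom]
        if (is.na(h)) unmapped[i] <- unmapped[i] + 1 else d[i, h] <- d[i, h] + 1
      }
    }
  }
  iid <- rownames(replicates[[1L]])
  if (!is.null(iid)) rownames(d) <- sub("_a$", "", iid[seq(1L, 2L * n, by = 2L)])
  structure(
    list(d = d / R, unmapped = unmapped / R, R = R),
    class = "dosage_matrix"
  )
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf(
    "<dosage_matrix> %d individuals x %d haplotypes over %d phasing replicates\n",
    nrow(x$d), ncol(x$d), x$R
  ))
  invisible(x)
}
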