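#' Hill number of order q
#'
#' Effective number of equally-abundant taxa: q = 0 gives observed richness,
#' q = 1 the exponential of Shannon entropy, q = 2 the inverse Simpson
#' concentration.
#'
#' @param counts non-negative abundance vector with positive total.
#' @param q diversity order, one of 0, 1, 2.
#' @return the Hill diversity (>= 1 for any non-degenerate vector).
#' @export
hill_number <- function(counts, q) {
  stop_if(!is.numeric(counts) || anyNA(counts) || any(counts < 0),
          "counts must be non-negative numbers")
  n <- sum(counts)
  stop_if(n <= 0, "total abundance must be positive")
  p <- counts[counts > 0] / n
  switch(as.character(q),
         "0" = length(p),
         "1" = exp(-sum(p * log(p))),
         "2" = 1 / sum(p^2),
         stop("q must be 0, 1 or 2", call. = FALSE))
}

#' Bias-corrected Chao1 richness estimate
#'
#' `S_obs + f1(f1-1) / (2(f2+1))`, defined also when no doubletons are
#' observed, with the standard variance formula for the bias-corrected
#' estimator.
#'
#' @param counts integer abundance vector.
#' @return list with `estimate`, `se`, `s_obs`, `f1`, `f2`.
#' @export
chao1 <- function(counts) {
  stop_if(!is_count_vector(counts), "counts must be non-negative integers")
  x <- counts[counts > 0]
  s_obs <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  correction <- f1 * (f1 - 1) / (2 * (f2 + 1))
  est <- s_obs + correction
  v <- correction +
    f1 * (2 * f1 - 1)^2 / (4 * (f2 + 1)^2) +
    f1^2 * f2 * (f1 - 1)^2 / (4 * (f2 + 1)^4)
  list(estimate = est, se = sqrt(max(v, 0)), s_obs = s_obs, f1 = f1, f2 = f2)
}

#' Estimated sample coverage (Chao--Jost)
#'
#' Estimated proportion of the assemblage's individuals that belong to
#' observed taxa: `1 - (f1/n) * (n-1)f1 / ((n-1)f1 + 2 f2)`.
#'
#' @param counts integer abundance vector with total n >= 1.
#' @return coverage estimate in \[0, 1\].
#' @export
sample_coverage <- function(counts) {
  stop_if(!is_count_vector(counts), "counts must be non-negative integers")
  n <- sum(counts)
  stop_if(n < 1, "need at least one read")
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f1 == 0) return(1)
  a <- (n - 1) * f1 / ((n - 1) * f1 + 2 * f2)
  1 - (f1 / n) * a
}

# Expected coverage of a without-replacement subsample of size m < n;
# at m = n the Chao--Jost estimate is used (the expectation formula gives 1).
expected_coverage <- function(counts, m) {
  x <- counts[counts > 0]
  n <- sum(x)
  if (m >= n) return(sample_coverage(counts))
  # E[C_m] = 1 - sum_i (x_i/n) * choose(n - x_i, m) / choose(n - 1, m)
  lref <- lchoose(n - 1, m)
  term <- ifelse(n - x >= m, exp(lchoose(n - x, m) - lref), 0)
  1 - sum((x / n) * term)
}

# Expected Hill number of order q for a without-replacement subsample of
# size m (exact hypergeometric expectations; see vignette for formulas).
rarefied_hill <- function(counts, q, m) {
  x <- counts[counts > 0]
  n <- sum(x)
  stop_if(m < 1 || m > n, "subsample size out of range")
  if (q == 0) {
    lref <- lchoose(n, m)
    absent <- ifelse(n - x >= m, exp(lchoose(n - x, m) - lref), 0)
    return(sum(1 - absent))
  }
  if (q == 2) {
    # inverse of E[sum (k_i/m)^2] under hypergeometric subsampling
    mu <- m * x / n
    v <- m * (x / n) * (1 - x / n) * (n - m) / (n - 1)
    return(1 / sum((v + mu^2) / m^2))
  }
  if (q == 1) {
    # E[-sum (k/m) log(k/m)] via the hypergeometric pmf of each taxon
    k <- seq_len(m)
    h <- -(k / m) * log(k / m) # contribution of a taxon drawn k times
    ent <- 0
    for (xi in unique(x)) {
      kk <- seq_len(min(xi, m))
      pr <- stats::dhyper(kk, xi, n - xi, m)
      ent <- ent + sum(x == xi) * sum(h[kk] * pr)
    }
    return(exp(ent))
  }
  stop("q must be 0, 1 or 2", call. = FALSE)
}

#' Coverage-normalized Hill number
#'
#' Finds the largest subsample size m whose expected coverage does not
#' exceed `target_coverage` (integer search on the monotone expected-coverage
#' curve, ties broken to the smaller m) and returns the expected Hill number
#' of order q at that m. Only interpolation (m <= n) is supported; the
#' target must not exceed the sample's estimated coverage.
#'
#' @param counts integer abundance vector.
#' @param q diversity order (0, 1 or 2).
#' @param target_coverage coverage to normalize to (default 0.9).
#' @return list with `diversity`, `m`, and the achieved `coverage`.
#' @export
coverage_normalized_hill <- function(counts, q, target_coverage = 0.9) {
  stop_if(!is_count_vector(counts), "counts must be non-negative integers")
  cov_n <- sample_coverage(counts)
  stop_if(target_coverage > cov_n + 1e-12,
          sprintf("target coverage %.3f exceeds estimated sample coverage %.3f; extrapolation is not supported",
                  target_coverage, cov_n))
  n <- sum(counts)
  lo <- 1L
  hi <- as.integer(n)
  if (expected_coverage(counts, hi) <= target_coverage) {
    m <- hi
  } else if (expected_coverage(counts, lo) >= target_coverage) {
    m <- lo
  } else {
    # smallest m with E[C_m] >= target, then step back to the tie-broken m
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (expected_coverage(counts, mid) >= target_coverage) hi <- mid else lo <- mid
    }
    m <- hi
  }
  list(diversity = rarefied_hill(counts, q, m), m = m,
       coverage = expected_coverage(counts, m))
}

#' Community evenness
#'
#' Default is the Hill evenness ratio `D(q=2) / D(q=0)`; Pielou's
#' `J = H / log(S)` is available as an option.
#'
#' @param counts non-negative abundance vector.
#' @param method `"hill_ratio"` (default) or `"pielou"`.
#' @return evenness in (0, 1\].
#' @export
evenness <- function(counts, method = c("hill_ratio", "pielou")) {
  method <- match.arg(method)
  if (method == "hill_ratio") {
    return(hill_number(counts, 2) / hill_number(counts, 0))
  }
  s <- hill_number(counts, 0)
  if (s == 1) return(1)
  log(hill_number(counts, 1)) / log(s)
}

#' Per-sample Hill diversity profile
#'
#' Observed Hill numbers (q = 0, 1, 2), estimated sample coverage,
#' coverage-normalized Hill numbers at `target_coverage`, and evenness for
#' every sample of an OTU table.
#'
#' @param t an `otu_table`.
#' @param target_coverage coverage for the normalized columns (default 0.9).
#' @param cap_target when `TRUE` (default), a sample whose estimated
#'   coverage falls below the target is normalized at its own estimated
#'   coverage instead (flagged in `target_capped`); with `FALSE` such a
#'   sample raises the [coverage_normalized_hill()] error.
#' @return data frame, one row per sample.
#' @export
hill_profile <- function(t, target_coverage = 0.9, cap_target = TRUE) {
  rows <- lapply(sample_ids(t), function(s) {
    x <- t$counts[s, ]
    target <- target_coverage
    capped <- FALSE
    if (cap_target && sample_coverage(x) < target) {
      target <- sample_coverage(x)
      capped <- TRUE
    }
    norm <- lapply(c(0, 1, 2), function(q) {
      coverage_normalized_hill(x, q, target)
    })
    data.frame(sample_id = s,
               q0 = hill_number(x, 0), q1 = hill_number(x, 1),
               q2 = hill_number(x, 2),
               coverage = sample_coverage(x),
               q0_norm = norm[[1]]$diversity, q1_norm = norm[[2]]$diversity,
               q2_norm = norm[[3]]$diversity, m_norm = norm[[1]]$m,
               target_capped = capped,
               evenness = evenness(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
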