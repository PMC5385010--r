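# shared fixtures and independent oracles

toy_otu <- function(counts, taxonomy = NULL) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("s", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("o", seq_len(ncol(counts)))
  }
  otu_table(counts, taxonomy = taxonomy)
}

# scaled-down generator config used across tests (2 cores, 500 taxa,
# ~2000 reads/sample) so simulation-based checks stay fast
small_config <- function(...) {
  synthetic_config(n_cores = 2, n_niche_taxa = 300, n_nested_taxa = 200,
                   reads_mean = 2000, ...)
}

# plain Rand index between two partitions
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  agree / choose(n, 2)
}

# brute-force per-pair Podani Jaccard decomposition
brute_decompose <- function(pa) {
  n <- nrow(pa)
  D <- Repl <- Rich <- matrix(0, n, n, dimnames = list(rownames(pa), rownames(pa)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- sum(pa[i, ] & pa[j, ])
      b <- sum(pa[i, ] & !pa[j, ])
      c <- sum(!pa[i, ] & pa[j, ])
      tot <- a + b + c
      D[i, j] <- (b + c) / tot
      Repl[i, j] <- 2 * min(b, c) / tot
      Rich[i, j] <- abs(b - c) / tot
    }
  }
  list(D = D, Repl = Repl, Rich = Rich)
}

# brute-force O(n^3) UPGMA agglomeration returning sorted merge heights
brute_upgma_heights <- function(d) {
  d <- as.matrix(d)
  active <- lapply(seq_len(nrow(d)), identity)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(active) - 1)) {
      for (j in seq(i + 1, length(active))) {
        h <- mean(d[active[[i]], active[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(active[[best[2]]], active[[best[3]]])
    active <- active[-c(best[2], best[3])]
    active[[length(active) + 1]] <- merged
  }
  heights
}
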