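#' Decompose one pairwise Jaccard dissimilarity
#'
#' Podani-family split of the presence/absence Jaccard dissimilarity into a
#' taxonomic replacement part and a richness-difference part. With `a`
#' shared OTUs and `b`, `c` OTUs unique to either sample:
#' `D = (b+c)/(a+b+c)`, `Repl = 2 min(b,c)/(a+b+c)`,
#' `Rich = |b-c|/(a+b+c)`, and `D = Repl + Rich` exactly.
#'
#' @param a,b,c non-negative integers; at least one must be positive.
#' @return named vector `c(D, Repl, Rich)`.
#' @export
jaccard_decompose <- function(a, b, c) {
  stop_if(any(c(a, b, c) < 0), "a, b, c must be non-negative")
  tot <- a + b + c
  stop_if(tot < 1, "dissimilarity undefined when a = b = c = 0")
  c(D = (b + c) / tot, Repl = 2 * min(b, c) / tot, Rich = abs(b - c) / tot)
}

#' Pairwise replacement/richness decomposition of a community table
#'
#' @param pa logical or 0/1 matrix, samples x OTUs (see
#'   [presence_absence()]), or an `otu_table` (converted at threshold 1).
#' @param allow_empty tolerate samples with no OTUs (pairs of two empty
#'   samples get zero dissimilarity). Used internally by the permutation
#'   nulls, where reshuffled tables may empty a sample; user-facing calls
#'   keep the default `FALSE` and fail loudly.
#' @return list of class `distance_decomposition` with square symmetric
#'   matrices `D`, `Repl`, `Rich` (zero diagonals, entries in \[0, 1\],
#'   `D = Repl + Rich` elementwise).
#' @export
decompose_matrix <- function(pa, allow_empty = FALSE) {
  if (inherits(pa, "otu_table")) pa <- presence_absence(pa)
  pa <- pa * 1
  stop_if(nrow(pa) < 2, "need at least two samples")
  empty <- which(rowSums(pa) == 0)
  stop_if(length(empty) > 0 && !allow_empty,
          sprintf("sample '%s' has no OTUs present", rownames(pa)[empty[1]]))
  A <- pa %*% t(pa)                    # shared OTUs
  rich <- rowSums(pa)
  B <- matrix(rich, nrow(pa), nrow(pa)) - A       # unique to row sample
  C <- t(B)
  tot <- A + B + C
  tot[tot == 0] <- 1                   # empty-vs-empty pairs: defined as 0
  D <- (B + C) / tot
  Repl <- 2 * pmin(B, C) / tot
  Rich <- abs(B - C) / tot
  diag(D) <- diag(Repl) <- diag(Rich) <- 0
  structure(list(D = D, Repl = Repl, Rich = Rich), class = "distance_decomposition")
}

#' @export
print.distance_decomposition <- function(x, ...) {
  cat(sprintf("distance_decomposition over %d samples (D = Repl + Rich)\n",
              nrow(x$D)))
  invisible(x)
}

#' Surface-to-layer turnover profile
#'
#' Jaccard dissimilarity between the surface layer and every deeper layer of
#' a per-depth sum table, split into replacement and richness-difference
#' components.
#'
#' @param sum_table an `otu_table` with one row per depth layer (see
#'   [build_sum_table()]).
#' @param surface_layer row label of the surface layer (e.g. `"0-1"`).
#' @return data frame with one row per non-surface layer, in table order:
#'   `layer`, `Distance`, `Repl`, `Richness`.
#' @export
surface_distance_profile <- function(sum_table, surface_layer) {
  pa <- presence_absence(sum_table)
  stop_if(!surface_layer %in% rownames(pa),
          sprintf("surface layer '%s' not found", surface_layer))
  surf <- pa[surface_layer, ]
  others <- setdiff(rownames(pa), surface_layer)
  rows <- lapply(others, function(ly) {
    x <- pa[ly, ]
    dec <- jaccard_decompose(a = sum(surf & x), b = sum(surf & !x),
                             c = sum(!surf & x))
    data.frame(layer = ly, Distance = dec[["D"]], Repl = dec[["Repl"]],
               Richness = dec[["Rich"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Gower-centered matrix G of a dissimilarity matrix; LCBD_i = G_ii / trace(G)
gower_center <- function(D) {
  n <- nrow(D)
  A <- -0.5 * D^2
  H <- diag(n) - matrix(1 / n, n, n)
  H %*% A %*% H
}

lcbd_values <- function(D, sqrt_transform = FALSE) {
  if (sqrt_transform) D <- sqrt(D)
  G <- gower_center(D)
  ss_total <- sum(diag(G))
  if (ss_total <= 1e-12) {
    return(list(lcbd = rep(NA_real_, nrow(D)), bd_total = 0, degenerate = TRUE))
  }
  list(lcbd = diag(G) / ss_total, bd_total = ss_total / (nrow(D) - 1),
       degenerate = FALSE)
}

#' Local contributions to beta-diversity from a dissimilarity matrix
#'
#' Gower-centers `-0.5 D^2` (optionally after an elementwise square root of
#' `D`, the usual device for embedding non-Euclidean component matrices) and
#' returns each sample's share of the total sum of squares. `BD_total` is
#' the total community variance, `SS_total / (n - 1)`.
#'
#' Significance is assessed against the unrestricted null in which each
#' OTU's occurrences are permuted independently across samples: supply the
#' community matrix `comm` and the function `dist_fun` that maps it to the
#' dissimilarity under test. With `comm = NULL` no p-values are computed.
#'
#' @param D square symmetric dissimilarity matrix, zero diagonal.
#' @param sqrt_transform take `sqrt(D)` before centering (default `FALSE`).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param comm optional samples x OTUs matrix generating `D`.
#' @param dist_fun optional `function(comm) -> D` used on permuted tables.
#' @return list with `lcbd`, `bd_total`, `p` (or `NULL`), `n_perm`,
#'   and `degenerate` (`TRUE` when the matrix has no variance, e.g. an
#'   all-zero component; contributions are then `NA`, never silent `NaN`).
#' @export
lcbd_from_distance <- function(D, sqrt_transform = FALSE, n_perm = 999,
                               seed = NULL, comm = NULL, dist_fun = NULL) {
  D <- as.matrix(D)
  stop_if(nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8,
          "D must be square and symmetric")
  stop_if(any(diag(D) != 0), "D must have a zero diagonal")
  obs <- lcbd_values(D, sqrt_transform)
  p <- NULL
  if (!is.null(comm) && !obs$degenerate) {
    stop_if(is.null(dist_fun), "dist_fun is required for permutation tests")
    n <- nrow(comm)
    p <- local_seed(seed, {
      exceed <- rep(0L, n)
      for (b in seq_len(n_perm)) {
        perm <- apply(comm, 2, function(col) col[sample.int(n)])
        rownames(perm) <- rownames(comm)
        lp <- lcbd_values(dist_fun(perm), sqrt_transform)$lcbd
        exceed <- exceed + (!is.na(lp) & lp >= obs$lcbd)
      }
      perm_pvalue(exceed, n_perm)
    })
  }
  list(lcbd = obs$lcbd, bd_total = obs$bd_total, p = p, n_perm = n_perm,
       degenerate = obs$degenerate)
}

#' Local contributions of the replacement and richness components
#'
#' Applies [lcbd_from_distance()] to the `Repl` and `Rich` matrices of a
#' presence/absence decomposition (square-root transform on by default),
#' with the per-OTU permutation null evaluated by re-decomposing each
#' permuted table.
#'
#' @param pa presence/absence matrix (samples x OTUs) or `otu_table`.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @param sqrt_transform see [lcbd_from_distance()] (default `TRUE`).
#' @return list with elements `repl` and `rich`, each as returned by
#'   [lcbd_from_distance()], plus the `decomposition`.
#' @export
component_local_contributions <- function(pa, n_perm = 999, seed = NULL,
                                          sqrt_transform = TRUE) {
  if (inherits(pa, "otu_table")) pa <- presence_absence(pa)
  pa <- pa * 1
  dec <- decompose_matrix(pa)
  seeds <- if (is.null(seed)) list(NULL, NULL) else list(seed, seed + 1L)
  repl <- lcbd_from_distance(dec$Repl, sqrt_transform, n_perm, seeds[[1]],
                             comm = pa,
                             dist_fun = function(m) decompose_matrix(m, allow_empty = TRUE)$Repl)
  rich <- lcbd_from_distance(dec$Rich, sqrt_transform, n_perm, seeds[[2]],
                             comm = pa,
                             dist_fun = function(m) decompose_matrix(m, allow_empty = TRUE)$Rich)
  list(repl = repl, rich = rich, decomposition = dec)
}

#' Species (OTU) contributions to beta-diversity
#'
#' Column-wise share of the total community variance of a Hellinger-
#' transformed matrix: `SCBD_j = SS_j / SS_total`, summing to 1.
#'
#' @param hellinger_matrix samples x OTUs real matrix (see [hellinger()]).
#' @return named numeric vector of SCBD values.
#' @export
scbd <- function(hellinger_matrix) {
  dev <- scale(hellinger_matrix, center = TRUE, scale = FALSE)
  ss_j <- colSums(dev^2)
  ss_total <- sum(ss_j)
  stop_if(ss_total <= 1e-12, "community matrix has no variance")
  ss_j / ss_total
}

#' Structuring OTUs by SCBD threshold
#'
#' @param scbd_values named SCBD vector (see [scbd()]).
#' @param threshold minimum contribution (default 0.005, i.e. 5 per mill).
#' @return named vector of contributions `> threshold`, sorted descending.
#' @export
structuring_otus <- function(scbd_values, threshold = 0.005) {
  keep <- scbd_values[scbd_values > threshold]
  keep[order(keep, decreasing = TRUE)]
}

#' Relative nestedness of a decomposition
#'
#' Share of community dissimilarity attributable to richness difference
#' rather than replacement — 1 for a perfectly nested profile (replacement
#' zero everywhere), 0 for pure replacement. Two aggregations are provided
#' and always reported with their definition: `"podani"` averages the
#' per-pair ratio `Rich/D` over pairs with `D > 0`; `"baselga_like"` is the
#' aggregate ratio `sum(Rich) / sum(D)` over all pairs.
#'
#' @param dec a `distance_decomposition`.
#' @param definition `"podani"` or `"baselga_like"`.
#' @return list with `value` in \[0, 1\] and `definition`.
#' @export
relative_nestedness <- function(dec, definition = c("podani", "baselga_like")) {
  definition <- match.arg(definition)
  lower <- lower.tri(dec$D)
  d <- dec$D[lower]
  rich <- dec$Rich[lower]
  value <- if (definition == "podani") {
    ok <- d > 0
    stop_if(!any(ok), "all pairs identical; nestedness undefined")
    mean(rich[ok] / d[ok])
  } else {
    stop_if(sum(d) == 0, "all pairs identical; nestedness undefined")
    sum(rich) / sum(d)
  }
  list(value = value, definition = definition)
}
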