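#' Centered, scaled PCA with a deterministic sign convention
#'
#' Thin wrapper around [stats::prcomp()] that fixes each axis' sign so the
#' largest-magnitude loading is positive, and reports per-axis variance
#' proportions.
#'
#' @param x numeric matrix, samples x variables, no `NA`.
#' @param center,scale passed to `prcomp` (defaults `TRUE`, matching a
#'   correlation-matrix PCA).
#' @return list with `scores`, `loadings`, `var_prop`.
#' @export
pca <- function(x, center = TRUE, scale = TRUE) {
  stop_if(anyNA(x), "NA values present; resolve them before PCA")
  stop_if(nrow(x) < 2 || ncol(x) < 2, "need >= 2 samples and >= 2 variables")
  sds <- apply(x, 2, stats::sd)
  stop_if(any(sds == 0),
          sprintf("zero-variance column '%s'", colnames(x)[sds == 0][1]))
  fit <- stats::prcomp(x, center = center, scale. = scale)
  flip <- apply(fit$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(fit$x, 2, flip, `*`)
  loadings <- sweep(fit$rotation, 2, flip, `*`)
  list(scores = scores, loadings = loadings,
       var_prop = fit$sdev^2 / sum(fit$sdev^2))
}

#' Nonmetric multidimensional scaling
#'
#' Kruskal stress-1 NMDS via `vegan::metaMDS` (isotonic regression with
#' random restarts), seeded for reproducibility.
#'
#' @param d a `dist` or symmetric dissimilarity matrix.
#' @param dims ordination dimensions (default 2).
#' @param restarts random restarts (default 20).
#' @param seed integer seed.
#' @return list with `scores` (samples x dims), `stress`, `converged`.
#' @export
nmds <- function(d, dims = 2, restarts = 20, seed = NULL) {
  d <- stats::as.dist(d)
  fit <- local_seed(seed, vegan::metaMDS(d, k = dims, trymax = restarts,
                                         trace = 0, wascores = FALSE))
  list(scores = vegan::scores(fit, display = "sites"), stress = fit$stress,
       converged = isTRUE(fit$converged))
}

#' Mantel correlation between two dissimilarity matrices
#'
#' Pearson correlation of the lower triangles with a joint row/column
#' permutation test (`vegan::mantel`).
#'
#' @param d1,d2 dissimilarity matrices over the same samples.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return list with `r` and `p`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  d1 <- stats::as.dist(d1)
  d2 <- stats::as.dist(d2)
  stop_if(attr(d1, "Size") != attr(d2, "Size"), "matrix dimensions differ")
  fit <- local_seed(seed, vegan::mantel(d1, d2, permutations = n_perm))
  list(r = unname(fit$statistic), p = fit$signif)
}

#' One-way PERMANOVA (distance-based pseudo-F)
#'
#' `vegan::adonis2` on a single grouping factor; p-value from permuting
#' group labels.
#'
#' @param d dissimilarity matrix or `dist`.
#' @param groups factor of group labels, one per sample.
#' @param n_perm permutations (default 1999).
#' @param seed integer seed.
#' @return list with `f`, `r2`, `p`.
#' @export
permanova <- function(d, groups, n_perm = 1999, seed = NULL) {
  groups <- as.factor(groups)
  stop_if(nlevels(droplevels(groups)) < 2, "need at least two groups")
  d <- stats::as.dist(d)
  df <- data.frame(g = groups)
  fit <- local_seed(seed, vegan::adonis2(d ~ g, data = df,
                                         permutations = n_perm))
  list(f = fit$F[1], r2 = fit$R2[1], p = fit$`Pr(>F)`[1])
}

#' Homogeneity of group dispersions with Tukey post hoc comparisons
#'
#' Principal-coordinate embedding of `d` (`vegan::betadisper`; negative
#' eigenvalues are handled by vegan and their magnitude is reported),
#' distances to group centroids, one-way ANOVA and Tukey HSD pairs.
#'
#' @param d dissimilarity matrix or `dist`.
#' @param groups factor, one label per sample; every group needs >= 2
#'   samples.
#' @return list with `dispersions` (per sample), `group_means`, `anova_f`,
#'   `anova_p`, `tukey` (pairwise table), `neg_eigenvalue_share`.
#' @export
dispersion_test <- function(d, groups) {
  groups <- as.factor(groups)
  stop_if(any(table(groups) < 2), "every group needs at least two samples")
  bd <- vegan::betadisper(stats::as.dist(d), groups, type = "centroid")
  eig <- bd$eig
  neg_share <- if (any(eig < 0)) sum(abs(eig[eig < 0])) / sum(abs(eig)) else 0
  if (neg_share > 0) {
    message(sprintf("PCoA: dropped negative eigenvalues carrying %.1f%% of total magnitude",
                    100 * neg_share))
  }
  av <- stats::aov(bd$distances ~ groups)
  s <- summary(av)[[1]]
  list(dispersions = bd$distances,
       group_means = tapply(bd$distances, groups, mean),
       anova_f = s$`F value`[1], anova_p = s$`Pr(>F)`[1],
       tukey = stats::TukeyHSD(av)$groups,
       neg_eigenvalue_share = neg_share)
}

#' Fit environmental vectors onto ordination scores
#'
#' Per-variable squared correlation with its least-squares projection onto
#' the ordination space, with permutation p-values (`vegan::envfit`).
#'
#' @param scores ordination scores, samples x axes.
#' @param env numeric matrix of environmental variables, no `NA`.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return data frame with `variable`, `r2`, `p`.
#' @export
envfit_vectors <- function(scores, env, n_perm = 999, seed = NULL) {
  env <- as.matrix(env)
  stop_if(anyNA(env), "NA values present in env")
  sds <- apply(env, 2, stats::sd)
  stop_if(any(sds == 0),
          sprintf("constant variable '%s'", colnames(env)[sds == 0][1]))
  fit <- local_seed(seed, vegan::envfit(scores, env, permutations = n_perm))
  data.frame(variable = names(fit$vectors$r), r2 = unname(fit$vectors$r),
             p = unname(fit$vectors$pvals), stringsAsFactors = FALSE)
}

fso_memberships <- function(x) {
  rng <- range(x)
  stop_if(diff(rng) == 0, "environmental axis is constant")
  (x - rng[1]) / (rng[2] - rng[1])
}

# similarity for FSO: dissimilarities already in [0, 1] (Jaccard family)
# keep their natural complement; larger scales are max-normalized first
fso_similarity <- function(d) 1 - d / max(max(d), 1)

fso_apparent <- function(S, mu) {
  n <- length(mu)
  vapply(seq_len(n), function(i) {
    w <- S[i, -i]
    sum(w * mu[-i]) / sum(w)
  }, numeric(1))
}

#' One-dimensional fuzzy set ordination
#'
#' Tests how well an environmental axis orders a community: fuzzy
#' memberships `mu` are the min-max scaled axis values; apparent memberships
#' `nu_i` average the memberships of the other samples weighted by community
#' similarity `S = 1 - D` (with `D` max-normalized first when it exceeds 1);
#' the statistic is `r = cor(mu, nu)`, with a permutation p-value from
#' reshuffling the axis.
#'
#' @param d community dissimilarity matrix.
#' @param x environmental axis values, one per sample.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return list with `mu`, `nu`, `r`, `p`, `dimensions = 1`.
#' @export
fso <- function(d, x, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  stop_if(nrow(d) != length(x), "axis length must match sample count")
  S <- fso_similarity(d)
  mu <- fso_memberships(x)
  nu <- fso_apparent(S, mu)
  r <- stats::cor(mu, nu)
  p <- local_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      mu_p <- fso_memberships(sample(x))
      exceed <- exceed + (stats::cor(mu_p, fso_apparent(S, mu_p)) >= r)
    }
    perm_pvalue(exceed, n_perm)
  })
  list(mu = mu, nu = nu, r = r, p = p, dimensions = 1)
}

#' Two-dimensional fuzzy set ordination
#'
#' Fits each axis independently as in [fso()] and reports the correlation
#' between the stacked membership vectors `(mu1, mu2)` and `(nu1, nu2)`;
#' the permutation null reshuffles both axes jointly.
#'
#' @param d community dissimilarity matrix.
#' @param x1,x2 two environmental axes.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return list with per-axis results (`axis1`, `axis2`), combined `r`, `p`,
#'   `dimensions = 2`.
#' @export
fso_2d <- function(d, x1, x2, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  S <- fso_similarity(d)
  stat <- function(a1, a2) {
    mu1 <- fso_memberships(a1); mu2 <- fso_memberships(a2)
    nu1 <- fso_apparent(S, mu1); nu2 <- fso_apparent(S, mu2)
    list(mu1 = mu1, mu2 = mu2, nu1 = nu1, nu2 = nu2,
         r = stats::cor(c(mu1, mu2), c(nu1, nu2)))
  }
  obs <- stat(x1, x2)
  p <- local_seed(seed, {
    exceed <- 0L
    n <- length(x1)
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      exceed <- exceed + (stat(x1[idx], x2[idx])$r >= obs$r)
    }
    perm_pvalue(exceed, n_perm)
  })
  list(axis1 = list(mu = obs$mu1, nu = obs$nu1, r = stats::cor(obs$mu1, obs$nu1)),
       axis2 = list(mu = obs$mu2, nu = obs$nu2, r = stats::cor(obs$mu2, obs$nu2)),
       r = obs$r, p = p, dimensions = 2)
}

#' Kulczynski dissimilarity between two abundance vectors
#'
#' `1 - 0.5 (W/sum(x) + W/sum(y))` with `W = sum(pmin(x, y))`.
#'
#' @param x,y non-negative vectors with positive totals.
#' @return dissimilarity in \[0, 1\].
#' @export
kulczynski_distance <- function(x, y) {
  stop_if(any(x < 0) || any(y < 0), "abundances must be non-negative")
  stop_if(sum(x) == 0 || sum(y) == 0, "zero-total vector")
  w <- sum(pmin(x, y))
  1 - 0.5 * (w / sum(x) + w / sum(y))
}

#' Kulczynski dissimilarity matrix of an OTU table
#'
#' @param t an `otu_table` or abundance matrix (samples x OTUs).
#' @return a `dist` object.
#' @export
kulczynski_matrix <- function(t) {
  m <- if (inherits(t, "otu_table")) t$counts else t
  stop_if(any(rowSums(m) == 0), "zero-total sample")
  vegan::vegdist(m, method = "kulczynski")
}

#' UPGMA (average-linkage) clustering
#'
#' @param d dissimilarity matrix or `dist`.
#' @param k optional number of groups to cut the dendrogram into.
#' @return list with the `hclust` object (`tree`), merge `heights`, and
#'   `groups` (cut assignments, or `NULL`).
#' @export
upgma <- function(d, k = NULL) {
  d <- stats::as.dist(d)
  stop_if(attr(d, "Size") < 2, "need at least two samples")
  tree <- stats::hclust(d, method = "average")
  groups <- if (!is.null(k)) stats::cutree(tree, k = k)
  list(tree = tree, heights = tree$height, groups = groups)
}

#' One-way ANOVA with Tukey HSD post hoc pairs
#'
#' @param values numeric response.
#' @param groups factor with >= 2 levels, each with >= 2 observations.
#' @return list with `f`, `df`, `p`, `tukey`.
#' @export
group_anova_tukey <- function(values, groups) {
  groups <- as.factor(groups)
  stop_if(nlevels(droplevels(groups)) < 2, "need at least two groups")
  stop_if(any(table(groups) < 2), "every group needs at least two values")
  av <- stats::aov(values ~ groups)
  s <- summary(av)[[1]]
  list(f = s$`F value`[1], df = s$Df, p = s$`Pr(>F)`[1],
       tukey = stats::TukeyHSD(av)$groups)
}
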