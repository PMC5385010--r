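test_that("PCA matches an eigen-decomposition oracle", {
  set.seed(53)
  x <- matrix(rnorm(12), nrow = 4, dimnames = list(NULL, c("a", "b", "c")))
  res <- pca(x)
  expect_equal(sum(res$var_prop), 1, tolerance = 1e-12)
  eig <- eigen(stats::cor(x))
  expect_equal(unname(res$var_prop), eig$values / sum(eig$values),
               tolerance = 1e-10)
  # scores agree with direct projection up to the fixed sign convention
  proj <- scale(x) %*% eig$vectors
  for (k in 1:3) {
    expect_equal(abs(unname(res$scores[, k])), abs(unname(proj[, k])),
                 tolerance = 1e-8)
    expect_gt(res$loadings[which.max(abs(res$loadings[, k])), k], 0)
  }
})

test_that("PCA flags degenerate inputs and perfect correlation", {
  z <- rnorm(10)
  x <- cbind(v1 = z, v2 = 2 * z + 5)
  res <- pca(x)
  expect_equal(res$var_prop[1], 1, tolerance = 1e-12)
  expect_error(pca(cbind(v1 = z, v2 = rep(1, 10))), "zero-variance.*v2")
  x[1, 1] <- NA
  expect_error(pca(x), "NA")
})

test_that("NMDS recovers planar configurations with near-zero stress", {
  set.seed(59)
  pts <- matrix(rnorm(20), ncol = 2)
  d <- dist(pts)
  fit <- nmds(d, dims = 2, restarts = 5, seed = 3)
  expect_lt(fit$stress, 0.01)
  fit2 <- nmds(d, dims = 2, restarts = 5, seed = 3)
  expect_identical(fit$scores, fit2$scores)
})

test_that("Mantel correlation is affine-invariant with valid permutations", {
  set.seed(61)
  d1 <- dist(matrix(rnorm(24), ncol = 2))
  expect_equal(mantel_test(d1, d1, n_perm = 49, seed = 1)$r, 1)
  expect_equal(mantel_test(d1, 2 * d1 + 5, n_perm = 49, seed = 1)$r, 1,
               tolerance = 1e-12)
  d_small <- dist(matrix(rnorm(10), ncol = 2))
  expect_error(mantel_test(d1, d_small), "differ")
})

test_that("PERMANOVA separates distinct clouds and ignores label names", {
  set.seed(67)
  pts <- rbind(matrix(rnorm(20, 0), ncol = 2),
               matrix(rnorm(20, 8), ncol = 2))
  d <- dist(pts)
  g <- rep(c("x", "y"), each = 10)
  res <- permanova(d, g, n_perm = 1999, seed = 5)
  expect_lte(res$p, 0.001)
  res2 <- permanova(d, rep(c("deep", "shallow"), each = 10),
                    n_perm = 199, seed = 5)
  expect_equal(res$f, res2$f)
  expect_error(permanova(d, rep("x", 20)), "two groups")
})

test_that("dispersion test flags heterogeneous groups, not translations", {
  set.seed(71)
  angles <- seq(0, 2 * pi, length.out = 11)[-11]
  radii <- seq(0.5, 1.5, length.out = 10) # varied, identical across groups
  compact <- radii * cbind(cos(angles), sin(angles))
  spread <- 5 * compact
  d <- dist(rbind(compact, spread))
  g <- rep(c("a", "b"), each = 10)
  res <- dispersion_test(d, g)
  expect_lt(res$tukey[1, "p adj"], 0.01)
  expect_true(all(res$dispersions >= 0))
  # identical internal geometry (rigid translation): no dispersion effect
  shifted <- cbind(compact[, 1] + 50, compact[, 2])
  d2 <- dist(rbind(compact, shifted))
  res2 <- dispersion_test(d2, g)
  expect_gt(res2$tukey[1, "p adj"], 0.95)
  expect_error(dispersion_test(d, c("a", rep("b", 19))), "two samples")
})

test_that("envfit reports unit fit for a variable equal to an axis", {
  set.seed(73)
  scores <- matrix(rnorm(30), ncol = 2, dimnames = list(NULL, c("N1", "N2")))
  env <- cbind(ax = scores[, 1], noise = rnorm(15))
  res <- envfit_vectors(scores, env, n_perm = 99, seed = 2)
  expect_equal(res$r2[res$variable == "ax"], 1, tolerance = 1e-10)
  expect_true(all(res$r2 >= 0 & res$r2 <= 1))
  expect_error(envfit_vectors(scores, cbind(konst = rep(2, 15))), "constant")
})

test_that("fuzzy memberships scale the axis and average under flat similarity", {
  d <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3)
  res <- fso(d, c(0, 5, 10), n_perm = 19, seed = 1)
  expect_equal(res$mu, c(0, 0.5, 1))
  # all off-diagonal similarities equal -> nu_i is the mean of the others
  d2 <- matrix(0.4, 4, 4); diag(d2) <- 0
  x <- c(2, 4, 6, 10)
  res2 <- fso(d2, x, n_perm = 19, seed = 1)
  mu <- (x - 2) / 8
  expect_equal(res2$nu,
               sapply(1:4, function(i) mean(mu[-i])), tolerance = 1e-12)
  expect_error(fso(d2, rep(3, 4)), "constant")
})

test_that("fuzzy set ordination detects a gradient and its absence", {
  set.seed(79)
  x <- seq(0, 10, length.out = 15)
  d <- as.matrix(dist(x)) + matrix(runif(225, 0, 0.3), 15, 15)
  d <- (d + t(d)) / 2; diag(d) <- 0
  res <- fso(d, x, n_perm = 199, seed = 4)
  expect_gt(res$r, 0.9)
  expect_lte(res$p, 0.01)
  res2d <- fso_2d(d, x, rev(x), n_perm = 99, seed = 4)
  expect_gt(res2d$r, 0.9)
  expect_equal(res2d$dimensions, 2)
})

test_that("Kulczynski dissimilarity matches its closed form", {
  expect_equal(kulczynski_distance(c(3, 1), c(3, 1)), 0)
  expect_equal(kulczynski_distance(c(2, 0), c(0, 5)), 1)
  expect_equal(kulczynski_distance(c(2, 0), c(1, 1)), 0.5)
  expect_error(kulczynski_distance(c(0, 0), c(1, 1)), "zero-total")
  set.seed(83)
  m <- matrix(rpois(30, 4) + 1, nrow = 3,
              dimnames = list(paste0("s", 1:3), paste0("o", 1:10)))
  dm <- as.matrix(kulczynski_matrix(m))
  expect_equal(dm["s1", "s3"], kulczynski_distance(m["s1", ], m["s3", ]),
               tolerance = 1e-12)
})

test_that("UPGMA reproduces hand agglomeration and a brute-force oracle", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 2
  d["A", "C"] <- d["C", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 8
  res <- upgma(d)
  expect_equal(res$heights, c(2, 7))
  # ultrametric input is reproduced exactly
  du <- stats::cophenetic(res$tree)
  expect_equal(upgma(du)$heights, res$heights)
  set.seed(89)
  for (i in 1:10) {
    dm <- as.matrix(dist(matrix(rnorm(16), ncol = 2)))
    expect_equal(upgma(dm)$heights, brute_upgma_heights(dm),
                 tolerance = 1e-10)
  }
  expect_error(upgma(matrix(0, 1, 1)), "two samples")
})

test_that("one-way ANOVA with Tukey pairs matches a textbook computation", {
  g <- rep(c("a", "b", "c"), each = 4)
  y <- c(1, 2, 3, 4, 2, 3, 4, 5, 10, 11, 12, 13)
  res <- group_anova_tukey(y, g)
  # hand computation of the one-way F statistic
  gm <- mean(y)
  ssb <- sum(4 * (tapply(y, g, mean) - gm)^2)
  ssw <- sum((y - tapply(y, g, mean)[g])^2)
  f_hand <- (ssb / 2) / (ssw / 9)
  expect_equal(res$f, f_hand, tolerance = 1e-10)
  expect_true(res$p > 0 && res$p <= 1)
  flat <- group_anova_tukey(c(1, 2, 1, 2, 1, 2), rep(c("a", "b", "c"), each = 2))
  expect_equal(flat$f, 0, tolerance = 1e-10)
  expect_error(group_anova_tukey(1:4, c("a", "a", "a", "b")), "two values")
})
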