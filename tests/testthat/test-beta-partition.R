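test_that("pairwise Jaccard decomposition matches closed forms", {
  expect_equal(unname(jaccard_decompose(5, 0, 0)), c(0, 0, 0))
  expect_equal(unname(jaccard_decompose(0, 4, 4)), c(1, 1, 0))
  expect_equal(unname(jaccard_decompose(2, 1, 3)), c(4 / 6, 2 / 6, 2 / 6))
  d <- jaccard_decompose(2, 1, 3)
  expect_equal(d[["D"]], d[["Repl"]] + d[["Rich"]])
  expect_error(jaccard_decompose(0, 0, 0), "undefined")
})

test_that("matrix decomposition equals brute-force per-pair recomputation", {
  set.seed(31)
  for (i in 1:20) {
    pa <- matrix(rbinom(40, 1, 0.5), nrow = 5,
                 dimnames = list(paste0("s", 1:5), paste0("o", 1:8)))
    pa[rowSums(pa) == 0, 1] <- 1
    dec <- decompose_matrix(pa)
    ref <- brute_decompose(pa == 1)
    expect_equal(dec$D, ref$D, tolerance = 1e-12)
    expect_equal(dec$Repl, ref$Repl, tolerance = 1e-12)
    expect_equal(dec$Rich, ref$Rich, tolerance = 1e-12)
  }
})

test_that("nested chains show no replacement; duplicates show no distance", {
  pa <- rbind(s1 = c(1, 1, 1, 1, 1),
              s2 = c(1, 1, 1, 0, 0),
              s3 = c(1, 1, 0, 0, 0))
  colnames(pa) <- paste0("o", 1:5)
  dec <- decompose_matrix(pa)
  expect_true(all(dec$Repl == 0))
  pa2 <- rbind(pa, s4 = pa["s1", ])
  dec2 <- decompose_matrix(pa2)
  expect_equal(unname(dec2$D["s1", "s4"]), 0)
  empty <- rbind(pa, s5 = rep(0, 5))
  expect_error(decompose_matrix(empty), "s5")
})

test_that("additivity D = Repl + Rich holds to 1e-12 on random tables", {
  set.seed(37)
  worst <- 0
  for (i in 1:200) {
    pa <- matrix(rbinom(60, 1, runif(1, 0.2, 0.8)), nrow = 6)
    dimnames(pa) <- list(paste0("s", 1:6), paste0("o", 1:10))
    pa[rowSums(pa) == 0, 1] <- 1
    dec <- decompose_matrix(pa)
    worst <- max(worst, max(abs(dec$D - dec$Repl - dec$Rich)))
  }
  expect_lt(worst, 1e-12)
})

test_that("LCBD is uniform for equidistant samples and sums to one", {
  n <- 5
  D <- matrix(0.7, n, n); diag(D) <- 0
  lc <- lcbd_from_distance(D)
  expect_equal(lc$lcbd, rep(1 / n, n), tolerance = 1e-12)
  set.seed(41)
  pa <- matrix(rbinom(80, 1, 0.5), nrow = 8)
  dimnames(pa) <- list(paste0("s", 1:8), paste0("o", 1:10))
  pa[rowSums(pa) == 0, 1] <- 1
  lc2 <- lcbd_from_distance(decompose_matrix(pa)$D, sqrt_transform = TRUE)
  expect_equal(sum(lc2$lcbd), 1, tolerance = 1e-10)
  expect_true(all(lc2$lcbd >= 0))
  expect_error(lcbd_from_distance(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("LCBD equals an explicit Gower-centering computation", {
  D <- matrix(0, 4, 4)
  D[lower.tri(D)] <- c(0.3, 0.8, 0.6, 0.5, 0.9, 0.4)
  D <- D + t(D)
  # independent oracle: center A = -0.5 D^2 by row/column/grand means
  A <- -0.5 * D^2
  rm_ <- rowMeans(A); cm_ <- colMeans(A); gm <- mean(A)
  G <- A - outer(rm_, rep(1, 4)) - outer(rep(1, 4), cm_) + gm
  expect_equal(lcbd_from_distance(D)$lcbd, diag(G) / sum(diag(G)),
               tolerance = 1e-12)
  expect_equal(lcbd_from_distance(D)$bd_total, sum(diag(G)) / 3,
               tolerance = 1e-12)
})

test_that("component contributions flag degenerate matrices and fix seeds", {
  # a balanced two-sample swap has zero richness difference everywhere
  pa <- rbind(s1 = c(1, 1, 0, 0), s2 = c(0, 0, 1, 1), s3 = c(1, 0, 1, 0))
  colnames(pa) <- paste0("o", 1:4)
  lc <- component_local_contributions(pa, n_perm = 19, seed = 1)
  expect_false(lc$repl$degenerate)
  all_equal <- rbind(s1 = c(1, 1), s2 = c(1, 1), s3 = c(1, 1))
  colnames(all_equal) <- c("o1", "o2")
  lc0 <- component_local_contributions(all_equal, n_perm = 19, seed = 1)
  expect_true(lc0$rich$degenerate)
  expect_true(all(is.na(lc0$rich$lcbd)))
  expect_null(lc0$rich$p)
  # identical seeds give identical permutation p-values
  set.seed(43)
  pa2 <- matrix(rbinom(120, 1, 0.5), nrow = 8)
  dimnames(pa2) <- list(paste0("s", 1:8), paste0("o", 1:15))
  pa2[rowSums(pa2) == 0, 1] <- 1
  a <- component_local_contributions(pa2, n_perm = 49, seed = 7)
  b <- component_local_contributions(pa2, n_perm = 49, seed = 7)
  expect_identical(a$repl$p, b$repl$p)
  expect_identical(a$rich$p, b$rich$p)
})

test_that("richness contributions concentrate on richness-extreme layers", {
  # deterministic nested chain: richness drops monotonically with depth
  pa <- t(sapply(10:3, function(k) c(rep(1, k), rep(0, 10 - k))))
  dimnames(pa) <- list(paste0("s", 1:8), paste0("o", 1:10))
  lc <- component_local_contributions(pa, n_perm = 19, seed = 2)
  top <- which.max(lc$rich$lcbd)
  expect_true(top %in% c(1, 8)) # an end of the richness gradient
})

test_that("SCBD matches hand-computed column deviations and sums to one", {
  h <- rbind(c(0.5, 0.5, 0.2), c(0.1, 0.5, 0.6), c(0.3, 0.5, 0.4))
  colnames(h) <- paste0("o", 1:3)
  s <- scbd(h)
  dev <- sweep(h, 2, colMeans(h))
  expect_equal(unname(s), unname(colSums(dev^2) / sum(dev^2)),
               tolerance = 1e-12)
  expect_equal(unname(s["o2"]), 0) # constant OTU contributes nothing
  expect_equal(sum(s), 1, tolerance = 1e-12)
  expect_error(scbd(matrix(0.4, 3, 3)), "variance")
})

test_that("structuring OTUs are selected and ordered by contribution", {
  s <- setNames(rep(0.002, 500), paste0("o", 1:500))
  expect_length(structuring_otus(s), 0)
  s2 <- c(o_dom = 0.34, setNames(rep(0.66 / 300, 300), paste0("o", 1:300)))
  top <- structuring_otus(s2)
  expect_equal(names(top)[1], "o_dom")
  expect_equal(structuring_otus(s2, threshold = 0),
               sort(s2[s2 > 0], decreasing = TRUE))
})

test_that("relative nestedness spans its extremes and matches brute force", {
  nested <- t(sapply(8:2, function(k) c(rep(1, k), rep(0, 8 - k))))
  dimnames(nested) <- list(paste0("s", 1:7), paste0("o", 1:8))
  dec_n <- decompose_matrix(nested)
  expect_equal(relative_nestedness(dec_n, "podani")$value, 1)
  expect_equal(relative_nestedness(dec_n, "baselga_like")$value, 1)
  swap <- rbind(s1 = c(1, 1, 0, 0), s2 = c(0, 0, 1, 1))
  colnames(swap) <- paste0("o", 1:4)
  dec_s <- decompose_matrix(swap)
  expect_equal(relative_nestedness(dec_s, "podani")$value, 0)
  expect_equal(relative_nestedness(dec_s, "baselga_like")$value, 0)
  expect_error(relative_nestedness(dec_n, "other"))
  set.seed(47)
  for (i in 1:10) {
    pa <- matrix(rbinom(48, 1, 0.5), nrow = 6)
    dimnames(pa) <- list(paste0("s", 1:6), paste0("o", 1:8))
    pa[rowSums(pa) == 0, 1] <- 1
    dec <- decompose_matrix(pa)
    ref <- brute_decompose(pa == 1)
    low <- lower.tri(ref$D)
    ok <- ref$D[low] > 0
    expect_equal(relative_nestedness(dec, "podani")$value,
                 mean((ref$Rich[low] / ref$D[low])[ok]))
    expect_equal(relative_nestedness(dec, "baselga_like")$value,
                 sum(ref$Rich[low]) / sum(ref$D[low]))
  }
})

test_that("surface profile handles identical and missing layers", {
  pa <- rbind(`0-1` = c(1, 1, 1, 0), `1-2` = c(1, 1, 1, 0),
              `2-3` = c(0, 1, 1, 1))
  colnames(pa) <- paste0("o", 1:4)
  t <- otu_table(pa * 5L)
  prof <- surface_distance_profile(t, "0-1")
  expect_equal(prof$Distance[prof$layer == "1-2"], 0)
  expect_equal(prof$Repl[prof$layer == "2-3"], 2 / 4)
  expect_error(surface_distance_profile(t, "9-10"), "not found")
})

test_that("a noise-free nested occupancy profile shows zero replacement", {
  # expected occupancy under pure burial: presence decays monotonically,
  # so every deeper layer's taxon set is nested in the shallower ones
  cfg <- small_config(seed = 51, theta = 0)
  com <- generate_community(cfg)
  taxa <- com$truth$taxa
  depths <- com$truth$depths
  resp <- sapply(seq_len(nrow(taxa)), function(k)
    taxa$surface[k] * exp(-taxa$lambda[k] * depths))
  pa <- (resp >= 0.05) * 1
  rownames(pa) <- com$truth$layer_labels
  colnames(pa) <- taxa$taxon_id
  pa <- pa[, colSums(pa) > 0, drop = FALSE]
  prof <- surface_distance_profile(otu_table(pa), "0-1")
  expect_true(all(prof$Repl == 0))
})
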