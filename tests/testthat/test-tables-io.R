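test_that("OTU table TSV round-trips and parses taxonomy", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\ts1\ts2\ttaxonomy",
               "o1\t5\t0\tArchaea;Euryarchaeota;x",
               "o2\t1\t2\tBacteria;Chloroflexi;y",
               "o3\t0\t7\tEukaryota;Ciliophora;z"), path)
  t <- read_otu_table(path)
  expect_equal(unname(t$counts),
               matrix(c(5L, 0L, 1L, 2L, 0L, 7L), nrow = 2,
                      dimnames = NULL))
  expect_equal(sample_ids(t), c("s1", "s2"))
  expect_equal(unname(otu_domains(t)),
               c("Archaea", "Bacteria", "Eukaryota"))
  # canonical writer reproduces the file byte-identically
  out <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(t, out)
  expect_identical(readLines(out), readLines(path))
})

test_that("malformed counts and duplicate ids are rejected with context", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\ts1", "o1\t-3"), path)
  expect_error(read_otu_table(path), "o1.*s1|-3")
  writeLines(c("otu_id\ts1", "o1\t2.5"), path)
  expect_error(read_otu_table(path), "malformed")
  writeLines(c("otu_id\ts1", "o1\t1", "o1\t2"), path)
  expect_error(read_otu_table(path), "duplicate")
  expect_error(otu_table(matrix(-1, 1, 1, dimnames = list("s", "o"))),
               "non-negative")
})

test_that("single-sample OTUs are stripped regardless of read count", {
  t <- toy_otu(matrix(c(10, 3, 0,    # o1 in s1, s2
                        500, 0, 0,   # o2 only in s1, many reads
                        1, 2, 4),    # o3 everywhere
                      nrow = 3,
                      dimnames = list(paste0("s", 1:3), paste0("o", 1:3))))
  s <- strip_single_sample_otus(t)
  expect_equal(otu_ids(s), c("o1", "o3"))
  expect_equal(sample_ids(s), sample_ids(t))
  # idempotent, and identity when every OTU is already shared
  expect_identical(strip_single_sample_otus(s), s)
})

test_that("rarefaction subsamples without replacement, reproducibly", {
  t <- toy_otu(matrix(c(600, 300, 100, 0,
                        200, 500, 200, 100), nrow = 2, byrow = TRUE))
  r <- rarefy(t, 642, seed = 42)
  expect_equal(unname(rowSums(r$counts)), c(642, 642))
  expect_true(all(r$counts <= t$counts))
  expect_identical(rarefy(t, 642, seed = 42)$counts, r$counts)
  expect_false(identical(rarefy(t, 642, seed = 43)$counts, r$counts))
  # depth equal to the sample total leaves the row unchanged
  expect_identical(rarefy(t, 1000, seed = 1)$counts[1, ], t$counts[1, ])
  expect_error(rarefy(t, 1001), "1000.*fewer than")
})

test_that("rarefaction preserves expected proportions", {
  x <- c(a = 500, b = 300, c = 150, d = 50)
  t <- toy_otu(matrix(x, nrow = 1, dimnames = list("s1", names(x))))
  m <- 100
  reps <- 1000
  set.seed(7)
  props <- t(vapply(seq_len(reps),
                    function(i) rarefy(t, m)$counts[1, ] / m,
                    numeric(4)))
  p <- x / sum(x)
  # hypergeometric SE of a per-draw proportion, averaged over reps
  se <- sqrt(p * (1 - p) * (sum(x) - m) / (m * (sum(x) - 1)) / reps)
  expect_true(all(abs(colMeans(props) - p) < 3 * se))
})

test_that("Hellinger transform yields unit row sums of squares", {
  t <- toy_otu(matrix(c(1, 0, 3), nrow = 1))
  h <- hellinger(t)
  expect_equal(unname(h[1, ]), c(0.5, 0, sqrt(3) / 2), tolerance = 1e-10)
  expect_equal(unname(hellinger(toy_otu(matrix(9, 1, 1)))[1, 1]), 1)
  set.seed(1)
  big <- toy_otu(matrix(rpois(60, 8), nrow = 6))
  expect_equal(unname(rowSums(hellinger(big)^2)), rep(1, 6),
               tolerance = 1e-12)
  bad <- matrix(c(1, 0), nrow = 2, dimnames = list(c("s1", "s2"), "o1"))
  expect_error(hellinger(toy_otu(bad)), "s2")
})

test_that("sum table caps replicates, sums per depth, then rarefies", {
  set.seed(3)
  counts <- rbind(r1 = c(rmultinom(1, 3000, rep(1, 30))),
                  r2 = c(rmultinom(1, 1500, rep(1, 30))))
  colnames(counts) <- paste0("o", 1:30)
  t <- otu_table(counts)
  meta <- sample_meta(c("r1", "r2"), c("A", "B"), c(0, 0), c(1, 1))
  # cap 2000: contributions 2000 + 1500 = 3500 before the final rarefaction
  s <- build_sum_table(t, meta, per_replicate_cap = 2000,
                       final_depth = 10000, seed = 1)
  expect_equal(unname(rowSums(s$counts)), 3500)
  # a replicate below the cap passes through unchanged
  one <- otu_table(counts["r2", , drop = FALSE])
  meta1 <- sample_meta("r2", "A", 0, 1)
  s1 <- build_sum_table(one, meta1, per_replicate_cap = 2000,
                        final_depth = 10000, seed = 1)
  expect_identical(s1$counts["0-1", ], counts["r2", ])
})

test_that("sum table has one row per layer at the common final depth", {
  cfg <- small_config(seed = 21)
  com <- generate_community(cfg)
  s <- build_sum_table(com$otu, com$meta, per_replicate_cap = 1000,
                       final_depth = 1800, seed = 2)
  n_layers <- length(unique(com$meta$layer_top_cm))
  expect_equal(nrow(s$counts), n_layers)
  expect_equal(unname(rowSums(s$counts)), rep(1800, n_layers))
  # per-depth cap reading: each layer capped before the final rarefaction
  s2 <- build_sum_table(com$otu, com$meta, per_replicate_cap = 1000,
                        final_depth = 1800, seed = 2, cap_scope = "depth")
  expect_equal(unname(rowSums(s2$counts)), rep(1000, n_layers))
})

test_that("arc-sine square-root transform matches closed forms", {
  expect_equal(arcsine_sqrt(c(0, 1, 0.25)), c(0, pi / 2, pi / 6))
  expect_error(arcsine_sqrt(1.01), "\\[0, 1\\]")
  expect_error(arcsine_sqrt(-0.1), "\\[0, 1\\]")
})

test_that("domain proportions use classified reads only", {
  tax <- c(o1 = "Archaea;x", o2 = "Bacteria;y", o3 = "Eukaryota;z",
           o4 = "unclassified")
  t <- toy_otu(matrix(c(10, 70, 20, 100,
                        50, 0, 0, 3,
                        0, 0, 0, 9), nrow = 3, byrow = TRUE,
                      dimnames = list(paste0("s", 1:3), names(tax))),
               taxonomy = tax)
  p <- domain_proportions(t)
  expect_equal(unname(p["s1", ]), c(0.10, 0.70, 0.20))
  expect_equal(unname(p["s2", ]), c(1, 0, 0))
  expect_true(all(is.na(p["s3", ]))) # only unclassified reads
  expect_equal(unname(rowSums(p[1:2, ])), c(1, 1))
})

test_that("outlier cells are replaced by the cross-core layer mean", {
  meta <- sample_meta(paste0("c", 1:4), paste0("C", 1:4), rep(4, 4), rep(5, 4))
  values <- matrix(c(4, 6, 8, 99), ncol = 1,
                   dimnames = list(meta$sample_id, "FI"))
  env <- env_matrix(values, meta, tags = list(present = "FI", past = character()))
  fixed <- outlier_replace(env, data.frame(parameter = "FI", core = "C4",
                                           layer_top_cm = 4))
  expect_equal(unname(fixed$env$values["c4", "FI"]), 6)
  expect_equal(fixed$log$old, 99)
  # no rules: unchanged; bad rule: error
  expect_identical(outlier_replace(env, NULL)$env$values, env$values)
  expect_error(outlier_replace(env, data.frame(parameter = "FI", core = "C9",
                                               layer_top_cm = 4)), "unique")
  # a missing replicate row is filled from the residual replicates
  values[2, 1] <- NA
  env2 <- env_matrix(values, meta, tags = list(present = "FI", past = character()))
  fixed2 <- outlier_replace(env2, data.frame(parameter = "FI", core = "C2",
                                             layer_top_cm = 4))
  expect_equal(unname(fixed2$env$values["c2", "FI"]), mean(c(4, 8, 99)))
})

test_that("environmental table round-trips with its tag sidecar", {
  meta <- sample_meta(c("a1", "a2"), c("A", "A"), c(0, 1), c(1, 2))
  values <- matrix(c(1.5, 2.5, 3.5, 4.5), nrow = 2,
                   dimnames = list(c("a1", "a2"), c("CH4", "Pb")))
  env <- env_matrix(values, meta)
  expect_equal(unname(env$category), c("present", "past"))
  path <- withr::local_tempfile(fileext = ".tsv")
  tags <- withr::local_tempfile(fileext = ".yml")
  write_env_table(env, path, tags_path = tags)
  back <- read_env_table(path, tags_path = tags)
  expect_equal(back$values, env$values)
  expect_equal(back$category, env$category)
  expect_equal(back$meta$midpoint_cm, c(0.5, 1.5))
})
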