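#' Per-layer turnover and richness summary table
#'
#' The depth-profile summary used throughout the package: for each layer of
#' a per-depth sum table it reports the surface-to-layer Jaccard distance
#' with its replacement and richness components, the local contributions of
#' the two components (with per-OTU permutation p-values), the observed OTU
#' count and the estimated sample coverage.
#'
#' @param sum_table an `otu_table` with one row per layer
#'   ([build_sum_table()]).
#' @param surface_layer row label of the surface layer.
#' @param n_perm permutations for the LC significance tests (default 999).
#' @param seed integer seed.
#' @return data frame with columns `layer`, `Distance`, `Repl`, `Richness`,
#'   `LCrepl`, `LCrepl_p`, `LCrich`, `LCrich_p`, `OTUs`, `Coverage`; the
#'   surface row carries `NA` distances.
#' @export
table2_profile <- function(sum_table, surface_layer, n_perm = 999,
                           seed = NULL) {
  prof <- surface_distance_profile(sum_table, surface_layer)
  lc <- component_local_contributions(sum_table, n_perm = n_perm, seed = seed)
  layers <- rownames(sum_table$counts)
  idx <- match(layers, prof$layer)
  data.frame(
    layer = layers,
    Distance = prof$Distance[idx], Repl = prof$Repl[idx],
    Richness = prof$Richness[idx],
    LCrepl = lc$repl$lcbd, LCrepl_p = lc$repl$p,
    LCrich = lc$rich$lcbd, LCrich_p = lc$rich$p,
    OTUs = unname(rowSums(sum_table$counts > 0)),
    Coverage = apply(sum_table$counts, 1, sample_coverage),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Pipeline configuration
#'
#' Bundles every stage setting of [run_pipeline()] with the defaults used
#' throughout the package. Inputs may be in-memory objects or file paths.
#'
#' @param otu an `otu_table` or TSV path.
#' @param env an `env_matrix` or TSV path (optional).
#' @param meta a `sample_meta` data frame (required when `otu` is given
#'   without embedded metadata).
#' @param env_tags YAML tag path when `env` is a path.
#' @param strip drop single-sample OTUs first (default `TRUE`).
#' @param rarefy_depth `"min"` or an integer read depth.
#' @param per_replicate_cap,final_depth sum-table settings.
#' @param surface_layer surface row label of the sum table.
#' @param coverage_target coverage for Hill normalization (default 0.9).
#' @param k horizon count for the UPGMA cut (default 3).
#' @param n_perm permutations for Mantel/envfit/LCBD/FSO (default 999).
#' @param n_perm_permanova permutations for PERMANOVA (default 1999).
#' @param outlier_rules optional data frame for [outlier_replace()].
#' @param age an optional [age_model()].
#' @param seed integer seed recorded in the report.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(otu, meta, env = NULL, env_tags = NULL,
                            strip = TRUE, rarefy_depth = "min",
                            per_replicate_cap = 2000, final_depth = 5987,
                            surface_layer = NULL, coverage_target = 0.9,
                            k = 3, n_perm = 999, n_perm_permanova = 1999,
                            outlier_rules = NULL, age = NULL, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full depth-profile analysis
#'
#' Stage order: strip singletons, rarefy, per-sample diversity, sum table,
#' surface turnover partition + component LCBD, UPGMA horizon clustering,
#' environmental PCA, ordination tests (NMDS, Mantel, PERMANOVA,
#' dispersion, envfit, FSO), decay and richness-trend models. Deterministic
#' for a fixed `seed`; every permutation statistic records its permutation
#' count.
#'
#' @param cfg a [pipeline_config()].
#' @return list of class `sediment_report` with one element per stage.
#' @export
run_pipeline <- function(cfg) {
  stop_if(!inherits(cfg, "pipeline_config"), "need a pipeline_config")
  otu <- if (is.character(cfg$otu)) read_otu_table(cfg$otu) else cfg$otu
  meta <- cfg$meta
  env <- if (is.character(cfg$env)) {
    read_env_table(cfg$env, tags_path = cfg$env_tags)
  } else cfg$env
  report <- list(config = list(seed = cfg$seed, n_perm = cfg$n_perm,
                               n_perm_permanova = cfg$n_perm_permanova,
                               coverage_target = cfg$coverage_target,
                               k = cfg$k))

  # --- preprocessing ---------------------------------------------------
  if (cfg$strip) otu <- strip_single_sample_otus(otu)
  depth <- if (identical(cfg$rarefy_depth, "min")) {
    min(rowSums(otu$counts))
  } else cfg$rarefy_depth
  rare <- rarefy(otu, depth, seed = cfg$seed)
  report$preprocess <- list(n_samples = nrow(otu$counts),
                            n_otus = ncol(otu$counts),
                            rarefy_depth = depth)
  hel <- hellinger(rare)
  d_comm <- stats::dist(hel)

  # --- per-sample diversity -------------------------------------------
  report$diversity <- hill_profile(rare, target_coverage = cfg$coverage_target)

  # --- sum table, partition, clustering -------------------------------
  sum_tab <- build_sum_table(otu, meta, cfg$per_replicate_cap,
                             cfg$final_depth, seed = cfg$seed + 1L)
  surface <- if (is.null(cfg$surface_layer)) {
    rownames(sum_tab$counts)[1]
  } else cfg$surface_layer
  report$table2 <- table2_profile(sum_tab, surface, n_perm = cfg$n_perm,
                                  seed = cfg$seed + 2L)
  dec <- decompose_matrix(sum_tab)
  report$nestedness <- list(
    podani = relative_nestedness(dec, "podani"),
    baselga_like = relative_nestedness(dec, "baselga_like"))
  report$scbd <- scbd(hellinger(sum_tab))
  report$structuring_otus <- structuring_otus(report$scbd)
  cl <- upgma(kulczynski_matrix(sum_tab), k = cfg$k)
  report$clusters <- cl$groups
  layer_of <- layer_label(meta)[match(sample_ids(rare), meta$sample_id)]
  groups <- factor(cl$groups[layer_of])

  # --- ordination statistics ------------------------------------------
  ord <- nmds(d_comm, seed = cfg$seed + 3L)
  depth_d <- stats::dist(meta$midpoint_cm[match(sample_ids(rare),
                                                meta$sample_id)])
  report$ordination <- list(
    stress = ord$stress,
    mantel_depth = mantel_test(d_comm, depth_d, cfg$n_perm, cfg$seed + 4L),
    permanova = permanova(d_comm, groups, cfg$n_perm_permanova, cfg$seed + 5L),
    dispersion = dispersion_test(d_comm, groups))
  report$horizon_diversity <- lapply(c(q0_norm = "q0_norm", q1_norm = "q1_norm",
                                       q2_norm = "q2_norm"), function(col) {
    group_anova_tukey(report$diversity[[col]], groups)
  })

  if (!is.null(env)) {
    if (!is.null(cfg$outlier_rules)) {
      env <- outlier_replace(env, cfg$outlier_rules)$env
    }
    env_aligned <- env$values[sample_ids(rare), , drop = FALSE]
    pres <- env_aligned[, env$category == "present", drop = FALSE]
    past <- env_aligned[, env$category == "past", drop = FALSE]
    pca_pres <- pca(pres)
    pca_past <- pca(past)
    report$env <- list(
      pca_present_var = pca_pres$var_prop[1:2],
      pca_past_var = pca_past$var_prop[1:2],
      mantel_present = mantel_test(d_comm, stats::dist(scale(pres)),
                                   cfg$n_perm, cfg$seed + 6L),
      mantel_past = mantel_test(d_comm, stats::dist(scale(past)),
                                cfg$n_perm, cfg$seed + 7L),
      envfit = envfit_vectors(ord$scores,
                              cbind(present_PC1 = pca_pres$scores[, 1],
                                    past_PC1 = pca_past$scores[, 1]),
                              cfg$n_perm, cfg$seed + 8L))
    # FSO of the partitioned community components against the PCA axes:
    # replacement ~ present PC1 (1-D), richness ~ past PC1+PC2 (2-D)
    dec_all <- decompose_matrix(rare)
    report$fso <- list(
      repl_present = fso(dec_all$Repl, pca_pres$scores[, 1], cfg$n_perm,
                         cfg$seed + 9L),
      rich_past = fso_2d(dec_all$Rich, pca_past$scores[, 1],
                         pca_past$scores[, 2], cfg$n_perm, cfg$seed + 10L))
    # --- decay + regression models ------------------------------------
    if ("DNA" %in% colnames(env_aligned)) {
      mids <- meta$midpoint_cm[match(sample_ids(rare), meta$sample_id)]
      fit <- fit_exponential_decay(mids, env_aligned[, "DNA"])
      report$decay <- list(a = fit$a, b = fit$b, r2 = fit$r2,
                           half_depth_cm = fit$half_depth_cm,
                           half_life_years = if (!is.null(cfg$age)) {
                             half_life_years(fit, cfg$age)
                           })
      props <- domain_proportions(rare)
      ok <- stats::complete.cases(props)
      report$dna_regression <- variance_partition_regression(
        env_aligned[ok, "DNA"],
        data.frame(Eukaryota = arcsine_sqrt(props[ok, "Eukaryota"]),
                   Bacteria = arcsine_sqrt(props[ok, "Bacteria"])))
    }
  }

  prof <- report$table2[!is.na(report$table2$Richness), ]
  mids <- layer_midpoints(prof$layer)
  report$richness_trend <- richness_trend(mids, prof$Richness)
  class(report) <- "sediment_report"
  report
}

#' Midpoints of "top-bottom" layer labels
#' @param labels character vector like `"0-1"`, `"26-30"`.
#' @return numeric midpoints in cm.
#' @export
layer_midpoints <- function(labels) {
  parts <- strsplit(labels, "-", fixed = TRUE)
  vapply(parts, function(p) mean(as.numeric(p)), numeric(1))
}

#' @export
print.sediment_report <- function(x, ...) {
  cat("sediment_report with sections:\n ",
      paste(setdiff(names(x), "config"), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a pipeline report
#'
#' `"json"` writes one JSON file; `"tsv-bundle"` writes the tabular
#' sections (per-layer turnover summary, per-sample diversity, cluster
#' assignments, SCBD) as TSVs plus a JSON of the scalar statistics.
#'
#' @param report a `sediment_report`.
#' @param outdir output directory.
#' @param format `"tsv-bundle"` (default) or `"json"`.
#' @return character vector of written paths, invisibly.
#' @export
render_report <- function(report, outdir, format = c("tsv-bundle", "json")) {
  format <- match.arg(format)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  slim <- report
  slim$diversity <- slim$table2 <- slim$scbd <- slim$clusters <- NULL
  slim <- rapply(slim, unclass, how = "replace")
  if (format == "json") {
    path <- file.path(outdir, "report.json")
    out <- rapply(report, unclass, how = "replace")
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE, na = "null")
    return(invisible(path))
  }
  paths <- c(file.path(outdir, "table2.tsv"),
             file.path(outdir, "diversity.tsv"),
             file.path(outdir, "clusters.tsv"),
             file.path(outdir, "scbd.tsv"),
             file.path(outdir, "statistics.json"))
  utils::write.table(report$table2, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$diversity, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(layer = names(report$clusters),
                                cluster = unname(report$clusters)),
                     paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(otu_id = names(report$scbd),
                                scbd = unname(report$scbd)),
                     paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(slim, paths[5], auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  invisible(paths)
}
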