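#!/usr/bin/env Rscript
# Stage 5 — multivariate structure and environmental coupling.
#
# UPGMA horizon clustering (Kulczynski distances on the sum table), NMDS of
# the rarefied community (Hellinger/Euclidean), Mantel tests against depth
# and the present/past environmental subsets, PERMANOVA and dispersion of
# the three horizons, envfit of the environmental principal components,
# and fuzzy set ordination of the replacement/richness community
# components against the present/past PCA axes.

source("analysis/_common.R")

fx <- load_fixtures()
rare <- read_otu_table("scratch/rarefied_table.tsv")
sum_tab <- read_otu_table("scratch/sum_table.tsv")
stats_out <- list()

cl <- upgma(kulczynski_matrix(sum_tab), k = 3)
cat("UPGMA horizons (k = 3):",
    paste(rle(unname(cl$groups))$lengths, collapse = " / "), "layers\n")

hel <- hellinger(rare)
d_comm <- dist(hel)
ord <- nmds(d_comm, seed = STUDY_SEED + 3L)
cat(sprintf("NMDS stress: %.3f\n", ord$stress))

meta_ord <- fx$meta[match(sample_ids(rare), fx$meta$sample_id), ]
stats_out$mantel_depth <- mantel_test(d_comm, dist(meta_ord$midpoint_cm),
                                      999, STUDY_SEED + 4L)
cat(sprintf("Mantel community vs depth: r = %.3f, p = %.3f\n",
            stats_out$mantel_depth$r, stats_out$mantel_depth$p))

groups <- factor(cl$groups[layer_label(meta_ord)])
stats_out$permanova <- permanova(d_comm, groups, 1999, STUDY_SEED + 5L)
disp <- dispersion_test(d_comm, groups)
stats_out$dispersion <- disp[c("group_means", "anova_f", "anova_p")]
cat(sprintf("PERMANOVA across horizons: F = %.1f, p = %.4f\n",
            stats_out$permanova$f, stats_out$permanova$p))
cat(sprintf("dispersion by horizon: %s (deepest most homogeneous)\n",
            paste(round(disp$group_means, 3), collapse = ", ")))

env_vals <- fx$env$values[sample_ids(rare), ]
pres <- env_vals[, fx$env$category == "present"]
past <- env_vals[, fx$env$category == "past"]
pca_pres <- pca(pres)
pca_past <- pca(past)
cat(sprintf("PCA axis-1 variance: present %.0f%%, past %.0f%%\n",
            100 * pca_pres$var_prop[1], 100 * pca_past$var_prop[1]))
stats_out$mantel_present <- mantel_test(d_comm, dist(scale(pres)), 999,
                                        STUDY_SEED + 6L)
stats_out$mantel_past <- mantel_test(d_comm, dist(scale(past)), 999,
                                     STUDY_SEED + 7L)
stats_out$envfit <- envfit_vectors(ord$scores,
                                   cbind(present_PC1 = pca_pres$scores[, 1],
                                         past_PC1 = pca_past$scores[, 1]),
                                   999, STUDY_SEED + 8L)

dec <- decompose_matrix(rare)
stats_out$fso_repl_present <- fso(dec$Repl, pca_pres$scores[, 1], 999,
                                  STUDY_SEED + 9L)[c("r", "p")]
stats_out$fso_rich_past <- fso_2d(dec$Rich, pca_past$scores[, 1],
                                  pca_past$scores[, 2], 999,
                                  STUDY_SEED + 10L)[c("r", "p")]
cat(sprintf("FSO replacement ~ present PC1: r = %.2f (p = %.3f)\n",
            stats_out$fso_repl_present$r, stats_out$fso_repl_present$p))
cat(sprintf("FSO richness ~ past PC1+PC2 (2-D): r = %.2f (p = %.3f)\n",
            stats_out$fso_rich_past$r, stats_out$fso_rich_past$p))

write_tsv(data.frame(layer = names(cl$groups), horizon = unname(cl$groups)),
          "05_horizon_clusters.tsv")
write_tsv(data.frame(sample_id = rownames(ord$scores), ord$scores,
                     horizon = as.character(groups)),
          "05_nmds_scores.tsv")
write_json_result(stats_out, "05_ordination_stats.json")
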