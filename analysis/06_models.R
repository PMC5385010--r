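#!/usr/bin/env Rscript
# Stage 6 — parametric models.
#
# Exponential DNA decay with half-depth and half-life (2 mm/a sedimentation
# rate), the variance-partitioned regression of DNA on arc-sine-transformed
# Eukaryota and Bacteria read proportions, and the linear depth trend of
# the richness component with its extrapolated full-dominance depth.

source("analysis/_common.R")

fx <- load_fixtures()
rare <- read_otu_table("scratch/rarefied_table.tsv")
out <- list()

dna <- fx$env$values[, "DNA"]
mids <- fx$meta$midpoint_cm[match(rownames(fx$env$values), fx$meta$sample_id)]
fit <- fit_exponential_decay(mids, dna)
age <- age_model(rate_cm_per_year = 0.2) # ca. 2 mm per year
out$decay <- list(a = fit$a, b = fit$b, r2 = fit$r2,
                  half_depth_cm = fit$half_depth_cm,
                  half_life_years = half_life_years(fit, age))
cat(sprintf("DNA(z) = %.1f exp(-%.3f z), r2 = %.2f; half-depth %.1f cm (%.0f a at 2 mm/a)\n",
            fit$a, fit$b, fit$r2, fit$half_depth_cm,
            out$decay$half_life_years))

props <- domain_proportions(rare)
ok <- complete.cases(props)
dna_rare <- dna[match(sample_ids(rare), rownames(fx$env$values))]
reg <- variance_partition_regression(
  dna_rare[ok],
  data.frame(Eukaryota = arcsine_sqrt(props[ok, "Eukaryota"]),
             Bacteria = arcsine_sqrt(props[ok, "Bacteria"])))
out$dna_regression <- list(shares = as.list(reg$shares), r2 = reg$r2,
                           shapiro_p = reg$shapiro_p,
                           max_cooks = reg$max_cooks)
cat(sprintf("DNA ~ domains: Eukaryota %.1f%%, Bacteria %.1f%% of variance (R2 = %.2f)\n",
            100 * reg$shares[1], 100 * reg$shares[2], reg$r2))

t2 <- read.delim(file.path(RESULTS_DIR, "04_turnover_partition.tsv"))
usable <- !is.na(t2$Richness)
trend <- richness_trend(layer_midpoints(t2$layer[usable]),
                        t2$Richness[usable], exclude = 1)
out$richness_trend <- trend[c("slope", "intercept", "r2", "f", "df", "p",
                              "extrapolated_depth_cm")]
cat(sprintf("richness component ~ depth: R2 = %.2f (F = %.0f, df = %d); 100%% at %.0f cm\n",
            trend$r2, trend$f, trend$df, trend$extrapolated_depth_cm))

write_json_result(out, "06_models.json")
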