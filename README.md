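# sedipart

Vertical partitioning of sediment microbiome β-diversity.

Depth-sliced sediment cores pose a specific ecological question: does the
microbial community change down-core because surface colonizers are buried
and die off (*nested burial*, turnover by richness loss), or because depth
specialists replace one another along redox and substrate gradients
(*niche replacement*, turnover by substitution)? `sedipart` is an R
package for metabarcoding surveys of replicated, depth-stratified cores —
lake or marine sediments, 454/Illumina OTU tables with domain-level
taxonomy — that answers this by partitioning presence/absence β-diversity
and tying the components to environmental history.

## What it computes

For each sample pair with `a` shared OTUs and `b`, `c` unique OTUs, the
Jaccard dissimilarity is decomposed (Podani family) as

    D = (b + c)/(a + b + c) = Repl + Rich
    Repl = 2·min(b, c)/(a + b + c)      # taxonomic replacement
    Rich = |b − c|/(a + b + c)          # richness difference

Around this core the package provides:

* matrix plumbing for OTU/taxonomy/environmental TSVs, singleton-sample
  stripping, seeded rarefaction, Hellinger transform, and the per-depth
  "sum table" (replicates capped at 2000 reads, summed per layer, layers
  rarefied to a common depth);
* local and species contributions to β-diversity (LCBD/SCBD) with a
  per-OTU permutation null, including component-wise local contributions
  (LCrepl/LCrich) and relative nestedness;
* Hill diversities (q = 0, 1, 2) normalized to equal sample coverage
  (Chao–Jost estimator, exact hypergeometric interpolation), bias-corrected
  Chao1, evenness;
* the multivariate toolkit wired for this design: UPGMA horizon clustering
  on Kulczynski distances, NMDS, Mantel, PERMANOVA, group-dispersion tests
  with Tukey HSD, envfit, and fuzzy set ordination of the replacement and
  richness components against "present" (activity) and "past"
  (conservative) environmental principal components;
* exponential DNA-decay fits with half-depth/half-life, the
  variance-partitioned regression of DNA on domain proportions, and the
  richness-component depth trend with extrapolation;
* a synthetic depth-profile generator implementing both structural models
  and their θ-mixture with full ground truth, so the entire pipeline is
  verifiable without any external data.

## Worked example

Simulate a four-core, 15-layer profile under the default study conditions
and partition its vertical turnover:

```r
library(sedipart)

cfg <- synthetic_config(seed = 42)        # theta = 0.75, 2000 taxa
com <- generate_community(cfg)
env <- generate_environment(cfg, com)

otu <- strip_single_sample_otus(com$otu)
sum_tab <- build_sum_table(otu, com$meta, per_replicate_cap = 2000,
                           final_depth = 5987, seed = 43)
t2 <- table2_profile(sum_tab, "0-1", n_perm = 199, seed = 44)
round(t2[c(2, 11, 15), c(2, 3, 4, 5, 7)], 3)
#>    Distance  Repl Richness LCrepl LCrich
#> 2     0.554 0.552    0.002  0.074  0.036
#> 11    0.686 0.583    0.104  0.066  0.065
#> 15    0.753 0.539    0.215  0.057  0.201

fit_exponential_decay(com$meta$midpoint_cm, env$dna)
#> decay_fit: y = 13.83 * exp(-0.1276 x), r2 = 0.993, half-depth 5.43 cm
```

Reading the output: the surface-to-layer Jaccard distance grows with
depth; just below the surface nearly all of it is replacement
(`Repl = 0.552` of `D = 0.554`), while at 26–30 cm the richness-difference
component has risen to 0.215 and carries a concentrated local contribution
(`LCrich = 0.201`) — the nested-burial signature of the deep, depauperate
horizon. The DNA profile recovers the generating decay curve
(13.9·e^(−0.128 z)), i.e. half the DNA is gone within ~5.4 cm of burial.

The `analysis/` directory holds the same workflow as numbered narrative
drivers (`01_simulate.R` … `06_models.R`), each writing its findings under
`results/analysis/`; bulky intermediates go to `scratch/`.

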