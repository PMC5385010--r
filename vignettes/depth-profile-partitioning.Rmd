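---
title: "Partitioning vertical turnover in sediment microbiome profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning vertical turnover in sediment microbiome profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedipart)
```

## The scientific question

Lake sediments accumulate organic matter from the water column while
hosting an active, stratified microbial community. Two simplified models
can explain how community composition changes down a sediment core:

1. **Nested burial** — the community consists of settling colonizers that
   are buried and progressively die off, so each deeper layer holds a
   subset of the taxa above it and turnover is driven by *richness loss*;
2. **Niche replacement** — taxa are depth specialists tracking redox and
   substrate gradients, so turnover is driven by *taxonomic replacement*.

`sedipart` implements the statistics that discriminate these models on
OTU tables from replicated, depth-sliced cores, and a generator that
simulates both models (and mixtures) with known ground truth so every
stage of the analysis can be verified end to end.

## The core statistic: replacement/richness partitioning

For a pair of samples with `a` shared OTUs and `b`, `c` OTUs unique to
either sample, the Jaccard dissimilarity is split (Podani family) as

\[
D = \frac{b+c}{a+b+c},\qquad
\mathrm{Repl} = \frac{2\min(b,c)}{a+b+c},\qquad
\mathrm{Rich} = \frac{|b-c|}{a+b+c},
\]

with the identity \(D = \mathrm{Repl} + \mathrm{Rich}\) holding exactly
(`decompose_matrix()` enforces it to 1e-12). A nested profile has
`min(b, c) = 0` for every pair, so replacement vanishes; a balanced
species swap has `b = c`, so the richness term vanishes. The
surface-to-layer profile of these components (`surface_distance_profile()`,
`table2_profile()`) is the study's central diagnostic.

Per-sample and per-OTU shares of the total community variance follow the
usual beta-diversity decomposition: Gower-center \(-\tfrac12 D^2\) and
read local contributions (LCBD) off the diagonal sum, and species
contributions (SCBD) from column sums of squares of the
Hellinger-transformed matrix. The component matrices `Repl` and `Rich`
are square-rooted before centering by default; both are non-Euclidean,
and the square root mitigates negative eigenvalues in the embedding (the
flag `sqrt_transform` exposes the choice).

**Permutation null for LCBD.** Significance of a local contribution is
assessed by permuting each OTU's occurrences independently across samples
(an unrestricted null), recomputing the dissimilarity and contributions
each time, with `p = (exceed + 1)/(n_perm + 1)`. This requires the
community table, not only the distance matrix, so `lcbd_from_distance()`
takes an optional `(comm, dist_fun)` pair; permuted tables may leave a
sample empty, which the internal lenient mode of `decompose_matrix()`
treats as zero dissimilarity among empty samples rather than an error.
Defaults: 999 permutations (1999 for PERMANOVA), all seeded.

**Relative nestedness.** The printed index this emulates could not be
tied to a single literature formula, and the package's contract (pure
replacement must score 0, a perfectly nested chain must score the
maximum) excludes the Podani–Schmera form \((a+|b-c|)/(a+b+c)\), which is
positive for pure replacement. Both implemented definitions are
richness-share measures: `"podani"` averages the per-pair ratio
`Rich/D`, `"baselga_like"` pools `sum(Rich)/sum(D)`. Every result is
labelled with its definition; no claim of equivalence to any published
value is made.

## Coverage-normalized Hill diversities

Raw richness is sampling-depth dependent, so layer diversities are
compared at equal *sample coverage* rather than equal reads. Coverage is
estimated from singletons and doubletons (Chao–Jost):
\(\hat C = 1 - \tfrac{f_1}{n}\,\tfrac{(n-1)f_1}{(n-1)f_1 + 2f_2}\).
`coverage_normalized_hill()` finds, by integer search on the monotone
expected-coverage curve, the subsample size `m` at which expected
coverage reaches the target (default 0.9; ties broken to smaller `m`),
and evaluates the expected Hill number at `m` under hypergeometric
(without-replacement) subsampling:

* `q = 0`: the classical rarefaction formula
  \(S(m) = \sum_i [1 - \binom{n-x_i}{m}/\binom{n}{m}]\);
* `q = 1`: \(\exp H(m)\) with \(H(m)\) the exact expected Shannon entropy
  of the subsample (hypergeometric pmf per taxon);
* `q = 2`: the inverse of the exact expectation of the plug-in Simpson
  concentration. This form (rather than the `(m-1)/m` unbiased-estimator
  variant) is used deliberately so that the interpolated value at `m = n`
  equals the observed inverse Simpson exactly — an invariant the test
  suite asserts for all three orders.

Because `q = 1` returns `exp(E[H])` and `q = 2` returns `1/E[C]`, the
Monte-Carlo oracle in the tests compares on the expectation scales
(entropy, concentration, richness), avoiding a spurious Jensen gap.
Extrapolation beyond the observed sample is not supported: a target above
the estimated coverage raises an error, and the bulk helper
`hill_profile()` instead caps the target at the sample's own coverage and
flags the row (`target_capped`), so profile-wide summaries never die on
one shallow sample. Evenness defaults to the Hill ratio
`D(q=2)/D(q=0)` (Pielou's J available), keeping the whole analysis inside
one diversity framework. Chao1 uses the bias-corrected form
`S_obs + f1(f1-1)/(2(f2+1))`, defined when `f2 = 0`.

## Ordination and environmental coupling

Standard multivariate steps are delegated to vegan and stats — `metaMDS`
(NMDS, classical-scaling start plus seeded random restarts), `mantel`,
`adonis2` (one-way PERMANOVA), `betadisper` + `TukeyHSD` (group
dispersion; the share of magnitude in negative PCoA eigenvalues is
reported and messaged), `envfit`, `prcomp` (centered, scaled PCA with a
deterministic sign convention: the largest-magnitude loading on each axis
is made positive), `hclust` (UPGMA) and `vegdist` (Kulczynski) — behind
thin, seeded wrappers so every statistic records its permutation count.

Fuzzy set ordination is implemented directly. Memberships are the
min-max scaled environmental axis, \(\mu_i \in [0,1]\); apparent
memberships average the other samples' memberships weighted by community
similarity, \(\nu_i = \sum_{j\ne i} S_{ij}\mu_j / \sum_{j\ne i} S_{ij}\);
the statistic is `r = cor(mu, nu)` with the axis permuted for the null.
Similarity is the complement `S = 1 - D` for dissimilarities already in
[0, 1] (the Jaccard-family components), with max-normalization first for
larger scales; a pure `1 - D/max(D)` rule would zero out the weights
whenever all off-diagonal dissimilarities are equal. The two-dimensional
variant fits each axis independently and correlates the stacked
\((\mu_1,\mu_2)\) with \((\nu_1,\nu_2)\), permuting both axes jointly —
one defensible reading of the multidimensional method, recorded here as
the package's choice.

## Parametric models

DNA depth profiles are fitted as \(y = a e^{-bz}\) by Levenberg–Marquardt
least squares (`minpack.lm`), initialized from the log-linear regression;
`r2` is computed on the original scale. A non-positive log-linear slope
short-circuits to a flagged `non_decay` fit instead of a degenerate
nonlinear solve. Half-depth is `ln 2 / b`; half-life requires an explicit
`age_model()` (constant sedimentation rate or monotone anchor
interpolation) because depth–age conversion is site-specific — no rate is
hard-coded. The DNA-vs-domains regression reports sequential (type I)
sums of squares as shares of total variance (so shares sum to the model
R²) together with Shapiro–Wilk and Cook's-distance diagnostics, and the
richness-component trend is an OLS on layer midpoints whose extrapolation
solves `fitted = 1` for the depth at which richness loss alone would
structure the community. Layers are half-open `[top, bottom)` intervals
labelled `"top-bottom"`; all regressions use midpoints.

## The synthetic generator

`synthetic_config()` encodes the study conditions as defaults: 4
replicate cores, 15 layers (1-cm slices to 10 cm, then 4-cm slices to
30 cm), ~6600 reads per sample (lognormal, sdlog 0.35), 2000 taxa, depth
zones bounded at 5 and 14 cm, DNA profile `13.9 * exp(-0.128 z)` with 5%
relative noise. Every taxon carries both structural responses, and its
expected abundance at depth `z` is the mixture

\[
p_k(z) \propto \theta\, h_k e^{-(z-c_k)^2/2w_k^2}
 + (1-\theta)\, s_k e^{-\lambda_k z},
\]

so the replacement weight `theta` grades the community smoothly from
purely nested (`theta = 0`) to purely niche-structured (`theta = 1`).
Design choices that matter:

* **Persistence–abundance coupling.** Burial-decay rates and abundance
  scales share a latent factor, so the lineages that persist at depth
  were already common at the surface. Without it, compositional read
  sampling turns a purely nested community into apparent replacement:
  rare slow-decaying taxa surface only in deep samples. With it, the
  nested-only regime keeps the replacement component near the sampling
  noise floor.
* **Zone geometry.** Niche centers sit within zones drawn in proportion
  to zone thickness (uniform taxa per cm), and niche breadths scale with
  the square root of zone thickness — gradients flatten with depth, deep
  layers are more similar to one another, and the niche model carries no
  built-in richness gradient that would confound the partition.
* **Domains as generative metadata.** Archaea are favoured in deep
  niches and slow decay, Eukaryota in the fast-decaying surface input
  (decay rates doubled), Bacteria mixed; the expected read fractions
  drift from roughly 10–15 : 60–70 : 25–30 (A:B:E) at the surface to an
  Archaea-dominated split at 30 cm. No taxonomic realism beyond these
  domain-level trends is claimed.
* **Replicate noise** is Dirichlet-multinomial (concentration 200),
  emulating the overdispersion of real replicate cores.
* `theta = 0.75` by default: replacement-dominated turnover with a
  persistent burial signal, matching the structure the statistics are
  designed to detect. Chosen once as a study condition.

"Present" environmental parameters are monotone transforms of a shared
activity latent (`exp(-0.128 z)`, the same scale that drives DNA decay)
plus noise; "past" parameters are smoothed random walks over depth shared
across cores and independent of activity. What passing tests on these
data do **not** show: real sediment communities have phylogenetic
structure, sequencing error, primer bias and relic DNA, none of which are
simulated; conclusions about those factors cannot be drawn from the
synthetic checks.

## Problem sizes and numerical conventions in the test suite

Simulation-based properties run on a reduced profile (2 cores, 500 taxa,
~2000 reads per sample) chosen to keep the checks sharp yet quick:
replacement-share recovery uses 10 seeds per `theta` in {0, 0.25, 0.5,
0.75, 1}; type-I error of the Mantel, PERMANOVA, FSO and LCBD permutation
tests is measured over 500 null simulations at 99 permutations each;
zone recovery uses the full-size generator with well-separated zones
(narrow niches, `theta = 1`), where the UPGMA k = 3 cut matches the true
zones with Rand index > 0.9; the nested-only contract (replacement below
0.1 down the whole profile) is checked in the crisp-occupancy regime
(~120 taxa at the default read depth), where presence/absence flips are
rare — with thousands of taxa at the same depth, detection noise alone
produces apparent replacement, which is precisely why the sum table and
singleton stripping exist. Rarefaction is multivariate hypergeometric
(without replacement), seeded; presence means count >= 1; permutation
p-values are always `(exceed + 1)/(n_perm + 1)`.

## Known limitations

* The two relative-nestedness definitions are labelled, not reconciled;
  neither is asserted against published values.
* Coverage normalization only interpolates; horizons whose estimated
  coverage is below the target are reported at their own coverage and
  flagged rather than extrapolated.
* The FSO's two-dimensional aggregation is one reading of the method;
  alternatives (sequential residual fitting) would need a reference
  implementation to compare against.
* The per-depth read cap is applied per replicate before summing (keeps
  cores equally weighted); the per-depth reading is available via
  `cap_scope = "depth"`.
* Depth–age mapping is left explicit because printed half-life and
  total-age figures generally imply different constant rates; users must
  choose their dating model.
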