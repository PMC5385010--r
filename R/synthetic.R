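#' Configuration for the synthetic depth-profile community generator
#'
#' Encodes the two competing structural models of vertical sediment
#' community organization and their mixture. *Nested burial*: every taxon
#' enters at the surface and decays exponentially with depth (taxon-specific
#' rate), so deeper communities are subsets of shallower ones. *Niche
#' replacement*: taxa respond to depth with Gaussian niches whose centers
#' sit in distinct depth zones, so communities turn over by substitution.
#' The replacement weight `theta` mixes the two (0 = purely nested,
#' 1 = purely niche-structured).
#'
#' Defaults emulate a 4-core, 15-layer, 30-cm profile (1-cm slices to 10 cm,
#' 4-cm slices below), ~6600 reads per sample, 2000 taxa, zone boundaries at
#' 5 and 14 cm, and a DNA profile `13.9 * exp(-0.128 z)`.
#'
#' @param n_cores replicate cores.
#' @param layer_breaks depth interval breaks in cm (length = layers + 1).
#' @param reads_mean,reads_sdlog lognormal read-depth distribution per
#'   sample.
#' @param n_niche_taxa,n_nested_taxa taxa per structural class.
#' @param theta replacement weight in \[0, 1\].
#' @param zone_boundaries interior depth-zone boundaries (cm).
#' @param niche_width_mean,niche_width_sdlog lognormal niche widths (cm).
#' @param nested_decay_rate,nested_decay_sdlog lognormal per-taxon burial
#'   decay rates (per cm).
#' @param dirichlet_conc Dirichlet concentration for replicate-core
#'   overdispersion (larger = more homogeneous replicates).
#' @param dna_a,dna_b,dna_sigma DNA profile amplitude, decay rate per cm and
#'   relative noise.
#' @param env_noise relative noise of the environmental generators.
#' @param seed integer seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cores = 4,
                             layer_breaks = c(0:10, seq(14, 30, by = 4)),
                             reads_mean = 6600, reads_sdlog = 0.35,
                             n_niche_taxa = 1200, n_nested_taxa = 800,
                             theta = 0.75,
                             zone_boundaries = c(5, 14),
                             niche_width_mean = 2.5, niche_width_sdlog = 0.3,
                             nested_decay_rate = 0.128,
                             nested_decay_sdlog = 0.5,
                             dirichlet_conc = 200,
                             dna_a = 13.9, dna_b = 0.128, dna_sigma = 0.05,
                             env_noise = 0.1,
                             seed = 1L) {
  cfg <- as.list(environment())
  problems <- character()
  if (theta < 0 || theta > 1) problems <- c(problems, "theta must be in [0, 1]")
  if (any(diff(layer_breaks) <= 0)) {
    problems <- c(problems, "layer_breaks must be strictly increasing")
  }
  if (nested_decay_rate <= 0 || dna_b <= 0 || niche_width_mean <= 0) {
    problems <- c(problems, "rates and widths must be positive")
  }
  if (n_cores < 1 || n_niche_taxa < 1 || n_nested_taxa < 1) {
    problems <- c(problems, "counts must be positive")
  }
  stop_if(length(problems) > 0,
          paste(c("invalid config:", problems), collapse = "\n  "))
  structure(cfg, class = "synthetic_config")
}

# zone label (a, b, c, ...) of each depth
zone_of <- function(z, boundaries) {
  letters[findInterval(z, boundaries) + 1]
}

draw_taxon_params <- function(cfg) {
  z_max <- max(cfg$layer_breaks)
  bounds <- c(0, cfg$zone_boundaries, z_max)
  n_zones <- length(bounds) - 1
  n_total <- cfg$n_niche_taxa + cfg$n_nested_taxa
  is_niche <- rep(c(TRUE, FALSE), c(cfg$n_niche_taxa, cfg$n_nested_taxa))

  # Every taxon carries both responses, mixed by theta downstream.
  # A shared persistence latent couples low burial-decay rates to high
  # abundance: lineages that persist under burial are those already
  # established in the community, so the taxa that dominate deep layers
  # were detectable at the surface (read sampling would otherwise turn a
  # purely nested community into apparent replacement).
  persistence <- stats::rnorm(n_total)
  scale_abund <- exp(1.2 * (0.8 * persistence + 0.6 * stats::rnorm(n_total)))
  lambda <- exp(log(cfg$nested_decay_rate) -
                  cfg$nested_decay_sdlog * persistence)

  # niche-class taxa: zone-centered Gaussian responses; nested-class taxa:
  # surface specialists (their niche sits at the sediment surface)
  # zone membership proportional to zone thickness (uniform taxa per cm)
  zone <- sample.int(n_zones, n_total, replace = TRUE,
                     prob = diff(bounds))
  zmid <- (bounds[zone] + bounds[zone + 1]) / 2
  zspan <- bounds[zone + 1] - bounds[zone]
  center <- pmin(pmax(zmid + stats::rnorm(n_total, 0, zspan / 5),
                      bounds[zone]), bounds[zone + 1])
  # niche breadth scales with zone thickness: gradients flatten with depth,
  # so deep specialists occupy broader depth ranges (deep layers end up
  # more similar to one another, without a built-in richness gradient)
  width <- sqrt(zspan / (bounds[2] - bounds[1])) *
    stats::rlnorm(n_total, log(cfg$niche_width_mean), cfg$niche_width_sdlog)
  center[!is_niche] <- abs(stats::rnorm(sum(!is_niche), 0, 1.5))
  width[!is_niche] <- stats::rlnorm(sum(!is_niche), log(cfg$niche_width_mean),
                                    cfg$niche_width_sdlog)
  zone[!is_niche] <- 1L

  # domains: Archaea favoured in deep niches and slow decay, Eukaryota in
  # the fast-decaying surface input, Bacteria mixed
  u <- stats::runif(n_total)
  p_a <- 0.05 + 0.6 * stats::plogis((center - 12) / 3)
  p_e <- 0.15 * exp(-center / 4)
  domain <- ifelse(u < p_a, "Archaea",
                   ifelse(u < p_a + p_e, "Eukaryota", "Bacteria"))
  domain[!is_niche] <- ifelse(u[!is_niche] < 0.45, "Eukaryota",
                              ifelse(u[!is_niche] < 0.95, "Bacteria",
                                     "Archaea"))
  lambda <- lambda * ifelse(domain == "Eukaryota", 2,
                            ifelse(domain == "Archaea", 0.5, 1))
  data.frame(
    taxon_id = sprintf("%s_%04d", ifelse(is_niche, "niche", "nested"),
                       c(seq_len(cfg$n_niche_taxa), seq_len(cfg$n_nested_taxa))),
    class = ifelse(is_niche, "niche", "nested"),
    zone = letters[zone], center = center, width = width,
    height = scale_abund, surface = scale_abund, lambda = lambda,
    domain = domain, stringsAsFactors = FALSE)
}

expected_abundance <- function(taxa, depths, theta) {
  gauss <- sapply(seq_len(nrow(taxa)), function(k) {
    taxa$height[k] * exp(-(depths - taxa$center[k])^2 / (2 * taxa$width[k]^2))
  })
  decay <- sapply(seq_len(nrow(taxa)), function(k) {
    taxa$surface[k] * exp(-taxa$lambda[k] * depths)
  })
  resp <- theta * gauss + (1 - theta) * decay
  resp <- matrix(resp, nrow = length(depths),
                 dimnames = list(NULL, taxa$taxon_id))
  sweep(resp, 1, rowSums(resp), `/`)
}

#' Generate a synthetic depth-stratified community
#'
#' Expected per-layer composition follows the theta-weighted mixture of the
#' niche and nested responses (see [synthetic_config()]); each replicate
#' core perturbs the layer composition with Dirichlet noise and reads are
#' drawn multinomially at a lognormal per-sample depth.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `otu` (an [otu_table()] with domain-level taxonomy),
#'   `meta` (a [sample_meta()]), and `truth` (taxon parameters, expected
#'   per-layer relative abundances, zone labels, `theta`, `seed`).
#' @export
generate_community <- function(cfg) {
  stop_if(!inherits(cfg, "synthetic_config"), "need a synthetic_config")
  local_seed(cfg$seed, {
    n_layers <- length(cfg$layer_breaks) - 1
    tops <- cfg$layer_breaks[-length(cfg$layer_breaks)]
    bottoms <- cfg$layer_breaks[-1]
    cores <- LETTERS[seq_len(cfg$n_cores)]
    meta <- sample_meta(
      sample_id = paste0(rep(cores, each = n_layers), "_",
                         rep(paste0(tops, "-", bottoms), cfg$n_cores)),
      core_id = rep(cores, each = n_layers),
      layer_top_cm = rep(tops, cfg$n_cores),
      layer_bottom_cm = rep(bottoms, cfg$n_cores))
    depths <- (tops + bottoms) / 2
    taxa <- draw_taxon_params(cfg)
    expected <- expected_abundance(taxa, depths, cfg$theta)
    counts <- matrix(0L, nrow = nrow(meta), ncol = nrow(taxa),
                     dimnames = list(meta$sample_id, taxa$taxon_id))
    reads <- pmax(200L, as.integer(round(stats::rlnorm(
      nrow(meta), log(cfg$reads_mean) - cfg$reads_sdlog^2 / 2,
      cfg$reads_sdlog))))
    for (i in seq_len(nrow(meta))) {
      layer_idx <- match(meta$layer_top_cm[i], tops)
      p <- expected[layer_idx, ]
      g <- stats::rgamma(length(p), shape = cfg$dirichlet_conc * p)
      if (sum(g) == 0) g <- p
      counts[i, ] <- as.integer(stats::rmultinom(1, reads[i], g / sum(g)))
    }
    taxonomy <- stats::setNames(paste0(taxa$domain, ";synthetic_lineage"),
                                taxa$taxon_id)
    truth <- list(taxa = taxa, expected = expected,
                  layer_labels = paste0(tops, "-", bottoms),
                  zones = zone_of(depths, cfg$zone_boundaries),
                  depths = depths, theta = cfg$theta, seed = cfg$seed)
    list(otu = otu_table(counts, taxonomy = taxonomy), meta = meta,
         truth = truth)
  })
}

#' Generate a synthetic environmental matrix and DNA profile
#'
#' "Present" parameters are monotone transforms of a shared activity latent
#' (`exp(-dna_b * z)`, the same decay scale that drives the DNA profile)
#' plus noise, so they express ongoing activity. "Past" parameters are
#' smoothed random walks over depth shared across cores, independent of the
#' activity latent, expressing conservative historical deposition. DNA is
#' `dna_a * exp(-dna_b * z) * (1 + eps)` and is stored as an untagged
#' column.
#'
#' @param cfg a [synthetic_config()].
#' @param community result of [generate_community()] on the same config
#'   (supplies the sample layout; the activity latent is shared by
#'   construction).
#' @return list with `env` (an [env_matrix()] with default present/past
#'   tags plus an untagged `DNA` column), `dna` (per-sample vector) and
#'   `activity` (per-sample latent).
#' @export
generate_environment <- function(cfg, community) {
  meta <- community$meta
  local_seed(cfg$seed + 1L, {
    z <- meta$midpoint_cm
    activity <- exp(-cfg$dna_b * z)
    tags <- default_env_tags()
    up <- c("BPP", "SO4", "RNA_DNA", "Cl")       # high where activity is high
    vals <- sapply(tags$present, function(par) {
      signal <- if (par %in% up) activity else 1 - activity
      scale_par <- stats::runif(1, 0.5, 20)
      scale_par * (signal + stats::rnorm(length(z), 0, cfg$env_noise))
    })
    n_layers <- length(unique(meta$layer_top_cm))
    tops <- sort(unique(meta$layer_top_cm))
    past_vals <- sapply(tags$past, function(par) {
      walk <- cumsum(stats::rnorm(n_layers))
      walk <- stats::filter(walk, rep(1 / 3, 3), sides = 2)
      walk[is.na(walk)] <- walk[!is.na(walk)][c(1, sum(!is.na(walk)))]
      walk <- as.numeric(scale(walk))
      layer_idx <- match(meta$layer_top_cm, tops)
      walk[layer_idx] + stats::rnorm(length(z), 0, cfg$env_noise)
    })
    dna <- cfg$dna_a * exp(-cfg$dna_b * z) *
      pmax(0.01, 1 + stats::rnorm(length(z), 0, cfg$dna_sigma))
    values <- cbind(vals, past_vals, DNA = dna)
    rownames(values) <- meta$sample_id
    list(env = env_matrix(values, meta, tags = tags), dna = dna,
         activity = activity)
  })
}

#' Write a complete synthetic fixture set to disk
#'
#' Emits the OTU TSV, environmental TSV, YAML tag sidecar, sample metadata
#' TSV and a ground-truth JSON (taxon parameters, zone labels, theta, seed)
#' into `outdir`. Re-running with the same config reproduces the files
#' byte-identically.
#'
#' @param outdir output directory (created if missing).
#' @param cfg a [synthetic_config()].
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture_set <- function(outdir, cfg) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  com <- generate_community(cfg)
  envr <- generate_environment(cfg, com)
  paths <- c(otu = file.path(outdir, "otu_table.tsv"),
             env = file.path(outdir, "env_table.tsv"),
             tags = file.path(outdir, "env_tags.yml"),
             meta = file.path(outdir, "sample_meta.tsv"),
             truth = file.path(outdir, "truth.json"))
  write_otu_table(com$otu, paths["otu"])
  write_env_table(envr$env, paths["env"], tags_path = paths["tags"])
  utils::write.table(as.data.frame(com$meta), paths["meta"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- com$truth
  truth$expected <- NULL # reproducible from taxa + config; keep JSON small
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(paths)
}
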