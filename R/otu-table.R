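#' Construct an OTU table
#'
#' The central community object: an integer count matrix with samples as rows
#' and OTUs as columns, optionally carrying a semicolon-delimited taxonomy
#' path per OTU (domain first: Archaea, Bacteria, Eukaryota or unclassified)
#' and a representative sequence per OTU.
#'
#' @param counts numeric matrix of non-negative integer counts,
#'   samples x OTUs, with row and column names.
#' @param taxonomy optional named character vector (one entry per OTU) of
#'   semicolon-delimited rank paths.
#' @param rep_seqs optional named character vector of representative
#'   sequences, treated as opaque strings.
#' @return an object of class `otu_table`.
#' @export
otu_table <- function(counts, taxonomy = NULL, rep_seqs = NULL) {
  stop_if(!is.matrix(counts), "`counts` must be a matrix (samples x OTUs)")
  stop_if(is.null(rownames(counts)) || is.null(colnames(counts)),
          "`counts` must have sample (row) and OTU (column) names")
  stop_if(anyDuplicated(rownames(counts)) > 0, "duplicate sample ids")
  stop_if(anyDuplicated(colnames(counts)) > 0, "duplicate OTU ids")
  stop_if(!is_count_vector(as.vector(counts)),
          "counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    stop_if(is.null(names(taxonomy)) || !all(names(taxonomy) %in% colnames(counts)),
            "taxonomy must be named by OTU id")
    taxonomy <- taxonomy[colnames(counts)]
    names(taxonomy) <- colnames(counts)
  }
  if (!is.null(rep_seqs)) {
    rep_seqs <- rep_seqs[colnames(counts)]
    names(rep_seqs) <- colnames(counts)
  }
  structure(list(counts = counts, taxonomy = taxonomy, rep_seqs = rep_seqs),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs, %s reads%s\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ","),
              if (is.null(x$taxonomy)) "" else ", with taxonomy"))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Sample ids of an OTU table
#' @param t an `otu_table`.
#' @return character vector.
#' @export
sample_ids <- function(t) rownames(t$counts)

#' OTU ids of an OTU table
#' @param t an `otu_table`.
#' @return character vector.
#' @export
otu_ids <- function(t) colnames(t$counts)

#' Domain (first taxonomy rank) of each OTU
#' @param t an `otu_table` with taxonomy.
#' @return named character vector of first-rank labels.
#' @export
otu_domains <- function(t) {
  stop_if(is.null(t$taxonomy), "OTU table carries no taxonomy")
  d <- vapply(strsplit(t$taxonomy, ";", fixed = TRUE), `[`, character(1), 1L)
  d[is.na(d) | d == ""] <- "unclassified"
  names(d) <- otu_ids(t)
  d
}

#' Read an OTU table from TSV
#'
#' Expected dialect: tab-separated, header row; first column `otu_id`; one
#' integer column per sample; optional `taxonomy` (semicolon path) and
#' `representative_sequence` columns. OTUs are rows on disk and columns in
#' memory.
#'
#' @param path file path.
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  stop_if(ncol(raw) < 2, "OTU table needs an id column and >=1 sample column")
  stop_if(names(raw)[1] != "otu_id", "first column must be named 'otu_id'")
  ids <- raw[[1]]
  stop_if(anyDuplicated(ids) > 0,
          sprintf("duplicate OTU id '%s'", ids[duplicated(ids)][1]))
  special <- intersect(c("taxonomy", "representative_sequence"), names(raw))
  sample_cols <- setdiff(names(raw)[-1], special)
  stop_if(anyDuplicated(sample_cols) > 0, "duplicate sample ids in header")
  counts <- matrix(0L, nrow = length(sample_cols), ncol = length(ids),
                   dimnames = list(sample_cols, ids))
  for (s in sample_cols) {
    v <- suppressWarnings(as.numeric(raw[[s]]))
    bad <- which(is.na(v) | v < 0 | abs(v - round(v)) > 1e-8)
    stop_if(length(bad) > 0,
            sprintf("malformed count '%s' for OTU '%s', sample '%s'",
                    raw[[s]][bad[1]], ids[bad[1]], s))
    counts[s, ] <- as.integer(round(v))
  }
  taxonomy <- if ("taxonomy" %in% special) stats::setNames(raw$taxonomy, ids)
  rep_seqs <- if ("representative_sequence" %in% special) {
    stats::setNames(raw$representative_sequence, ids)
  }
  otu_table(counts, taxonomy = taxonomy, rep_seqs = rep_seqs)
}

#' Write an OTU table to TSV (canonical dialect)
#'
#' Deterministic column order: `otu_id`, samples in table order, then
#' `taxonomy` and `representative_sequence` if present. Round-trips
#' byte-identically through [read_otu_table()].
#'
#' @param t an `otu_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(t, path) {
  df <- data.frame(otu_id = otu_ids(t), t(t$counts), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(t$taxonomy)) df$taxonomy <- unname(t$taxonomy)
  if (!is.null(t$rep_seqs)) df$representative_sequence <- unname(t$rep_seqs)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Remove OTUs present in only one sample
#'
#' Random burial events (bird droppings, rainfall washes, etc.) leave rare
#' OTUs confined to a single sample; these are stripped regardless of read
#' count. Idempotent; the sample set is unchanged.
#'
#' @param t an `otu_table`.
#' @return filtered `otu_table` keeping exactly the OTUs with non-zero
#'   counts in at least two samples.
#' @export
strip_single_sample_otus <- function(t) {
  keep <- colSums(t$counts > 0) >= 2
  otu_table(t$counts[, keep, drop = FALSE],
            taxonomy = if (!is.null(t$taxonomy)) t$taxonomy[keep],
            rep_seqs = if (!is.null(t$rep_seqs)) t$rep_seqs[keep])
}

#' Rarefy each sample to a fixed read depth
#'
#' Subsampling without replacement (multivariate hypergeometric), as in
#' `vegan::rrarefy`, reproducible for a fixed seed.
#'
#' @param t an `otu_table`.
#' @param depth target reads per sample (positive integer).
#' @param seed integer seed or `NULL` to use the current RNG stream.
#' @return rarefied `otu_table`; every row sums to `depth`.
#' @export
rarefy <- function(t, depth, seed = NULL) {
  stop_if(!is.numeric(depth) || length(depth) != 1 || depth < 1,
          "`depth` must be a positive integer")
  tot <- rowSums(t$counts)
  low <- which(tot < depth)
  stop_if(length(low) > 0,
          sprintf("sample '%s' has %d reads, fewer than depth %d",
                  sample_ids(t)[low[1]], tot[low[1]], as.integer(depth)))
  # counts are validated as integers above; rrarefy's "observed counts"
  # heuristic warning misfires on small tables
  counts <- local_seed(seed, suppressWarnings(vegan::rrarefy(t$counts, depth)))
  otu_table(counts, taxonomy = t$taxonomy, rep_seqs = t$rep_seqs)
}

#' Hellinger transform
#'
#' Square root of relative abundance per sample; rows then have unit sum of
#' squares, making Euclidean distances ecologically interpretable.
#'
#' @param t an `otu_table` with positive sample totals.
#' @return real matrix, samples x OTUs.
#' @export
hellinger <- function(t) {
  tot <- rowSums(t$counts)
  zero <- which(tot == 0)
  stop_if(length(zero) > 0,
          sprintf("sample '%s' has zero total reads", sample_ids(t)[zero[1]]))
  vegan::decostand(t$counts, method = "hellinger")
}

#' Build the per-depth sum table
#'
#' Pools replicate cores per depth layer: each replicate is subsampled
#' (without replacement) to at most `per_replicate_cap` reads so replicates
#' contribute with equal weight, replicates are summed per layer, and the
#' summed table is finally rarefied to
#' `min(final_depth, minimum layer total)` reads per layer.
#'
#' @param t an `otu_table` of all replicate samples.
#' @param meta a [sample_meta()] data frame matching the samples of `t`.
#' @param per_replicate_cap reads retained per replicate before summing.
#' @param final_depth target reads per layer for the final rarefaction.
#' @param seed integer seed.
#' @param cap_scope `"replicate"` (default; cap each replicate, then sum) or
#'   `"depth"` (sum replicates first, then cap each layer at
#'   `per_replicate_cap * n_replicates` is *not* applied — the layer is
#'   simply capped at `per_replicate_cap` reads). Both readings of a
#'   per-depth read cap are available; the replicate-wise one keeps cores
#'   equally weighted.
#' @return an `otu_table` with one row per depth layer, ordered by layer
#'   midpoint, rows labelled by layer interval (e.g. `"0-1"`).
#' @export
build_sum_table <- function(t, meta, per_replicate_cap = 2000,
                            final_depth = 5987, seed = NULL,
                            cap_scope = c("replicate", "depth")) {
  cap_scope <- match.arg(cap_scope)
  stop_if(!all(sample_ids(t) %in% meta$sample_id),
          "every sample needs a metadata row")
  meta <- meta[match(sample_ids(t), meta$sample_id), ]
  layer <- layer_label(meta)
  ord <- order(meta$midpoint_cm)
  layers <- unique(layer[ord])
  local_seed(seed, {
    pooled <- matrix(0L, nrow = length(layers), ncol = ncol(t$counts),
                     dimnames = list(layers, otu_ids(t)))
    for (ly in layers) {
      rows <- which(layer == ly)
      if (cap_scope == "replicate") {
        for (r in rows) {
          x <- t$counts[r, ]
          if (sum(x) > per_replicate_cap) {
            x <- as.integer(suppressWarnings(
              vegan::rrarefy(matrix(x, nrow = 1), per_replicate_cap)))
          }
          pooled[ly, ] <- pooled[ly, ] + as.integer(x)
        }
      } else {
        x <- as.integer(colSums(t$counts[rows, , drop = FALSE]))
        if (sum(x) > per_replicate_cap) {
          x <- as.integer(suppressWarnings(
            vegan::rrarefy(matrix(x, nrow = 1), per_replicate_cap)))
        }
        pooled[ly, ] <- x
      }
    }
    target <- min(final_depth, min(rowSums(pooled)))
    rarefy(otu_table(pooled, taxonomy = t$taxonomy), depth = target)
  })
}

#' Arc-sine square-root transform of proportions
#'
#' @param p numeric vector in \[0, 1\].
#' @return `asin(sqrt(p))`, in radians.
#' @export
arcsine_sqrt <- function(p) {
  stop_if(!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1),
          "proportions must lie in [0, 1]")
  asin(sqrt(p))
}

#' Per-sample domain read proportions
#'
#' Fraction of reads assigned to Archaea, Bacteria and Eukaryota per sample,
#' among reads classified to one of the three domains (unclassified reads
#' are excluded from the denominator).
#'
#' @param t an `otu_table` with taxonomy.
#' @return matrix, samples x 3 (`Archaea`, `Bacteria`, `Eukaryota`); rows sum
#'   to 1, or are `NA` for samples with no domain-classified reads.
#' @export
domain_proportions <- function(t) {
  dom <- otu_domains(t)
  doms <- c("Archaea", "Bacteria", "Eukaryota")
  reads <- sapply(doms, function(d) {
    rowSums(t$counts[, dom == d, drop = FALSE])
  })
  reads <- matrix(reads, nrow = nrow(t$counts),
                  dimnames = list(sample_ids(t), doms))
  tot <- rowSums(reads)
  out <- reads / tot
  out[tot == 0, ] <- NA_real_
  out
}

#' Presence/absence matrix of an OTU table
#'
#' @param t an `otu_table`.
#' @param threshold minimum count for presence (default 1).
#' @return logical matrix, samples x OTUs.
#' @export
presence_absence <- function(t, threshold = 1) t$counts >= threshold
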