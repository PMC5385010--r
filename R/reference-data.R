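#' Published per-layer turnover profile of a 30-cm lake-sediment core survey
#'
#' The printed per-layer summary of a four-core, 15-layer lake-sediment
#' metabarcoding survey: surface-to-layer Jaccard distance with its
#' replacement and richness components, local contributions of the two
#' components (with significance marks), observed OTU counts and sample
#' coverage of the rarefied per-depth sum table. Used as the in-package
#' reference input for the richness-trend regression.
#'
#' @return data frame with one row per layer (`layer`, `Distance`, `Repl`,
#'   `Richness`, `LCrepl`, `LCrepl_sig`, `LCrich`, `LCrich_sig`, `OTUs`,
#'   `Coverage`).
#' @export
reference_turnover_profile <- function() {
  path <- system.file("extdata", "sediment_turnover_profile.tsv",
                      package = "sedipart")
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA")
}
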