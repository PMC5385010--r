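#' Sample metadata for a depth-stratified core survey
#'
#' @param sample_id sample identifiers.
#' @param core_id replicate core labels (e.g. A--D).
#' @param layer_top_cm,layer_bottom_cm depth interval in cm; layers are
#'   half-open `[top, bottom)`.
#' @param age_years optional age at the layer midpoint.
#' @return data frame of class `sample_meta` with a derived `midpoint_cm`.
#' @export
sample_meta <- function(sample_id, core_id, layer_top_cm, layer_bottom_cm,
                        age_years = NULL) {
  stop_if(anyDuplicated(sample_id) > 0, "duplicate sample ids")
  stop_if(any(layer_top_cm < 0) || any(layer_top_cm >= layer_bottom_cm),
          "need 0 <= layer_top_cm < layer_bottom_cm")
  out <- data.frame(sample_id = as.character(sample_id),
                    core_id = as.character(core_id),
                    layer_top_cm = as.numeric(layer_top_cm),
                    layer_bottom_cm = as.numeric(layer_bottom_cm),
                    midpoint_cm = (layer_top_cm + layer_bottom_cm) / 2,
                    stringsAsFactors = FALSE)
  if (!is.null(age_years)) out$age_years <- as.numeric(age_years)
  class(out) <- c("sample_meta", "data.frame")
  out
}

#' Layer interval label, e.g. "0-1" or "26-30"
#' @param meta a [sample_meta()] data frame.
#' @return character vector.
#' @export
layer_label <- function(meta) {
  fmt <- function(x) sub("\\.0+$", "", format(x, trim = TRUE))
  paste0(fmt(meta$layer_top_cm), "-", fmt(meta$layer_bottom_cm))
}

#' Default present/past parameter categories
#'
#' "Present" parameters express ongoing microbial processes (pore-water
#' chemistry, activity measures); "past" parameters are conservative once
#' buried and record the lake's history (elemental totals, heavy metals).
#'
#' @return list with character vectors `present` and `past`.
#' @export
default_env_tags <- function() {
  list(
    present = c("CH4", "CO2", "DOC", "BPP", "SRP", "NH4", "SO4", "Cl",
                "Fe_diss", "Mn_diss", "FI", "RNA_DNA"),
    past = c("TC", "TN", "dry_weight", "TP", "TS", "TH", "Al", "As", "Ca",
             "Cu", "Fe", "Mg", "Mn", "Pb", "Ti", "Zn")
  )
}

#' Construct an environmental parameter matrix
#'
#' @param values numeric matrix, samples x parameters, with dimnames.
#'   `NA` entries are allowed and are kept explicit; downstream operations
#'   that cannot accept `NA` fail loudly rather than impute.
#' @param meta a [sample_meta()] data frame covering the samples.
#' @param tags list with elements `present` and `past` naming parameter
#'   categories; parameters in neither are `untagged`. Defaults to
#'   [default_env_tags()] intersected with the available parameters.
#' @return object of class `env_matrix`.
#' @export
env_matrix <- function(values, meta, tags = NULL) {
  stop_if(!is.matrix(values) || !is.numeric(values),
          "`values` must be a numeric matrix")
  stop_if(is.null(rownames(values)) || is.null(colnames(values)),
          "`values` must have sample and parameter names")
  stop_if(!all(rownames(values) %in% meta$sample_id),
          "every sample needs a metadata row")
  if (is.null(tags)) tags <- default_env_tags()
  tags$present <- intersect(tags$present, colnames(values))
  tags$past <- intersect(tags$past, colnames(values))
  stop_if(length(intersect(tags$present, tags$past)) > 0,
          "present and past tags must be disjoint")
  category <- rep("untagged", ncol(values))
  names(category) <- colnames(values)
  category[tags$present] <- "present"
  category[tags$past] <- "past"
  meta <- meta[match(rownames(values), meta$sample_id), ]
  structure(list(values = values, meta = meta, category = category),
            class = "env_matrix")
}

#' @export
print.env_matrix <- function(x, ...) {
  cat(sprintf("env_matrix: %d samples x %d parameters (%d present, %d past, %d untagged)\n",
              nrow(x$values), ncol(x$values),
              sum(x$category == "present"), sum(x$category == "past"),
              sum(x$category == "untagged")))
  invisible(x)
}

#' Subset the parameters of an env_matrix by category
#'
#' @param env an `env_matrix`.
#' @param category one of `"present"`, `"past"`, `"untagged"`.
#' @return numeric sub-matrix (samples x parameters).
#' @export
env_subset <- function(env, category = c("present", "past", "untagged")) {
  category <- match.arg(category)
  env$values[, env$category == category, drop = FALSE]
}

#' Read an environmental table from TSV
#'
#' Dialect: tab-separated; columns `sample_id`, `core`, `layer_top_cm`,
#' `layer_bottom_cm`, then one numeric column per parameter. An optional
#' YAML sidecar assigns present/past tags (`tags_path`, keys `present` and
#' `past`).
#'
#' @param path TSV path.
#' @param tags_path optional YAML file with `present:`/`past:` lists.
#' @return an [env_matrix()].
#' @export
read_env_table <- function(path, tags_path = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("sample_id", "core", "layer_top_cm", "layer_bottom_cm")
  stop_if(!all(need %in% names(raw)),
          sprintf("missing column(s): %s",
                  paste(setdiff(need, names(raw)), collapse = ", ")))
  meta <- sample_meta(raw$sample_id, raw$core, raw$layer_top_cm,
                      raw$layer_bottom_cm)
  params <- setdiff(names(raw), need)
  values <- as.matrix(raw[, params, drop = FALSE])
  rownames(values) <- raw$sample_id
  tags <- if (!is.null(tags_path)) yaml::read_yaml(tags_path)
  env_matrix(values, meta, tags = tags)
}

#' Write an environmental table (and optional tag sidecar) to TSV
#'
#' @param env an `env_matrix`.
#' @param path TSV output path.
#' @param tags_path optional YAML path for the present/past tags.
#' @return `path`, invisibly.
#' @export
write_env_table <- function(env, path, tags_path = NULL) {
  df <- data.frame(sample_id = env$meta$sample_id,
                   core = env$meta$core_id,
                   layer_top_cm = env$meta$layer_top_cm,
                   layer_bottom_cm = env$meta$layer_bottom_cm,
                   env$values, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(tags_path)) {
    yaml::write_yaml(list(present = names(env$category)[env$category == "present"],
                          past = names(env$category)[env$category == "past"]),
                     tags_path)
  }
  invisible(path)
}

#' Replace flagged outlier cells by the cross-core layer mean
#'
#' Each rule names a parameter, a core and a layer top; the flagged cell is
#' replaced by the mean of the same layer's values in the other cores
#' (ignoring `NA`). The same mechanism fills missing replicate rows.
#'
#' @param env an `env_matrix`.
#' @param rules data frame with columns `parameter`, `core`, `layer_top_cm`.
#' @return list with the corrected `env_matrix` (`env`) and a provenance data
#'   frame (`log`) recording each replacement (old and new value).
#' @export
outlier_replace <- function(env, rules) {
  if (is.null(rules) || nrow(rules) == 0) {
    return(list(env = env, log = data.frame()))
  }
  values <- env$values
  meta <- env$meta
  log <- NULL
  for (i in seq_len(nrow(rules))) {
    par <- rules$parameter[i]
    stop_if(!par %in% colnames(values), sprintf("unknown parameter '%s'", par))
    in_layer <- meta$layer_top_cm == rules$layer_top_cm[i]
    target <- which(in_layer & meta$core_id == rules$core[i])
    stop_if(length(target) != 1,
            sprintf("rule %d: no unique cell for core '%s', layer top %s",
                    i, rules$core[i], rules$layer_top_cm[i]))
    donors <- which(in_layer & meta$core_id != rules$core[i])
    donor_vals <- values[donors, par]
    stop_if(all(is.na(donor_vals)),
            sprintf("rule %d: no donor values in other cores", i))
    new <- mean(donor_vals, na.rm = TRUE)
    log <- rbind(log, data.frame(parameter = par, core = rules$core[i],
                                 layer_top_cm = rules$layer_top_cm[i],
                                 old = values[target, par], new = new))
    values[target, par] <- new
  }
  list(env = env_matrix(values, meta,
                        tags = list(present = names(env$category)[env$category == "present"],
                                    past = names(env$category)[env$category == "past"])),
       log = log)
}
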