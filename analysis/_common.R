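# shared setup for the numbered analysis drivers: paths and the study-wide
# seed. Fixtures (bulky) live under scratch/, findings (small tables) under
# results/. Each driver regenerates the fixtures if they are missing, so
# every script is runnable standalone from the repository root.

library(sedipart)

STUDY_SEED <- 20120326L # coring date of the emulated campaign
FIXTURE_DIR <- "scratch/fixtures"
RESULTS_DIR <- "results/analysis"

dir.create(FIXTURE_DIR, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

study_config <- function() synthetic_config(seed = STUDY_SEED)

ensure_fixtures <- function() {
  if (!file.exists(file.path(FIXTURE_DIR, "otu_table.tsv"))) {
    message("fixtures missing; regenerating (see 01_simulate.R)")
    write_fixture_set(FIXTURE_DIR, study_config())
  }
}

load_fixtures <- function() {
  ensure_fixtures()
  meta_raw <- read.delim(file.path(FIXTURE_DIR, "sample_meta.tsv"))
  list(otu = read_otu_table(file.path(FIXTURE_DIR, "otu_table.tsv")),
       env = read_env_table(file.path(FIXTURE_DIR, "env_table.tsv"),
                            tags_path = file.path(FIXTURE_DIR, "env_tags.yml")),
       meta = sample_meta(meta_raw$sample_id, meta_raw$core_id,
                          meta_raw$layer_top_cm, meta_raw$layer_bottom_cm),
       truth = jsonlite::read_json(file.path(FIXTURE_DIR, "truth.json"),
                                   simplifyVector = TRUE))
}

write_tsv <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}

write_json_result <- function(x, name) {
  path <- file.path(RESULTS_DIR, name)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  message("wrote ", path)
}
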