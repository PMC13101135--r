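# Shared settings for the analysis workflow. The demonstration study uses a
# 60+25+40-feature panel so the exact SHAP interaction stage (quadratic in the
# retained feature count) finishes in minutes on one CPU; all thresholds are
# the study defaults (see ?run_config).

library(dsinet)

WORKFLOW_SEED <- as.integer(Sys.getenv("DSINET_SEED", "1"))
RESULTS_DIR <- "results"

demo_sim_config <- function(seed = WORKFLOW_SEED) {
  sim_config(n_accessions = 200, n_snps = 60, n_ld_blocks = 6,
             n_metabolites = 25, n_taxa = 40, seed = seed)
}

demo_rf_hyper <- function() list(num_trees = 200, mtry_frac = 1 / 3, min_node = 5)

demo_gbt_hyper <- function() list(max_depth = 3, eta = 0.3, nrounds = 60,
                                  subsample = 0.8)

res_path <- function(...) {
  dir.create(file.path(RESULTS_DIR, ...), recursive = TRUE, showWarnings = FALSE)
  file.path(RESULTS_DIR, ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
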