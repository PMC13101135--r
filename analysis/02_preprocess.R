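#!/usr/bin/env Rscript
# Preprocess both conditions: missing-value filtering (feature-first), MAF
# filter (0.05) and greedy windowed LD pruning (r^2 0.95, window 100) on the
# genome, column scaling of every layer, and concatenation into one feature
# stack per condition.

source("analysis/00_config.R")

cfg <- run_config(seed = WORKFLOW_SEED)
counts <- list()
for (cond in c("control", "drought")) {
  study <- read_study_dir(file.path(RESULTS_DIR, "study", cond))
  pp <- preprocess_study(study, cfg)
  res_path("preprocessed")
  counts[[cond]] <- data.frame(
    condition = cond,
    snps_after_maf = pp$n_snps_after_maf,
    snps_after_ld = sum(pp$stack$layer_of == "genome"),
    metabolites = sum(pp$stack$layer_of == "metabolome"),
    taxa = sum(pp$stack$layer_of == "microbiome"),
    stacked = ncol(pp$stack$matrix)
  )
}
write_tsv(do.call(rbind, counts), file.path(RESULTS_DIR, "preprocessed",
                                            "feature_counts.tsv"))
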