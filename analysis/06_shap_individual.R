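#!/usr/bin/env Rscript
# Individual-feature SHAP: refit per-condition models on the theta > 0.01
# (either condition) subset for leaf dry weight, explain them exactly, and
# rank the drought/control log2 mean-|SHAP| ratios; |ratio| > 2.5 marks
# condition-specific features.

source("analysis/00_config.R")

cfg <- run_config(seed = WORKFLOW_SEED)
pp <- list(); theta <- list()
for (cond in c("control", "drought")) {
  study <- read_study_dir(file.path(RESULTS_DIR, "study", cond))
  pp[[cond]] <- preprocess_study(study, cfg)
  imp <- utils::read.delim(file.path(RESULTS_DIR, "rf",
                                     paste0("importance_", cond, ".tsv")))
  theta[[cond]] <- stats::setNames(imp$theta, imp$feature)
}
shared <- intersect(names(theta$control), names(theta$drought))

res <- run_shap_individual(
  pp$control$stack, pp$drought$stack,
  pp$control$study$phenotypes[, cfg$trait],
  pp$drought$study$phenotypes[, cfg$trait],
  theta$control[shared], theta$drought[shared],
  hyper = demo_rf_hyper(), threshold = cfg$theta_individual,
  ratio_threshold = cfg$log2_ratio,
  seed = substream_seed(WORKFLOW_SEED, "shap"))

dir <- res_path("shap")
write_tsv(res$summary, file.path(dir, "log2_ratio.tsv"))
top <- res$summary[res$summary$display, ]
message(length(res$selected), " features explained; ",
        nrow(top), " pass |log2 ratio| > ", cfg$log2_ratio)
if (nrow(top)) {
  message("most condition-specific: ",
          paste(utils::head(top$feature, 5), collapse = ", "))
}
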