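#!/usr/bin/env Rscript
# Multi-kernel BLUP per condition: one linear kernel per omics layer, EM-REML
# variance components per trait, feature coefficients back-projected through
# the kernel pseudo-inverse, column-standardized B, and the SVD latent map
# whose first two factors display the feature-trait structure.

source("analysis/00_config.R")

cfg <- run_config(seed = WORKFLOW_SEED)
for (cond in c("control", "drought")) {
  study <- read_study_dir(file.path(RESULTS_DIR, "study", cond))
  pp <- preprocess_study(study, cfg)
  mk <- run_mkblup(pp$study)
  dir <- res_path("blup")
  write_tsv(data.frame(trait = rownames(mk$vc_table), mk$vc_table,
                       check.names = FALSE),
            file.path(dir, paste0("variance_components_", cond, ".tsv")))
  lm_ <- svd_project(mk$coefficients)
  write_tsv(data.frame(trait = rownames(lm_$trait_projection),
                       lm_$trait_projection),
            file.path(dir, paste0("trait_projection_", cond, ".tsv")))
  write_tsv(data.frame(feature = rownames(lm_$feature_projection),
                       layer = unname(mk$coefficients$layer_of[
                         rownames(lm_$feature_projection)]),
                       lm_$feature_projection),
            file.path(dir, paste0("feature_projection_", cond, ".tsv")))
  message(cond, ": top singular values ",
          paste(signif(lm_$d[1:3], 3), collapse = ", "))
}
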