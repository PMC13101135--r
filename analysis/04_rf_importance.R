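#!/usr/bin/env Rscript
# Random-forest importance per condition: one forest per trait, gain
# (variance-reduction) importance normalized per trait into B^(RF), total
# importance theta, the two selection screens (theta > 0.01 either condition;
# theta > 0.001 both), and the permutation predictive-signal check for the
# representative trait.

source("analysis/00_config.R")

cfg <- run_config(seed = WORKFLOW_SEED)
theta <- list()
dir <- res_path("rf")
for (cond in c("control", "drought")) {
  study <- read_study_dir(file.path(RESULTS_DIR, "study", cond))
  pp <- preprocess_study(study, cfg)
  rf <- run_rf_importance(pp$study, hyper = demo_rf_hyper(),
                          seed = substream_seed(WORKFLOW_SEED, paste0("rf-", cond)))
  theta[[cond]] <- rf$theta
  write_tsv(data.frame(feature = rownames(rf$B_rf),
                       layer = unname(rf$stack$layer_of[rownames(rf$B_rf)]),
                       rf$B_rf, theta = rf$theta, check.names = FALSE),
            file.path(dir, paste0("importance_", cond, ".tsv")))

  chk <- permutation_signal_check(rf$stack,
                                  pp$study$phenotypes[, cfg$trait],
                                  demo_rf_hyper(), n_perm = 10, cv_folds = 5,
                                  seed = substream_seed(WORKFLOW_SEED, paste0("sig-", cond)))
  message(sprintf("%s %s: CV R^2 %.3f vs null max %.3f",
                  cond, cfg$trait, chk$observed_r2, max(chk$null_r2)))
}

shared <- intersect(names(theta$control), names(theta$drought))
sel_ind <- select_features(theta$control[shared], theta$drought[shared],
                           cfg$theta_individual, "either")
sel_int <- select_features(theta$control[shared], theta$drought[shared],
                           cfg$theta_interaction, "both")
writeLines(sel_ind, file.path(dir, "selected_individual.txt"))
writeLines(sel_int, file.path(dir, "selected_interaction.txt"))
message("selected: ", length(sel_ind), " (individual screen), ",
        length(sel_int), " (interaction screen)")
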