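#!/usr/bin/env Rscript
# Simulate the paired control/drought multi-omics study with known ground
# truth: shared genotypes, per-condition metabolome/microbiome, nine
# correlated biomass traits, and one drought-only metabolite x taxon
# interaction planted on leaf dry weight.

source("analysis/00_config.R")

cfg <- demo_sim_config()
ps <- simulate_paired_study(cfg)

dir <- res_path("study")
write_study_dir(ps$control, file.path(dir, "control"))
write_study_dir(ps$drought, file.path(dir, "drought"))
write_ground_truth(ps$truth, file.path(dir, "ground_truth.json"))

message("accessions: ", nrow(ps$control$phenotypes),
        "; SNPs: ", ncol(ps$control$layers$genome$data),
        "; metabolites: ", ncol(ps$control$layers$metabolome$data),
        "; taxa: ", ncol(ps$control$layers$microbiome$data))
message("planted: ", paste(ps$truth$planted_interactions$feature_a,
                           ps$truth$planted_interactions$feature_b,
                           sep = " x "),
        " (", ps$truth$planted_interactions$condition, ")")
vf <- ps$truth$variance_fractions$drought["leaf_dry_weight", ]
message("drought leaf_dry_weight variance split: ",
        paste(sprintf("%s %.2f", names(vf), vf), collapse = ", "))
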