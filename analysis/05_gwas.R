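#!/usr/bin/env Rscript
# LMM GWAS baseline on leaf dry weight (control condition): GRM from the
# MAF-filtered panel, three GRM principal components as covariates, one null
# variance-component fit reused across SNPs, Wald tests, hits at p < 1e-5,
# and the overlap with the SHAP-selected SNP set.

source("analysis/00_config.R")

cfg <- run_config(seed = WORKFLOW_SEED)
study <- read_study_dir(file.path(RESULTS_DIR, "study", "control"))
study <- suppressMessages(filter_missing(study))

sel_path <- file.path(RESULTS_DIR, "rf", "selected_individual.txt")
shap_snps <- if (file.exists(sel_path)) {
  sel <- readLines(sel_path)
  sel[grepl("^Chr", sel)]
} else NULL

gw <- run_gwas(study, trait = cfg$trait, maf_min = cfg$maf_min,
               n_pcs = cfg$n_pcs, alpha = cfg$alpha, shap_snps = shap_snps)
dir <- res_path("gwas")
write_tsv(gw$scan, file.path(dir, "scan.tsv"))
write_tsv(gw$hits, file.path(dir, "hits.tsv"))
writeLines(gw$overlap, file.path(dir, "overlap_with_shap.txt"))
message(nrow(gw$hits), " hit(s) at p < ", cfg$alpha,
        "; overlap with SHAP-selected SNPs: ", length(gw$overlap))
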