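# Orchestration: configuration with the study's default thresholds, seeded
# end-to-end runs (simulate -> preprocess -> BLUP/RF/GWAS -> SHAP ->
# interaction network), a manifest with content hashes, and a
# machine-readable run report.

#' Pipeline run configuration
#'
#' Collects every stage threshold with its default: MAF 0.05, LD r^2 0.95
#' (window 100), theta screens 0.01 (individual, either condition) and 0.001
#' (interaction, both), log2 SHAP-ratio display 2.5, |Z| >= 30, B = 100
#' permutations, B_boot = 100 bootstraps, epsilon = 1e-12, stability count
#' >= 2, GWAS alpha 1e-5, trait "leaf_dry_weight". The configuration is
#' echoed verbatim into the run report.
#'
#' @param ... overrides for any default (unknown names are an error).
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    trait = "leaf_dry_weight",
    maf_min = 0.05,
    ld_r2 = 0.95,
    ld_window = 100L,
    theta_individual = 0.01,
    theta_interaction = 0.001,
    log2_ratio = 2.5,
    z_min = 30,
    n_perm = 100L,
    n_boot = 100L,
    epsilon = 1e-12,
    stability_min_count = 2L,
    alpha = 1e-5,
    n_pcs = 3L,
    cv_folds = 5L,
    seed = 1L,
    sim = NULL,     # a sim_config(); NULL means the caller provides studies
    rf_hyper = NULL,
    gbt_hyper = NULL,
    rf_grid = NULL,
    gbt_grid = NULL
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(overrides)] <- overrides
  structure(defaults, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file; @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  plain <- unclass(config)
  plain$sim <- if (!is.null(config$sim)) unclass(config$sim) else NULL
  plain$sim$planted_interactions <- if (!is.null(config$sim)) {
    as.list(config$sim$planted_interactions)
  } else NULL
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$sim)) {
    s <- raw$sim
    pi <- if (!is.null(s$planted_interactions)) {
      as.data.frame(s$planted_interactions, stringsAsFactors = FALSE)
    } else NULL
    sim <- sim_config(
      n_accessions = s$n_accessions, n_snps = s$n_snps,
      n_ld_blocks = s$n_ld_blocks, maf_range = unlist(s$maf_range),
      ld_rho = s$ld_rho, n_metabolites = s$n_metabolites, n_taxa = s$n_taxa,
      zero_prob = s$zero_prob, n_traits = s$n_traits,
      trait_names = unlist(s$trait_names),
      heritability_target = s$heritability_target, v_linear = s$v_linear,
      trait_cor = s$trait_cor, n_causal_snps = s$n_causal_snps,
      n_causal_metabolites = s$n_causal_metabolites,
      n_causal_taxa = s$n_causal_taxa, planted_interactions = pi,
      noise_sd = s$noise_sd, representative_trait = s$representative_trait,
      seed = s$seed
    )
  }
  raw$sim <- NULL
  cfg <- do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
  cfg$sim <- sim
  cfg
}

#' Preprocess one study
#'
#' Missingness filter, MAF filter and greedy LD pruning on the genome layer,
#' per-layer column scaling, and concatenation into a feature stack.
#'
#' @param study an [omics_study()]; @param config a [run_config()].
#' @return list with `study` (scaled), `stack`, `raw` (filtered, unscaled
#'   study) and `n_snps_after_maf`.
#' @export
preprocess_study <- function(study, config) {
  study <- filter_missing(study)
  geno <- maf_filter(study$layers$genome, config$maf_min)
  kept <- ld_prune(geno, config$ld_r2, config$ld_window)
  geno <- omics_layer("genome", geno$data[, kept, drop = FALSE])
  layers <- list(
    genome = layer_unchecked("genome", scale_columns(geno$data)),
    metabolome = layer_unchecked("metabolome",
                                 scale_columns(study$layers$metabolome$data)),
    microbiome = layer_unchecked("microbiome",
                                 scale_columns(study$layers$microbiome$data))
  )
  scaled <- omics_study(study$condition, layers, study$phenotypes)
  list(study = scaled, stack = build_feature_stack(scaled), raw = study,
       n_snps_after_maf = ncol(geno$data))
}

#' Run the full pipeline end to end
#'
#' Simulates (or takes) a paired study, preprocesses both conditions, runs
#' the BLUP, RF-importance and GWAS stages, the individual-SHAP screen, and
#' the differential interaction network, writing every stage output plus a
#' manifest with content hashes under `out_dir`.
#'
#' @param config a [run_config()]; `config$sim` must be a [sim_config()]
#'   unless `studies` is given.
#' @param out_dir output directory.
#' @param studies optional list with `control` and `drought`
#'   [omics_study()] objects (overrides simulation).
#' @return list of in-memory stage results; files and `manifest.tsv` are
#'   written under `out_dir`.
#' @export
run_all <- function(config, out_dir, studies = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(studies) && is.null(config$sim)) {
    stop("config$sim is NULL and no studies were provided", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  log_lines <- character(0)
  stage <- function(name, expr) {
    tic <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    log_lines <<- c(log_lines,
                    sprintf("%s\t%.2fs", name, proc.time()[["elapsed"]] - tic))
    res
  }

  truth <- NULL
  if (is.null(studies)) {
    sim <- stage("simulate", simulate_paired_study(config$sim))
    studies <- list(control = sim$control, drought = sim$drought)
    truth <- sim$truth
    write_ground_truth(truth, file.path(out_dir, "ground_truth.json"))
  }

  prep <- stage("preprocess", lapply(studies, preprocess_study, config = config))
  trait <- config$trait
  if (!trait %in% prep$control$study$trait_names) {
    stop("trait '", trait, "' not present in the study", call. = FALSE)
  }

  blup <- stage("blup", lapply(prep, function(pp) run_mkblup(pp$study)))
  for (cond in names(blup)) {
    utils::write.table(
      data.frame(trait = rownames(blup[[cond]]$vc_table),
                 blup[[cond]]$vc_table, check.names = FALSE),
      file.path(out_dir, paste0("blup_vc_", cond, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  rf <- stage("rf", lapply(names(prep), function(cond) {
    run_rf_importance(prep[[cond]]$study, hyper = config$rf_hyper,
                      grid = if (is.null(config$rf_grid)) default_rf_grid() else config$rf_grid,
                      tune_trait = trait, cv_folds = config$cv_folds,
                      seed = substream_seed(config$seed, paste0("rf-", cond)))
  }))
  names(rf) <- names(prep)
  for (cond in names(rf)) {
    utils::write.table(
      data.frame(feature = rownames(rf[[cond]]$B_rf), rf[[cond]]$B_rf,
                 theta = rf[[cond]]$theta, check.names = FALSE),
      file.path(out_dir, paste0("rf_importance_", cond, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # thetas aligned on the shared feature universe
  shared <- intersect(names(rf$control$theta), names(rf$drought$theta))
  theta_c <- rf$control$theta[shared]
  theta_d <- rf$drought$theta[shared]

  gwas <- stage("gwas", run_gwas(prep$control$raw, trait = trait,
                                 maf_min = config$maf_min, n_pcs = config$n_pcs,
                                 alpha = config$alpha))
  utils::write.table(gwas$scan, file.path(out_dir, "gwas_scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gwas$hits, file.path(out_dir, "gwas_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  shap <- stage("shap_individual", run_shap_individual(
    prep$control$stack, prep$drought$stack,
    prep$control$study$phenotypes[, trait],
    prep$drought$study$phenotypes[, trait],
    theta_c, theta_d, hyper = rf$control$hyper,
    threshold = config$theta_individual,
    ratio_threshold = config$log2_ratio,
    seed = substream_seed(config$seed, "shap")))
  utils::write.table(shap$summary, file.path(out_dir, "shap_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  net <- stage("interactions", run_interaction_network(
    prep$control$stack, prep$drought$stack,
    prep$control$study$phenotypes[, trait],
    prep$drought$study$phenotypes[, trait],
    theta_c, theta_d, hyper = config$gbt_hyper,
    grid = if (is.null(config$gbt_grid)) default_gbt_grid() else config$gbt_grid,
    theta_min = config$theta_interaction, z_min = config$z_min,
    n_perm = config$n_perm, n_boot = config$n_boot,
    epsilon = config$epsilon, min_count = config$stability_min_count,
    cv_folds = config$cv_folds, seed = substream_seed(config$seed, "net")))
  export_network(net$network_stable, out_dir, "network")
  jsonlite::write_json(list(mu0 = net$null$mu0, sigma0 = net$null$sigma0,
                            B = config$n_perm),
                       file.path(out_dir, "null_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  writeLines(log_lines, file.path(out_dir, "stages.log"))
  # stages.log carries wall-clock timings; the manifest hashes only the
  # deterministic outputs
  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   c("manifest.tsv", "stages.log"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  result <- list(config = config, truth = truth, prep = prep, blup = blup,
                 rf = rf, theta = list(control = theta_c, drought = theta_d),
                 gwas = gwas, shap = shap, net = net, out_dir = out_dir,
                 elapsed = proc.time()[["elapsed"]] - t0)
  invisible(result)
}

#' Write the machine-readable run report
#'
#' Summarizes a completed [run_all()] result: feature counts after every
#' filter, theta-selection sizes, GWAS hits, top SHAP-ratio features, network
#' edge count and density (edges / C(p', 2)), per-edge statistics, and the
#' exact thresholds used.
#'
#' @param result the list returned by [run_all()].
#' @param path output JSON path (default `report.json` in the run directory).
#' @return the report list, invisibly; the JSON file is written to `path`.
#' @export
write_report <- function(result, path = file.path(result$out_dir, "report.json")) {
  needed <- c("config", "prep", "rf", "gwas", "shap", "net")
  missing <- needed[!vapply(needed, function(f) !is.null(result[[f]]), logical(1))]
  if (length(missing)) {
    stop("incomplete run; missing stage(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cfg <- result$config
  p_universe <- length(result$net$universe)
  edges <- result$net$network_stable$edges
  report <- list(
    thresholds = unclass(cfg)[c("trait", "maf_min", "ld_r2", "ld_window",
                                "theta_individual", "theta_interaction",
                                "log2_ratio", "z_min", "n_perm", "n_boot",
                                "epsilon", "stability_min_count", "alpha",
                                "n_pcs", "seed")],
    feature_counts = lapply(result$prep, function(pp) {
      c(lapply(pp$study$layers, function(l) ncol(l$data)),
        list(n_snps_after_maf = pp$n_snps_after_maf,
             stacked = ncol(pp$stack$matrix)))
    }),
    theta_selection = list(
      individual = length(select_features(result$theta$control,
                                          result$theta$drought,
                                          cfg$theta_individual, "either")),
      interaction = p_universe
    ),
    gwas_hits = result$gwas$hits$id,
    top_shap_ratio = utils::head(
      result$shap$summary$feature[result$shap$summary$display], 20),
    network = list(
      n_nodes = nrow(result$net$network_stable$nodes),
      n_edges = nrow(edges),
      density = network_density(nrow(edges), p_universe),
      null = list(mu0 = result$net$null$mu0, sigma0 = result$net$null$sigma0),
      edges = edges
    )
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
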