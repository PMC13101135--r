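# Synthetic paired-study generator: LD structure, compositional closure,
# condition gating, variance accounting, determinism.

test_that("invalid configurations are rejected", {
  expect_error(simulate_genotypes(1, 5, 1), ">= 2")
  expect_error(simulate_genotypes(10, 2, 5), "blocks")
  expect_error(simulate_genotypes(10, 5, 1, maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulate_genotypes(10, 5, 1, maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(zero_prob = 1), "zero_prob")
  expect_error(sim_config(heritability_target = 1), "heritability_target")
  expect_error(sim_config(planted_interactions = data.frame(
    feature_a = "a", feature_b = "b", condition = "wet", effect_size = 1)),
    "condition")
})

test_that("genotypes are dosages with block LD and MAF control", {
  G <- simulate_genotypes(300, 40, 4, c(0.1, 0.5), seed = 7)
  expect_true(all(G %in% 0:2))
  f <- colMeans(G) / 2
  expect_true(all(pmin(f, 1 - f) >= 0.1))
  expect_identical(G, simulate_genotypes(300, 40, 4, c(0.1, 0.5), seed = 7))

  # perfect copy rule: one block, shared haplotype signal, identical columns
  G1 <- simulate_genotypes(50, 2, 1, c(0.2, 0.4), seed = 3, ld_rho = 1)
  expect_identical(unname(G1[, 1]), unname(G1[, 2]))
  expect_equal(cor(G1[, 1], G1[, 2])^2, 1)
})

test_that("within-block r^2 exceeds cross-block r^2", {
  G <- simulate_genotypes(2000, 40, 10, c(0.1, 0.5), seed = 13)
  blk <- attr(G, "block")
  r2 <- cor(G)^2
  same <- outer(blk, blk, "==") & upper.tri(r2)
  diff_blk <- outer(blk, blk, "!=") & upper.tri(r2)
  expect_gt(mean(r2[same]), mean(r2[diff_blk]) + 0.2)
  expect_lt(mean(r2[diff_blk]), 0.05)
})

test_that("metabolome intensities are positive log-normal", {
  M <- simulate_metabolome(5000, 4, seed = 2, log_mean = 0, log_sd = 1)
  expect_true(all(M > 0))
  lm_ <- colMeans(log(M))
  ls_ <- apply(log(M), 2, sd)
  expect_true(all(abs(lm_) < 0.1))
  expect_true(all(abs(ls_ - 1) < 0.1))
  expect_identical(M, simulate_metabolome(5000, 4, seed = 2))
})

test_that("microbiome rows are compositional with controlled zero fraction", {
  A0 <- simulate_microbiome(50, 10, zero_prob = 0, seed = 1)
  expect_true(all(A0 > 0))
  expect_true(all(abs(rowSums(A0) - 1) < 1e-9))

  A <- simulate_microbiome(1000, 50, zero_prob = 0.4, seed = 4)
  expect_true(all(abs(rowSums(A) - 1) < 1e-9))
  expect_true(all(rowSums(A > 0) >= 1))
  expect_lt(abs(mean(A == 0) - 0.4), 0.03)
})

test_that("null phenotypes are pure standard normal noise", {
  ps <- tiny_paired_study()
  G <- ps$control$layers$genome$data
  M <- ps$control$layers$metabolome$data
  A <- ps$control$layers$microbiome$data
  truth <- list(causal_snp_ids = character(0),
                causal_metabolite_ids = character(0),
                causal_taxon_ids = character(0),
                snp_effects = NULL, metabolite_effects = NULL,
                taxon_effects = NULL,
                heritability_target = 0, v_linear = 0, trait_cor = 0,
                trait_names = c("t1", "t2"), planted_interactions = NULL,
                representative_trait = "t1")
  sim <- simulate_phenotypes(G, M, A, truth, "control", noise_sd = 1, seed = 9)
  expect_equal(unname(apply(sim$phenotypes, 2, var)), c(1, 1), tolerance = 0.4)
  expect_equal(unname(sim$truth$variance_fractions[, "noise"]), c(1, 1),
               tolerance = 1e-9)
})

test_that("planted interactions are condition-gated exactly", {
  ps <- tiny_paired_study()
  # same truth, same seed, only the condition label differs
  frac_c <- ps$truth$variance_fractions$control["leaf_dry_weight", "interaction"]
  frac_d <- ps$truth$variance_fractions$drought["leaf_dry_weight", "interaction"]
  expect_identical(unname(frac_c), 0)
  expect_gt(frac_d, 0.1)
  # absent planted ids raise an invalid-config error
  truth <- ps$truth
  truth$planted_interactions$feature_a <- "no_such_feature"
  expect_error(
    simulate_phenotypes(ps$control$layers$genome$data,
                        ps$control$layers$metabolome$data,
                        ps$control$layers$microbiome$data,
                        truth, "drought", seed = 1),
    "no_such_feature")
})

test_that("single causal SNP at target heritability 0.5 gives R^2 ~ 0.5", {
  G <- simulate_genotypes(2000, 5, 5, c(0.2, 0.5), seed = 31)
  M <- simulate_metabolome(2000, 2, seed = 32)
  A <- simulate_microbiome(2000, 3, zero_prob = 0, seed = 33)
  truth <- list(causal_snp_ids = colnames(G)[1],
                causal_metabolite_ids = character(0),
                causal_taxon_ids = character(0),
                snp_effects = matrix(1, 1, 1,
                                     dimnames = list(colnames(G)[1], "t1")),
                metabolite_effects = NULL, taxon_effects = NULL,
                heritability_target = 0.5, v_linear = 0, trait_cor = 0,
                trait_names = "t1", planted_interactions = NULL,
                representative_trait = "t1")
  sim <- simulate_phenotypes(G, M, A, truth, "control", noise_sd = sqrt(0.5),
                             seed = 34)
  r2 <- summary(lm(sim$phenotypes[, 1] ~ G[, 1]))$r.squared
  expect_lt(abs(r2 - 0.5), 0.05)
})

test_that("paired studies share accessions and genotypes, and are deterministic", {
  ps <- tiny_paired_study()
  expect_identical(rownames(ps$control$phenotypes),
                   rownames(ps$drought$phenotypes))
  expect_identical(ps$control$layers$genome$data, ps$drought$layers$genome$data)
  expect_identical(colnames(ps$control$layers$metabolome$data),
                   colnames(ps$drought$layers$metabolome$data))
  ps2 <- simulate_paired_study(tiny_sim_config())
  expect_identical(ps$control$phenotypes, ps2$control$phenotypes)
  expect_identical(ps$drought$layers$microbiome$data,
                   ps2$drought$layers$microbiome$data)
})

test_that("realized additive variance tracks the heritability target at n = 1000", {
  cfg <- sim_config(n_accessions = 1000, n_snps = 80, n_ld_blocks = 8,
                    n_metabolites = 10, n_taxa = 12, seed = 41,
                    planted_interactions = NULL)
  ps <- simulate_paired_study(cfg)
  frac <- ps$truth$variance_fractions$control[, "genetic"]
  expect_true(all(abs(frac - cfg$heritability_target) < 0.1))
})
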