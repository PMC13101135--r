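# Synthetic two-condition multi-omics studies with known ground truth.
#
# The generator emulates the design of a paired field study: one shared
# genotype panel, per-condition rhizosphere metabolome and microbiome layers,
# and correlated biomass traits built from additive SNP effects, linear omics
# effects, and condition-specific metabolite x taxon product interactions.

TRAIT_NAMES_DEFAULT <- c(
  "shoot_fresh_weight", "shoot_dry_weight", "leaf_fresh_weight",
  "leaf_dry_weight", "growth_stage", "plant_height", "main_stem_length",
  "n_nodes", "n_branches"
)

#' Simulation configuration
#'
#' Defines one paired (control/drought) synthetic study. Defaults describe the
#' package's reference study: 200 accessions, 300 SNPs in 10 LD blocks with
#' MAF in \[0.05, 0.5\], 50 log-normal metabolites, 80 zero-inflated
#' compositional taxa, 9 correlated biomass traits with additive-genetic
#' variance fraction 0.3 and one drought-only metabolite x taxon interaction
#' strong enough to explain roughly a fifth of the drought trait variance.
#'
#' @param n_accessions number of accessions shared by the two conditions.
#' @param n_snps,n_ld_blocks genotype panel size and number of LD blocks.
#' @param maf_range target minor-allele-frequency interval, within (0, 0.5].
#' @param ld_rho within-block latent haplotype correlation; `1` makes every
#'   SNP in a block an exact copy of the block haplotype.
#' @param n_metabolites,n_taxa widths of the metabolome/microbiome layers.
#' @param zero_prob probability of a structural zero per microbiome cell.
#' @param n_traits number of phenotypes (default 9).
#' @param trait_names trait labels; must have length `n_traits`.
#' @param heritability_target fraction of trait variance from additive SNP
#'   effects, in \[0, 1).
#' @param v_linear variance contributed by linear metabolite/taxon effects.
#' @param trait_cor compound-symmetry correlation of the trait residuals.
#' @param n_causal_snps,n_causal_metabolites,n_causal_taxa causal feature counts.
#' @param planted_interactions data.frame with columns `feature_a`,
#'   `feature_b`, `condition`, `effect_size` and optionally `trait`; each row
#'   plants one pairwise product interaction active only in that condition.
#' @param noise_sd residual standard deviation of each trait.
#' @param representative_trait trait receiving planted interactions when a row
#'   has no `trait` entry (default `"leaf_dry_weight"`).
#' @param seed base RNG seed fanned out to per-stage streams.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_accessions = 200, n_snps = 300, n_ld_blocks = 10,
                       maf_range = c(0.05, 0.5), ld_rho = 0.95,
                       n_metabolites = 50, n_taxa = 80, zero_prob = 0.3,
                       n_traits = 9, trait_names = NULL,
                       heritability_target = 0.3, v_linear = 0.2,
                       trait_cor = 0.3,
                       n_causal_snps = 10, n_causal_metabolites = 5,
                       n_causal_taxa = 5,
                       planted_interactions = default_planted_interactions(),
                       noise_sd = sqrt(0.5),
                       representative_trait = "leaf_dry_weight",
                       seed = 1L) {
  assert_count(n_accessions, "n_accessions", min = 2L)
  assert_count(n_snps, "n_snps")
  assert_count(n_ld_blocks, "n_ld_blocks")
  assert_count(n_metabolites, "n_metabolites")
  assert_count(n_taxa, "n_taxa", min = 2L)
  assert_count(n_traits, "n_traits")
  assert_prob(zero_prob, "zero_prob", closed_upper = FALSE)
  assert_prob(heritability_target, "heritability_target", closed_upper = FALSE)
  if (n_snps < n_ld_blocks) stop("`n_snps` must be >= `n_ld_blocks`", call. = FALSE)
  if (length(maf_range) != 2L || any(!is.finite(maf_range)) ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("`maf_range` must be an interval within (0, 0.5]", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (is.null(trait_names)) {
    trait_names <- if (n_traits <= length(TRAIT_NAMES_DEFAULT)) {
      TRAIT_NAMES_DEFAULT[seq_len(n_traits)]
    } else sprintf("trait_%02d", seq_len(n_traits))
  }
  stopifnot(length(trait_names) == n_traits)
  if (!is.null(planted_interactions) && nrow(planted_interactions) > 0) {
    needed <- c("feature_a", "feature_b", "condition", "effect_size")
    if (!all(needed %in% names(planted_interactions))) {
      stop("`planted_interactions` needs columns ",
           paste(needed, collapse = ", "), call. = FALSE)
    }
    if (any(!is.finite(planted_interactions$effect_size))) {
      stop("planted effect sizes must be finite", call. = FALSE)
    }
    if (!all(planted_interactions$condition %in% c("control", "drought"))) {
      stop("planted interaction `condition` must be 'control' or 'drought'",
           call. = FALSE)
    }
  }
  structure(list(
    n_accessions = as.integer(n_accessions), n_snps = as.integer(n_snps),
    n_ld_blocks = as.integer(n_ld_blocks), maf_range = maf_range,
    ld_rho = ld_rho, n_metabolites = as.integer(n_metabolites),
    n_taxa = as.integer(n_taxa), zero_prob = zero_prob,
    n_traits = as.integer(n_traits), trait_names = trait_names,
    heritability_target = heritability_target, v_linear = v_linear,
    trait_cor = trait_cor, n_causal_snps = as.integer(n_causal_snps),
    n_causal_metabolites = as.integer(n_causal_metabolites),
    n_causal_taxa = as.integer(n_causal_taxa),
    planted_interactions = planted_interactions, noise_sd = noise_sd,
    representative_trait = representative_trait, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_planted_interactions <- function() {
  data.frame(
    feature_a = "met_001", feature_b = "taxon_001",
    condition = "drought", effect_size = 0.55,
    trait = "leaf_dry_weight", stringsAsFactors = FALSE
  )
}

#' Simulate a genotype panel with block LD structure
#'
#' Dosages in \{0,1,2\} arise from two latent haplotypes per LD block: each
#' allele is a threshold crossing of `ld_rho * block_haplotype +
#' sqrt(1 - ld_rho^2) * snp_noise`, so SNPs in a block share high pairwise r^2
#' while cross-block r^2 is zero in expectation. SNPs whose realized sample
#' MAF falls below `maf_range[1]` are rejection-resampled. With `ld_rho = 1`
#' every SNP in a block is an exact copy of the block haplotype signal.
#'
#' @param n accessions (>= 2); @param m SNPs; @param blocks LD blocks (m >= blocks).
#' @param maf_range target MAF interval within (0, 0.5].
#' @param seed RNG seed; @param ld_rho within-block haplotype correlation.
#' @return n x m integer matrix with accession rownames and "ChrXX-pos" SNP
#'   colnames; LD-block assignment in `attr(, "block")`.
#' @export
simulate_genotypes <- function(n, m, blocks, maf_range = c(0.05, 0.5),
                               seed = 1L, ld_rho = 0.95) {
  assert_count(n, "n", min = 2L)
  assert_count(m, "m")
  assert_count(blocks, "blocks")
  if (m < blocks) stop("`m` must be >= `blocks`", call. = FALSE)
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("`maf_range` must be an interval within (0, 0.5]", call. = FALSE)
  }
  block_of <- sort(rep_len(seq_len(blocks), m))
  snp_ids <- character(m)
  pos <- 0L
  for (j in seq_len(m)) {
    chrom <- (block_of[j] - 1L) %% 20L + 1L
    pos <- if (j > 1L && block_of[j] != block_of[j - 1L]) 10000L else pos + 997L
    snp_ids[j] <- sprintf("Chr%02d-%d", chrom, pos + block_of[j] * 100000L)
  }
  acc_ids <- sprintf("acc_%03d", seq_len(n))
  with_stream(seed, {
    G <- matrix(0L, n, m, dimnames = list(acc_ids, snp_ids))
    for (b in seq_len(blocks)) {
      cols <- which(block_of == b)
      repeat {
        h1 <- stats::rnorm(n)
        h2 <- stats::rnorm(n)
        p_blk <- stats::runif(1, maf_range[1], maf_range[2])
        ok <- TRUE
        for (j in cols) {
          p_j <- if (ld_rho >= 1) p_blk else stats::runif(1, maf_range[1], maf_range[2])
          thr <- stats::qnorm(p_j)
          for (attempt in seq_len(200L)) {
            if (ld_rho >= 1) {
              a1 <- as.integer(h1 < thr); a2 <- as.integer(h2 < thr)
            } else {
              s <- sqrt(1 - ld_rho^2)
              a1 <- as.integer(ld_rho * h1 + s * stats::rnorm(n) < thr)
              a2 <- as.integer(ld_rho * h2 + s * stats::rnorm(n) < thr)
            }
            d <- a1 + a2
            f <- mean(d) / 2
            if (min(f, 1 - f) >= maf_range[1]) break
            if (ld_rho >= 1) break # copy rule: resample the whole block instead
          }
          f <- mean(a1 + a2) / 2
          if (min(f, 1 - f) < maf_range[1]) { ok <- FALSE; break }
          G[, j] <- a1 + a2
        }
        if (ok) break
      }
    }
    attr(G, "block") <- block_of
    G
  })
}

#' Simulate positive log-normal metabolite intensities
#'
#' @param n accessions; @param k metabolites; @param seed RNG seed.
#' @param log_mean,log_sd per-feature log-scale moments (recycled to length k).
#' @return n x k positive matrix ("met_###" colnames).
#' @export
simulate_metabolome <- function(n, k, seed = 1L, log_mean = 0, log_sd = 1) {
  assert_count(n, "n")
  assert_count(k, "k")
  log_mean <- rep_len(log_mean, k)
  log_sd <- rep_len(log_sd, k)
  with_stream(seed, {
    M <- vapply(seq_len(k), function(j) exp(stats::rnorm(n, log_mean[j], log_sd[j])),
                numeric(n))
    dimnames(M) <- list(sprintf("acc_%03d", seq_len(n)), sprintf("met_%03d", seq_len(k)))
    M
  })
}

#' Simulate zero-inflated compositional microbiome profiles
#'
#' Latent log-normal abundances are hit by independent structural zeros with
#' probability `zero_prob`, rows left all-zero are resampled, and each row is
#' renormalized to sum to one (relative abundances).
#'
#' @param n accessions; @param t taxa (>= 2); @param zero_prob zero probability.
#' @param seed RNG seed.
#' @return n x t matrix with non-negative entries and unit row sums.
#' @export
simulate_microbiome <- function(n, t, zero_prob = 0.3, seed = 1L) {
  assert_count(n, "n")
  assert_count(t, "t", min = 2L)
  assert_prob(zero_prob, "zero_prob", closed_upper = FALSE)
  with_stream(seed, {
    A <- matrix(0, n, t,
                dimnames = list(sprintf("acc_%03d", seq_len(n)),
                                sprintf("taxon_%03d", seq_len(t))))
    for (i in seq_len(n)) {
      repeat {
        lat <- exp(stats::rnorm(t, 0, 1.5))
        keep <- stats::rbinom(t, 1L, 1 - zero_prob)
        row <- lat * keep
        if (sum(row) > 0) break
      }
      A[i, ] <- row / sum(row)
    }
    A
  })
}

# Draw shared causal-effect structure for one paired study. Features named in
# planted interactions are always part of the causal linear sets: interacting
# features in the emulated study were individually important (they must pass
# the theta importance screen), and a pure product of standardized features
# has no marginal signal for an importance screen or a greedy tree to find.
draw_ground_truth <- function(config, geno_ids, met_ids, taxon_ids, seed) {
  planted_feats <- if (!is.null(config$planted_interactions)) {
    unique(c(config$planted_interactions$feature_a,
             config$planted_interactions$feature_b))
  } else character(0)
  with_stream(seed, {
    causal_snps <- if (config$n_causal_snps > 0) {
      sort(sample(geno_ids, min(config$n_causal_snps, length(geno_ids))))
    } else character(0)
    causal_met <- if (config$n_causal_metabolites > 0) {
      sort(sample(met_ids, min(config$n_causal_metabolites, length(met_ids))))
    } else character(0)
    causal_tax <- if (config$n_causal_taxa > 0) {
      sort(sample(taxon_ids, min(config$n_causal_taxa, length(taxon_ids))))
    } else character(0)
    causal_snps <- sort(union(causal_snps, intersect(planted_feats, geno_ids)))
    causal_met <- sort(union(causal_met, intersect(planted_feats, met_ids)))
    causal_tax <- sort(union(causal_tax, intersect(planted_feats, taxon_ids)))
    q <- config$n_traits
    draw_effects <- function(ids) {
      eff <- matrix(stats::rnorm(length(ids) * q), length(ids), q,
                    dimnames = list(ids, config$trait_names))
      # planted features get unit-scale effects (the draw's RMS) instead of a
      # chance draw, so their individual importance never degenerates to zero
      eff[rownames(eff) %in% planted_feats, ] <- 1
      eff
    }
    list(
      causal_snp_ids = causal_snps,
      causal_metabolite_ids = causal_met,
      causal_taxon_ids = causal_tax,
      snp_effects = draw_effects(causal_snps),
      metabolite_effects = draw_effects(causal_met),
      taxon_effects = draw_effects(causal_tax),
      heritability_target = config$heritability_target,
      v_linear = config$v_linear,
      trait_cor = config$trait_cor,
      trait_names = config$trait_names,
      planted_interactions = config$planted_interactions,
      representative_trait = config$representative_trait
    )
  })
}

# Standardize columns (divisor n); constant columns map to zero columns.
std_cols_safe <- function(x) {
  s <- col_sd_pop(x)
  s[s == 0] <- Inf
  sweep(sweep(x, 2, colMeans(x)), 2, s, "/")
}

# Rescale a component vector to a target population variance (0 stays 0).
scale_to_var <- function(v, target_var) {
  s <- stats::sd(v) * sqrt((length(v) - 1) / length(v))
  if (s == 0 || target_var <= 0) return(v * 0)
  v / s * sqrt(target_var)
}

#' Simulate correlated phenotypes from multi-omics layers
#'
#' Each trait is a sum of additive SNP effects (rescaled so their sample
#' variance matches `heritability_target`), linear metabolite/taxon effects
#' (variance `v_linear`), planted pairwise product interactions of
#' column-standardized features (active only when `condition` matches the
#' planted condition), and Gaussian noise correlated across traits.
#'
#' @param genotypes,metabolome,microbiome aligned accession x feature matrices.
#' @param truth a truth spec from [draw_ground_truth()] / [simulate_paired_study()].
#' @param condition `"control"` or `"drought"`.
#' @param noise_sd residual SD; @param seed RNG seed.
#' @return list with `phenotypes` (n x q) and `truth` (realized ground truth,
#'   condition-labeled, including variance fractions per trait).
#' @export
simulate_phenotypes <- function(genotypes, metabolome, microbiome, truth,
                                condition, noise_sd = sqrt(0.5), seed = 1L) {
  stopifnot(identical(rownames(genotypes), rownames(metabolome)),
            identical(rownames(genotypes), rownames(microbiome)))
  n <- nrow(genotypes)
  q <- length(truth$trait_names)
  planted <- truth$planted_interactions
  if (!is.null(planted) && nrow(planted) > 0) {
    universe <- c(colnames(genotypes), colnames(metabolome), colnames(microbiome))
    missing <- setdiff(unique(c(planted$feature_a, planted$feature_b)), universe)
    if (length(missing) > 0) {
      stop("planted interaction features not present in any layer: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  Gs <- std_cols_safe(genotypes[, truth$causal_snp_ids, drop = FALSE])
  Ms <- std_cols_safe(metabolome[, truth$causal_metabolite_ids, drop = FALSE])
  Ts <- std_cols_safe(microbiome[, truth$causal_taxon_ids, drop = FALSE])
  all_std <- cbind(std_cols_safe(genotypes), std_cols_safe(metabolome),
                   std_cols_safe(microbiome))
  rep_trait <- if (truth$representative_trait %in% truth$trait_names) {
    truth$representative_trait
  } else truth$trait_names[1]

  with_stream(seed, {
    E <- matrix(stats::rnorm(n * q), n, q)
    if (q > 1 && truth$trait_cor != 0) {
      R <- matrix(truth$trait_cor, q, q); diag(R) <- 1
      E <- E %*% chol(R)
    }
    E <- E * noise_sd
    Y <- matrix(0, n, q, dimnames = list(rownames(genotypes), truth$trait_names))
    frac <- matrix(0, q, 4, dimnames = list(truth$trait_names,
                                            c("genetic", "linear", "interaction", "noise")))
    for (j in seq_len(q)) {
      g <- if (ncol(Gs) > 0) {
        scale_to_var(drop(Gs %*% truth$snp_effects[, j]), truth$heritability_target)
      } else numeric(n)
      lin_raw <- numeric(n)
      if (ncol(Ms) > 0) lin_raw <- lin_raw + drop(Ms %*% truth$metabolite_effects[, j])
      if (ncol(Ts) > 0) lin_raw <- lin_raw + drop(Ts %*% truth$taxon_effects[, j])
      lin <- scale_to_var(lin_raw, truth$v_linear)
      inter <- numeric(n)
      if (!is.null(planted) && nrow(planted) > 0) {
        for (r in seq_len(nrow(planted))) {
          target <- if ("trait" %in% names(planted) && !is.na(planted$trait[r])) {
            planted$trait[r]
          } else rep_trait
          if (planted$condition[r] != condition || target != truth$trait_names[j]) next
          # gated product: feature_b (e.g. the taxon) acts as a presence
          # gate on feature_a's effect — the pair's contribution is
          # feature_a where feature_b is high and nothing where it is low.
          # feature_a keeps the marginal signal an importance screen and a
          # greedy tree need, while most of the term's variance stays pure
          # interaction.
          z <- all_std[, planted$feature_a[r]] *
            pmax(all_std[, planted$feature_b[r]], 0)
          inter <- inter + planted$effect_size[r] * scale_to_var(z, 1)
        }
      }
      y <- g + lin + inter + E[, j]
      Y[, j] <- y
      vp <- function(v) stats::var(v) * (n - 1) / n
      frac[j, ] <- c(vp(g), vp(lin), vp(inter), vp(E[, j])) / vp(y)
    }
    realized <- truth
    realized$condition <- condition
    realized$variance_fractions <- frac
    list(phenotypes = Y, truth = realized)
  })
}

#' Simulate a paired control/drought multi-omics study
#'
#' The two conditions share the genotype matrix, accession ids, feature ids
#' and causal-effect structure; metabolome and microbiome layers and trait
#' noise are re-drawn per condition, and planted interactions act only in
#' their labeled condition.
#'
#' @param config a [sim_config()].
#' @return list with `control` and `drought` [omics_study()] objects and
#'   `truth` (condition-labeled realized ground truth).
#' @export
simulate_paired_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  G <- simulate_genotypes(config$n_accessions, config$n_snps, config$n_ld_blocks,
                          config$maf_range, seed = substream_seed(config$seed, "geno"),
                          ld_rho = config$ld_rho)
  studies <- list()
  truths <- list()
  truth_spec <- NULL
  for (cond in c("control", "drought")) {
    M <- simulate_metabolome(config$n_accessions, config$n_metabolites,
                             seed = substream_seed(config$seed, paste0("metab-", cond)))
    A <- simulate_microbiome(config$n_accessions, config$n_taxa, config$zero_prob,
                             seed = substream_seed(config$seed, paste0("micro-", cond)))
    if (is.null(truth_spec)) {
      truth_spec <- draw_ground_truth(config, colnames(G), colnames(M), colnames(A),
                                    seed = substream_seed(config$seed, "effects"))
    }
    sim <- simulate_phenotypes(G, M, A, truth_spec, cond, config$noise_sd,
                               seed = substream_seed(config$seed, paste0("pheno-", cond)))
    studies[[cond]] <- omics_study(
      condition = cond,
      layers = list(
        genome = omics_layer("genome", G),
        metabolome = omics_layer("metabolome", M),
        microbiome = omics_layer("microbiome", A)
      ),
      phenotypes = sim$phenotypes
    )
    truths[[cond]] <- sim$truth
  }
  truth <- truths$control
  truth$condition <- NULL
  truth$variance_fractions <- list(control = truths$control$variance_fractions,
                                   drought = truths$drought$variance_fractions)
  list(control = studies$control, drought = studies$drought, truth = truth)
}

#' Write ground truth as JSON
#'
#' @param truth realized ground truth from [simulate_paired_study()].
#' @param path output file.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth
  out$variance_fractions <- lapply(truth$variance_fractions, function(m) {
    if (is.matrix(m)) as.data.frame(m) else m
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
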