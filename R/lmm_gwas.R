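# Single-SNP association scan under a linear mixed model: GRM, genotype PCs
# as covariates, one null variance-component fit reused across SNPs
# (EMMAX-style), GLS per SNP with a Wald test.

#' Genomic relationship matrix
#'
#' `GRM = W W' / m` with W the column-standardized (divisor n) dosage matrix.
#' Monomorphic SNPs must be removed first (see [maf_filter()]).
#'
#' @param genotypes complete accession x SNP dosage matrix or genome layer.
#' @return symmetric PSD n x n matrix.
#' @export
compute_grm <- function(genotypes) {
  G <- if (inherits(genotypes, "omics_layer")) genotypes$data else genotypes
  if (anyNA(G)) stop("genotypes must be complete", call. = FALSE)
  s <- col_sd_pop(G)
  if (any(s == 0)) {
    stop("monomorphic SNP(s) present; apply maf_filter first: ",
         paste(utils::head(colnames(G)[s == 0], 5), collapse = ", "), call. = FALSE)
  }
  W <- sweep(sweep(G, 2, colMeans(G)), 2, s, "/")
  tcrossprod(W) / ncol(W)
}

#' Principal-component covariates from the GRM
#'
#' @param grm n x n relationship matrix.
#' @param k number of components (0 <= k < n; default 3).
#' @return n x k matrix of unit-norm eigenvectors, ordered by eigenvalue.
#' @export
pca_covariates <- function(grm, k = 3L) {
  n <- nrow(grm)
  if (k >= n) stop("k must be < n", call. = FALSE)
  if (k == 0L) return(matrix(numeric(0), n, 0))
  es <- eigen(grm, symmetric = TRUE)
  pcs <- es$vectors[, seq_len(k), drop = FALSE]
  colnames(pcs) <- paste0("PC", seq_len(k))
  rownames(pcs) <- rownames(grm)
  pcs
}

#' Mixed-model association scan
#'
#' Variance components `(sigma_g^2, sigma_e^2)` are estimated once under the
#' null model (intercept + covariates + GRM random effect); each SNP is then
#' tested by GLS regression of the response on `[1, covariates, SNP]` under
#' the fitted covariance, with a Wald t-test. MAF filtering (default 0.05) is
#' assumed already applied; per-SNP MAF is reported.
#'
#' @param y complete response vector.
#' @param genotypes complete accession x SNP dosage matrix or genome layer.
#' @param covariates optional n x k covariate matrix (e.g. [pca_covariates()]).
#' @param grm relationship matrix from [compute_grm()].
#' @return data.frame with `id`, `beta`, `se`, `p`, `maf`, sorted as input.
#' @export
lmm_scan <- function(y, genotypes, covariates = NULL, grm) {
  G <- if (inherits(genotypes, "omics_layer")) genotypes$data else genotypes
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(G) == n, nrow(grm) == n)
  if (anyNA(y) || anyNA(G)) stop("inputs must be complete", call. = FALSE)
  X0 <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates) && ncol(covariates) > 0) X0 <- cbind(X0, covariates)
  if (qr(X0)$rank < ncol(X0)) stop("singular covariate block", call. = FALSE)

  fit <- fit_multikernel_lmm(y, list(grm = grm))
  sg <- fit$components$sigma2[["grm"]]
  se2 <- fit$components$sigma2_e

  es <- eigen(grm, symmetric = TRUE)
  d <- sg * pmax(es$values, 0) + se2
  Tm <- sweep(t(es$vectors), 1, sqrt(d), "/") # whitening: V^{-1/2'} rows
  yw <- drop(Tm %*% y)
  Xw <- Tm %*% X0
  Gw <- Tm %*% G
  qr0 <- qr(Xw)
  ry <- qr.resid(qr0, yw)
  RG <- qr.resid(qr0, Gw)
  gg <- colSums(RG^2)
  gy <- colSums(RG * ry)
  beta <- gy / gg
  df <- n - ncol(X0) - 1L
  rss <- sum(ry^2) - beta * gy
  sigma2_hat <- pmax(rss, 0) / df
  se <- sqrt(sigma2_hat / gg)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  f <- colMeans(G) / 2
  data.frame(id = colnames(G), beta = beta, se = se, p = p,
             maf = pmin(f, 1 - f), row.names = NULL, stringsAsFactors = FALSE)
}

#' Significant GWAS hits
#'
#' @param result a [lmm_scan()] data.frame.
#' @param alpha strict significance threshold (default 1e-5).
#' @return hits with `p < alpha`, sorted by ascending p.
#' @export
significant_hits <- function(result, alpha = 1e-5) {
  hits <- result[result$p < alpha, , drop = FALSE]
  hits[order(hits$p), , drop = FALSE]
}

#' Run the GWAS stage on one study
#'
#' MAF-filters the genome layer, computes GRM and PCs, scans the
#' representative trait and reports hits plus the overlap with a set of
#' SHAP-selected SNPs when given.
#'
#' @param study complete [omics_study()]; @param trait trait name.
#' @param maf_min MAF threshold; @param n_pcs number of GRM PCs.
#' @param alpha significance threshold; @param shap_snps optional SNP id set.
#' @return list with `scan`, `hits`, and `overlap` (ids in both hit list and
#'   `shap_snps`).
#' @export
run_gwas <- function(study, trait = "leaf_dry_weight", maf_min = 0.05,
                     n_pcs = 3L, alpha = 1e-5, shap_snps = NULL) {
  stopifnot(inherits(study, "omics_study"), trait %in% study$trait_names)
  geno <- maf_filter(study$layers$genome, maf_min)
  grm <- compute_grm(geno)
  pcs <- pca_covariates(grm, n_pcs)
  scan <- lmm_scan(study$phenotypes[, trait], geno, pcs, grm)
  hits <- significant_hits(scan, alpha)
  overlap <- if (is.null(shap_snps)) character(0) else intersect(hits$id, shap_snps)
  list(scan = scan, hits = hits, overlap = overlap)
}
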