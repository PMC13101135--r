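# Shared fixtures, built in code and cached per test session.

tiny_sim_config <- function(seed = 11, ...) {
  sim_config(n_accessions = 80, n_snps = 60, n_ld_blocks = 5,
             n_metabolites = 15, n_taxa = 20, seed = seed, ...)
}

# One small paired study reused across test files.
tiny_paired_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_paired_study(tiny_sim_config())
    cache
  }
})

tiny_rf_hyper <- function() list(num_trees = 100, mtry_frac = 1 / 3, min_node = 5)

tiny_gbt_hyper <- function() list(max_depth = 2, eta = 0.3, nrounds = 40,
                                  subsample = 0.8)

# A deterministic small regression problem with an interaction, shared by the
# SHAP and network tests.
tiny_xy <- function(n = 120, p = 8, seed = 5, interaction = TRUE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  y <- 0.8 * X[, 1] + if (interaction) 1.2 * X[, 2] * X[, 3] else 0
  y <- y + rnorm(n, sd = 0.3)
  list(X = X, y = y)
}

# Independent REML oracle: single kernel + residual, profiled restricted
# likelihood over the variance ratio on the kernel eigenbasis, optimized by
# stats::optimize. Shares no code with fit_multikernel_lmm.
reml_oracle_1k <- function(y, K) {
  n <- length(y)
  es <- eigen(K, symmetric = TRUE)
  lam <- pmax(es$values, 0)
  yt <- drop(crossprod(es$vectors, y))
  xt <- drop(crossprod(es$vectors, rep(1, n)))
  # restricted log-likelihood at (sg, se)
  rll <- function(sg, se) {
    d <- sg * lam + se
    a <- sum(xt^2 / d)
    mu <- sum(xt * yt / d) / a
    r <- yt - mu * xt
    -0.5 * (sum(log(d)) + log(a) + sum(r^2 / d))
  }
  # profile out total variance for fixed ratio h = sg / (sg + se)
  prof <- function(h) {
    d0 <- h * lam + (1 - h)
    a <- sum(xt^2 / d0)
    mu <- sum(xt * yt / d0) / a
    r <- yt - mu * xt
    s2 <- sum(r^2 / d0) / (n - 1)
    rll(h * s2, (1 - h) * s2)
  }
  opt <- stats::optimize(prof, c(1e-6, 1 - 1e-6), maximum = TRUE)
  h <- opt$maximum
  d0 <- h * lam + (1 - h)
  a <- sum(xt^2 / d0)
  mu <- sum(xt * yt / d0) / a
  r <- yt - mu * xt
  s2 <- sum(r^2 / d0) / (n - 1)
  list(sigma2_g = h * s2, sigma2_e = (1 - h) * s2, loglik = opt$objective)
}
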