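# Differential SHAP interaction networks: interaction identities, null
# Z-scores, empirical p-values, network assembly, sweeps, stability,
# binomial support, export round trip.

test_that("interaction tensors satisfy symmetry and row-sum consistency", {
  d <- tiny_xy(n = 150, p = 6, seed = 30)
  m <- fit_gbt_model(d$X, d$y, tiny_gbt_hyper(), seed = 4)
  im <- shap_interaction_matrix(m, d$X)
  expect_lt(max(abs(im$phi - t(im$phi))), 1e-8)
  # per-sample: sum_j phi_ij(x) = phi_i(x)
  tens <- predict(m, xgboost::xgb.DMatrix(d$X, nthread = 1),
                  predinteraction = TRUE)
  contrib <- predict(m, xgboost::xgb.DMatrix(d$X, nthread = 1),
                     predcontrib = TRUE)
  expect_lt(max(abs(apply(tens, c(1, 2), sum) - contrib)), 1e-5)
  expect_error(shap_interaction_matrix(m, d$X, max_features = 3), "theta")
})

test_that("an additive stump ensemble has no off-diagonal interactions", {
  d <- tiny_xy(n = 200, p = 5, seed = 31, interaction = FALSE)
  m <- dsinet:::fit_xgb(d$X, d$y, list(max_depth = 1, eta = 0.3),
                        nrounds = 60L, seed = 2)
  im <- shap_interaction_matrix(m, d$X)
  off <- im$phi; diag(off) <- 0
  expect_lt(max(abs(off)), 1e-8)
})

test_that("differential matrix is an antisymmetric elementwise difference", {
  A <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  B <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = dimnames(A))
  d <- differential_matrix(A, B)
  expect_equal(d["a", "b"], 0.6)
  expect_equal(differential_matrix(B, A), -d)
  expect_equal(differential_matrix(A, A), 0 * A)
  dimnames(B) <- list(c("a", "x"), c("a", "x"))
  expect_error(differential_matrix(A, B), "share")
})

test_that("shared tuning needs one universe and picks the better depth", {
  d1 <- tiny_xy(n = 100, p = 5, seed = 32)
  d2 <- tiny_xy(n = 100, p = 5, seed = 33)
  bad <- d2$X; colnames(bad)[1] <- "other"
  expect_error(tune_gbt_shared(d1$X, d1$y, bad, d2$y), "align")
  grid1 <- data.frame(max_depth = 3L, eta = 0.1, nrounds = 50L, subsample = 0.8)
  t1 <- tune_gbt_shared(d1$X, d1$y, d2$X, d2$y, grid1, cv_folds = 3, seed = 1)
  expect_equal(t1$best$max_depth, 3L)
  # identical conditions: objective equals the single-condition CV RMSE
  t2 <- tune_gbt_shared(d1$X, d1$y, d1$X, d1$y, grid1, cv_folds = 3, seed = 1)
  expect_equal(t2$table$mean_cv_rmse,
               mean(rep(t2$table$mean_cv_rmse, 2)))
  # a depth able to express the planted interaction beats stumps
  grid <- data.frame(max_depth = c(1L, 3L), eta = 0.2, nrounds = 80L,
                     subsample = 1.0)
  hits <- sum(vapply(1:3, function(s) {
    da <- tiny_xy(n = 150, p = 5, seed = 40 + s)
    db <- tiny_xy(n = 150, p = 5, seed = 50 + s)
    tune_gbt_shared(da$X, da$y, db$X, db$y, grid, cv_folds = 3,
                    seed = s)$best$max_depth == 3L
  }, logical(1)))
  expect_gte(hits, 2L)
})

test_that("null z-scores pool the strict upper triangle with sample SD", {
  ids <- c("a", "b")
  dp <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(ids, ids))
  r1 <- matrix(c(9, -1, -1, 9), 2, 2, dimnames = list(ids, ids))
  r2 <- matrix(c(9, 1, 1, 9), 2, 2, dimnames = list(ids, ids))
  nz <- null_zscores(dp, list(r1, r2))
  expect_equal(nz$mu0, 0)           # diagonals (9s) excluded from pooling
  expect_equal(nz$sigma0, sqrt(2))  # sample SD of {-1, 1}
  expect_equal(nz$Z["a", "b"], 2 / sqrt(2))
  expect_equal(nz$Z["a", "a"][[1]], 0 / sqrt(2) * 0 + (0 - 0) / sqrt(2))
  r_const <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(ids, ids))
  expect_error(null_zscores(dp, list(r_const, r_const)), "degenerate")
  expect_error(null_zscores(dp, list(r1)), "2")
})

test_that("empirical p-values follow the add-one two-sided formula", {
  ids <- c("a", "b")
  mk <- function(v) matrix(c(0, v, v, 0), 2, 2, dimnames = list(ids, ids))
  # B = 3 nulls {1, 2, 3}, observed 2.5 -> p = (1 + 1) / 4
  p <- empirical_pvalues(mk(2.5), list(mk(1), mk(2), mk(3)))
  expect_equal(p["a", "b"], 0.5)
  # observed beats all 100 nulls -> p = 1 / 101
  reps <- lapply(1:100, function(b) mk(0.01 * b))
  expect_equal(empirical_pvalues(mk(2), reps)["a", "b"], 1 / 101)
  # observed 0 -> every |null| >= 0 -> p = 1
  expect_equal(empirical_pvalues(mk(0), reps)["a", "b"], 1)
})

test_that("network assembly applies the inclusive |Z| cutoff and labels signs", {
  ids <- sprintf("f%02d", 1:4)
  dp <- matrix(0, 4, 4, dimnames = list(ids, ids))
  dp["f01", "f02"] <- 0.5; dp["f02", "f01"] <- 0.5
  dp["f03", "f04"] <- -0.4; dp["f04", "f03"] <- -0.4
  Z <- dp * 100 # 50, -40
  p <- matrix(1, 4, 4, dimnames = dimnames(dp))
  lo <- stats::setNames(c("genome", "metabolome", "microbiome", "metabolome"), ids)
  net <- build_network(dp, Z, p, z_min = 40, layer_of = lo)
  expect_identical(nrow(net$edges), 2L) # |Z| = 40 kept (inclusive)
  expect_identical(net$edges$sign[net$edges$from == "f01"], "drought-stronger")
  expect_identical(net$edges$sign[net$edges$from == "f03"], "control-stronger")
  expect_identical(sort(net$nodes$id), ids)
  expect_identical(net$nodes$degree, rep(1L, 4))
  empty <- build_network(dp, Z, p, z_min = 1000, layer_of = lo)
  expect_identical(nrow(empty$edges), 0L)
  expect_identical(nrow(empty$nodes), 0L)
  expect_equal(network_density(160, 2729, percent = TRUE), 0.0043, tolerance = 1e-2)
})

test_that("sweep networks are nested and theta endpoints are honored", {
  set.seed(35)
  ids <- sprintf("f%02d", 1:10)
  dp <- matrix(0, 10, 10, dimnames = list(ids, ids))
  dp[upper.tri(dp)] <- rnorm(45)
  dp <- dp + t(dp)
  Z <- dp * 40
  p <- matrix(0.5, 10, 10, dimnames = dimnames(dp))
  theta <- stats::setNames(seq(0.0005, 0.012, length.out = 10), ids)
  sw <- threshold_sweeps(dp, Z, p, theta, theta, z_min = 10,
                         layer_of = stats::setNames(rep("genome", 10), ids))
  sizes <- vapply(sw$z_networks, function(nw) nrow(nw$edges), integer(1))
  expect_false(is.unsorted(rev(sizes))) # monotone nesting over z
  for (i in seq_along(sw$z_networks)[-1]) {
    prev <- sw$z_networks[[i - 1]]$edges
    cur <- sw$z_networks[[i]]$edges
    expect_true(all(paste(cur$from, cur$to) %in% paste(prev$from, prev$to)))
  }
  expect_identical(names(sw$theta_networks)[1], "theta0.001")
  expect_identical(names(sw$theta_networks)[10], "theta0.010")
  th_sizes <- vapply(sw$theta_networks, function(nw) nrow(nw$edges), integer(1))
  expect_false(is.unsorted(rev(th_sizes))) # nesting over theta too
})

test_that("binomial edge support matches the exact tail", {
  expect_equal(binomial_edge_support(100, 1.5e-4, 2), 1.1e-4, tolerance = 0.02)
  expect_identical(binomial_edge_support(100, 0.5, 0), 1)
  # independent oracle: complement of pbinom
  expect_equal(binomial_edge_support(100, 1.5e-4, 3),
               pbinom(2, 100, 1.5e-4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(binomial_edge_support(30, 0.2, 5),
               pbinom(4, 30, 0.2, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("stability filtering is inclusive at min_count and annotates n_obs", {
  ids <- c("a", "b", "c")
  dp <- matrix(0.5, 3, 3, dimnames = list(ids, ids)); diag(dp) <- 0
  Z <- dp * 100
  p <- matrix(0.01, 3, 3, dimnames = dimnames(dp))
  net <- build_network(dp, Z, p, z_min = 30)
  n_obs <- matrix(0L, 3, 3, dimnames = list(ids, ids))
  n_obs["a", "b"] <- 2L; n_obs["a", "c"] <- 1L; n_obs["b", "c"] <- 5L
  stab <- structure(list(n_obs = n_obs, B_boot = 10L, epsilon = 1e-12),
                    class = "stability_result")
  out <- filter_by_stability(net, stab, min_count = 2)
  expect_setequal(paste(out$edges$from, out$edges$to), c("a b", "b c"))
  expect_setequal(out$edges$n_obs, c(2L, 5L))
  ident <- filter_by_stability(net, stab, min_count = 0)
  expect_identical(nrow(ident$edges), nrow(net$edges))
})

test_that("permutation null and bootstrap replicates are reproducible and shaped", {
  d <- tiny_xy(n = 80, p = 5, seed = 36)
  dc <- list(X = d$X, y = d$y)
  dd <- list(X = d$X, y = rev(d$y))
  hy <- list(max_depth = 2, eta = 0.3, nrounds = 20, subsample = 0.8)
  reps <- permutation_null(dc, dd, hy, B = 3, seed = 9)
  expect_length(reps, 3)
  expect_identical(dim(reps[[1]]), c(5L, 5L))
  reps2 <- permutation_null(dc, dd, hy, B = 3, seed = 9)
  expect_identical(reps, reps2)
  expect_error(permutation_null(dc, dd, hy, B = 1), "B")

  stab <- bootstrap_stability(dc, dd, hy, B_boot = 3, seed = 9)
  expect_true(all(stab$n_obs >= 0 & stab$n_obs <= 3))
  expect_true(all(stab$n_obs == round(stab$n_obs)))
  stab2 <- bootstrap_stability(dc, dd, hy, B_boot = 3, seed = 9)
  expect_identical(stab$n_obs, stab2$n_obs)
})

test_that("condition swap negates dPhi and Z and keeps |Z| edges", {
  set.seed(37)
  ids <- sprintf("f%02d", 1:6)
  dp <- matrix(0, 6, 6, dimnames = list(ids, ids))
  dp[upper.tri(dp)] <- rnorm(15); dp <- dp + t(dp)
  reps <- lapply(1:5, function(b) {
    m <- matrix(0, 6, 6, dimnames = list(ids, ids))
    m[upper.tri(m)] <- rnorm(15, sd = 0.3); m + t(m)
  })
  nz <- null_zscores(dp, reps)
  nz_sw <- null_zscores(-dp, lapply(reps, function(m) -m))
  expect_equal(nz_sw$Z, -nz$Z)
  expect_equal(nz_sw$mu0, -nz$mu0)
  p <- empirical_pvalues(dp, reps)
  p_sw <- empirical_pvalues(-dp, lapply(reps, function(m) -m))
  expect_equal(p, p_sw)
  lo <- stats::setNames(rep("genome", 6), ids)
  e1 <- build_network(dp, nz$Z, p, 1, lo)$edges
  e2 <- build_network(-dp, nz_sw$Z, p_sw, 1, lo)$edges
  expect_identical(paste(e1$from, e1$to), paste(e2$from, e2$to))
})

test_that("network export round-trips through TSV and GraphML", {
  ids <- c("Chr01-5", "met_001", "taxon_002")
  dp <- matrix(0, 3, 3, dimnames = list(ids, ids))
  dp["Chr01-5", "met_001"] <- 0.8; dp["met_001", "Chr01-5"] <- 0.8
  dp["met_001", "taxon_002"] <- -0.3; dp["taxon_002", "met_001"] <- -0.3
  Z <- dp * 50
  p <- matrix(0.02, 3, 3, dimnames = dimnames(dp))
  n_obs <- matrix(7L, 3, 3, dimnames = dimnames(dp))
  lo <- stats::setNames(c("genome", "metabolome", "microbiome"), ids)
  net <- build_network(dp, Z, p, z_min = 10, layer_of = lo, n_obs = n_obs)
  dir <- withr::local_tempdir()
  paths <- export_network(net, dir)
  tab <- read.delim(paths["tsv"])
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("featureA", "layerB", "delta_phi", "z", "p", "n_obs",
                    "sign") %in% names(tab)))
  back <- read_network_graphml(paths["graphml"])
  expect_setequal(back$nodes$id, net$nodes$id)
  eo <- net$edges[order(net$edges$from, net$edges$to), ]
  eb <- back$edges[order(back$edges$from, back$edges$to), ]
  expect_equal(eb$delta_phi, eo$delta_phi)
  expect_equal(eb$z, eo$z)
  expect_identical(eb$n_obs, eo$n_obs)
  # degree in the file equals the recomputed incident-edge count
  deg <- table(c(back$edges$from, back$edges$to))
  expect_identical(as.integer(deg[back$nodes$id[back$nodes$degree > 0]]),
                   back$nodes$degree[back$nodes$degree > 0])
  expect_error(export_network(net, dir, formats = "dot"), "unknown")
  empty <- build_network(dp, Z * 0, p, 30, lo)
  ep <- export_network(empty, dir, basename = "empty", formats = "tsv")
  expect_identical(nrow(read.delim(ep["tsv"])), 0L)
})
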