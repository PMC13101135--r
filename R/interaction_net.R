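# Differential SHAP-interaction network inference: shared-hyperparameter
# gradient-boosted models per condition, exact per-sample SHAP interaction
# tensors averaged into symmetric interaction matrices Phi, the differential
# matrix dPhi = Phi_drought - Phi_control, permutation-null Z-scores and
# empirical p-values, Z/theta threshold sweeps, bootstrap edge stability, a
# binomial support argument, and network assembly/export.

#' Default gradient-boosting tuning grid
#'
#' Depth \{2,3,4\}, learning rate \{0.05, 0.1\}, trees \{200, 500\},
#' subsample \{0.8, 1.0\}.
#' @return data.frame of hyperparameter combinations.
#' @export
default_gbt_grid <- function() {
  expand.grid(max_depth = c(2L, 3L, 4L), eta = c(0.05, 0.1),
              nrounds = c(200L, 500L), subsample = c(0.8, 1.0),
              KEEP.OUT.ATTRS = FALSE)
}

gbt_xgb_params <- function(hyper) {
  p <- list(max_depth = as.integer(hyper$max_depth), eta = hyper$eta,
            subsample = hyper$subsample)
  if (!is.null(hyper$colsample_bynode)) p$colsample_bynode <- hyper$colsample_bynode
  if (!is.null(hyper$min_child_weight)) {
    p$min_child_weight <- as.integer(hyper$min_child_weight)
  }
  if (!is.null(hyper$gamma)) p$gamma <- hyper$gamma
  if (!is.null(hyper$num_parallel_tree)) {
    p$num_parallel_tree <- as.integer(hyper$num_parallel_tree)
  }
  p
}

#' Fit one gradient-boosted tree ensemble
#'
#' @param X complete feature matrix with colnames; @param y response.
#' @param hyper list/row with `max_depth`, `eta`, `nrounds`, `subsample`.
#' @param seed integer seed.
#' @return an `xgb.Booster`.
#' @export
fit_gbt_model <- function(X, y, hyper, seed) {
  fit_xgb(X, y, gbt_xgb_params(hyper), nrounds = as.integer(hyper$nrounds),
          seed = seed)
}

#' Tune one shared hyperparameter set for both conditions
#'
#' Scores each grid point by the mean of the two conditions' cross-validated
#' RMSEs, so a single tuned configuration applies to control and drought
#' models alike (comparability of the two interaction matrices). Ties break
#' toward fewer trees, then shallower depth.
#'
#' @param stack_control,stack_drought per-condition `feature_stack`s (or
#'   matrices) over a common feature universe.
#' @param y_control,y_drought responses.
#' @param grid data.frame like [default_gbt_grid()]; @param cv_folds folds.
#' @param seed RNG seed.
#' @return list with `best`, `cv_rmse`, and the scored `table`.
#' @export
tune_gbt_shared <- function(stack_control, y_control, stack_drought, y_drought,
                            grid = default_gbt_grid(), cv_folds = 5L, seed = 1L) {
  Xc <- if (inherits(stack_control, "feature_stack")) stack_control$matrix else stack_control
  Xd <- if (inherits(stack_drought, "feature_stack")) stack_drought$matrix else stack_drought
  if (!identical(colnames(Xc), colnames(Xd))) {
    stop("feature universes differ between conditions; align them first",
         call. = FALSE)
  }
  if (nrow(grid) == 0L) stop("empty tuning grid", call. = FALSE)
  ord <- order(grid$nrounds, grid$max_depth)
  grid <- grid[ord, , drop = FALSE]
  score <- vapply(seq_len(nrow(grid)), function(i) {
    rmse <- function(X, y, tag) {
      pred <- kfold_oof(X, y, cv_folds, substream_seed(seed, tag),
                        function(Xtr, ytr, s) fit_gbt_model(Xtr, ytr, grid[i, ], s))
      sqrt(mean((y - pred)^2))
    }
    (rmse(Xc, y_control, "control") + rmse(Xd, y_drought, "drought")) / 2
  }, numeric(1))
  best <- which.min(score)
  list(best = as.list(grid[best, , drop = FALSE]), cv_rmse = score[best],
       table = cbind(grid, mean_cv_rmse = score))
}

#' Mean SHAP interaction matrix of a tree ensemble
#'
#' Computes the exact per-sample TreeSHAP interaction tensor and averages the
#' per-sample interaction magnitudes into the symmetric p' x p' strength
#' matrix `Phi_ij = mean_x |phi_ij(x)|`; the diagonal holds the main-effect
#' terms, and per sample the row sums of the (signed) interaction tensor
#' reproduce the individual SHAP values. Magnitude averaging is used because
#' the signed per-sample values of a symmetric interaction (e.g. a product
#' term) cancel in expectation, which would make the condition difference
#' `dPhi` sign-uninterpretable; on `|phi|` scale, `dPhi > 0` reads directly
#' as "interaction stronger under drought".
#'
#' @param model an `xgb.Booster`; @param X its feature matrix.
#' @param condition optional condition tag.
#' @param max_features guard on p' (default 3000): beyond it the exact tensor
#'   is computationally prohibitive and theta filtering should be tightened.
#' @return an `interaction_matrix`: list with `phi`, `feature_ids`, `condition`.
#' @export
shap_interaction_matrix <- function(model, X, condition = NULL,
                                    max_features = 3000L) {
  p <- ncol(X)
  if (p > max_features) {
    stop(sprintf(paste0("p' = %d exceeds the %d-feature cap for exact SHAP ",
                        "interactions; tighten the theta filter first"),
                 p, max_features), call. = FALSE)
  }
  tens <- predict(model, xgboost::xgb.DMatrix(X, nthread = 1),
                  predinteraction = TRUE)
  phi <- colMeans(abs(tens))[seq_len(p), seq_len(p), drop = FALSE]
  phi <- (phi + t(phi)) / 2 # symmetrize away float32 rounding of the tensor
  dimnames(phi) <- list(colnames(X), colnames(X))
  structure(list(phi = phi, feature_ids = colnames(X), condition = condition),
            class = "interaction_matrix")
}

#' Differential interaction matrix
#'
#' `dPhi = Phi_drought - Phi_control`; positive entries mark interactions that
#' are stronger under drought.
#'
#' @param phi_drought,phi_control `interaction_matrix` objects (or matrices)
#'   over identical feature ids.
#' @return matrix dPhi with feature dimnames.
#' @export
differential_matrix <- function(phi_drought, phi_control) {
  pd <- if (inherits(phi_drought, "interaction_matrix")) phi_drought$phi else phi_drought
  pc <- if (inherits(phi_control, "interaction_matrix")) phi_control$phi else phi_control
  if (!identical(dimnames(pd), dimnames(pc))) {
    stop("interaction matrices must share feature ids and order", call. = FALSE)
  }
  pd - pc
}

#' Fit both condition models and compute one differential interaction matrix
#'
#' @param Xc,yc,Xd,yd per-condition feature matrices and responses over a
#'   shared feature universe.
#' @param hyper shared gradient-boosting hyperparameters; @param seed seed.
#' @return the matrix `dPhi = Phi_drought - Phi_control`.
#' @export
delta_phi_once <- function(Xc, yc, Xd, yd, hyper, seed) {
  mc <- fit_gbt_model(Xc, yc, hyper, substream_seed(seed, "fit-control"))
  md <- fit_gbt_model(Xd, yd, hyper, substream_seed(seed, "fit-drought"))
  differential_matrix(shap_interaction_matrix(md, Xd, "drought"),
                      shap_interaction_matrix(mc, Xc, "control"))
}

#' Permutation null distribution of the differential interaction matrix
#'
#' Per replicate the response vector is independently permuted within each
#' condition (features fixed), both models are refit with the shared
#' hyperparameters, and the null `dPhi^(b)` is recorded. Replicate `b` uses
#' the RNG stream `(seed, "perm", b)`, so a seed reproduces the replicate set.
#'
#' @param data_control,data_drought lists with `X` (matrix) and `y`.
#' @param hyper shared gradient-boosting hyperparameters.
#' @param B number of replicates (>= 2; default 100).
#' @param seed base seed.
#' @return list of B matrices `dPhi^(b)`.
#' @export
permutation_null <- function(data_control, data_drought, hyper, B = 100L,
                             seed = 1L) {
  if (B < 2L) stop("B must be >= 2", call. = FALSE)
  lapply(seq_len(B), function(b) {
    sb <- substream_seed(seed, "perm", b)
    yc <- with_stream(substream_seed(sb, "shuffle-control"), sample(data_control$y))
    yd <- with_stream(substream_seed(sb, "shuffle-drought"), sample(data_drought$y))
    delta_phi_once(data_control$X, yc, data_drought$X, yd, hyper, sb)
  })
}

#' Pooled-null Z-scores for the differential interaction matrix
#'
#' All strictly upper-triangular (off-diagonal) entries of the B null
#' matrices are pooled; their mean and sample SD (divisor n-1) standardize
#' every observed entry: `Z_ij = (dPhi_ij - mu0) / sigma0`.
#'
#' @param delta_phi observed dPhi; @param replicates list from [permutation_null()].
#' @return list with `mu0`, `sigma0`, `Z` (matrix).
#' @export
null_zscores <- function(delta_phi, replicates) {
  if (length(replicates) < 2L) stop("need >= 2 null replicates", call. = FALSE)
  ut <- upper.tri(delta_phi)
  pooled <- unlist(lapply(replicates, function(m) m[ut]), use.names = FALSE)
  mu0 <- mean(pooled)
  sigma0 <- stats::sd(pooled)
  if (!is.finite(sigma0) || sigma0 == 0) {
    stop("degenerate null: pooled entries have zero spread", call. = FALSE)
  }
  list(mu0 = mu0, sigma0 = sigma0, Z = (delta_phi - mu0) / sigma0)
}

#' Two-sided add-one empirical p-values
#'
#' `p_ij = (1 + #{b : |dPhi^(b)_ij| >= |dPhi_ij|}) / (B + 1)`.
#'
#' @param delta_phi observed dPhi; @param replicates null replicates.
#' @return matrix of p-values in `[1/(B+1), 1]`.
#' @export
empirical_pvalues <- function(delta_phi, replicates) {
  if (length(replicates) < 1L) stop("need >= 1 null replicate", call. = FALSE)
  count <- matrix(0, nrow(delta_phi), ncol(delta_phi))
  a <- abs(delta_phi)
  for (m in replicates) count <- count + (abs(m) >= a)
  p <- (1 + count) / (length(replicates) + 1)
  dimnames(p) <- dimnames(delta_phi)
  p
}

#' Assemble the thresholded interaction network
#'
#' Keeps unordered pairs i < j with `|Z_ij| >= z_min` (inclusive;
#' default 30). Edge sign comes from `sign(dPhi)` (positive =
#' drought-stronger); nodes carry their omics layer, degree, and a hub flag
#' (top decile of degree).
#'
#' @param delta_phi,Z,p aligned matrices; @param z_min |Z| cutoff.
#' @param layer_of named feature -> layer map.
#' @param n_obs optional bootstrap stability counts (matrix).
#' @return an `interaction_network`: list with `nodes` and `edges` data.frames.
#' @export
build_network <- function(delta_phi, Z, p, z_min = 30, layer_of = NULL,
                          n_obs = NULL) {
  stopifnot(identical(dim(delta_phi), dim(Z)), identical(dim(Z), dim(p)))
  ids <- rownames(delta_phi)
  sel <- which(upper.tri(Z) & abs(Z) >= z_min, arr.ind = TRUE)
  edges <- data.frame(
    from = ids[sel[, 1]], to = ids[sel[, 2]],
    delta_phi = delta_phi[sel], z = Z[sel], p = p[sel],
    n_obs = if (is.null(n_obs)) rep(NA_integer_, nrow(sel)) else n_obs[sel],
    sign = ifelse(delta_phi[sel] > 0, "drought-stronger", "control-stronger"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  network_from_edges(edges, layer_of)
}

# Rebuild node table (degree, hub flag) from an edge list.
network_from_edges <- function(edges, layer_of = NULL) {
  node_ids <- sort(unique(c(edges$from, edges$to)))
  degree <- vapply(node_ids, function(v) sum(edges$from == v) + sum(edges$to == v),
                   numeric(1))
  hub <- if (length(degree)) degree >= stats::quantile(degree, 0.9) else logical(0)
  nodes <- data.frame(
    id = node_ids,
    layer = if (is.null(layer_of)) rep(NA_character_, length(node_ids)) else
      unname(layer_of[node_ids]),
    degree = as.integer(degree), hub = hub,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = edges), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network: %d nodes, %d edges>\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Network density
#'
#' Edges divided by the number of unordered feature pairs `choose(p', 2)`.
#'
#' @param n_edges edge count; @param n_features universe size p'.
#' @param percent return a percentage instead of a fraction.
#' @return density (0 when `n_features < 2`).
#' @export
network_density <- function(n_edges, n_features, percent = FALSE) {
  pairs <- choose(n_features, 2)
  d <- if (pairs > 0) n_edges / pairs else 0
  if (percent) 100 * d else d
}

#' Z and theta threshold sweeps
#'
#' (a) Networks at every |Z| cutoff in `z_grid` (edge sets are nested:
#' raising the cutoff never adds an edge). (b) At fixed `z_min`, networks
#' restricted to features passing the `mode = "both"` theta selection at each
#' value of `theta_grid`; an edge survives iff both endpoints stay selected.
#' Per-edge theta persistence (the largest theta at which the edge survives)
#' is reported.
#'
#' @param delta_phi,Z,p aligned matrices; @param theta_control,theta_drought
#'   total-importance vectors on the shared universe.
#' @param layer_of feature -> layer map; @param n_obs optional stability counts.
#' @param z_grid |Z| cutoffs (default 10..60); @param z_min cutoff used in the
#'   theta sweep; @param theta_grid theta values (default range 0.001..0.01).
#' @return list with `z_networks`, `theta_networks`, `edge_persistence`.
#' @export
threshold_sweeps <- function(delta_phi, Z, p, theta_control, theta_drought,
                             layer_of = NULL, n_obs = NULL,
                             z_grid = c(10, 20, 30, 40, 50, 60), z_min = 30,
                             theta_grid = seq(0.001, 0.01, by = 0.001)) {
  z_networks <- lapply(z_grid, function(zc) {
    build_network(delta_phi, Z, p, zc, layer_of, n_obs)
  })
  names(z_networks) <- paste0("z", z_grid)
  base_net <- build_network(delta_phi, Z, p, z_min, layer_of, n_obs)
  theta_networks <- lapply(theta_grid, function(th) {
    kept <- select_features(theta_control, theta_drought, th, mode = "both")
    edges <- base_net$edges
    edges <- edges[edges$from %in% kept & edges$to %in% kept, , drop = FALSE]
    network_from_edges(edges, layer_of)
  })
  names(theta_networks) <- sprintf("theta%.3f", theta_grid)
  persistence <- if (nrow(base_net$edges)) {
    vapply(seq_len(nrow(base_net$edges)), function(i) {
      alive <- vapply(theta_networks, function(nw) {
        any(nw$edges$from == base_net$edges$from[i] &
              nw$edges$to == base_net$edges$to[i])
      }, logical(1))
      if (any(alive)) max(theta_grid[alive]) else NA_real_
    }, numeric(1))
  } else numeric(0)
  edge_persistence <- cbind(base_net$edges[, c("from", "to"), drop = FALSE],
                            theta_max = persistence)
  list(z_networks = z_networks, theta_networks = theta_networks,
       edge_persistence = edge_persistence)
}

#' Bootstrap edge stability
#'
#' Per replicate, `(x, y)` pairs are resampled with replacement independently
#' per condition, both models refit, and `dPhi_boot^(b)` computed; the
#' presence stability `n_obs_ij` counts replicates with
#' `|dPhi_boot^(b)_ij| > epsilon`.
#'
#' @param data_control,data_drought lists with `X` and `y`.
#' @param hyper shared hyperparameters; @param B_boot replicates (>= 2).
#' @param epsilon numerical tolerance (default 1e-12); @param seed base seed
#'   (stream `(seed, "boot", b)` per replicate).
#' @return a `stability_result`: list with integer matrix `n_obs`, `B_boot`,
#'   `epsilon`.
#' @export
bootstrap_stability <- function(data_control, data_drought, hyper,
                                B_boot = 100L, epsilon = 1e-12, seed = 1L) {
  if (B_boot < 2L) stop("B_boot must be >= 2", call. = FALSE)
  p <- ncol(data_control$X)
  n_obs <- matrix(0L, p, p, dimnames = list(colnames(data_control$X),
                                            colnames(data_control$X)))
  for (b in seq_len(B_boot)) {
    sb <- substream_seed(seed, "boot", b)
    ic <- with_stream(substream_seed(sb, "resample-control"),
                      sample.int(length(data_control$y), replace = TRUE))
    id <- with_stream(substream_seed(sb, "resample-drought"),
                      sample.int(length(data_drought$y), replace = TRUE))
    d <- delta_phi_once(data_control$X[ic, , drop = FALSE], data_control$y[ic],
                        data_drought$X[id, , drop = FALSE], data_drought$y[id],
                        hyper, sb)
    n_obs <- n_obs + (abs(d) > epsilon)
  }
  structure(list(n_obs = n_obs, B_boot = as.integer(B_boot), epsilon = epsilon),
            class = "stability_result")
}

#' Filter a network by bootstrap stability
#'
#' Drops edges observed in fewer than `min_count` bootstrap replicates
#' (default: `n_obs < 2` excluded) and annotates survivors with their counts.
#'
#' @param network an `interaction_network`; @param stability a
#'   `stability_result` on the same universe; @param min_count inclusive
#'   retention threshold.
#' @return the filtered `interaction_network`.
#' @export
filter_by_stability <- function(network, stability, min_count = 2L) {
  stopifnot(inherits(network, "interaction_network"),
            inherits(stability, "stability_result"))
  edges <- network$edges
  if (nrow(edges)) {
    edges$n_obs <- stability$n_obs[cbind(edges$from, edges$to)]
    edges <- edges[edges$n_obs >= min_count, , drop = FALSE]
  }
  layer_of <- stats::setNames(network$nodes$layer, network$nodes$id)
  network_from_edges(edges, if (all(is.na(layer_of))) NULL else layer_of)
}

#' Binomial support for repeated edge appearance
#'
#' Exact tail probability `P(X >= k_min)` for
#' `X ~ Binomial(B_boot, p_rate)`, by direct summation of the binomial mass
#' (no normal approximation): the chance that a purely spurious edge, whose
#' per-replicate appearance rate is `p_rate`, shows up in at least `k_min`
#' bootstrap replicates.
#'
#' @param B_boot number of replicates; @param p_rate per-replicate rate.
#' @param k_min minimum appearance count.
#' @return the exact tail probability.
#' @export
binomial_edge_support <- function(B_boot, p_rate, k_min) {
  stopifnot(p_rate >= 0, p_rate <= 1, k_min >= 0, k_min <= B_boot)
  if (k_min == 0) return(1)
  k <- seq.int(k_min, B_boot)
  sum(exp(lchoose(B_boot, k) + k * log(p_rate) + (B_boot - k) * log1p(-p_rate)))
}

#' Export a network as an edge-list TSV and/or GraphML
#'
#' The TSV carries featureA, featureB, layerA, layerB, delta_phi, z, p,
#' n_obs, sign; the GraphML carries the same edge attributes plus node layer,
#' degree and hub flag, and round-trips through [read_network_graphml()].
#'
#' @param network an `interaction_network`.
#' @param dir output directory; @param basename file stem.
#' @param formats subset of `c("tsv", "graphml")`.
#' @return named character vector of written paths.
#' @export
export_network <- function(network, dir, basename = "network",
                           formats = c("tsv", "graphml")) {
  stopifnot(inherits(network, "interaction_network"))
  unknown <- setdiff(formats, c("tsv", "graphml"))
  if (length(unknown)) {
    stop("unknown export format(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  layer_of <- stats::setNames(network$nodes$layer, network$nodes$id)
  out <- character(0)
  if ("tsv" %in% formats) {
    path <- file.path(dir, paste0(basename, "_edges.tsv"))
    e <- network$edges
    tab <- data.frame(featureA = e$from, featureB = e$to,
                      layerA = unname(layer_of[e$from]),
                      layerB = unname(layer_of[e$to]),
                      delta_phi = e$delta_phi, z = e$z, p = e$p,
                      n_obs = e$n_obs, sign = e$sign,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    out["tsv"] <- path
  }
  if ("graphml" %in% formats) {
    path <- file.path(dir, paste0(basename, ".graphml"))
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                       vertices = network$nodes)
    igraph::write_graph(g, path, format = "graphml")
    out["graphml"] <- path
  }
  out
}

#' @rdname export_network
#' @param path a GraphML file written by [export_network()].
#' @return `read_network_graphml` returns the reconstructed
#'   `interaction_network`.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vat <- igraph::as_data_frame(g, what = "vertices")
  eat <- igraph::as_data_frame(g, what = "edges")
  nodes <- data.frame(id = vat$name, layer = vat$layer,
                      degree = as.integer(vat$degree),
                      hub = as.logical(vat$hub),
                      row.names = NULL, stringsAsFactors = FALSE)
  edges <- data.frame(from = eat$from, to = eat$to,
                      delta_phi = eat$delta_phi, z = eat$z, p = eat$p,
                      n_obs = as.integer(eat$n_obs), sign = eat$sign,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "interaction_network")
}

#' Run the full differential-interaction stage
#'
#' Restricts both conditions to the theta `mode = "both"` universe, tunes (or
#' takes) one shared hyperparameter set, computes the observed dPhi, the
#' permutation-null Z-scores and empirical p-values, bootstrap stability, the
#' thresholded network and its stability-filtered version.
#'
#' @param stack_control,stack_drought per-condition `feature_stack`s.
#' @param y_control,y_drought representative-trait responses.
#' @param theta_control,theta_drought total-importance vectors.
#' @param hyper optional shared hyperparameters (tuned when NULL with `grid`).
#' @param grid tuning grid; @param theta_min interaction screen (0.001).
#' @param z_min |Z| cutoff (30); @param n_perm,n_boot replicate counts;
#' @param epsilon stability tolerance; @param min_count stability filter (2);
#' @param cv_folds tuning folds; @param seed base seed.
#' @return list with the universe, hyperparameters, `delta_phi`, `null`
#'   (mu0/sigma0/Z), `p`, `stability`, `network` (unfiltered) and
#'   `network_stable` (stability-filtered).
#' @export
run_interaction_network <- function(stack_control, stack_drought, y_control,
                                    y_drought, theta_control, theta_drought,
                                    hyper = NULL, grid = default_gbt_grid(),
                                    theta_min = 0.001, z_min = 30,
                                    n_perm = 100L, n_boot = 100L,
                                    epsilon = 1e-12, min_count = 2L,
                                    cv_folds = 5L, seed = 1L) {
  universe <- select_features(theta_control, theta_drought, theta_min,
                              mode = "both")
  universe <- intersect(intersect(stack_control$feature_ids,
                                  stack_drought$feature_ids), universe)
  Xc <- stack_control$matrix[, universe, drop = FALSE]
  Xd <- stack_drought$matrix[, universe, drop = FALSE]
  layer_of <- stack_control$layer_of[universe]
  if (is.null(hyper)) {
    hyper <- tune_gbt_shared(Xc, y_control, Xd, y_drought, grid, cv_folds,
                             substream_seed(seed, "tune"))$best
  }
  delta <- delta_phi_once(Xc, y_control, Xd, y_drought, hyper,
                          substream_seed(seed, "observed"))
  dc <- list(X = Xc, y = y_control)
  dd <- list(X = Xd, y = y_drought)
  reps <- permutation_null(dc, dd, hyper, n_perm, seed)
  null <- null_zscores(delta, reps)
  pmat <- empirical_pvalues(delta, reps)
  stability <- bootstrap_stability(dc, dd, hyper, n_boot, epsilon, seed)
  network <- build_network(delta, null$Z, pmat, z_min, layer_of,
                           stability$n_obs)
  list(universe = universe, hyper = hyper, delta_phi = delta, null = null,
       p = pmat, stability = stability, network = network,
       network_stable = filter_by_stability(network, stability, min_count))
}
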