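# Per-trait random-forest models (xgboost parallel-tree mode: one boosting
# round, eta = 1, row/column subsampling), grid-search tuning, gain-based
# (variance-reduction) importance, the normalized importance matrix B^(RF),
# total importance theta, threshold feature selection, and a permutation
# predictive-signal check.

#' Default random-forest tuning grid
#'
#' Trees in \{500, 1000\}, per-split feature fraction in \{0.1, 1/3, 0.5\},
#' minimum node size in \{3, 5, 10\}.
#' @return data.frame of hyperparameter combinations.
#' @export
default_rf_grid <- function() {
  expand.grid(num_trees = c(500L, 1000L), mtry_frac = c(0.1, 1 / 3, 0.5),
              min_node = c(3L, 5L, 10L), KEEP.OUT.ATTRS = FALSE)
}

# Internal: one xgboost fit with fixed C++ RNG seed.
fit_xgb <- function(X, y, params, nrounds, seed) {
  stopifnot(!is.null(colnames(X)))
  dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  params <- c(params, list(objective = "reg:squarederror", nthread = 1,
                           seed = as.integer(seed)))
  xgboost::xgb.train(params = params, data = dm, nrounds = nrounds, verbose = 0)
}

rf_xgb_params <- function(hyper) {
  list(max_depth = 8, eta = 1, num_parallel_tree = as.integer(hyper$num_trees),
       subsample = 0.8, colsample_bynode = hyper$mtry_frac,
       min_child_weight = as.integer(hyper$min_node))
}

#' Fit one regression random forest
#'
#' @param X complete, scaled feature matrix with colnames; @param y response.
#' @param hyper list/row with `num_trees`, `mtry_frac`, `min_node`.
#' @param seed integer seed (reproduces the fit exactly).
#' @return an `xgb.Booster`.
#' @export
fit_rf_model <- function(X, y, hyper, seed) {
  fit_xgb(X, y, rf_xgb_params(hyper), nrounds = 1L, seed = seed)
}

# Total split gain (impurity/variance reduction) per feature; features never
# used as a split contribute exactly 0.
raw_gain_importance <- function(model, feature_ids) {
  dt <- xgboost::xgb.model.dt.tree(model = model)
  splits <- dt$Feature != "Leaf"
  agg <- tapply(dt$Gain[splits], dt$Feature[splits], sum)
  imp <- stats::setNames(rep(0, length(feature_ids)), feature_ids)
  imp[names(agg)] <- as.numeric(agg)
  imp
}

# k-fold out-of-fold predictions, deterministic in `seed`.
kfold_oof <- function(X, y, cv_folds, seed, fit_fun) {
  n <- length(y)
  folds <- with_stream(substream_seed(seed, "folds"),
                       sample(rep_len(seq_len(cv_folds), n)))
  pred <- numeric(n)
  for (f in seq_len(cv_folds)) {
    idx <- folds == f
    model <- fit_fun(X[!idx, , drop = FALSE], y[!idx],
                     substream_seed(seed, "cvfit", f))
    pred[idx] <- predict(model, X[idx, , drop = FALSE])
  }
  pred
}

#' Grid-search tuning of the random forest by cross-validated RMSE
#'
#' Returns the grid point with minimal mean CV RMSE; ties break toward fewer
#' trees, then a smaller per-split feature fraction.
#'
#' @param X,y data; @param grid data.frame like [default_rf_grid()].
#' @param cv_folds folds (n >= cv_folds >= 2); @param seed RNG seed.
#' @return list with `best` (hyperparameter list), `cv_rmse`, and the scored `table`.
#' @export
tune_rf <- function(X, y, grid = default_rf_grid(), cv_folds = 5L, seed = 1L) {
  if (nrow(grid) == 0L) stop("empty tuning grid", call. = FALSE)
  if (length(y) < cv_folds) stop("n < cv_folds", call. = FALSE)
  if (cv_folds < 2L) stop("cv_folds must be >= 2", call. = FALSE)
  ord <- order(grid$num_trees, grid$mtry_frac)
  grid <- grid[ord, , drop = FALSE]
  rmse <- vapply(seq_len(nrow(grid)), function(i) {
    pred <- kfold_oof(X, y, cv_folds, seed,
                      function(Xtr, ytr, s) fit_rf_model(Xtr, ytr, grid[i, ], s))
    sqrt(mean((y - pred)^2))
  }, numeric(1))
  best <- which.min(rmse) # which.min takes the first minimum: the tie-break order
  list(best = as.list(grid[best, , drop = FALSE]), cv_rmse = rmse[best],
       table = cbind(grid, cv_rmse = rmse))
}

#' Fit per-trait forests and collect raw importances
#'
#' One independent regression forest per trait; raw importance is the total
#' impurity (variance) reduction each feature contributes across all splits.
#'
#' @param stack a `feature_stack` (scaled); @param Y accession x trait matrix.
#' @param hyper tuned hyperparameters; @param seed base seed.
#' @return a `forest_bundle`: list with `models`, `importance_raw` (p x q,
#'   >= 0), `hyper`, `seed`, `layer_of`.
#' @export
fit_forests <- function(stack, Y, hyper, seed = 1L) {
  stopifnot(inherits(stack, "feature_stack"))
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  constant <- apply(Y, 2, function(v) stats::var(v) == 0)
  if (any(constant)) {
    stop("constant trait(s): ", paste(colnames(Y)[constant], collapse = ", "),
         call. = FALSE)
  }
  models <- list()
  I_raw <- matrix(0, ncol(stack$matrix), ncol(Y),
                  dimnames = list(stack$feature_ids, colnames(Y)))
  for (j in seq_len(ncol(Y))) {
    tr <- colnames(Y)[j]
    models[[tr]] <- fit_rf_model(stack$matrix, Y[, j], hyper,
                                 substream_seed(seed, "forest", j))
    I_raw[, j] <- raw_gain_importance(models[[tr]], stack$feature_ids)
  }
  structure(list(models = models, importance_raw = I_raw, hyper = hyper,
                 seed = seed, layer_of = stack$layer_of),
            class = "forest_bundle")
}

#' Normalize a raw importance matrix column-wise
#'
#' Each trait column is divided by its sum, so columns of B^(RF) sum to one.
#'
#' @param I_raw p x q non-negative raw importance matrix.
#' @return the normalized matrix B^(RF).
#' @export
normalize_importance <- function(I_raw) {
  if (!is.matrix(I_raw)) I_raw <- as.matrix(I_raw)
  cs <- colSums(I_raw)
  if (any(cs <= 0)) {
    stop("importance column(s) with non-positive sum: ",
         paste(colnames(I_raw)[cs <= 0], collapse = ", "), call. = FALSE)
  }
  sweep(I_raw, 2, cs, "/")
}

#' Total importance per feature
#'
#' `theta_i = sum_j B^(RF)_ij`; the grand total equals the number of traits.
#'
#' @param B_rf normalized importance matrix.
#' @return named numeric vector theta.
#' @export
total_importance <- function(B_rf) {
  rowSums(B_rf)
}

#' Select features by total importance under two conditions
#'
#' `mode = "either"` keeps features whose theta strictly exceeds `threshold`
#' in at least one condition (individual-SHAP screen, threshold 0.01);
#' `mode = "both"` requires both conditions (interaction screen, 0.001).
#'
#' @param theta_control,theta_drought named theta vectors on a shared universe.
#' @param threshold strict threshold; @param mode `"either"` or `"both"`.
#' @return character vector of selected feature ids (order of `theta_control`).
#' @export
select_features <- function(theta_control, theta_drought, threshold,
                            mode = c("either", "both")) {
  mode <- match.arg(mode)
  if (!setequal(names(theta_control), names(theta_drought))) {
    stop("theta vectors must share one feature universe", call. = FALSE)
  }
  theta_drought <- theta_drought[names(theta_control)]
  keep <- if (mode == "either") {
    theta_control > threshold | theta_drought > threshold
  } else {
    theta_control > threshold & theta_drought > threshold
  }
  out <- names(theta_control)[keep]
  if (length(out) == 0L) warning("no features selected at threshold ", threshold)
  out
}

#' Permutation check of predictive signal
#'
#' Compares the forest's cross-validated R^2 on the observed response with a
#' null distribution from refitting after randomly permuting the response.
#'
#' @param stack a `feature_stack` (or plain matrix with colnames).
#' @param y response vector; @param hyper forest hyperparameters.
#' @param n_perm permutation replicates (>= 10); @param cv_folds folds.
#' @param seed base seed (same seed reproduces the same permutations).
#' @return list with `observed_r2`, `null_r2`, and `quantile` (the observed
#'   score's empirical quantile within the null).
#' @export
permutation_signal_check <- function(stack, y, hyper, n_perm = 20L,
                                     cv_folds = 5L, seed = 1L) {
  if (n_perm < 10L) stop("n_perm must be >= 10", call. = FALSE)
  X <- if (inherits(stack, "feature_stack")) stack$matrix else stack
  cv_r2 <- function(resp, s) {
    pred <- kfold_oof(X, resp, cv_folds, s,
                      function(Xtr, ytr, sf) fit_rf_model(Xtr, ytr, hyper, sf))
    1 - sum((resp - pred)^2) / sum((resp - mean(resp))^2)
  }
  observed <- cv_r2(y, substream_seed(seed, "obs"))
  null <- vapply(seq_len(n_perm), function(b) {
    yp <- with_stream(substream_seed(seed, "perm", b), sample(y))
    cv_r2(yp, substream_seed(seed, "permcv", b))
  }, numeric(1))
  list(observed_r2 = observed, null_r2 = null,
       quantile = mean(null < observed))
}

#' Run the random-forest importance stage for one study
#'
#' @param study complete [omics_study()]; layers are scaled, stacked, and one
#'   forest per trait is fit with `hyper` (tuned first when `hyper` is NULL,
#'   on the representative trait).
#' @param hyper optional hyperparameters; @param grid tuning grid;
#' @param tune_trait trait used for tuning; @param cv_folds,seed controls.
#' @return list with `stack`, `bundle`, `B_rf`, `theta`.
#' @export
run_rf_importance <- function(study, hyper = NULL, grid = default_rf_grid(),
                              tune_trait = "leaf_dry_weight", cv_folds = 5L,
                              seed = 1L) {
  stopifnot(inherits(study, "omics_study"))
  layers <- lapply(study$layers, function(l) layer_unchecked(l$name, scale_columns(l$data)))
  scaled <- omics_study(study$condition, layers, study$phenotypes)
  stack <- build_feature_stack(scaled)
  if (is.null(hyper)) {
    if (!tune_trait %in% study$trait_names) tune_trait <- study$trait_names[1]
    hyper <- tune_rf(stack$matrix, study$phenotypes[, tune_trait], grid,
                     cv_folds, substream_seed(seed, "tune"))$best
  }
  bundle <- fit_forests(stack, study$phenotypes, hyper, seed)
  B_rf <- normalize_importance(bundle$importance_raw)
  list(stack = stack, bundle = bundle, B_rf = B_rf,
       theta = total_importance(B_rf), hyper = hyper)
}
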