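# Individual-feature SHAP attribution on per-condition tree ensembles:
# exact tree-path SHAP values, mean-|SHAP| summaries, and the
# drought/control log2-ratio screen for condition-specific features.

#' Exact TreeSHAP explanation of a tree-ensemble model
#'
#' Computes exact path-dependent TreeSHAP values for every sample; per sample
#' the base value plus the row sum equals the model prediction (local
#' accuracy), and features used in no tree get an identically zero column.
#'
#' @param model an `xgb.Booster` fitted on exactly the columns of `X`.
#' @param X complete matrix with the model's feature columns.
#' @param condition optional condition tag carried on the result.
#' @return a `shap_matrix`: list with `values` (n x p), `base` (expected
#'   prediction), `feature_ids`, `condition`.
#' @export
explain_model <- function(model, X, condition = NULL) {
  feats <- xgboost::getinfo(model, "feature_name")
  if (length(feats) && !identical(feats, colnames(X))) {
    stop("feature mismatch between model and X", call. = FALSE)
  }
  contrib <- predict(model, xgboost::xgb.DMatrix(X, nthread = 1),
                     predcontrib = TRUE)
  p <- ncol(X)
  structure(list(values = contrib[, seq_len(p), drop = FALSE],
                 base = contrib[1, p + 1L],
                 feature_ids = colnames(X), condition = condition),
            class = "shap_matrix")
}

#' Refit a per-condition model on a selected feature subset
#'
#' Restricts the feature stack to the selection (every id must exist) and
#' refits the forest with the same engine, hyperparameters and seed stream as
#' [fit_forests()]; selecting all features therefore reproduces the original
#' fit for the same seed.
#'
#' @param stack a `feature_stack`; @param y response vector for the chosen trait.
#' @param selected_features ids from [select_features()].
#' @param hyper forest hyperparameters; @param seed seed;
#' @param trait_index index of the trait within the original fit's seed fan-out.
#' @return list with `model`, `X` (restricted matrix), `layer_of`.
#' @export
refit_on_selection <- function(stack, y, selected_features, hyper, seed = 1L,
                               trait_index = 1L) {
  stopifnot(inherits(stack, "feature_stack"))
  if (length(selected_features) == 0L) stop("empty feature selection", call. = FALSE)
  missing <- setdiff(selected_features, stack$feature_ids)
  if (length(missing)) {
    stop("selected feature(s) absent from stack: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- stack$feature_ids[stack$feature_ids %in% selected_features]
  X <- stack$matrix[, keep, drop = FALSE]
  model <- fit_rf_model(X, y, hyper, substream_seed(seed, "forest", trait_index))
  list(model = model, X = X, layer_of = stack$layer_of[keep])
}

#' Mean absolute SHAP value per feature
#'
#' @param shap a `shap_matrix`.
#' @return named non-negative vector, `v_i = mean_samples |phi_i|`.
#' @export
mean_abs_shap <- function(shap) {
  stopifnot(inherits(shap, "shap_matrix"))
  stats::setNames(colMeans(abs(shap$values)), shap$feature_ids)
}

#' Drought/control log2 ratio of mean absolute SHAP values
#'
#' `r = log2(mean_drought / mean_control)`; features with a zero control mean
#' (or zero drought mean, where the log ratio is -Inf) are flagged invalid,
#' reported via `message()`, and excluded from ranking.
#'
#' @param summary_drought,summary_control named mean-|SHAP| vectors on a
#'   shared feature universe.
#' @param display_threshold two-sided strict display screen on |r|
#'   (default 2.5).
#' @return data.frame with `feature`, `mean_control`, `mean_drought`,
#'   `log2_ratio`, `valid`, `display` (|r| > threshold), sorted by |r| among
#'   valid features.
#' @export
shap_log2_ratio <- function(summary_drought, summary_control,
                            display_threshold = 2.5) {
  if (!setequal(names(summary_drought), names(summary_control))) {
    stop("summaries must share one feature universe", call. = FALSE)
  }
  feats <- names(summary_control)
  d <- summary_drought[feats]
  cc <- summary_control[feats]
  valid <- cc > 0 & d > 0
  if (any(!valid)) {
    message("excluded ", sum(!valid),
            " feature(s) with zero mean |SHAP| in a condition: ",
            paste(utils::head(feats[!valid], 5), collapse = ", "))
  }
  r <- rep(NA_real_, length(feats))
  r[valid] <- log2(d[valid] / cc[valid])
  out <- data.frame(feature = feats, mean_control = as.numeric(cc),
                    mean_drought = as.numeric(d), log2_ratio = r,
                    valid = valid,
                    display = !is.na(r) & abs(r) > display_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-abs(ifelse(is.na(out$log2_ratio), -Inf, out$log2_ratio))), ]
}

#' Run the individual-SHAP stage for a condition pair
#'
#' Selects features with theta above `threshold` in either condition, refits
#' each condition's model on that subset for the representative trait,
#' explains both models exactly, and screens the log2 ratio.
#'
#' @param stack_control,stack_drought per-condition `feature_stack`s.
#' @param y_control,y_drought representative-trait responses.
#' @param theta_control,theta_drought total-importance vectors.
#' @param hyper forest hyperparameters; @param threshold theta screen (0.01).
#' @param ratio_threshold display screen on |log2 ratio| (2.5).
#' @param seed base seed.
#' @return list with `selected`, per-condition `shap`, `summary`
#'   (the [shap_log2_ratio()] table).
#' @export
run_shap_individual <- function(stack_control, stack_drought, y_control,
                                y_drought, theta_control, theta_drought,
                                hyper, threshold = 0.01, ratio_threshold = 2.5,
                                seed = 1L) {
  selected <- select_features(theta_control, theta_drought, threshold,
                              mode = "either")
  rc <- refit_on_selection(stack_control, y_control, selected, hyper,
                           substream_seed(seed, "control"))
  rd <- refit_on_selection(stack_drought, y_drought, selected, hyper,
                           substream_seed(seed, "drought"))
  shap_c <- explain_model(rc$model, rc$X, condition = "control")
  shap_d <- explain_model(rd$model, rd$X, condition = "drought")
  summary <- shap_log2_ratio(mean_abs_shap(shap_d), mean_abs_shap(shap_c),
                             display_threshold = ratio_threshold)
  list(selected = selected, shap_control = shap_c, shap_drought = shap_d,
       summary = summary)
}
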