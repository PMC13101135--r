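# Multi-kernel linear mixed model (BLUP): per-layer linear kernels, EM-REML
# variance components, per-layer BLUPs, feature-coefficient back-projection,
# column standardization, and SVD latent feature-trait maps.
#
# Model per trait j:  y = 1*mu + sum_l u_l + e,
#   Var[y] = sum_l K_l sigma_l^2 + I sigma_e^2   (one record per accession,
# so every incidence matrix Z_l is the identity and is not carried around).

#' Linear (inner-product) kernel of a scaled feature matrix
#'
#' @param X n x p_l complete, column-scaled feature matrix.
#' @return K = X X' / p_l, a symmetric PSD n x n matrix.
#' @export
linear_kernel <- function(X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (ncol(X) == 0L) stop("feature matrix has zero columns", call. = FALSE)
  if (anyNA(X)) stop("feature matrix must be complete", call. = FALSE)
  tcrossprod(X) / ncol(X)
}

# REML log-likelihood pieces for the intercept-only mixed model, generic path.
reml_pieces <- function(y, V) {
  n <- length(y)
  ch <- chol(V)
  Vinv <- chol2inv(ch)
  one <- rep(1, n)
  Vi1 <- Vinv %*% one
  a <- drop(crossprod(one, Vi1))
  mu <- drop(crossprod(Vi1, y)) / a
  Py <- Vinv %*% y - Vi1 * (drop(crossprod(Vi1, y)) / a)
  P <- Vinv - tcrossprod(Vi1) / a
  ll <- -0.5 * (2 * sum(log(diag(ch))) + log(a) + drop(crossprod(y, Py)))
  list(P = P, Py = drop(Py), mu = mu, Vinv = Vinv, loglik = ll)
}

#' Fit a multi-kernel mixed model by EM-REML
#'
#' Variance components for each kernel plus the residual are estimated by a
#' monotone EM-REML fixed-point iteration (variance floor `1e-8`, convergence
#' when the REML log-likelihood moves by less than `tol`). Each step first
#' tries the faster multiplicative score fixed point
#' `sigma^2 <- sigma^2 * (y'P K P y) / tr(P K)` and falls back to the plain
#' EM update whenever that proposal would lower the restricted likelihood, so
#' the likelihood trace is non-decreasing. BLUPs are
#' `u_l = sigma_l^2 K_l V^{-1} (y - 1 mu)` at the fitted covariance, with a
#' GLS intercept. A single-kernel fit uses the kernel eigenbasis, making each
#' EM step O(n).
#'
#' @param y complete numeric response, length n >= 10.
#' @param kernels named list of symmetric PSD n x n kernel matrices.
#' @param max_iter,tol EM controls.
#' @return list with `components` (mu, per-layer `sigma2`, `sigma2_e`,
#'   `loglik`, `iterations`, `converged`, per-iteration `loglik_trace`) and
#'   `blup` (named list of length-n random-effect vectors).
#' @export
fit_multikernel_lmm <- function(y, kernels, max_iter = 5000L, tol = 1e-6) {
  stopifnot(is.list(kernels), length(kernels) >= 1L)
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("`y` must be complete", call. = FALSE)
  if (n < 10L) stop("need at least 10 observations", call. = FALSE)
  if (stats::var(y) == 0) stop("`y` is constant", call. = FALSE)
  for (K in kernels) stopifnot(is.matrix(K), nrow(K) == n, ncol(K) == n)
  if (is.null(names(kernels))) names(kernels) <- paste0("k", seq_along(kernels))
  L <- length(kernels)
  floor_v <- 1e-8
  vy <- stats::var(y)
  sig <- rep(vy / (L + 1), L)
  sig_e <- vy / (L + 1)
  trace <- numeric(0)

  if (L == 1L) {
    es <- eigen(kernels[[1]], symmetric = TRUE)
    lam <- pmax(es$values, 0)
    yt <- drop(crossprod(es$vectors, y))
    xt <- drop(crossprod(es$vectors, rep(1, n)))
    # O(n) REML pieces in the kernel eigenbasis
    pieces1 <- function(sg, se) {
      d <- sg * lam + se
      a <- sum(xt^2 / d)
      w <- yt / d - (xt / d) * (sum(xt * yt / d) / a)
      list(
        ll = -0.5 * (sum(log(d)) + log(a) + sum(yt * w)), w = w, d = d, a = a,
        qK = sum(lam * w^2), tK = sum(lam / d) - sum(xt^2 * lam / d^2) / a,
        qI = sum(w^2), tI = sum(1 / d) - sum(xt^2 / d^2) / a
      )
    }
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      pc <- pieces1(sig[1], sig_e)
      trace <- c(trace, pc$ll)
      if (is.finite(ll_old) && abs(pc$ll - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- pc$ll
      prop_g <- max(floor_v, sig[1] * pc$qK / pc$tK)
      prop_e <- max(floor_v, sig_e * pc$qI / pc$tI)
      if (is.finite(prop_g) && is.finite(prop_e) &&
          pieces1(prop_g, prop_e)$ll >= pc$ll) {
        sig[1] <- prop_g; sig_e <- prop_e
      } else {
        sig[1] <- max(floor_v, sig[1] + sig[1]^2 / n * (pc$qK - pc$tK))
        sig_e <- max(floor_v, sig_e + sig_e^2 / n * (pc$qI - pc$tI))
      }
    }
    d <- sig[1] * lam + sig_e
    a <- sum(xt^2 / d)
    mu <- sum(xt * yt / d) / a
    w <- (yt - mu * xt) / d
    u <- list(drop(es$vectors %*% (sig[1] * lam * w)))
    names(u) <- names(kernels)
    iterations <- it
  } else {
    piecesL <- function(sg, se) {
      V <- diag(se, n)
      for (l in seq_len(L)) V <- V + sg[l] * kernels[[l]]
      pc <- reml_pieces(y, V)
      qK <- tK <- numeric(L)
      for (l in seq_len(L)) {
        qK[l] <- drop(crossprod(pc$Py, kernels[[l]] %*% pc$Py))
        tK[l] <- sum(pc$P * kernels[[l]]) # tr(P K), both symmetric
      }
      c(pc, list(qK = qK, tK = tK, qI = drop(crossprod(pc$Py)),
                 tI = sum(diag(pc$P))))
    }
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      pc <- piecesL(sig, sig_e)
      trace <- c(trace, pc$loglik)
      if (is.finite(ll_old) && abs(pc$loglik - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- pc$loglik
      prop <- pmax(floor_v, sig * pc$qK / pc$tK)
      prop_e <- max(floor_v, sig_e * pc$qI / pc$tI)
      if (all(is.finite(c(prop, prop_e))) &&
          piecesL(prop, prop_e)$loglik >= pc$loglik) {
        sig <- prop; sig_e <- prop_e
      } else {
        sig <- pmax(floor_v, sig + sig^2 / n * (pc$qK - pc$tK))
        sig_e <- max(floor_v, sig_e + sig_e^2 / n * (pc$qI - pc$tI))
      }
    }
    pc <- piecesL(sig, sig_e)
    mu <- pc$mu
    resid <- drop(pc$Vinv %*% (y - mu))
    u <- lapply(seq_len(L), function(l) sig[l] * drop(kernels[[l]] %*% resid))
    names(u) <- names(kernels)
    iterations <- it
  }
  if (!converged) {
    stop(errorCondition(
      sprintf("EM-REML did not converge in %d iterations", max_iter),
      class = c("dsinet_reml_nonconvergence", "error", "condition"),
      last = list(sigma2 = stats::setNames(sig, names(kernels)),
                  sigma2_e = sig_e, loglik = trace[length(trace)])
    ))
  }
  list(
    components = list(mu = mu, sigma2 = stats::setNames(sig, names(kernels)),
                      sigma2_e = sig_e, loglik = trace[length(trace)],
                      iterations = iterations, converged = converged,
                      loglik_trace = trace),
    blup = u
  )
}

#' Evaluate the BLUP formula at given variance components
#'
#' `u_l = sigma_l^2 K_l V^{-1} (y - 1 mu)` with
#' `V = sum_l sigma_l^2 K_l + sigma_e^2 I` and a GLS intercept. A component
#' with `sigma_l^2 = 0` yields an exactly zero effect vector.
#'
#' @param y response vector; @param kernels named list of kernels.
#' @param sigma2 per-kernel variances; @param sigma2_e residual variance.
#' @return named list of length-n BLUP vectors.
#' @export
blup_effects <- function(y, kernels, sigma2, sigma2_e) {
  n <- length(y)
  V <- diag(sigma2_e, n)
  for (l in seq_along(kernels)) V <- V + sigma2[l] * kernels[[l]]
  pc <- reml_pieces(y, V)
  resid <- drop(pc$Vinv %*% (y - pc$mu))
  u <- lapply(seq_along(kernels), function(l) sigma2[l] * drop(kernels[[l]] %*% resid))
  names(u) <- names(kernels)
  u
}

#' Back-project sample-level BLUPs to feature coefficients
#'
#' For a linear kernel `K = X X' / p`, the feature coefficient vector is
#' `b = X' K^+ u` (Moore-Penrose pseudo-inverse with relative singular-value
#' cutoff `1e-10`), so that `X b = p * u` whenever K has full rank.
#'
#' @param X n x p_l scaled feature matrix underlying the kernel.
#' @param K the matching [linear_kernel()] output.
#' @param u length-n BLUP vector for this layer.
#' @return length-p_l coefficient vector, named by feature.
#' @export
reconstruct_coefficients <- function(X, K, u) {
  if (!is.matrix(X)) X <- as.matrix(X)
  u <- as.numeric(u)
  if (nrow(X) != length(u) || nrow(K) != length(u)) {
    stop("dimension mismatch between X, K and u", call. = FALSE)
  }
  s <- svd(K)
  keep <- s$d > 1e-10 * s$d[1]
  Kinv_u <- s$v[, keep, drop = FALSE] %*%
    (crossprod(s$u[, keep, drop = FALSE], u) / s$d[keep])
  stats::setNames(drop(crossprod(X, Kinv_u)), colnames(X))
}

#' Standardize each column of a coefficient matrix
#'
#' Enforces the convention `sum_i B_ij = 0` and `(1/p) sum_i B_ij^2 = 1` per
#' trait column (mean zero, mean-square one with divisor p).
#'
#' @param B_raw p x q matrix of raw coefficients.
#' @param feature_ids,trait_names,layer_of,source metadata carried on the result.
#' @return a `coefficient_matrix`: list with standardized `B` plus metadata.
#' @export
standardize_columns <- function(B_raw, feature_ids = rownames(B_raw),
                                trait_names = colnames(B_raw),
                                layer_of = NULL, source = "blup") {
  if (!is.matrix(B_raw)) B_raw <- as.matrix(B_raw)
  ctr <- sweep(B_raw, 2, colMeans(B_raw))
  ms <- colMeans(ctr^2)
  if (any(ms == 0)) {
    stop("zero-variance coefficient column(s): ",
         paste(trait_names[ms == 0], collapse = ", "), call. = FALSE)
  }
  B <- sweep(ctr, 2, sqrt(ms), "/")
  dimnames(B) <- list(feature_ids, trait_names)
  structure(list(B = B, feature_ids = feature_ids, trait_names = trait_names,
                 layer_of = layer_of, source = source),
            class = "coefficient_matrix")
}

#' SVD latent map of a feature x trait matrix
#'
#' Decomposes `B = U D V'` and projects traits as `U sqrt(D)` and features as
#' `V sqrt(D)` (first `k` factors). Each factor's sign is fixed so that its
#' largest-|loading| feature entry is positive.
#'
#' @param B a `coefficient_matrix` or a plain p x q matrix.
#' @param k number of latent factors to report (default 2).
#' @return a `latent_map`: list with `d`, `U`, `V`, `trait_projection`,
#'   `feature_projection`.
#' @export
svd_project <- function(B, k = 2L) {
  meta <- NULL
  if (inherits(B, "coefficient_matrix")) { meta <- B; B <- B$B }
  if (!is.matrix(B)) B <- as.matrix(B)
  s <- svd(B)
  for (j in seq_along(s$d)) {
    i <- which.max(abs(s$v[, j]))
    if (s$v[i, j] < 0) {
      s$v[, j] <- -s$v[, j]
      s$u[, j] <- -s$u[, j]
    }
  }
  k <- min(k, length(s$d))
  sq <- sqrt(s$d)
  trait_proj <- s$u[, seq_len(k), drop = FALSE] %*% diag(sq[seq_len(k)], k)
  feat_proj <- s$v[, seq_len(k), drop = FALSE] %*% diag(sq[seq_len(k)], k)
  # svd() drops dimnames; restore from the input matrix
  rownames(trait_proj) <- rownames(B)
  rownames(feat_proj) <- colnames(B)
  colnames(trait_proj) <- colnames(feat_proj) <- paste0("factor", seq_len(k))
  structure(list(d = s$d, U = s$u, V = s$v,
                 trait_projection = trait_proj, feature_projection = feat_proj,
                 meta = meta),
            class = "latent_map")
}

#' Run the full multi-kernel BLUP stage on one study
#'
#' Builds per-layer linear kernels from scaled layer matrices, fits the
#' multi-kernel mixed model for every trait, back-projects feature
#' coefficients, stacks them into the global matrix B and standardizes its
#' columns.
#'
#' @param study a complete (no missing values) [omics_study()].
#' @param layers layer names to include.
#' @return list with per-trait `fits`, the `coefficients`
#'   (`coefficient_matrix`) and a variance-component table `vc_table`.
#' @export
run_mkblup <- function(study, layers = c("genome", "metabolome", "microbiome")) {
  stopifnot(inherits(study, "omics_study"))
  layers <- intersect(c("genome", "metabolome", "microbiome"), layers)
  Xs <- lapply(layers, function(nm) scale_columns(study$layers[[nm]]$data))
  names(Xs) <- layers
  kernels <- lapply(Xs, linear_kernel)
  traits <- study$trait_names
  fits <- list()
  Bcols <- list()
  vc <- list()
  for (tr in traits) {
    fit <- fit_multikernel_lmm(study$phenotypes[, tr], kernels)
    fits[[tr]] <- fit
    b <- unlist(lapply(layers, function(nm) {
      reconstruct_coefficients(Xs[[nm]], kernels[[nm]], fit$blup[[nm]])
    }))
    Bcols[[tr]] <- b
    vc[[tr]] <- c(fit$components$sigma2, sigma2_e = fit$components$sigma2_e)
  }
  B_raw <- do.call(cbind, Bcols)
  layer_of <- stats::setNames(
    rep(layers, vapply(Xs, ncol, integer(1))),
    unlist(lapply(Xs, colnames))
  )
  coef <- standardize_columns(B_raw, feature_ids = rownames(B_raw),
                              trait_names = traits, layer_of = layer_of,
                              source = "blup")
  list(fits = fits, coefficients = coef,
       vc_table = do.call(rbind, vc))
}
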