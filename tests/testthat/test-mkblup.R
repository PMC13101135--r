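# Multi-kernel BLUP: kernel algebra, EM-REML against an independent profiled
# oracle, parameter recovery, coefficient back-projection, SVD latent maps.

test_that("linear kernel matches hand arithmetic and is symmetric", {
  expect_equal(linear_kernel(diag(2)), 0.5 * diag(2))
  X <- matrix(c(1, 3, 2, 4), 2, 2) # rows [1,2], [3,4]
  expect_equal(linear_kernel(X), matrix(c(2.5, 5.5, 5.5, 12.5), 2, 2))
  set.seed(1)
  K <- linear_kernel(matrix(rnorm(40), 8, 5))
  expect_lt(max(abs(K - t(K))), 1e-12)
  expect_error(linear_kernel(matrix(numeric(0), 2, 0)), "zero columns")
})

test_that("EM-REML agrees with the profiled single-kernel oracle", {
  set.seed(42)
  n <- 200
  X <- matrix(rnorm(n * 50), n)
  K <- tcrossprod(scale(X)) / 50
  y <- drop(t(chol(K + 1e-6 * diag(n))) %*% rnorm(n)) + rnorm(n)
  fit <- fit_multikernel_lmm(y, list(g = K))
  ora <- reml_oracle_1k(y, K)
  expect_equal(fit$components$sigma2[["g"]], ora$sigma2_g, tolerance = 0.02)
  expect_equal(fit$components$sigma2_e, ora$sigma2_e, tolerance = 0.02)
  expect_equal(fit$components$loglik, ora$loglik, tolerance = 1e-4)
  # the EM trace is monotone non-decreasing
  expect_false(is.unsorted(fit$components$loglik_trace))
})

test_that("REML recovers variance components in simulation", {
  # sigma_g^2 = sigma_e^2 = 1, n = 500; a handful of replicates here, the
  # full 50-replicate recovery study lives in the acceptance suite
  n <- 500
  est <- t(vapply(1:5, function(r) {
    set.seed(100 + r)
    X <- matrix(rnorm(n * 200), n)
    K <- tcrossprod(scale(X)) / 200
    g <- drop(t(chol(K + 1e-8 * diag(n))) %*% rnorm(n))
    y <- g + rnorm(n)
    fit <- fit_multikernel_lmm(y, list(g = K))
    c(fit$components$sigma2[["g"]], fit$components$sigma2_e)
  }, numeric(2)))
  expect_equal(mean(est[, 1]), 1, tolerance = 0.15)
  expect_equal(mean(est[, 2]), 1, tolerance = 0.15)
})

test_that("an irrelevant second kernel absorbs little variance", {
  n <- 300
  frac <- vapply(1:3, function(r) {
    set.seed(200 + r)
    X1 <- matrix(rnorm(n * 100), n)
    K1 <- tcrossprod(scale(X1)) / 100
    X2 <- matrix(rnorm(n * 100), n)
    K2 <- tcrossprod(scale(X2)) / 100
    y <- drop(t(chol(K1 + 1e-8 * diag(n))) %*% rnorm(n)) + rnorm(n)
    fit <- fit_multikernel_lmm(y, list(real = K1, fake = K2))
    fit$components$sigma2[["fake"]] / var(y)
  }, numeric(1))
  expect_lt(mean(frac), 0.1)
})

test_that("errors carry diagnostics and degenerate inputs are caught", {
  K <- diag(20)
  expect_error(fit_multikernel_lmm(rep(1, 20), list(K)), "constant")
  expect_error(fit_multikernel_lmm(rnorm(5), list(diag(5))), "10")
  set.seed(3)
  y <- rnorm(20)
  err <- tryCatch(fit_multikernel_lmm(y, list(K), max_iter = 1),
                  error = identity)
  expect_s3_class(err, "dsinet_reml_nonconvergence")
  expect_true(is.numeric(err$last$sigma2_e)) # last iterate attached
})

test_that("BLUP formula gives exact zero for a zeroed component and shrinks with noise", {
  set.seed(7)
  n <- 40
  X <- matrix(rnorm(n * 10), n)
  K <- tcrossprod(scale(X)) / 10
  y <- rnorm(n)
  u <- blup_effects(y, list(g = K, h = diag(n)), sigma2 = c(1, 0), sigma2_e = 1)
  expect_identical(unname(u$h), rep(0, n))
  # ||u|| non-increasing in sigma_e^2 on a one-kernel grid
  norms <- vapply(c(0.1, 0.5, 1, 2, 5), function(se) {
    sqrt(sum(blup_effects(y, list(g = K), 1, se)$g^2))
  }, numeric(1))
  expect_false(is.unsorted(rev(norms)))
})

test_that("coefficient reconstruction satisfies its algebraic identities", {
  # X = I2, K = 0.5 I, u = (1,2) -> b = X' K^-1 u = (2,4)
  b <- reconstruct_coefficients(diag(2), linear_kernel(diag(2)), c(1, 2))
  expect_equal(unname(b), c(2, 4))
  expect_identical(unname(reconstruct_coefficients(diag(2), 0.5 * diag(2),
                                                   c(0, 0))), c(0, 0))
  # full-rank K: X b = p * u
  set.seed(11)
  X <- matrix(rnorm(15 * 40), 15, 40)
  K <- linear_kernel(X)
  u <- rnorm(15)
  b <- reconstruct_coefficients(X, K, u)
  expect_lt(max(abs(X %*% b - 40 * u)), 1e-8)
  expect_error(reconstruct_coefficients(X, K, rnorm(10)), "mismatch")
})

test_that("reconstruct -> restandardize is invariant to positive rescaling of u", {
  set.seed(12)
  X <- matrix(rnorm(20 * 30), 20, 30,
              dimnames = list(NULL, paste0("f", 1:30)))
  K <- linear_kernel(X)
  u <- rnorm(20)
  b1 <- reconstruct_coefficients(X, K, u)
  b2 <- reconstruct_coefficients(X, K, 3.7 * u)
  B1 <- standardize_columns(cbind(t1 = b1))
  B2 <- standardize_columns(cbind(t1 = b2))
  expect_equal(B1$B, B2$B, tolerance = 1e-10)
})

test_that("column standardization enforces mean 0 / mean-square 1", {
  B <- standardize_columns(cbind(t1 = c(1, 2, 3)))
  expect_equal(unname(B$B[, 1]), c(-sqrt(1.5), 0, sqrt(1.5)))
  # idempotence
  again <- standardize_columns(B$B)
  expect_equal(again$B, B$B, tolerance = 1e-12)
  expect_error(standardize_columns(cbind(flat = c(5, 5, 5))), "flat")
})

test_that("SVD projection is an exact factorization with fixed signs", {
  set.seed(13)
  B <- matrix(rnorm(100), 20, 5,
              dimnames = list(paste0("f", 1:20), paste0("t", 1:5)))
  lm_ <- svd_project(B)
  expect_lt(max(abs(lm_$U %*% diag(lm_$d) %*% t(lm_$V) - B)), 1e-8)
  expect_lt(max(abs(crossprod(lm_$U) - diag(5))), 1e-10)
  expect_lt(max(abs(crossprod(lm_$V) - diag(5))), 1e-10)
  expect_false(is.unsorted(rev(lm_$d)))
  # sign convention: the largest-|loading| feature entry of each factor > 0
  for (j in 1:2) expect_gt(lm_$V[which.max(abs(lm_$V[, j])), j], 0)
  # (U sqrt(D)) (V sqrt(D))' reconstructs B
  k <- length(lm_$d)
  full <- svd_project(B, k = k)
  expect_lt(max(abs(full$trait_projection %*% t(full$feature_projection) - B)),
            1e-8)
  # rank-1 input has a single singular value
  r1 <- svd_project(outer(rnorm(6), rnorm(3)))
  expect_lt(r1$d[2], 1e-10)
})
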