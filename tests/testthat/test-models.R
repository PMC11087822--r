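test_that("naive predictor scores every new drug with ADR prevalence", {
  Y <- interaction_matrix(matrix(c(1, 1, 0, 1), 2, 2),
                          c("a1", "a2"), c("d1", "d2"))
  sc <- naive_fit_predict(Y, c("n1", "n2", "n3"))
  expect_equal(unname(sc[, 1]), c(0.5, 1.0))
  expect_true(all(sc == sc[, 1]))                    # constant across drugs

  Yz <- interaction_matrix(rbind(c(0, 0), c(1, 0)), c("a1", "a2"),
                           c("d1", "d2"))
  expect_equal(unname(naive_fit_predict(Yz, "n1")[1, 1]), 0)

  Yr <- random_interaction_matrix(20, 15, seed = 6)
  sc <- naive_fit_predict(Yr, "new")
  expect_equal(unname(sc[, 1]), unname(apply(Yr$values, 1, sum) / 15))
})

test_that("kr_fit solves the penalized least-squares objective", {
  X <- random_feature_table(12, 20, seed = 7)
  K <- rbf_kernel(X, X, 2)
  set.seed(8)
  targ <- matrix(rnorm(12 * 3), 12, 3)

  # lambda = 0 with invertible K interpolates
  W0 <- kr_fit(K, targ, 0)
  expect_lt(max(abs(K$values %*% W0$W - targ)), 1e-6)

  # massive shrinkage kills the coefficients
  Wbig <- kr_fit(K, targ, 1e8)
  expect_lt(sqrt(sum(Wbig$W^2)), 1e-4)

  # closed form matches an independent iterative minimizer
  W1 <- kr_fit(K, targ, 1)
  obj <- function(W) sum((targ - K$values %*% W)^2) + sum(W^2)
  o <- kr_optim_oracle(K$values, targ, 1)
  expect_lt(abs(obj(W1$W) - o$value) / o$value, 1e-6)

  # rkhs variant solves (K + lambda I) W = targets
  Wr <- kr_fit(K, targ, 0.5, form = "rkhs")
  expect_equal((K$values + diag(0.5, 12)) %*% Wr$W, targ, ignore_attr = TRUE)

  expect_error(kr_fit(K, targ, -1), "non-negative")
  expect_error(kr_fit(K, targ[1:5, ], 1), "target rows")
})

test_that("kr_predict returns K_new W and interpolates duplicated drugs", {
  X <- random_feature_table(10, 15, seed = 9)
  K <- rbf_kernel(X, X, 2)
  set.seed(10)
  targ <- matrix(rnorm(10 * 2), 10, 2)
  W <- kr_fit(K, targ, 0)
  # a new drug identical to training drug 4 reproduces its target row
  Kn <- structure(list(values = K$values[4, , drop = FALSE], sigma = 2,
                       source_features = "rand"), class = "kernel_matrix")
  expect_equal(kr_predict(Kn, W), targ[4, , drop = FALSE],
               ignore_attr = TRUE, tolerance = 1e-5)

  Kz <- structure(list(values = matrix(0, 2, 10), sigma = 2,
                       source_features = "rand"), class = "kernel_matrix")
  expect_true(all(kr_predict(Kz, W) == 0))
  expect_error(kr_predict(Kz, kr_fit(rbf_kernel(random_feature_table(5, 15,
    seed = 1), sigma = 2), matrix(rnorm(10), 5, 2), 1)), "match")
})

test_that("kr predictions scale linearly with the targets", {
  X <- random_feature_table(9, 12, seed = 11)
  K <- rbf_kernel(X, X, 1.5)
  set.seed(12)
  targ <- matrix(rnorm(9 * 4), 9, 4)
  p1 <- kr_predict(K, kr_fit(K, targ, 2))
  p3 <- kr_predict(K, kr_fit(K, 3 * targ, 2))
  expect_equal(p3, 3 * p1, tolerance = 1e-10)
})

test_that("nmf_factorize descends monotonically and recovers planted factors", {
  Yr <- random_interaction_matrix(30, 20, density = 0.3, seed = 13)
  fp <- nmf_factorize(Yr, 5, seed = 13, max_iter = 200, tol = 0)
  expect_true(all(fp$U >= 0) && all(fp$V >= 0))
  expect_true(all(diff(fp$objective_trace) <= 1e-10))
  # stored objective agrees with a recomputation from the factors
  expect_lt(abs(fp$objective - sum((Yr$values - tcrossprod(fp$U, fp$V))^2)) /
              max(fp$objective, 1), 1e-8)

  # planted rank-1 structure is recovered essentially exactly
  set.seed(14)
  u <- rgamma(25, 1); v <- rgamma(18, 1)
  Yp <- outer(u, v)
  fp1 <- nmf_factorize(Yp, 1, seed = 3, max_iter = 2000, tol = 0)
  expect_lt(fp1$objective, 1e-6 * sum(Yp^2))

  Y0 <- matrix(0, 4, 4)
  fp0 <- nmf_factorize(Y0, 2, seed = 1)
  expect_equal(fp0$objective, 0)
  expect_true(all(fp0$U == 0) && all(fp0$V == 0))

  expect_error(nmf_factorize(Yr, 21, seed = 1), "L must be")
})

test_that("nmf_factorize is deterministic for a fixed seed", {
  Yr <- random_interaction_matrix(15, 12, seed = 15)
  a <- nmf_factorize(Yr, 3, seed = 42)
  b <- nmf_factorize(Yr, 3, seed = 42)
  expect_identical(a, b)
  c <- nmf_factorize(Yr, 3, seed = 43)
  expect_false(identical(a$U, c$U))
})

test_that("vkr composition reconstructs exactly-low-rank data", {
  # binary block matrix of exact non-negative rank 3 (disjoint blocks),
  # invertible kernel, lambda = 0
  set.seed(16)
  M <- 12; N <- 10; L <- 3
  row_grp <- rep(1:L, length.out = M); col_grp <- rep(1:L, length.out = N)
  Y <- interaction_matrix(1 * outer(row_grp, col_grp, `==`),
                          sprintf("a%02d", 1:M), sprintf("d%03d", 1:N))
  X <- random_feature_table(N, 25, seed = 17)
  K <- rbf_kernel(X, X, 2)
  fit <- vkr_fit(Y, K, L = L, lambda = 0, seed = 5,
                 max_iter = 20000, tol = 0)
  recon <- vkr_predict(fit$factors$U, fit$coef, K)
  expect_lt(max(abs(recon - Y$values)), 1e-4)

  # shrinkage limit: enormous lambda drives scores to ~0
  fitL <- vkr_fit(Y, K, L = 2, lambda = 1e10, seed = 5)
  expect_lt(max(abs(vkr_predict(fitL$factors$U, fitL$coef, K))), 1e-3)

  # fixed seed gives bit-identical factors and coefficients
  f1 <- vkr_fit(Y, K, L = 2, lambda = 1, seed = 9)
  f2 <- vkr_fit(Y, K, L = 2, lambda = 1, seed = 9)
  expect_identical(f1, f2)
})

test_that("vkr_predict composes U with the kernel-regressed drug factor", {
  set.seed(18)
  U <- diag(3)
  W <- structure(list(W = matrix(rnorm(12), 4, 3), lambda = 1,
                      form = "primal"), class = "coefficient_matrix")
  Kn <- structure(list(values = matrix(runif(8), 2, 4), sigma = 1,
                       source_features = "x"), class = "kernel_matrix")
  expect_equal(vkr_predict(U, W, Kn), t(Kn$values %*% W$W),
               ignore_attr = TRUE)
  Kz <- structure(list(values = matrix(0, 2, 4), sigma = 1,
                       source_features = "x"), class = "kernel_matrix")
  expect_true(all(vkr_predict(U, W, Kz) == 0))
  expect_error(vkr_predict(matrix(1, 3, 2), W, Kn), "component counts")
})

test_that("new drug identical to a training drug gets its NMF reconstruction", {
  set.seed(19)
  Y <- random_interaction_matrix(14, 9, density = 0.35, seed = 19)
  X <- random_feature_table(9, 30, seed = 20)
  K <- rbf_kernel(X, X, 2)
  fit <- vkr_fit(Y, K, L = 4, lambda = 0, seed = 2)
  j <- 5
  Kn <- structure(list(values = K$values[j, , drop = FALSE], sigma = 2,
                       source_features = "rand"), class = "kernel_matrix")
  sc <- vkr_predict(fit$factors$U, fit$coef, Kn)
  expect_equal(unname(sc[, 1]),
               unname(fit$factors$U %*% fit$factors$V[j, ])[, 1],
               tolerance = 1e-4)
})

test_that("mkr blends two single-kernel KR score matrices", {
  Xa <- random_feature_table(10, 15, seed = 21, name = "DGI")
  Xb <- random_feature_table(10, 18, seed = 22, name = "Chem")
  Xan <- random_feature_table(3, 15, seed = 23); Xbn <- random_feature_table(3, 18, seed = 24)
  rownames(Xan$values) <- Xan$drug_ids <- sprintf("n%d", 1:3)
  rownames(Xbn$values) <- Xbn$drug_ids <- sprintf("n%d", 1:3)
  pa <- list(train = rbf_kernel(Xa, Xa, 2), new = rbf_kernel(Xan, Xa, 2))
  pb <- list(train = rbf_kernel(Xb, Xb, 3), new = rbf_kernel(Xbn, Xb, 3))
  set.seed(25)
  targ <- matrix(rnorm(10 * 4), 10, 4)

  s1 <- kr_predict(pa$new, kr_fit(pa$train, targ, 0.5))
  s2 <- kr_predict(pb$new, kr_fit(pb$train, targ, 2))
  expect_equal(mkr_fit_predict(list(pa, pb), targ, c(0.5, 2), mix = 1), s1)
  expect_equal(mkr_fit_predict(list(pa, pb), targ, c(0.5, 2), mix = 0.4),
               0.4 * s1 + 0.6 * s2)
  expect_equal(mkr_fit_predict(list(pa, pa), targ, c(0.5, 0.5), mix = 0.3),
               kr_predict(pa$new, kr_fit(pa$train, targ, 0.5)))
  expect_error(mkr_fit_predict(list(pa, pb), targ, c(1, 1), mix = 1.2),
               "mix")
})

test_that("a flat kernel makes KR scores constant per ADR (naive-like limit)", {
  Y <- random_interaction_matrix(8, 12, density = 0.3, seed = 26)
  X <- random_feature_table(12, 20, seed = 27)
  Xn <- random_feature_table(4, 20, seed = 28)
  rownames(Xn$values) <- Xn$drug_ids <- sprintf("n%d", 1:4)
  K <- rbf_kernel(X, X, 1e6)
  Kn <- rbf_kernel(Xn, X, 1e6)
  W <- kr_fit(K, t(Y$values), lambda = 1)
  sc <- t(kr_predict(Kn, W))                       # ADR x new drug
  spread <- apply(sc, 1, function(r) diff(range(r)))
  expect_lt(max(spread), 1e-6)
})
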