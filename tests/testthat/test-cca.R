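test_that("standardize centres and scales exactly", {
  expect_equal(as.vector(standardize(matrix(1:3))), c(-1, 0, 1))
  set.seed(2)
  X <- matrix(rnorm(50 * 4, mean = 5, sd = 3), 50, 4)
  Z <- standardize(X)
  expect_equal(unname(colMeans(Z)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unclass(unname(standardize(Z))), unclass(unname(Z)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(standardize(cbind(a = rep(2, 5), b = 1:5)), "zero-variance")
})

test_that("identical one-column blocks give a canonical correlation of 1", {
  x <- rnorm(30)
  fit <- fit_cca(matrix(x), matrix(x))
  expect_equal(fit$cor, 1, tolerance = 1e-10)
})

test_that("canonical correlations match the generalized-eigenproblem oracle", {
  # fixed small integer table, then random instances
  X <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8,
                2, 1, 4, 3, 6, 5, 8, 7), 8, 2)
  Y <- matrix(c(1, 3, 2, 5, 4, 7, 6, 8,
                8, 6, 7, 4, 5, 2, 3, 2), 8, 2)
  expect_equal(fit_cca(X, Y)$cor, cca_oracle(X, Y), tolerance = 1e-8)
  for (seed in 1:5) {
    set.seed(seed)
    p <- sample(2:4, 1); q <- sample(2:4, 1)
    Xr <- matrix(rnorm(100 * p), 100, p)
    Yr <- Xr[, 1] %o% runif(q) + matrix(rnorm(100 * q), 100, q)
    expect_equal(fit_cca(Xr, Yr)$cor, cca_oracle(Xr, Yr), tolerance = 1e-8)
  }
})

test_that("canonical correlations are invariant to within-block mixing and scaling", {
  set.seed(10)
  s <- planted_cca_sample(300, 3, 4, c(0.7, 0.3), seed = 10)
  base <- fit_cca(s$X, s$Y)$cor
  for (seed in 1:5) {
    set.seed(seed)
    Mx <- matrix(rnorm(9), 3, 3); My <- matrix(rnorm(16), 4, 4)
    stopifnot(abs(det(Mx)) > 1e-6, abs(det(My)) > 1e-6)
    mixed <- fit_cca(s$X %*% Mx, s$Y %*% My)$cor
    expect_equal(mixed, base, tolerance = 1e-8)
  }
  # shifting and scaling raw variables changes nothing
  X2 <- sweep(sweep(s$X, 2, c(3, -2, 100), `*`), 2, c(1, 5, -7), `+`)
  expect_equal(fit_cca(X2, s$Y)$cor, base, tolerance = 1e-10)
})

test_that("independent blocks yield near-zero canonical correlations", {
  set.seed(123)
  X <- matrix(rnorm(10000 * 2), ncol = 2)
  Y <- matrix(rnorm(10000 * 2), ncol = 2)
  expect_lt(max(fit_cca(X, Y)$cor), 0.05)
})

test_that("rank-deficient blocks error without ridge and fit with one", {
  set.seed(4)
  x <- rnorm(50)
  X <- cbind(x, x)  # singular climate block
  Y <- matrix(rnorm(100), 50, 2)
  expect_error(fit_cca(X, Y), "ridge")
  fit <- fit_cca(X, Y, ridge = 1e-6)
  expect_true(all(fit$cor >= 0 & fit$cor <= 1))
})

test_that("loadings, cross-loadings and scores obey the sample identities", {
  s <- planted_cca_sample(400, 4, 5, c(0.8, 0.4), seed = 77)
  fit <- fit_cca(s$X, s$Y)
  # cross-loading(v, k) = r_k * loading(v, k), exactly in-sample
  expect_equal(fit$xcross, sweep(fit$xload, 2, fit$cor, `*`),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$ycross, sweep(fit$yload, 2, fit$cor, `*`),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(abs(fit$xload) <= 1 + 1e-12))
  # unit-variance scores, positively correlated pairs, dominant loading
  # oriented positive
  expect_equal(apply(fit$scores_x, 2, sd), rep(1, 4), tolerance = 1e-8,
               ignore_attr = TRUE)
  for (k in seq_along(fit$cor)) {
    expect_equal(cor(fit$scores_x[, k], fit$scores_y[, k]), fit$cor[k],
                 tolerance = 1e-10)
    expect_gt(max(fit$xload[, k]), 0)
  }
  expect_equal(sum(fit$proportions), 100, tolerance = 1e-9)
})

test_that("eigenvalue proportions implement lambda = r^2/(1-r^2) shares", {
  expect_equal(eigen_proportions(c(0.8, 0.6)), c(75.96439, 24.03561),
               tolerance = 1e-5)
  expect_equal(eigen_proportions(0.3), 100)
  expect_error(eigen_proportions(c(0.5, 1.0)), "descending|infinite")
  expect_error(eigen_proportions(c(1.0, 0.5)), "infinite")
  expect_error(eigen_proportions(c(0.2, 0.8)), "descending")
})

test_that("sequential Bartlett tests reproduce hand-worked values", {
  t0 <- wilks_tests(c(0, 0), n = 100, p = 2, q = 2)
  expect_equal(t0$lambda, c(1, 1))
  expect_equal(t0$chisq, c(0, 0))
  expect_equal(t0$p_value, c(1, 1))

  tt <- wilks_tests(c(0.9, 0.1), n = 50, p = 2, q = 2)
  expect_equal(tt$lambda[1], 0.19 * 0.99, tolerance = 1e-12)
  expect_equal(tt$chisq[1], -46.5 * log(0.1881), tolerance = 1e-10)
  expect_equal(tt$df, c(4, 1))
  expect_equal(tt$lambda[2], 0.99, tolerance = 1e-12)
})

test_that("small samples relative to block width trigger a warning", {
  set.seed(6)
  expect_warning(fit_cca(matrix(rnorm(24), 6, 4), matrix(rnorm(18), 6, 3)),
                 "unstable")
})
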