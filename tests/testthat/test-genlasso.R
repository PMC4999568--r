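test_that("soft_threshold implements sign(z) * max(|z| - t, 0)", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(-3, 2), -1)
  expect_equal(soft_threshold(c(-2, 0, 2), c(1, 1, 3)), c(-1, 0, 0))
})

test_that("lambda_max is the exact null-model boundary", {
  set.seed(10)
  x <- rnorm(8)
  y3 <- 3 * x / sum(x * x)   # single column with x'y = 3
  expect_equal(lambda_max(matrix(x), y3), 6)
  # y orthogonal to all columns
  X <- qr.Q(qr(matrix(rnorm(40), 10)))[, 1:3]
  y <- rnorm(10)
  y <- y - X %*% crossprod(X, y)
  expect_equal(lambda_max(X, y), 0, tolerance = 1e-12)
  # grid-search oracle: smallest grid lambda with an all-zero solution
  inst <- random_instance(77, n = 10, p = 5)
  lm0 <- lambda_max(inst$X, inst$y)
  grid <- seq(0.5 * lm0, 1.5 * lm0, length.out = 201)
  zero <- vapply(grid, function(l)
    max(abs(lasso_cd(inst$X, inst$y, l))) == 0, logical(1))
  first_zero <- grid[which(zero)[1]]
  expect_lte(abs(first_zero - lm0), diff(grid[1:2]) + 1e-9)
  expect_equal(max(abs(lasso_cd(inst$X, inst$y, lm0))), 0)
})

test_that("lasso_cd recovers closed forms at the boundary cases", {
  inst <- random_instance(21, n = 12, p = 4)
  # lambda = 0: least squares
  expect_equal(lasso_cd(inst$X, inst$y, 0),
               drop(qr.solve(inst$X, inst$y)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # minimum-norm solution under rank deficiency
  Xr <- cbind(inst$X, inst$X[, 1])
  br <- lasso_cd(Xr, inst$y, 0)
  expect_equal(drop(Xr %*% br), drop(inst$X %*% qr.solve(inst$X, inst$y)),
               tolerance = 1e-8)
  expect_equal(br[1], br[5], tolerance = 1e-8)  # min-norm splits the pair
  # orthonormal design: coordinate-wise soft thresholding
  Q <- qr.Q(qr(matrix(rnorm(8), 4)))[, 1:2]
  y <- rnorm(4)
  lam <- 0.7
  expect_equal(lasso_cd(Q, y, lam),
               soft_threshold(drop(crossprod(Q, y)), lam / 2),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("coordinate-descent objective is non-increasing over sweeps", {
  for (seed in 1:5) {
    inst <- random_instance(seed + 100)
    G <- crossprod(inst$X)
    g <- drop(crossprod(inst$X, inst$y))
    tr <- infolasso:::cpp_cd_obj_trace(G, g, sum(inst$y^2),
                                       0.3 * lambda_max(inst$X, inst$y),
                                       1e-10, 10000L)
    expect_true(all(diff(tr) <= 1e-10))
  }
})

test_that("fit_penalty_free reduces to OLS at its lambda limits", {
  inst <- random_instance(31, n = 25, p = 6)
  X <- inst$X; y <- inst$y
  # lambda = 0: full OLS
  f0 <- fit_penalty_free(X, y, free = c(1, 3), lambda = 0)
  ols <- coef(lm(y ~ X))
  expect_equal(c(f0$beta0, unname(f0$beta)), unname(ols), tolerance = 1e-7)
  # very large lambda: penalized block dies, free block is OLS on [1, X_S]
  fL <- fit_penalty_free(X, y, free = c(1, 3), lambda = 1e9)
  expect_true(all(fL$beta[-c(1, 3)] == 0))
  olsS <- coef(lm(y ~ X[, c(1, 3)]))
  expect_equal(c(fL$beta0, unname(fL$beta[c(1, 3)])), unname(olsS),
               tolerance = 1e-8)
  # empty free set at lambda 0 is OLS too
  fe <- fit_penalty_free(X, y, lambda = 0)
  expect_equal(c(fe$beta0, unname(fe$beta)), unname(ols), tolerance = 1e-7)
})

test_that("every returned fit carries a passing KKT certificate", {
  for (seed in 1:40) {
    inst <- random_instance(seed + 300)
    ns <- sample(0:min(3, inst$p - 1), 1)
    S <- if (ns > 0) sample(inst$p, ns) else integer(0)
    lam <- runif(1, 0, 2 * lambda_max(inst$X, inst$y))
    fit <- fit_penalty_free(inst$X, inst$y, free = S, lambda = lam,
                            standardize = sample(c(TRUE, FALSE), 1))
    expect_true(fit$kkt$ok)
    # exact free-block stationarity
    expect_lt(fit$kkt$max_free, 1e-8)
  }
})

test_that("free-block residual orthogonality X_b' r = 0 holds exactly", {
  inst <- random_instance(55, n = 20, p = 6)
  fit <- fit_penalty_free(inst$X, inst$y, free = c(2, 5), lambda = 1.3)
  r <- inst$y - fit$beta0 - drop(inst$X %*% fit$beta)
  Xb <- cbind(1, inst$X[, c(2, 5)])
  expect_lt(max(abs(crossprod(Xb, r))), 1e-8)
})

test_that("weighted fits obey the Proposition 1 scaling identity", {
  inst <- random_instance(61, n = 20, p = 2)
  X <- inst$X; y <- inst$y
  lam <- 0.8
  f_d <- fit_weighted(X, y, d = c(2, 1), lambda = lam)
  Xh <- X; Xh[, 1] <- Xh[, 1] / 2
  f_h <- fit_weighted(Xh, y, d = c(1, 1), lambda = lam)
  expect_equal(f_d$beta[1], f_h$beta[1] / 2, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(f_d$beta[2], f_h$beta[2], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(f_d$beta0, f_h$beta0, tolerance = 1e-8)
  # all-ones weights equal the plain penalty-free lasso
  f_1 <- fit_weighted(X, y, d = c(1, 1), lambda = lam)
  f_p <- fit_penalty_free(X, y, lambda = lam, standardize = FALSE)
  expect_equal(f_1$beta, f_p$beta, tolerance = 1e-9)
})

test_that("solution path is continuous in lambda", {
  inst <- random_instance(71, n = 25, p = 8)
  lam <- 0.4 * lambda_max(inst$X, inst$y)
  f1 <- fit_penalty_free(inst$X, inst$y, lambda = lam, standardize = FALSE)
  for (eps in c(1e-2, 1e-3)) {
    f2 <- fit_penalty_free(inst$X, inst$y, lambda = lam * (1 - eps),
                           standardize = FALSE)
    expect_lt(abs(f2$objective - f1$objective) / abs(f1$objective),
              5 * eps)
  }
})

test_that("dimension and degeneracy contracts are enforced", {
  inst <- random_instance(81, n = 6, p = 8)
  expect_error(fit_penalty_free(inst$X, inst$y, free = 1:5, lambda = 1),
               "fewer columns than samples")
  # duplicated free column: pseudoinverse with a warning, fit still valid
  Xd <- cbind(inst$X[, 1], inst$X[, 1], inst$X[, 2])
  colnames(Xd) <- c("a", "b", "c")
  expect_warning(fd <- fit_penalty_free(Xd, inst$y, free = c(1, 2),
                                        lambda = 0.5),
                 "pseudoinverse")
  r <- inst$y - fd$beta0 - drop(Xd %*% fd$beta)
  expect_lt(max(abs(crossprod(cbind(1, Xd[, 1:2]), r))), 1e-8)
})
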