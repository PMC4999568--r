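test_that("each greedy criterion matches an independent stepwise scorer", {
  df <- baseline_table()
  for (mth in c("mim", "mifs", "mrmr", "jmi", "cmim")) {
    got <- greedy_mi_select(df, method = mth, K = 3, beta = 0.7)
    expect_equal(got$feature, brute_greedy(df, mth, 3, beta = 0.7),
                 info = mth)
  }
})

test_that("MIFS with beta = 0 reproduces the MIM ordering", {
  df <- baseline_table(seed = 29)
  expect_equal(greedy_mi_select(df, method = "mifs", K = 6, beta = 0)$feature,
               greedy_mi_select(df, method = "mim", K = 6)$feature)
})

test_that("MRMR equals MIFS with beta = 1/|S| at every step", {
  df <- baseline_table(seed = 31)
  mr <- greedy_mi_select(df, method = "mrmr", K = 5)
  # first pick is the marginal-MI argmax, like every criterion
  expect_equal(mr$feature[1],
               greedy_mi_select(df, method = "mim", K = 1)$feature)
  # every prefix matches the independent scorer that applies the MIFS
  # formula with beta = 1/|S| at each step (the mean-redundancy reading)
  for (k in 1:5) {
    expect_equal(mr$feature[1:k], brute_greedy(df, "mrmr", k))
  }
})

test_that("all greedy criteria agree on the first (marginal MI) pick", {
  df <- baseline_table(seed = 37)
  first <- vapply(c("mim", "mifs", "mrmr", "jmi", "cmim"), function(m)
    greedy_mi_select(df, method = m, K = 1)$feature, character(1))
  expect_length(unique(first), 1L)
})

test_that("CMIM never selects an exact duplicate of a chosen feature", {
  df <- baseline_table(seed = 41)
  df$dup <- df$s1                      # exact copy of the top feature
  got <- greedy_mi_select(df, method = "cmim", K = 6)
  expect_equal(got$feature[1], "s1")
  expect_false("dup" %in% got$feature[1:5])
  # the duplicate scores zero once s1 is in the set
  expect_equal(conditional_mi(df$dup, df$class, df$s1), 0, tolerance = 1e-12)
})

test_that("selector output is deterministic", {
  df <- baseline_table(seed = 43)
  expect_identical(greedy_mi_select(df, method = "jmi", K = 4),
                   greedy_mi_select(df, method = "jmi", K = 4))
})

test_that("SFFS dominates plain forward selection and matches exhaustive search at p = 5", {
  set.seed(47)
  n <- 40
  y <- rbinom(n, 1, 0.5)
  df <- data.frame(
    a = y + rnorm(n, sd = 0.8),
    b = y - rnorm(n, sd = 0.9),
    c = rnorm(n),
    d = rnorm(n),
    e = y * rnorm(n),
    class = y)
  sel <- sffs_select(df, max_K = 4)
  # plain SFS oracle
  crit <- function(S) evaluate_subset(df, features = S)$accuracy
  S <- character(0); sfs_best <- -Inf
  for (k in 1:4) {
    rem <- setdiff(letters[1:5], S)
    vals <- vapply(rem, function(f) crit(c(S, f)), numeric(1))
    S <- c(S, rem[which.max(vals)])
    sfs_best <- max(sfs_best, max(vals))
  }
  expect_gte(sel$criterion, sfs_best)
  # exhaustive oracle over all 31 nonempty subsets up to size 4
  subsets <- unlist(lapply(1:4, function(k)
    combn(letters[1:5], k, simplify = FALSE)), recursive = FALSE)
  best_ex <- max(vapply(subsets, crit, numeric(1)))
  expect_equal(sel$criterion, best_ex)
})

test_that("PCA-95 keeps the smallest component set reaching the variance target", {
  # construct a table whose sample covariance is exactly diag(9, .5, .5)
  set.seed(53)
  A <- matrix(rnorm(60), 20)
  Ac <- scale(A, center = TRUE, scale = FALSE)
  C <- crossprod(Ac) / 19
  X <- Ac %*% solve(chol(C)) %*% diag(sqrt(c(9, 0.5, 0.5)))
  colnames(X) <- c("a", "b", "c")
  df <- as.data.frame(X); df$class <- rep(c(0, 1), 10)
  tf <- pca95_transform(df)
  expect_equal(ncol(tf$X), 2L)      # 90% < 95% <= 95%
  ex <- attr(tf, "explained")
  expect_equal(ex$variance_fraction[1:2], c(0.9, 0.05), tolerance = 1e-9)
  # all variance in one feature -> one component
  df1 <- data.frame(a = rnorm(20), b = 0, c = 0, class = rep(c(0, 1), 10))
  expect_equal(ncol(suppressWarnings(pca95_transform(df1))$X), 1L)
  # eigendecomposition oracle on a random table
  set.seed(59)
  df2 <- as.data.frame(matrix(rnorm(200), 20))
  df2$class <- rep(c(0, 1), 10)
  tf2 <- pca95_transform(df2)
  ev <- eigen(cov(as.matrix(df2[, 1:10])), symmetric = TRUE)$values
  ex2 <- attr(tf2, "explained")
  expect_equal(sum(ex2$variance_fraction), 1, tolerance = 1e-12)
  expect_equal(ex2$variance_fraction, ev / sum(ev), tolerance = 1e-9)
})

test_that("the logistic lasso baseline honours its contracts", {
  ft <- gen_linear_binary(synthetic_spec(n = 50, p = 10, seed = 61))
  sel <- l1_logistic_select(ft)
  expect_equal(sel$accuracy, max(sel$accuracy_by_lambda$accuracy))
  expect_equal(sel$n_features, length(sel$features))
  # ties to the largest lambda
  top <- sel$accuracy_by_lambda$lambda[
    sel$accuracy_by_lambda$accuracy == sel$accuracy]
  expect_equal(sel$best_lambda, max(top))
  # subgradient conditions at the chosen lambda (glmnet scale:
  # (1/n)|x_j'(y - p)| <= lambda for zero coefficients)
  X <- ft$X; y <- ft$y; n <- nrow(X)
  eta <- sel$coefficients[1] + drop(X %*% sel$coefficients[-1])
  pr <- 1 / (1 + exp(-eta))
  score <- drop(crossprod(X, y - pr)) / n
  zero <- sel$coefficients[-1] == 0
  expect_true(all(abs(score[zero]) <= sel$best_lambda + 1e-4))
  active <- which(!zero)
  if (length(active)) {
    # glmnet's default convergence leaves a small stationarity residual
    expect_true(all(abs(score[active] -
      sel$best_lambda * sign(sel$coefficients[-1][active])) <
        0.1 * sel$best_lambda + 1e-4))
  }
  # a huge penalty leaves the intercept-only majority-class model
  sel0 <- l1_logistic_select(ft, lambda_grid = c(50, 20))
  expect_equal(sel0$n_features, 0L)
  maj <- as.integer(mean(y) >= 0.5)
  expect_equal(sel0$accuracy, mean(y == maj))
})

test_that("baseline comparison table has one row per method with valid metrics", {
  ft <- gen_linear_binary(synthetic_spec(n = 40, p = 8, seed = 67))
  tbl <- baseline_compare(ft, methods = c("mim", "cmim", "pca95"),
                          K_max = 5, top_k = 5)
  expect_equal(nrow(tbl), 3L)
  expect_true(all(tbl$accuracy >= 0 & tbl$accuracy <= 1))
  expect_true(all(tbl$n_features >= 1))
})
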