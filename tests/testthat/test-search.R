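test_that("the 0.5 decision rule sends the boundary to the positive class", {
  mk <- function(b0, b) {
    structure(list(beta0 = b0, beta = b, feature_names = names(b)),
              class = "penalty_free_fit")
  }
  X <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_true(all(classify(mk(0.5, c(a = 0, b = 0)), X) == 1L))
  expect_true(all(classify(mk(1, c(a = 0, b = 0)), X) == 1L))
  expect_true(all(classify(mk(0.49, c(a = 0, b = 0)), X) == 0L))
})

test_that("a perfectly separating free feature gives LOOCV accuracy 1", {
  set.seed(90)
  y <- rep(c(0L, 1L), each = 6)
  df <- data.frame(sig = y + 0, noise = rnorm(12), class = y)
  ev <- loocv_evaluate(df, free = "sig")
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  # and training accuracy 1 at lambda = 0 for a separated 1-D problem
  fit <- fit_penalty_free(as.matrix(df[, 1:2]), y, free = 1, lambda = 0)
  expect_equal(mean(classify(fit, as.matrix(df[, 1:2])) == y), 1)
})

test_that("LOOCV folds match a hand-built per-fold OLS oracle", {
  # all features free at lambda = 0: each fold is a plain OLS fit
  set.seed(91)
  df <- data.frame(x1 = rnorm(8), x2 = rnorm(8),
                   class = rep(c(0L, 1L), 4))
  ev <- loocv_evaluate(df, free = c("x1", "x2"), lambda_grid = 0)
  oracle <- vapply(1:8, function(f) {
    fit <- lm(class ~ x1 + x2, data = df[-f, ])
    as.integer(predict(fit, df[f, ]) >= 0.5)
  }, integer(1))
  expect_equal(ev$predictions$prediction, oracle)
  expect_equal(ev$accuracy, mean(oracle == df$class))
})

test_that("reported LOOCV accuracy is the maximum over the lambda grid", {
  ft <- gen_linear_binary(synthetic_spec(n = 30, p = 8, seed = 9))
  ev <- loocv_evaluate(ft, free = "f1")
  expect_equal(ev$accuracy, max(ev$accuracy_by_lambda$accuracy))
  # ties resolve to the largest lambda
  top <- ev$accuracy_by_lambda$lambda[
    ev$accuracy_by_lambda$accuracy == ev$accuracy]
  expect_equal(ev$best_lambda, max(top))
  # confusion identity on the per-fold predictions
  m <- infolasso:::classification_metrics(ev$predictions$truth,
                                          ev$predictions$prediction)
  expect_equal(m$accuracy, ev$accuracy)
})

test_that("independent labels give chance-level LOOCV accuracy", {
  accs <- vapply(1:100, function(s) {
    ft <- gen_linear_binary(synthetic_spec(n = 50, p = 10,
                                           informative = integer(0),
                                           coefs = numeric(0), seed = s))
    loocv_evaluate(ft, lambda_grid = c(10, 1, 0.1))$accuracy
  }, numeric(1))
  # selection over 3 lambdas lifts the maximum slightly above 0.5
  expect_gt(mean(accs), 0.40)
  expect_lt(mean(accs), 0.62)
})

test_that("stopping rule and tie semantics follow the accuracy trace", {
  rows <- tibble::tibble(
    size = c(1, 1, 2, 2, 3, 3),
    free = list("a", "b", c("a", "b"), c("a", "c"), letters[1:3],
                c("a", "b", "d")),
    accuracy = c(0.80, 0.75, 0.85, 0.85, 0.82, 0.80))
  res <- infolasso:::resolve_search(c(0.80, 0.85, 0.82), rows)
  expect_equal(res$stop_after, 3)
  expect_equal(res$best_accuracy, 0.85)
  expect_equal(nrow(res$winners), 2)
  expect_true(all(res$winners$size == 2))
  # equal best accuracy across sizes: tied models of both sizes co-exist
  rows2 <- rows
  rows2$accuracy <- c(0.80, 0.75, 0.85, 0.83, 0.85, 0.80)
  res2 <- infolasso:::resolve_search(c(0.80, 0.85, 0.85), rows2)
  expect_equal(res2$stop_after, 3)
  expect_equal(sort(unique(res2$winners$size)), c(2, 3))
})

test_that("search on two candidates equals exhaustive subset evaluation", {
  ft <- gen_linear_binary(synthetic_spec(n = 30, p = 5, seed = 13))
  cands <- c("f1", "f2")
  res <- search_penalty_free_sets(ft, candidates = cands)
  ex <- lapply(list("f1", "f2", c("f1", "f2")), function(S)
    loocv_evaluate(ft, free = S))
  acc <- vapply(ex, `[[`, numeric(1), "accuracy")
  a1 <- max(acc[1:2]); a2 <- acc[3]
  best <- if (a2 < a1) a1 else max(a1, a2)
  expect_equal(res$best_accuracy, best)
  expect_equal(res$trace$best_accuracy[1], a1)
})

test_that("a single-feature table yields that feature trivially", {
  ft <- gen_linear_binary(synthetic_spec(n = 30, p = 1, informative = 1,
                                         coefs = 2, seed = 5))
  res <- run_framework(ft)
  expect_equal(res$candidates$kept$feature, "f1")
  expect_equal(res$search$best_sets$free[[1]], "f1")
})

test_that("penalty-free features stay in the model unless back-solved to zero", {
  ft <- gen_linear_binary(synthetic_spec(n = 40, p = 10, seed = 17))
  fit <- fit_penalty_free(ft$X, ft$y, free = c(3, 7), lambda = 5)
  expect_true(all(fit$beta[c(3, 7)] != 0))
  expect_setequal(fit$feature_names[fit$free], c("f3", "f7"))
})

test_that("oversized candidate sets require an explicit override", {
  ft <- gen_linear_binary(synthetic_spec(n = 30, p = 20, seed = 3))
  expect_error(search_penalty_free_sets(ft, candidates = paste0("f", 1:16)),
               "allow_large")
})

test_that("the end-to-end framework recovers a planted linear signal", {
  ft <- gen_linear_binary(synthetic_spec(n = 50, p = 45, seed = 1))
  res <- run_framework(ft)
  act <- res$search$best_sets$active[[1]]
  expect_true(all(c("f1", "f2") %in% act))
  expect_gt(glance(res)$accuracy, 0.8)
})

test_that("nested per-fold selection reports an honest accuracy", {
  ft <- gen_linear_binary(synthetic_spec(n = 24, p = 5, seed = 19))
  res <- run_framework(ft, top_k = 3, nlambda = 20, nested = TRUE)
  expect_true(is.finite(res$nested$accuracy))
  expect_gte(res$nested$accuracy, 0)
  expect_lte(res$nested$accuracy, 1)
  expect_equal(glance(res)$nested_accuracy, res$nested$accuracy)
})

test_that("the exact path engine agrees with tightly converged coordinate descent", {
  worst <- 0
  for (rep in 1:4) {
    set.seed(400 + rep)
    ft <- gen_linear_binary(synthetic_spec(n = 25, p = 9, seed = 40 + rep))
    env <- infolasso:::build_loocv_env(ft$X, ft$y, TRUE)
    S <- sort(sample(9, sample(0:2, 1)))
    grid <- infolasso:::full_data_grid(ft$X, ft$y, S, TRUE, 40, 1e-3)
    sc <- infolasso:::loocv_scores_env(env, S, grid)
    for (f in sample(25, 3)) {
      ib <- c(1L, S + 1L); ia <- setdiff(seq_len(10), ib)
      G <- env$G[, , f]; g <- env$g[, f]
      Mb <- solve(G[ib, ib, drop = FALSE])
      W <- Mb %*% G[ib, ia, drop = FALSE]
      Gat <- G[ia, ia] - t(G[ib, ia, drop = FALSE]) %*% W
      Gat <- (Gat + t(Gat)) / 2
      gat <- drop(g[ia] - t(W) %*% g[ib])
      cd <- infolasso:::cpp_cd_path(Gat, gat, grid, 1e-11, 500000L,
                                    numeric(length(ia)))
      bb <- Mb %*% (g[ib] - G[ib, ia, drop = FALSE] %*% cd$theta)
      ref <- drop(env$xh[f, ib] %*% bb) + drop(env$xh[f, ia] %*% cd$theta)
      worst <- max(worst, max(abs(sc[f, ] - ref)))
    }
  }
  expect_lt(worst, 1e-6)
})
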