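# LOOCV machinery shared by the penalty-free subset search and the
# baseline selectors.  For each fold we precompute the Gram matrix of the
# augmented (intercept + scaled features) training design, X'y, and the
# held-out row on the training fold's scale; every subset evaluation then
# reduces to small block algebra plus a coordinate-descent path in C++.

build_loocv_env <- function(X, y, standardize = TRUE) {
  n <- nrow(X); p <- ncol(X)
  G <- array(0, dim = c(p + 1L, p + 1L, n))
  g <- matrix(0, p + 1L, n)
  xh <- matrix(0, n, p + 1L)
  for (f in seq_len(n)) {
    Xtr <- X[-f, , drop = FALSE]
    s <- if (standardize) {
      sdv <- apply(Xtr, 2, sd)
      ifelse(sdv > 0, sdv, 1)
    } else rep(1, p)
    Z <- cbind(1, sweep(Xtr, 2, s, "/"))
    G[, , f] <- crossprod(Z)
    g[, f] <- crossprod(Z, y[-f])
    xh[f, ] <- c(1, X[f, ] / s)
  }
  list(G = G, g = g, xh = xh, y = y, n = n, p = p,
       standardize = standardize)
}

# lambda grid for a given free set, from the full-data projected problem:
# lambda_max = 2 max_j |x_j' (I - P) y| over penalized columns
full_data_grid <- function(X, y, free, standardize, nlambda, ratio) {
  p <- ncol(X)
  pen <- setdiff(seq_len(p), free)
  if (!length(pen)) return(0)
  scales <- rep(1, p)
  if (standardize) {
    s <- apply(X[, pen, drop = FALSE], 2, sd)
    scales[pen] <- ifelse(s > 0, s, 1)
  }
  Xs <- sweep(X, 2, scales, "/")
  Xb <- cbind(1, Xs[, free, drop = FALSE])
  Xa <- Xs[, pen, drop = FALSE]
  qb <- qr(Xb)
  ry <- qr.resid(qb, y)
  lambda_grid_geom(2 * max(abs(crossprod(Xa, ry))), n = nlambda,
                   ratio = ratio)
}

# per-subset lambda grid straight from the full-data augmented Gram:
# lambda_max = 2 max |g_a - G_ab (G_bb)^+ g_b|
gram_lambda_grid <- function(G0, g0, free, nlambda, ratio) {
  ib <- c(1L, free + 1L)
  ia <- setdiff(seq_along(g0), ib)
  if (!length(ia)) return(0)
  Gbb <- G0[ib, ib, drop = FALSE]
  Mbg <- tryCatch(solve(Gbb, g0[ib]), error = function(e) {
    sv <- svd(Gbb)
    pos <- sv$d > max(sv$d, 1) * 1e-12
    sv$v %*% ((crossprod(sv$u, g0[ib])) * ifelse(pos, 1 / sv$d, 0))
  })
  gat <- g0[ia] - drop(G0[ia, ib, drop = FALSE] %*% Mbg)
  lambda_grid_geom(2 * max(abs(gat)), n = nlambda, ratio = ratio)
}

loocv_scores_env <- function(env, free, lambdas, tol = 1e-8,
                             max_iter = 1e5) {
  idx_b <- c(0L, as.integer(free))
  idx_a <- setdiff(seq_len(env$p), free)
  res <- cpp_loocv_scores(env$G, env$g, env$xh, idx_b, idx_a,
                          as.numeric(lambdas), tol, as.integer(max_iter))
  res$scores
}

#' Leave-one-out evaluation of a penalty-free set
#'
#' Holds out each sample in turn, fits the penalty-free generalized lasso
#' on the remainder at every lambda of the grid, and classifies the
#' held-out sample by `score >= 0.5`. Metrics are reported at the
#' accuracy-maximizing lambda, ties resolved to the largest (sparsest)
#' lambda.
#'
#' @inheritParams rank_features
#' @param free Penalty-free feature set (names or column indices).
#' @param lambda_grid Optional lambda sequence (descending); by default a
#'   geometric grid of `nlambda` points from the projected-problem
#'   `lambda_max` down to `lambda_min_ratio` times it.
#' @param nlambda,lambda_min_ratio Grid controls.
#' @param standardize Scale penalized columns to unit sd within each
#'   training fold.
#' @return An object of class `loocv_eval`: accuracy, sensitivity,
#'   specificity, `best_lambda`, the per-lambda accuracy curve, and the
#'   per-fold predictions at the best lambda.
#' @export
loocv_evaluate <- function(data, label = "class", free = integer(0),
                           lambda_grid = NULL, nlambda = 100,
                           lambda_min_ratio = 1e-3, standardize = TRUE,
                           positive_class = NULL) {
  ft <- as_feature_table(data, label = label, positive_class = positive_class)
  if (length(unique(ft$y)) < 2L) abort("Both classes must be present.")
  if (nrow(ft$X) < 3L) abort("LOOCV needs at least 3 samples.")
  free <- resolve_features(free, ft$feature_names, ncol(ft$X))
  if (length(free) + 1L >= nrow(ft$X) - 1L) {
    abort("Free set too large for leave-one-out fitting.")
  }
  env <- build_loocv_env(ft$X, ft$y, standardize)
  if (is.null(lambda_grid)) {
    lambda_grid <- full_data_grid(ft$X, ft$y, free, standardize, nlambda,
                                  lambda_min_ratio)
  }
  lambda_grid <- sort(as.numeric(lambda_grid), decreasing = TRUE)
  scores <- loocv_scores_env(env, free, lambda_grid)
  pred <- scores >= 0.5
  acc <- colMeans(pred == ft$y)
  best <- best_lambda_index(acc)
  m <- classification_metrics(ft$y, as.integer(pred[, best]))
  structure(list(
    accuracy = m$accuracy, sensitivity = m$sensitivity,
    specificity = m$specificity,
    best_lambda = lambda_grid[best],
    free = ft$feature_names[free],
    lambda_grid = lambda_grid,
    accuracy_by_lambda = tibble::tibble(lambda = lambda_grid,
                                        accuracy = as.numeric(acc)),
    predictions = tibble::tibble(fold = seq_len(env$n),
                                 truth = ft$y,
                                 prediction = as.integer(pred[, best]))
  ), class = "loocv_eval")
}

#' @export
print.loocv_eval <- function(x, ...) {
  cat(sprintf("<loocv_eval> free = {%s}; accuracy %.3f (sens %.3f, spec %.3f) at lambda %.4g\n",
              paste(x$free, collapse = ", "), x$accuracy, x$sensitivity,
              x$specificity, x$best_lambda))
  invisible(x)
}

#' @export
glance.loocv_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
                 specificity = x$specificity, best_lambda = x$best_lambda,
                 n_free = length(x$free))
}

# stopping rule and winner bookkeeping, factored out so the semantics can
# be exercised directly: sizes are scanned in order, the scan stops as
# soon as the best accuracy at a size fails to improve on the previous
# size's best ("cannot be further improved"), and the winners are all
# evaluated sets achieving the overall best accuracy among the sizes
# scanned (ties, including across neighbouring sizes, co-exist).
resolve_search <- function(size_best, set_rows) {
  stop_after <- length(size_best)
  for (m in seq_along(size_best)) {
    if (m > 1 && size_best[m] <= size_best[m - 1]) { stop_after <- m; break }
  }
  scanned <- seq_len(stop_after)
  best_acc <- max(size_best[scanned])
  winners <- dplyr::filter(set_rows, .data$size %in% scanned,
                           .data$accuracy == best_acc)
  list(stop_after = stop_after, best_accuracy = best_acc, winners = winners)
}

#' Search penalty-free subsets of the candidate set by LOOCV
#'
#' Enumerates subsets of the (decorrelated, MI-ordered) candidate set in
#' increasing size: first every single candidate penalty-free, then all
#' pairs, then all triples, and so on. Each subset is scored by
#' [loocv_evaluate()]. The scan stops as soon as the best accuracy at a
#' size fails to improve on the previous size's best. All subsets
#' achieving the overall best accuracy among the scanned sizes are
#' reported (ties, including across neighbouring sizes, co-exist), each
#' refit on the full data at its best lambda.
#'
#' @inheritParams loocv_evaluate
#' @param candidates A `candidate_set` from [decorrelate()], or a
#'   character vector of feature names in priority order.
#' @param max_size Cap on the subset size (defaults to the candidate
#'   count).
#' @param allow_large Permit candidate sets larger than 15 (full
#'   enumeration grows combinatorially; the intended regime is ~10
#'   candidates).
#' @return An object of class `infolasso_search`; see [tidy()] /
#'   [glance()] / [autoplot()] methods. `best_sets` holds one row per
#'   winning penalty-free set with its lambda, LOOCV metrics, active
#'   features after the full-data refit, and training accuracy.
#' @export
search_penalty_free_sets <- function(data, label = "class", candidates,
                                     lambda_grid = NULL, nlambda = 100,
                                     lambda_min_ratio = 1e-3,
                                     standardize = TRUE, max_size = NULL,
                                     allow_large = FALSE,
                                     positive_class = NULL) {
  ft <- as_feature_table(data, label = label, positive_class = positive_class)
  cand_names <- if (inherits(candidates, "candidate_set")) {
    candidates$kept$feature
  } else as.character(candidates)
  if (!length(cand_names)) abort("Candidate set is empty.")
  cand_idx <- match(cand_names, ft$feature_names)
  if (anyNA(cand_idx)) abort("Candidate features not found in the data.")
  k <- length(cand_idx)
  if (k > 15 && !allow_large) {
    abort("More than 15 candidates; full enumeration is expensive. Set `allow_large = TRUE` to override.")
  }
  max_size <- min(max_size %||% k, k, nrow(ft$X) - 3L)
  env <- build_loocv_env(ft$X, ft$y, standardize)
  # full-data Gram (same scaling convention as the folds) for the
  # per-subset lambda grids
  s_full <- if (standardize) {
    sdv <- apply(ft$X, 2, sd)
    ifelse(sdv > 0, sdv, 1)
  } else rep(1, ncol(ft$X))
  Z0 <- cbind(1, sweep(ft$X, 2, s_full, "/"))
  G0 <- crossprod(Z0)
  g0 <- drop(crossprod(Z0, ft$y))

  sub_size <- integer(0)
  sub_idx <- list()
  sub_lambda <- numeric(0)
  sub_acc <- numeric(0)
  size_best <- numeric(0)
  fixed_grid <- if (!is.null(lambda_grid)) {
    sort(as.numeric(lambda_grid), decreasing = TRUE)
  } else NULL
  for (m in seq_len(max_size)) {
    subsets <- combn(cand_idx, m, simplify = FALSE)
    accs_m <- numeric(length(subsets))
    for (si in seq_along(subsets)) {
      S <- subsets[[si]]
      grid <- fixed_grid %||% gram_lambda_grid(G0, g0, S, nlambda,
                                               lambda_min_ratio)
      scores <- loocv_scores_env(env, S, grid)
      acc <- colMeans((scores >= 0.5) == ft$y)
      b <- best_lambda_index(acc)
      sub_size <- c(sub_size, m)
      sub_idx[[length(sub_idx) + 1L]] <- S
      sub_lambda <- c(sub_lambda, grid[b])
      accs_m[si] <- acc[b]
    }
    sub_acc <- c(sub_acc, accs_m)
    size_best[m] <- max(accs_m)
    if (m > 1 && size_best[m] <= size_best[m - 1]) break
  }
  set_rows <- tibble::tibble(
    size = sub_size,
    free = purrr::map(sub_idx, ~ ft$feature_names[.x]),
    free_idx = sub_idx,
    lambda = sub_lambda,
    accuracy = sub_acc)
  res <- resolve_search(size_best, set_rows)

  best_sets <- res$winners
  details <- purrr::pmap(
    list(best_sets$free_idx, best_sets$lambda),
    function(S, lam) {
      fit <- fit_penalty_free(ft$X, ft$y, free = S, lambda = lam,
                              standardize = standardize)
      active <- ft$feature_names[fit$beta != 0]
      scores <- loocv_scores_env(env, S, lam)
      pred <- as.integer(scores >= 0.5)
      m <- classification_metrics(ft$y, pred)
      train_acc <- mean(predict(fit, ft$X, type = "class") == ft$y)
      list(fit = fit, active = active, sens = m$sensitivity,
           spec = m$specificity, train = train_acc, pred = pred)
    })
  best_sets$active <- purrr::map(details, "active")
  best_sets$n_active <- lengths(best_sets$active)
  best_sets$sensitivity <- purrr::map_dbl(details, "sens")
  best_sets$specificity <- purrr::map_dbl(details, "spec")
  best_sets$training_accuracy <- purrr::map_dbl(details, "train")
  # all winners are exact accuracy ties; order them sparsest-first so the
  # summary row is the most parsimonious of the tied models
  ord <- order(best_sets$n_active, best_sets$size)
  best_sets <- best_sets[ord, ]
  details <- details[ord]

  structure(list(
    best_sets = best_sets,
    fits = purrr::map(details, "fit"),
    predictions = purrr::map(details, "pred"),
    trace = tibble::tibble(size = seq_along(size_best),
                           best_accuracy = size_best),
    stopped_at = res$stop_after,
    best_accuracy = res$best_accuracy,
    candidates = cand_names,
    truth = ft$y,
    evaluated = dplyr::select(set_rows, "size", "free", "lambda",
                              "accuracy")
  ), class = "infolasso_search")
}

#' @export
print.infolasso_search <- function(x, ...) {
  cat(sprintf("<infolasso_search> %d candidate(s); best LOOCV accuracy %.3f; %d winning set(s)\n",
              length(x$candidates), x$best_accuracy, nrow(x$best_sets)))
  for (i in seq_len(nrow(x$best_sets))) {
    cat(sprintf("  free = {%s} -> active = {%s} (lambda %.4g)\n",
                paste(x$best_sets$free[[i]], collapse = ", "),
                paste(x$best_sets$active[[i]], collapse = ", "),
                x$best_sets$lambda[i]))
  }
  invisible(x)
}

#' @export
tidy.infolasso_search <- function(x, ...) {
  dplyr::select(x$best_sets, "size", "free", "active", "n_active",
                "lambda", "accuracy", "sensitivity", "specificity",
                "training_accuracy")
}

#' @export
glance.infolasso_search <- function(x, ...) {
  b <- x$best_sets[1L, ]
  tibble::tibble(accuracy = b$accuracy,
                 sensitivity = b$sensitivity,
                 specificity = b$specificity,
                 training_accuracy = b$training_accuracy,
                 n_active = b$n_active,
                 lambda = b$lambda,
                 n_winning_sets = nrow(x$best_sets))
}

#' Plot the accuracy-by-subset-size trace of a search
#'
#' @param object An `infolasso_search`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.infolasso_search <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$size, y = .data$best_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$trace$size) +
    ggplot2::labs(x = "penalty-free set size",
                  y = "best LOOCV accuracy",
                  title = "Penalty-free subset search") +
    ggplot2::theme_minimal()
}

#' Run the integrated ranking and selection framework end to end
#'
#' Ranks all features by mutual information with the class, removes
#' correlated features from the top `top_k`, then searches penalty-free
#' subsets of the remaining candidates with the generalized lasso and
#' leave-one-out cross-validation. With `nested = TRUE` the whole
#' pipeline (ranking, decorrelation and search) is additionally re-run
#' inside each leave-one-out fold and the held-out sample is predicted by
#' that fold's winning model, giving a selection-leakage-free accuracy
#' estimate alongside the default (ranking computed once on the full
#' data, which is the classical protocol for this framework).
#'
#' @inheritParams decorrelate
#' @inheritParams search_penalty_free_sets
#' @param nested Also compute a nested-LOOCV accuracy (slower).
#' @return An object of class `infolasso_result`, containing the
#'   `ranking`, `candidates`, `search` and a `report` for the best model.
#' @examples
#' spec <- synthetic_spec(n = 40, p = 8, seed = 3)
#' ft <- gen_linear_binary(spec)
#' res <- run_framework(ft, top_k = 4)
#' glance(res)
#' @export
run_framework <- function(data, label = "class", positive_class = NULL,
                          bins = 4, base = 2, top_k = 10, threshold = 0.6,
                          nlambda = 100, lambda_min_ratio = 1e-3,
                          standardize = TRUE, max_size = NULL,
                          allow_large = FALSE, nested = FALSE) {
  ft <- as_feature_table(data, label = label, positive_class = positive_class)
  top_k <- min(top_k, ncol(ft$X))
  ranking <- rank_features(ft, bins = bins, base = base)
  cands <- decorrelate(ft, top_k = top_k, threshold = threshold,
                       ranking = ranking, bins = bins, base = base)
  search <- search_penalty_free_sets(ft, candidates = cands,
                                     nlambda = nlambda,
                                     lambda_min_ratio = lambda_min_ratio,
                                     standardize = standardize,
                                     max_size = max_size,
                                     allow_large = allow_large)
  b <- search$best_sets[1L, ]
  rep <- report(method = "penalty-free search",
                features = b$active[[1L]],
                lambda = b$lambda,
                truth = ft$y,
                predictions = search$predictions[[1L]],
                training_accuracy = b$training_accuracy)
  nested_metrics <- NULL
  if (nested) {
    nested_metrics <- nested_loocv(ft, bins = bins, base = base,
                                   top_k = top_k, threshold = threshold,
                                   nlambda = nlambda,
                                   lambda_min_ratio = lambda_min_ratio,
                                   standardize = standardize,
                                   max_size = max_size,
                                   allow_large = allow_large)
  }
  structure(list(ranking = ranking, candidates = cands, search = search,
                 report = rep, nested = nested_metrics, table = ft),
            class = "infolasso_result")
}

# honest LOOCV: redo ranking + decorrelation + search on each training fold
nested_loocv <- function(ft, ...) {
  n <- nrow(ft$X)
  pred <- integer(n)
  for (f in seq_len(n)) {
    sub <- new_feature_table(ft$X[-f, , drop = FALSE], ft$y[-f],
                             ft$feature_names)
    res <- run_framework(sub, nested = FALSE, ...)
    pred[f] <- predict(res$search$fits[[1L]],
                       ft$X[f, , drop = FALSE], type = "class")
  }
  classification_metrics(ft$y, pred)
}

#' @export
print.infolasso_result <- function(x, ...) {
  cat("Integrated MI ranking + penalty-free lasso selection\n")
  cat(sprintf("  candidates after decorrelation: %s\n",
              paste(x$candidates$kept$feature, collapse = ", ")))
  print(x$search)
  print(x$report)
  if (!is.null(x$nested)) {
    cat(sprintf("  nested LOOCV accuracy: %.3f\n", x$nested$accuracy))
  }
  invisible(x)
}

#' @export
tidy.infolasso_result <- function(x, ...) tidy(x$search)

#' @export
glance.infolasso_result <- function(x, ...) {
  out <- glance(x$search)
  if (!is.null(x$nested)) out$nested_accuracy <- x$nested$accuracy
  out
}

#' @export
autoplot.infolasso_result <- function(object, ...) autoplot(object$search, ...)

#' Classify samples with a fitted model
#'
#' Decision rule for squared-loss classification with labels coded 0/1:
#' predict class 1 when the linear score `beta0 + x' beta` is at least
#' 0.5 (the boundary goes to the positive class).
#'
#' @param fit A `penalty_free_fit`.
#' @param newdata Feature matrix or data frame.
#' @return Integer vector of 0/1 classes.
#' @export
classify <- function(fit, newdata) {
  predict(fit, newdata, type = "class")
}
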