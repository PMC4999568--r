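# Comparison selectors: greedy MI criteria (MIM/MIFS/MRMR/JMI/CMIM),
# Pudil's floating search, PCA-95%, and L1-penalized logistic regression.
# All baselines that need a downstream classifier use the same rule as the
# framework: an unpenalized least-squares fit on the selected subset with
# the 0.5 decision threshold, evaluated by LOOCV — so methods differ only
# in which features they pick.

#' Greedy forward selection with a mutual-information criterion
#'
#' At each step the candidate `X_k` maximizing the criterion score is
#' added:
#' * `mim`: `I(X_k; Y)`
#' * `mifs`: `I(X_k; Y) - beta * sum_{j in S} I(X_k; X_j)`
#' * `mrmr`: MIFS with `beta = 1/|S|` (mean redundancy)
#' * `jmi`: `sum_{j in S} I(X_k, X_j; Y)` (joint variable = crossed bins)
#' * `cmim`: `min_{j in S} I(X_k; Y | X_j)`
#'
#' The first feature is always the marginal-MI argmax; ties go to the
#' lowest column index. With `beta = 0`, MIFS reduces to MIM.
#'
#' @inheritParams rank_features
#' @param method One of `"mim"`, `"mifs"`, `"mrmr"`, `"jmi"`, `"cmim"`.
#' @param K Number of features to select.
#' @param beta MIFS redundancy weight (ignored by the other criteria).
#' @return A tibble with columns `step`, `feature`, `index`, `score` in
#'   selection order.
#' @export
greedy_mi_select <- function(data, label = "class", method = c("mim", "mifs",
                             "mrmr", "jmi", "cmim"), K = 10, beta = 1,
                             bins = 4, base = 2, positive_class = NULL) {
  method <- match.arg(method)
  ft <- as_feature_table(data, label = label, positive_class = positive_class)
  p <- ncol(ft$X)
  if (K > p || K < 1) abort("`K` must be between 1 and p.")
  bx <- lapply(seq_len(p), function(j) discretize_ef(ft$X[, j], bins))
  y <- ft$y
  rel <- vapply(bx, function(b) plugin_mi(b, y, base = base), numeric(1))

  # lazily filled pairwise caches
  mi_xx <- matrix(NA_real_, p, p)
  jmi_xy <- matrix(NA_real_, p, p)
  cmi_xy <- matrix(NA_real_, p, p)
  get_mi_xx <- function(k, j) {
    if (is.na(mi_xx[k, j])) {
      v <- plugin_mi(bx[[k]], bx[[j]], base = base)
      mi_xx[k, j] <<- v; mi_xx[j, k] <<- v
    }
    mi_xx[k, j]
  }
  get_jmi <- function(k, j) {
    if (is.na(jmi_xy[k, j])) {
      joint <- interaction(bx[[k]], bx[[j]], drop = TRUE)
      v <- plugin_mi(joint, y, base = base)
      jmi_xy[k, j] <<- v; jmi_xy[j, k] <<- v
    }
    jmi_xy[k, j]
  }
  get_cmi <- function(k, j) {
    if (is.na(cmi_xy[k, j])) {
      out <- 0
      for (zz in unique(bx[[j]])) {
        idx <- bx[[j]] == zz
        out <- out + mean(idx) * plugin_mi(bx[[k]][idx], y[idx], base = base)
      }
      cmi_xy[k, j] <<- max(0, out)
    }
    cmi_xy[k, j]
  }

  selected <- integer(0)
  scores <- numeric(0)
  for (step in seq_len(K)) {
    remaining <- setdiff(seq_len(p), selected)
    sc <- vapply(remaining, function(k) {
      if (!length(selected)) return(rel[k])
      switch(method,
        mim = rel[k],
        mifs = rel[k] - beta * sum(vapply(selected, function(j)
          get_mi_xx(k, j), numeric(1))),
        mrmr = rel[k] - (1 / length(selected)) *
          sum(vapply(selected, function(j) get_mi_xx(k, j), numeric(1))),
        jmi = sum(vapply(selected, function(j) get_jmi(k, j), numeric(1))),
        cmim = min(vapply(selected, function(j) get_cmi(k, j), numeric(1)))
      )
    }, numeric(1))
    pick <- remaining[order(-sc, remaining)[1L]]
    selected <- c(selected, pick)
    scores <- c(scores, sc[remaining == pick])
  }
  tibble::tibble(step = seq_len(K),
                 feature = ft$feature_names[selected],
                 index = selected,
                 score = scores)
}

#' LOOCV accuracy of the unpenalized least-squares classifier on a subset
#'
#' The shared downstream classifier for the baseline selectors: ordinary
#' least squares of the 0/1 label on the subset (plus intercept), decision
#' threshold 0.5, evaluated by leave-one-out cross-validation.
#'
#' @inheritParams loocv_evaluate
#' @param features Feature names or indices of the subset.
#' @return A `loocv_eval`.
#' @export
evaluate_subset <- function(data, label = "class", features,
                            positive_class = NULL) {
  # a very large penalty zeroes the penalized block exactly, leaving the
  # free-block OLS fit
  loocv_evaluate(data, label = label, free = features,
                 lambda_grid = 1e300, positive_class = positive_class)
}

#' Pudil's sequential floating forward selection (SFFS)
#'
#' Sequential forward selection with conditional backward exclusion:
#' after each forward addition, features are removed as long as removal
#' improves the best known criterion value for the reduced size. The
#' criterion is the LOOCV accuracy of the unpenalized least-squares
#' classifier ([evaluate_subset()]). Returns the best subset found over
#' all sizes up to `max_K` (ties to the smaller size).
#'
#' @inheritParams evaluate_subset
#' @param max_K Largest subset size to explore.
#' @return A list with `features` (character vector), `criterion` (its
#'   LOOCV accuracy) and `trace` (best criterion by size).
#' @export
sffs_select <- function(data, label = "class", max_K = 10,
                        positive_class = NULL) {
  ft <- as_feature_table(data, label = label, positive_class = positive_class)
  p <- ncol(ft$X)
  max_K <- min(max_K, p, nrow(ft$X) - 4L)
  cache <- new.env(parent = emptyenv())
  crit <- function(S) {
    key <- paste(sort(S), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- evaluate_subset(ft, features = sort(S))$accuracy
    cache[[key]] <- v
    v
  }
  best_by_size <- rep(-Inf, max_K)
  best_set_by_size <- vector("list", max_K)
  note <- function(S) {
    k <- length(S)
    if (k >= 1 && k <= max_K && crit(S) > best_by_size[k]) {
      best_by_size[k] <<- crit(S)
      best_set_by_size[[k]] <<- sort(S)
    }
  }
  S <- integer(0)
  while (length(S) < max_K) {
    remaining <- setdiff(seq_len(p), S)
    vals <- vapply(remaining, function(k) crit(c(S, k)), numeric(1))
    S <- c(S, remaining[order(-vals, remaining)[1L]])
    note(S)
    # conditional exclusion
    while (length(S) > 2) {
      vals <- vapply(S, function(k) crit(setdiff(S, k)), numeric(1))
      drop_k <- S[order(-vals, S)[1L]]
      reduced <- setdiff(S, drop_k)
      if (crit(reduced) > best_by_size[length(reduced)]) {
        S <- reduced
        note(S)
      } else break
    }
  }
  sizes <- which(is.finite(best_by_size))
  k_best <- sizes[order(-best_by_size[sizes], sizes)[1L]]
  list(features = ft$feature_names[best_set_by_size[[k_best]]],
       criterion = best_by_size[k_best],
       trace = tibble::tibble(size = sizes,
                              criterion = best_by_size[sizes]))
}

#' PCA reduction keeping 95% of the variance
#'
#' Centers the features, computes principal components, and keeps the
#' smallest leading set whose cumulative explained variance reaches
#' `var_frac`. The component scores become the new features.
#'
#' @inheritParams rank_features
#' @param var_frac Cumulative explained-variance target.
#' @return A `feature_table` of component scores (features `PC1`, ...),
#'   with attributes `explained` (tibble of per-component variance
#'   fractions) and `rotation`.
#' @export
pca95_transform <- function(data, label = "class", var_frac = 0.95,
                            positive_class = NULL) {
  ft <- as_feature_table(data, label = label, positive_class = positive_class)
  pc <- stats::prcomp(ft$X, center = TRUE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(frac) >= var_frac)[1L]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  out <- new_feature_table(scores, ft$y, colnames(scores))
  attr(out, "explained") <- tibble::tibble(component = seq_along(frac),
                                           variance_fraction = frac,
                                           cumulative = cumsum(frac))
  attr(out, "rotation") <- pc$rotation
  out
}

#' L1-penalized logistic regression baseline
#'
#' Fits a lasso-penalized logistic regression (unpenalized intercept)
#' along a lambda path, picks lambda by LOOCV accuracy (ties to the
#' largest lambda, `lambda = 0` excluded from the grid), and reports the
#' features with nonzero coefficients at the chosen lambda. Decision
#' rule: predicted probability at least 0.5.
#'
#' @inheritParams rank_features
#' @param nlambda Path length when `lambda_grid` is not given.
#' @param lambda_grid Optional decreasing lambda sequence (on glmnet's
#'   scale).
#' @return An object of class `l1lr_fit` with the selected features,
#'   LOOCV metrics at the chosen lambda, training accuracy, and the
#'   per-lambda accuracy curve.
#' @export
l1_logistic_select <- function(data, label = "class", nlambda = 100,
                               lambda_grid = NULL, positive_class = NULL) {
  ft <- as_feature_table(data, label = label, positive_class = positive_class)
  if (length(unique(ft$y)) < 2L) abort("Both classes must be present.")
  X <- ft$X; y <- ft$y; n <- nrow(X)
  full <- glmnet::glmnet(X, y, family = "binomial", nlambda = nlambda,
                         lambda = lambda_grid)
  grid <- full$lambda
  preds <- matrix(NA_real_, n, length(grid))
  for (f in seq_len(n)) {
    fit <- glmnet::glmnet(X[-f, , drop = FALSE], y[-f],
                          family = "binomial", lambda = grid)
    eta <- drop(fit$a0 + X[f, ] %*% as.matrix(fit$beta))
    pr <- 1 / (1 + exp(-eta))
    if (length(pr) < length(grid)) pr <- c(pr, rep(pr[length(pr)],
                                                   length(grid) - length(pr)))
    preds[f, ] <- pr
  }
  acc <- colMeans((preds >= 0.5) == y)
  b <- best_lambda_index(acc)   # grid is descending: ties -> largest lambda
  pred_b <- as.integer(preds[, b] >= 0.5)
  m <- classification_metrics(y, pred_b)
  cf <- coef(full, s = grid[b])
  nz <- which(as.numeric(cf)[-1L] != 0)
  train_pred <- as.integer(
    predict(full, X, s = grid[b], type = "response") >= 0.5)
  structure(list(
    features = ft$feature_names[nz],
    n_features = length(nz),
    best_lambda = grid[b],
    accuracy = m$accuracy,
    sensitivity = m$sensitivity,
    specificity = m$specificity,
    training_accuracy = mean(train_pred == y),
    accuracy_by_lambda = tibble::tibble(lambda = grid,
                                        accuracy = as.numeric(acc)),
    predictions = tibble::tibble(fold = seq_len(n), truth = y,
                                 prediction = pred_b),
    coefficients = setNames(as.numeric(cf), rownames(cf)),
    fit = full
  ), class = "l1lr_fit")
}

#' @export
print.l1lr_fit <- function(x, ...) {
  cat(sprintf("<l1lr_fit> %d features at lambda %.4g; LOOCV accuracy %.3f\n",
              x$n_features, x$best_lambda, x$accuracy))
  invisible(x)
}

#' @export
glance.l1lr_fit <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
                 specificity = x$specificity,
                 training_accuracy = x$training_accuracy,
                 n_features = x$n_features, lambda = x$best_lambda)
}

#' Compare the framework against the baseline selectors
#'
#' Runs a chosen set of selectors on one feature table and summarises
#' each with the shared least-squares LOOCV classifier (the framework and
#' the logistic lasso use their own fitted models). For the greedy MI
#' selectors the number of features is chosen by maximizing the LOOCV
#' accuracy over prefixes of the greedy order up to `K_max` (ties to the
#' smallest subset).
#'
#' @inheritParams run_framework
#' @param methods Any of `"framework"`, `"mim"`, `"mifs"`, `"mrmr"`,
#'   `"jmi"`, `"cmim"`, `"sffs"`, `"pca95"`, `"l1lr"`.
#' @param K_max Cap for the per-method feature count search.
#' @param mifs_beta Redundancy weight for MIFS.
#' @return A tibble with one row per method: feature count, LOOCV
#'   accuracy, training accuracy, sensitivity and specificity.
#' @export
baseline_compare <- function(data, label = "class",
                             methods = c("framework", "mrmr", "sffs",
                                         "pca95", "mim", "mifs", "jmi",
                                         "cmim"),
                             K_max = 15, mifs_beta = 1, bins = 4,
                             top_k = 10, threshold = 0.6,
                             positive_class = NULL) {
  ft <- as_feature_table(data, label = label, positive_class = positive_class)
  K_max <- min(K_max, ncol(ft$X), nrow(ft$X) - 5L)
  rows <- purrr::map(methods, function(mth) {
    if (mth == "framework") {
      res <- run_framework(ft, bins = bins, top_k = top_k,
                           threshold = threshold)
      g <- glance(res)
      return(tibble::tibble(method = "framework",
                            n_features = g$n_active,
                            accuracy = g$accuracy,
                            training_accuracy = g$training_accuracy,
                            sensitivity = g$sensitivity,
                            specificity = g$specificity))
    }
    if (mth == "l1lr") {
      g <- glance(l1_logistic_select(ft))
      return(tibble::tibble(method = "l1lr", n_features = g$n_features,
                            accuracy = g$accuracy,
                            training_accuracy = g$training_accuracy,
                            sensitivity = g$sensitivity,
                            specificity = g$specificity))
    }
    if (mth == "pca95") {
      tf <- pca95_transform(ft)
      ev <- evaluate_subset(tf, features = tf$feature_names)
      fit <- fit_penalty_free(tf$X, tf$y,
                              free = seq_along(tf$feature_names),
                              lambda = 1e300)
      train <- mean(classify(fit, tf$X) == tf$y)
      return(tibble::tibble(method = "pca95",
                            n_features = length(tf$feature_names),
                            accuracy = ev$accuracy,
                            training_accuracy = train,
                            sensitivity = ev$sensitivity,
                            specificity = ev$specificity))
    }
    if (mth == "sffs") {
      sel <- sffs_select(ft, max_K = K_max)
      feats <- sel$features
    } else {
      ord <- greedy_mi_select(ft, method = mth, K = K_max,
                              beta = mifs_beta, bins = bins)
      evals <- purrr::map_dbl(seq_len(K_max), function(k)
        evaluate_subset(ft, features = ord$feature[seq_len(k)])$accuracy)
      feats <- ord$feature[seq_len(which.max(evals))]
    }
    ev <- evaluate_subset(ft, features = feats)
    fit <- fit_penalty_free(ft$X, ft$y, free = feats, lambda = 1e300)
    train <- mean(classify(fit, ft$X) == ft$y)
    tibble::tibble(method = mth, n_features = length(feats),
                   accuracy = ev$accuracy, training_accuracy = train,
                   sensitivity = ev$sensitivity,
                   specificity = ev$specificity)
  })
  dplyr::bind_rows(rows)
}
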