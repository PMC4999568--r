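#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - t, 0)`, the elementary update of lasso coordinate
#' descent.
#'
#' @param z Numeric vector.
#' @param t Nonnegative threshold.
#' @return Numeric vector of the same length as `z`.
#' @export
soft_threshold <- function(z, t) {
  stopifnot(all(t >= 0))
  sign(z) * pmax(abs(z) - t, 0)
}

#' Smallest lambda with an all-zero lasso solution
#'
#' For the objective `||y - X beta||^2 + lambda ||beta||_1` (RSS scale,
#' no 1/2 factor) the null model is optimal exactly when
#' `lambda >= 2 max_j |x_j' y|`.
#'
#' @param X Design matrix.
#' @param y Response vector.
#' @return The boundary lambda.
#' @export
lambda_max <- function(X, y) {
  X <- as.matrix(X)
  if (ncol(X) == 0L) return(0)
  2 * max(abs(crossprod(X, y)))
}

#' Lasso by cyclic coordinate descent
#'
#' Minimizes `||y - X beta||^2 + lambda ||beta||_1` without an intercept
#' (callers absorb it; [fit_penalty_free()] keeps the intercept in its free
#' block). At `lambda = 0` the minimum-norm least-squares solution is
#' returned. Convergence is declared when the largest coefficient change
#' in a sweep falls below `tol`; non-convergence returns the current
#' iterate with a warning and `converged = FALSE`.
#'
#' @param X Design matrix (n x m). All-zero columns get coefficient 0.
#' @param y Response vector.
#' @param lambda Nonnegative penalty.
#' @param tol Convergence tolerance on the max absolute coefficient change.
#' @param max_iter Maximum number of full sweeps.
#' @return Numeric coefficient vector with attributes `converged`,
#'   `n_iter` and `objective`.
#' @export
lasso_cd <- function(X, y, lambda, tol = 1e-8, max_iter = 1e5) {
  X <- as.matrix(X)
  check_scalar_number(lambda, "lambda")
  if (lambda < 0) abort("`lambda` must be nonnegative.")
  if (lambda == 0) {
    beta <- as.numeric(qr_minnorm(X, y))
    attr(beta, "converged") <- TRUE
    attr(beta, "n_iter") <- 0L
  } else {
    G <- crossprod(X)
    g <- drop(crossprod(X, y))
    fit <- cpp_cd_path(G, g, lambda, tol, as.integer(max_iter),
                       numeric(ncol(X)))
    beta <- drop(fit$theta)
    if (!all(fit$converged == 1)) {
      warn(sprintf("Coordinate descent did not converge in %d sweeps.",
                   as.integer(max_iter)))
    }
    attr(beta, "converged") <- all(fit$converged == 1)
    attr(beta, "n_iter") <- sum(fit$iters)
  }
  attr(beta, "objective") <- sum((y - X %*% beta)^2) + lambda * sum(abs(beta))
  beta
}

# minimum-norm least squares via SVD pseudoinverse
qr_minnorm <- function(X, y) {
  if (ncol(X) == 0L) return(numeric(0))
  sv <- svd(X)
  pos <- sv$d > max(dim(X)) * .Machine$double.eps * max(sv$d, 1)
  dinv <- ifelse(pos, 1 / sv$d, 0)
  sv$v %*% (dinv * crossprod(sv$u, y))
}

#' Generalized lasso with a penalty-free feature block
#'
#' Fits `min ||y - beta0 - X beta||^2 + lambda * sum_{j notin S} w_j |beta_j|`
#' where `S` is the penalty-free set and the intercept is always free. The
#' problem is reduced to a standard lasso: with `X_b = [1, X_S]` and
#' `X_a = X_{S^c}`, the penalized block is projected onto the orthogonal
#' complement of the free block (`P = X_b (X_b'X_b)^+ X_b'`), coordinate
#' descent solves the lasso in `theta_a` on `((I-P)y, (I-P)X_a)`, and the
#' free block is recovered by the back-solve
#' `beta_b = (X_b'X_b)^+ X_b' (y - X_a theta_a)`. The free-block residual
#' orthogonality `X_b' r = 0` then holds at numerical tolerance.
#'
#' With `standardize = TRUE` (default) penalized columns are scaled to unit
#' standard deviation before solving and the coefficients are scaled back,
#' which makes the effective penalty weight of feature `j` equal to its
#' standard deviation (`w_j = sd(x_j)`); free columns are never touched.
#' With `standardize = FALSE` all `w_j = 1`.
#'
#' @param X Numeric feature matrix (n x p).
#' @param y Numeric response (for classification, 0/1 labels).
#' @param free Penalty-free feature set: column indices or names (may be
#'   empty, giving a plain lasso with unpenalized intercept).
#' @param lambda Nonnegative penalty level.
#' @param standardize Scale penalized columns to unit sd before solving.
#' @param tol,max_iter Coordinate-descent convergence controls.
#' @return An object of class `penalty_free_fit` with the intercept
#'   `beta0`, full coefficient vector `beta` (original scale), the free
#'   set, effective weights `d`, the reduced-problem solution `theta_a`,
#'   the back-solved free block `beta_b`, the objective value, and a KKT
#'   certificate.
#' @examples
#' spec <- synthetic_spec(n = 30, p = 5, seed = 2)
#' ft <- gen_linear_binary(spec)
#' fit <- fit_penalty_free(ft$X, ft$y, free = c("f1"), lambda = 2)
#' tidy(fit)
#' @export
fit_penalty_free <- function(X, y, free = integer(0), lambda,
                             standardize = TRUE, tol = 1e-8, max_iter = 1e5) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  check_scalar_number(lambda, "lambda")
  if (lambda < 0) abort("`lambda` must be nonnegative.")
  free <- resolve_features(free, colnames(X), p)
  if (length(free) + 1L >= n) {
    abort("Free block plus intercept must have fewer columns than samples.")
  }
  pen <- setdiff(seq_len(p), free)
  scales <- rep(1, p)
  if (standardize && length(pen)) {
    s <- apply(X[, pen, drop = FALSE], 2, sd)
    scales[pen] <- ifelse(s > 0, s, 1)
  }
  Xs <- sweep(X, 2, scales, "/")
  Z <- cbind(1, Xs)
  G <- crossprod(Z)
  g <- drop(crossprod(Z, y))
  idx_b <- c(0L, free)            # 0-based into augmented columns
  idx_a <- pen                    # augmented index = pen + 1 - 1 = pen
  fit <- cpp_fit_pf(G, g, idx_b, idx_a, lambda, tol, as.integer(max_iter))
  if (fit$rank_deficient) {
    warn("Singular free block; Moore-Penrose pseudoinverse used.")
  }
  theta_a <- drop(fit$theta)
  beta_b <- drop(fit$beta_b)
  beta <- numeric(p)
  beta[pen] <- theta_a / scales[pen]
  beta[free] <- beta_b[-1L]
  beta0 <- beta_b[1L]
  names(beta) <- colnames(X)
  d <- scales
  d[free] <- 0
  fitted <- drop(beta0 + X %*% beta)
  obj <- sum((y - fitted)^2) + lambda * sum(d * abs(beta))
  out <- structure(list(
    beta0 = beta0, beta = beta, lambda = lambda,
    free = free, d = d,
    theta_a = theta_a, beta_b = beta_b,
    fitted = fitted, residuals = y - fitted,
    objective = obj,
    converged = all(fit$converged == 1),
    n_iter = sum(fit$iters),
    standardize = standardize,
    feature_names = colnames(X)
  ), class = "penalty_free_fit")
  out$kkt <- kkt_check(out, X, y)
  if (!out$converged) warn("Penalty-free lasso did not converge.")
  out
}

resolve_features <- function(free, nms, p) {
  if (is.character(free)) {
    idx <- match(free, nms)
    if (anyNA(idx)) {
      abort(sprintf("Unknown feature(s): %s.",
                    paste(free[is.na(idx)], collapse = ", ")))
    }
    return(sort(idx))
  }
  free <- as.integer(free)
  if (length(free) && (min(free) < 1L || max(free) > p)) {
    abort("Free-set indices out of range.")
  }
  sort(unique(free))
}

#' Generalized lasso with arbitrary nonnegative penalty weights
#'
#' Minimizes `||y - beta0 - X beta||^2 + lambda * sum_j d_j |beta_j|` for a
#' nonnegative weight vector `d` (a diagonal generalized-lasso penalty).
#' Weighted columns are rescaled (`x_j -> x_j / d_j`, coefficients scaled
#' back), reducing the problem to [fit_penalty_free()] with free set
#' `{j : d_j = 0}` — the weighted penalty and the rescaled standard lasso
#' are the same problem.
#'
#' @inheritParams fit_penalty_free
#' @param d Nonnegative weight vector of length `p`; zero entries are
#'   penalty-free.
#' @return A `penalty_free_fit` (coefficients on the original scale, `d`
#'   as supplied).
#' @export
fit_weighted <- function(X, y, d, lambda, tol = 1e-8, max_iter = 1e5) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (length(d) != p || any(d < 0) || anyNA(d)) {
    abort("`d` must be a nonnegative weight vector of length p.")
  }
  free <- which(d == 0)
  mult <- ifelse(d > 0, d, 1)
  Xr <- sweep(X, 2, mult, "/")
  fit <- fit_penalty_free(Xr, y, free = free, lambda = lambda,
                          standardize = FALSE, tol = tol,
                          max_iter = max_iter)
  fit$beta <- fit$beta / mult
  names(fit$beta) <- colnames(X)
  fit$d <- d
  fit$fitted <- drop(fit$beta0 + X %*% fit$beta)
  fit$residuals <- y - fit$fitted
  fit$objective <- sum(fit$residuals^2) + lambda * sum(d * abs(fit$beta))
  fit$kkt <- kkt_check(fit, X, y)
  fit
}

#' KKT certificate for a penalty-free / weighted lasso fit
#'
#' Checks first-order optimality of `min RSS + lambda sum d_j |beta_j|`
#' with unpenalized intercept: for penalized `beta_j != 0`,
#' `2 x_j' r = lambda d_j sign(beta_j)`; for penalized `beta_j = 0`,
#' `|2 x_j' r| <= lambda d_j`; for the free block (intercept and free
#' features), exact stationarity `x_j' r = 0`.
#'
#' @param fit A `penalty_free_fit`.
#' @param X,y The data the fit was computed on.
#' @param tol Tolerance for the certificate.
#' @return List with `ok`, `max_free` (free-block stationarity residual)
#'   and `max_violation` (worst penalized subgradient violation).
#' @export
kkt_check <- function(fit, X, y, tol = 1e-6) {
  X <- as.matrix(X)
  r <- y - fit$beta0 - drop(X %*% fit$beta)
  grad <- 2 * drop(crossprod(X, r))
  free_stat <- c(sum(r), grad[fit$free] / 2)
  pen <- setdiff(seq_len(ncol(X)), fit$free)
  viol <- 0
  if (length(pen)) {
    lam_d <- fit$lambda * fit$d[pen]
    gj <- grad[pen]
    bj <- fit$beta[pen]
    active <- bj != 0
    if (any(active)) {
      viol <- max(viol, abs(gj[active] - lam_d[active] * sign(bj[active])))
    }
    if (any(!active)) {
      viol <- max(viol, max(0, max(abs(gj[!active]) - lam_d[!active])))
    }
  }
  scale <- max(1, abs(free_stat), fit$lambda)
  list(ok = max(abs(free_stat)) <= tol * scale && viol <= tol * scale,
       max_free = max(abs(free_stat)),
       max_violation = viol)
}

#' Predict from a penalty-free fit
#'
#' @param object A `penalty_free_fit`.
#' @param newdata Matrix or data frame of features (columns matched by
#'   name when available).
#' @param type `"response"` for the linear score, `"class"` for the 0/1
#'   decision `score >= 0.5`.
#' @param ... Unused.
#' @return Numeric scores or integer classes.
#' @export
predict.penalty_free_fit <- function(object, newdata,
                                     type = c("response", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (!is.null(colnames(X)) && !is.null(object$feature_names) &&
      all(object$feature_names %in% colnames(X))) {
    X <- X[, object$feature_names, drop = FALSE]
  }
  score <- drop(object$beta0 + X %*% object$beta)
  if (type == "class") as.integer(score >= 0.5) else score
}

#' @export
print.penalty_free_fit <- function(x, ...) {
  cat(sprintf("<penalty_free_fit> lambda = %.4g; free = {%s}; %d active features\n",
              x$lambda,
              paste(x$feature_names[x$free] %||% x$free, collapse = ", "),
              sum(x$beta != 0)))
  invisible(x)
}

#' @export
tidy.penalty_free_fit <- function(x, ...) {
  nm <- x$feature_names %||% paste0("x", seq_along(x$beta))
  tibble::tibble(
    term = c("(Intercept)", nm),
    estimate = c(x$beta0, unname(x$beta)),
    penalty_free = c(TRUE, seq_along(x$beta) %in% x$free),
    weight = c(0, unname(x$d)))
}

#' @export
glance.penalty_free_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda,
                 objective = x$objective,
                 n_active = sum(x$beta != 0),
                 n_free = length(x$free),
                 converged = x$converged,
                 kkt_ok = x$kkt$ok)
}
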