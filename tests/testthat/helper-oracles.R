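# Independent oracles used across the suite.

# entropy-based mutual information on already-discrete vectors:
# I(A;B) = H(A) + H(B) - H(A,B), an independent route to the plug-in sum
entropy_mi <- function(a, b, base = 2) {
  H <- function(x) {
    p <- table(x) / length(x)
    p <- p[p > 0]
    -sum(p * log(p)) / log(base)
  }
  H(a) + H(b) - H(paste(a, b))
}

# proximal-gradient (FISTA) solver for
#   min ||y - b0 - X b||^2 + lam * sum(v_j |b_j|)
# with unpenalized intercept; independent of coordinate descent and glmnet
fista_weighted_lasso <- function(X, y, v, lam, iters = 50000) {
  Z <- cbind(1, X)
  L <- 2 * max(eigen(crossprod(Z), symmetric = TRUE,
                     only.values = TRUE)$values)
  th <- z <- numeric(ncol(Z))
  tk <- 1
  for (i in seq_len(iters)) {
    grad <- -2 * drop(crossprod(Z, y - Z %*% z))
    th_new <- z - grad / L
    th_new[-1] <- sign(th_new[-1]) * pmax(abs(th_new[-1]) - lam * v / L, 0)
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- th_new + ((tk - 1) / tk_new) * (th_new - th)
    th <- th_new
    tk <- tk_new
  }
  list(beta0 = th[1], beta = th[-1])
}

weighted_obj <- function(X, y, b0, b, v, lam) {
  sum((y - b0 - drop(X %*% b))^2) + lam * sum(v * abs(b))
}

# glmnet solution of min RSS + lam * sum(v_j |b_j|) with unpenalized
# intercept (glmnet rescales penalty factors to sum to p, hence the
# lambda conversion)
glmnet_weighted <- function(X, y, v, lam) {
  n <- nrow(X); p <- ncol(X)
  lam_g <- lam * sum(v) / (2 * n * p)
  f <- glmnet::glmnet(X, y, lambda = lam_g, penalty.factor = v,
                      standardize = FALSE, thresh = 1e-14)
  b <- as.numeric(coef(f))
  list(beta0 = b[1], beta = b[-1])
}

# small deterministic feature table used by several io / search tests
toy_table <- function() {
  data.frame(
    a = c(0.1, 0.9, 1.1, 0.2, 1.3, -0.2),
    b = c(1.0, 0.5, 0.2, 0.9, 0.1, 1.2),
    class = c(0, 1, 1, 0, 1, 0)
  )
}

random_instance <- function(seed, n = NULL, p = NULL) {
  set.seed(seed)
  n <- n %||% sample(12:30, 1)
  p <- p %||% sample(3:10, 1)
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- paste0("x", seq_len(p))
  list(X = X, y = rnorm(n), n = n, p = p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
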