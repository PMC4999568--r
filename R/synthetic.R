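#' Specify a synthetic binary-classification data-generating process
#'
#' The generator draws feature vectors from a multivariate normal
#' (standard normal features, optionally with equicorrelated blocks) and
#' produces labels from a linear-threshold rule:
#' `y = 1{ sum_j coef_j x_j + eps > 0 }` with `eps ~ N(0, noise_sd^2)`.
#'
#' The defaults reproduce the package's reference simulation: `n = 50`
#' samples, `p = 45` features of which exactly two (features 1 and 2,
#' coefficients `2` and `-2`) are related to the response, unit noise,
#' independent null features.
#'
#' @param n Number of samples.
#' @param p Number of features.
#' @param informative Indices of response-related features.
#' @param coefs Their coefficients (same length as `informative`).
#' @param noise_sd Standard deviation of the latent noise (> 0).
#' @param blocks Optional list of correlated blocks, each a
#'   `list(features = <indices>, rho = <pairwise correlation>)` with
#'   `|rho| < 1`.
#' @param seed Integer seed; the generator is a pure function of the spec
#'   including the seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 50, p = 45, informative = c(1, 2),
                           coefs = c(2, -2), noise_sd = 1, blocks = NULL,
                           seed = 0) {
  stopifnot(n >= 2, p >= 1, length(informative) == length(coefs),
            noise_sd > 0)
  if (length(informative) &&
      (min(informative) < 1 || max(informative) > p)) {
    abort("`informative` indices must lie in 1..p.")
  }
  for (b in blocks) {
    if (abs(b$rho) >= 1) abort("Block correlation must satisfy |rho| < 1.")
    if (min(b$features) < 1 || max(b$features) > p) {
      abort("Block feature indices must lie in 1..p.")
    }
  }
  structure(list(n = n, p = p, informative = as.integer(informative),
                 coefs = as.numeric(coefs), noise_sd = noise_sd,
                 blocks = blocks, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> n = %d, p = %d, informative = {%s}, noise_sd = %g, seed = %d\n",
              x$n, x$p,
              paste(sprintf("%d (%.2g)", x$informative, x$coefs),
                    collapse = ", "),
              x$noise_sd, x$seed))
  invisible(x)
}

#' Generate a synthetic feature table with linear-threshold labels
#'
#' Deterministic given the spec (including its seed): repeated calls
#' return identical tables. Features are standard normal; blocks listed in
#' the spec are drawn equicorrelated via a Cholesky factor.
#'
#' @param spec A [synthetic_spec()].
#' @return A `feature_table` with features `f1 ... fp`.
#' @examples
#' ft <- gen_linear_binary(synthetic_spec(n = 20, p = 5, seed = 1))
#' table(ft$y)
#' @export
gen_linear_binary <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    X <- matrix(stats::rnorm(spec$n * spec$p), spec$n, spec$p)
    for (b in spec$blocks) {
      k <- length(b$features)
      Sigma <- matrix(b$rho, k, k); diag(Sigma) <- 1
      L <- chol(Sigma)
      X[, b$features] <- X[, b$features, drop = FALSE] %*% L
    }
    z <- drop(X[, spec$informative, drop = FALSE] %*% spec$coefs) +
      stats::rnorm(spec$n, sd = spec$noise_sd)
    y <- as.integer(z > 0)
    colnames(X) <- paste0("f", seq_len(spec$p))
    new_feature_table(X, y, colnames(X))
  })
}

#' Generate a table with an explicitly correlated feature block
#'
#' Convenience wrapper around [gen_linear_binary()] for specs that carry
#' at least one correlated block (a fixture for the decorrelation step and
#' for weak-marginal / strong-joint signals such as a difference of two
#' highly correlated features).
#'
#' @param spec A [synthetic_spec()] with non-empty `blocks`.
#' @return A `feature_table`.
#' @export
gen_correlated_block <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(spec$blocks) || !length(spec$blocks)) {
    abort("`spec$blocks` must specify at least one correlated block.")
  }
  gen_linear_binary(spec)
}

#' Benchmark the framework against comparison methods over seeds
#'
#' For each seed, generates a dataset from the spec and runs each method,
#' recording its LOOCV (validation) accuracy, training accuracy, and
#' number of selected features — the columns of the simulated-comparison
#' table this package is built around.
#'
#' @param spec A [synthetic_spec()]; its `seed` field is replaced by each
#'   element of `seeds` in turn.
#' @param methods Subset of `"framework"` and `"l1lr"` (L1-penalized
#'   logistic regression); the full baseline battery is available through
#'   [baseline_compare()].
#' @param seeds Integer vector of seeds.
#' @param top_k,threshold,bins Framework settings, see [run_framework()].
#' @return A tibble of class `benchmark_result` with one row per
#'   seed x method; `glance()` aggregates to per-method means and
#'   standard deviations.
#' @export
run_benchmark <- function(spec = synthetic_spec(),
                          methods = c("framework", "l1lr"),
                          seeds = 0:49, top_k = 10, threshold = 0.6,
                          bins = 4) {
  methods <- match.arg(methods, c("framework", "l1lr"), several.ok = TRUE)
  rows <- purrr::map(seeds, function(s) {
    sp <- spec
    sp$seed <- as.integer(s)
    ft <- gen_linear_binary(sp)
    purrr::map(methods, function(mth) {
      if (mth == "framework") {
        g <- glance(run_framework(ft, bins = bins, top_k = top_k,
                                  threshold = threshold))
        tibble::tibble(seed = s, method = "framework",
                       validation_accuracy = g$accuracy,
                       training_accuracy = g$training_accuracy,
                       n_features = g$n_active)
      } else {
        g <- glance(l1_logistic_select(ft))
        tibble::tibble(seed = s, method = "l1lr",
                       validation_accuracy = g$accuracy,
                       training_accuracy = g$training_accuracy,
                       n_features = g$n_features)
      }
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  class(rows) <- c("benchmark_result", class(rows))
  rows
}

#' @export
glance.benchmark_result <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$method),
    mean_validation_accuracy = mean(.data$validation_accuracy),
    sd_validation_accuracy = sd(.data$validation_accuracy),
    mean_training_accuracy = mean(.data$training_accuracy),
    mean_n_features = mean(.data$n_features),
    n_seeds = dplyr::n(),
    .groups = "drop")
}

#' Plot benchmark accuracies by method
#'
#' @param object A `benchmark_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.benchmark_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$method,
                               y = .data$validation_accuracy)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "LOOCV accuracy",
                  title = "Simulated benchmark") +
    ggplot2::theme_minimal()
}
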