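#' Equal-frequency discretization
#'
#' Bins a numeric vector into (approximately) equal-frequency bins using
#' type-1 (order-statistic) quantile breaks, so the binning is invariant
#' under strictly monotone transforms of the data. Vectors with at most
#' `bins` distinct values are used as-is, one bin per value.
#'
#' @param x Numeric vector.
#' @param bins Target number of bins (`>= 2`).
#' @return Integer vector of bin indices.
#' @export
discretize_ef <- function(x, bins = 4) {
  stopifnot(is.numeric(x), bins >= 2)
  if (length(x) < bins) {
    warn(sprintf("Fewer samples (%d) than bins (%d); using distinct values.",
                 length(x), bins))
  }
  ux <- sort(unique(x))
  if (length(ux) <= bins) return(match(x, ux))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        type = 1, names = FALSE))
  as.integer(cut(x, breaks = br, include.lowest = TRUE, labels = FALSE))
}

# plug-in MI (in `base` units) of two discrete vectors
plugin_mi <- function(a, b, base = 2) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  pij <- outer(px, py)
  idx <- p > 0
  max(0, sum(p[idx] * log(p[idx] / pij[idx])) / log(base))
}

plugin_entropy <- function(a, base = 2) {
  p <- table(a) / length(a)
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Mutual information between a feature and the class label
#'
#' Plug-in estimate of `I(X; Y)` after equal-frequency binning of `x`.
#' `0 log 0` terms contribute zero; the result is clipped to be
#' nonnegative and is bounded by `min(H(binned x), H(y))`.
#'
#' @param x Numeric feature vector.
#' @param y Binary (0/1) label vector.
#' @param bins Number of equal-frequency bins for `x`.
#' @param base Logarithm base; 2 gives bits.
#' @return Nonnegative mutual information estimate.
#' @examples
#' mi_score(c(0, 0, 1, 1), c(0, 0, 1, 1)) # one bit
#' @export
mi_score <- function(x, y, bins = 4, base = 2) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (!all(y %in% c(0, 1))) abort("`y` must be binary 0/1.")
  if (length(unique(y)) < 2L) {
    warn("Constant label vector; mutual information is 0 by convention.")
    return(0)
  }
  plugin_mi(discretize_ef(x, bins), y, base = base)
}

#' Mutual information between two features
#'
#' Both arguments are binned with [discretize_ef()] before the plug-in
#' estimate; used by the MIFS/MRMR redundancy terms.
#'
#' @inheritParams mi_score
#' @param x1,x2 Numeric feature vectors.
#' @return Nonnegative mutual information estimate.
#' @export
pairwise_mi <- function(x1, x2, bins = 4, base = 2) {
  stopifnot(length(x1) == length(x2), length(x1) >= 2)
  plugin_mi(discretize_ef(x1, bins), discretize_ef(x2, bins), base = base)
}

#' Conditional mutual information I(X; Y | Z)
#'
#' Plug-in estimate on binned data, used by the CMIM criterion. Computed
#' stratum-by-stratum over the conditioning variable.
#'
#' @inheritParams mi_score
#' @param x Candidate feature.
#' @param y Binary label.
#' @param z Conditioning feature.
#' @return Nonnegative conditional mutual information estimate.
#' @export
conditional_mi <- function(x, y, z, bins = 4, base = 2) {
  stopifnot(length(x) == length(y), length(y) == length(z))
  bx <- discretize_ef(x, bins)
  bz <- discretize_ef(z, bins)
  n <- length(x)
  out <- 0
  for (zz in unique(bz)) {
    idx <- bz == zz
    pz <- mean(idx)
    if (sum(idx) >= 1L) {
      out <- out + pz * plugin_mi(bx[idx], y[idx], base = base)
    }
  }
  max(0, out)
}

#' Rank features by mutual information with the class
#'
#' Computes the plug-in MI of every feature against the binary label and
#' orders features by descending score, ties broken by original column
#' order.
#'
#' @param data A data frame with a label column, or a `feature_table`.
#' @param label Label column name (ignored for `feature_table` input).
#' @param positive_class See [as_feature_table()].
#' @param bins,base Estimator configuration, see [mi_score()].
#' @return A tibble of class `mi_ranking` with columns `rank`, `feature`,
#'   `index` (original column position) and `mi`, sorted by rank.
#' @examples
#' spec <- synthetic_spec(n = 40, p = 6, seed = 1)
#' ft <- gen_linear_binary(spec)
#' rank_features(ft)
#' @export
rank_features <- function(data, label = "class", positive_class = NULL,
                          bins = 4, base = 2) {
  ft <- as_feature_table(data, label = label, positive_class = positive_class)
  scores <- vapply(seq_len(ncol(ft$X)),
                   function(j) mi_score(ft$X[, j], ft$y, bins = bins,
                                        base = base),
                   numeric(1))
  ord <- order(-scores, seq_along(scores))
  out <- tibble::tibble(rank = seq_along(ord),
                        feature = ft$feature_names[ord],
                        index = ord,
                        mi = scores[ord])
  attr(out, "bins") <- bins
  attr(out, "base") <- base
  class(out) <- c("mi_ranking", class(out))
  out
}

#' Remove correlated (redundant) features from the top of an MI ranking
#'
#' Takes the `top_k` highest-MI features and scans them in descending MI
#' order; a feature is dropped when its absolute Pearson (or Spearman)
#' correlation with an already-retained feature reaches `threshold`, so the
#' highest-MI member of any correlated clique is the one kept. This mirrors
#' the redundancy-removal step applied to the top ten cortical-thickness
#' regions with a 0.6 cutoff in the motivating application.
#'
#' @inheritParams rank_features
#' @param top_k How many top-ranked features to consider.
#' @param threshold Absolute correlation at or above which a pair is
#'   deemed redundant, in (0, 1].
#' @param ranking Optionally a precomputed [rank_features()] result.
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @return An object of class `candidate_set`: list with `kept` (tibble of
#'   retained features in MI order), `removed` (tibble with the retained
#'   partner and the offending correlation) and `threshold`.
#' @export
decorrelate <- function(data, label = "class", top_k = 10, threshold = 0.6,
                        ranking = NULL, positive_class = NULL, bins = 4,
                        base = 2, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ft <- as_feature_table(data, label = label, positive_class = positive_class)
  if (is.null(ranking)) {
    ranking <- rank_features(ft, bins = bins, base = base)
  }
  p <- ncol(ft$X)
  if (top_k < 1 || top_k > p) abort("`top_k` must be between 1 and p.")
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1].")
  top <- head(ranking, top_k)
  kept <- integer(0)
  removed <- list()
  for (r in seq_len(nrow(top))) {
    j <- top$index[r]
    if (sd(ft$X[, j]) == 0) {
      warn(sprintf("Feature '%s' has zero variance; correlations with it are taken as 0.",
                   top$feature[r]))
    }
    hit <- NA_integer_
    rho <- NA_real_
    for (k in kept) {
      r_jk <- safe_cor(ft$X[, j], ft$X[, k], method)
      if (abs(r_jk) >= threshold) { hit <- k; rho <- r_jk; break }
    }
    if (is.na(hit)) {
      kept <- c(kept, j)
    } else {
      removed[[length(removed) + 1L]] <- tibble::tibble(
        feature = ft$feature_names[j], index = j,
        retained_feature = ft$feature_names[hit], retained_index = hit,
        correlation = rho)
    }
  }
  structure(list(
    kept = dplyr::filter(top, .data$index %in% kept),
    removed = if (length(removed)) dplyr::bind_rows(removed) else
      tibble::tibble(feature = character(), index = integer(),
                     retained_feature = character(),
                     retained_index = integer(), correlation = numeric()),
    threshold = threshold,
    method = method
  ), class = "candidate_set")
}

safe_cor <- function(a, b, method) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b, method = method)
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d kept, %d removed (|r| >= %.2f, %s)\n",
              nrow(x$kept), nrow(x$removed), x$threshold, x$method))
  print(x$kept)
  invisible(x)
}

#' @export
tidy.candidate_set <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$kept, status = "kept",
                  retained_feature = NA_character_, correlation = NA_real_),
    dplyr::mutate(x$removed, status = "removed")
  )
}
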