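# shared internal helpers

# geometric grid from hi down to hi * ratio; degenerate hi -> single 0
lambda_grid_geom <- function(hi, n = 100, ratio = 1e-3) {
  if (!is.finite(hi) || hi <= 0) return(0)
  hi * exp(seq(0, log(ratio), length.out = n))
}

# confusion-matrix summary with class 1 positive; NA rates when undefined
classification_metrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  tp <- sum(truth == 1 & pred == 1)
  tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  tibble::tibble(
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    tp = tp, tn = tn, fp = fp, fn = fn
  )
}

# index of the best accuracy; ties resolved to the first index, which is the
# largest lambda when the grid is descending
best_lambda_index <- function(acc) which.max(acc)

check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
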