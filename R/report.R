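#' Assemble a selection/classification report
#'
#' A report records, for one selection method, the chosen features, the
#' penalty level, leave-one-out metrics derived from per-fold predictions,
#' and the training accuracy. Accuracy, sensitivity and specificity are
#' recomputed from the per-fold predictions so the confusion-matrix
#' identities hold by construction.
#'
#' @param method Method name (string).
#' @param features Character vector of selected feature names (may be
#'   empty).
#' @param lambda Penalty level at which the final model was fit.
#' @param truth Integer 0/1 vector of true labels, one per held-out fold.
#' @param predictions Integer 0/1 vector of held-out predictions.
#' @param training_accuracy Accuracy of the final model on the full
#'   training data.
#' @return An object of class `infolasso_report`.
#' @export
report <- function(method, features, lambda, truth, predictions,
                   training_accuracy = NA_real_) {
  m <- classification_metrics(truth, predictions)
  structure(list(
    method = method,
    features = as.character(features),
    lambda = lambda,
    accuracy = m$accuracy,
    sensitivity = m$sensitivity,
    specificity = m$specificity,
    training_accuracy = training_accuracy,
    folds = tibble::tibble(fold = seq_along(truth),
                           truth = as.integer(truth),
                           prediction = as.integer(predictions))
  ), class = "infolasso_report")
}

#' Write a report to JSON (and optionally a plain-text table)
#'
#' The JSON file is machine-readable and round-trips through
#' [read_report()]. An empty selected-feature list is serialized as an
#' explicit empty array. When `text_path` is given, a small human-readable
#' table is written there as well.
#'
#' @param x An `infolasso_report`.
#' @param path Output JSON path.
#' @param text_path Optional path for a plain-text rendering.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, text_path = NULL) {
  stopifnot(inherits(x, "infolasso_report"))
  payload <- list(
    method = x$method,
    features = I(x$features),
    lambda = x$lambda,
    accuracy = x$accuracy,
    sensitivity = x$sensitivity,
    specificity = x$specificity,
    training_accuracy = x$training_accuracy,
    folds = x$folds
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", na = "null")
  if (!is.null(text_path)) {
    writeLines(format(x), text_path)
  }
  invisible(path)
}

#' Read a report back from JSON
#'
#' @param path Path written by [write_report()].
#' @return An `infolasso_report`.
#' @export
read_report <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- report(method = p$method,
                features = as.character(unlist(p$features)),
                lambda = p$lambda,
                truth = p$folds$truth,
                predictions = p$folds$prediction,
                training_accuracy = p$training_accuracy %||% NA_real_)
  out
}

#' @export
format.infolasso_report <- function(x, ...) {
  c(sprintf("Method:             %s", x$method),
    sprintf("Selected features:  %s",
            if (length(x$features)) paste(x$features, collapse = ", ")
            else "(none)"),
    sprintf("Lambda:             %.6g", x$lambda),
    sprintf("Testing accuracy:   %.4f", x$accuracy),
    sprintf("Training accuracy:  %.4f", x$training_accuracy),
    sprintf("Sensitivity:        %.4f", x$sensitivity),
    sprintf("Specificity:        %.4f", x$specificity))
}

#' @export
print.infolasso_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
glance.infolasso_report <- function(x, ...) {
  tibble::tibble(method = x$method,
                 n_features = length(x$features),
                 accuracy = x$accuracy,
                 training_accuracy = x$training_accuracy,
                 sensitivity = x$sensitivity,
                 specificity = x$specificity,
                 lambda = x$lambda)
}
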