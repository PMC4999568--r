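#' Build a feature table from a data frame
#'
#' A feature table is the package's central container: an `n x p` numeric
#' matrix of features (e.g. cortical thickness in mm over atlas regions of
#' interest), unique feature names, and a binary class label with class 1
#' the "positive" (case) class used for sensitivity.
#'
#' Labels may be coded `{0, 1}`, `{-1, +1}` (mapped to `{0, 1}`), logical,
#' or as two string/factor levels together with an explicit
#' `positive_class`.
#'
#' @param data A data frame with one label column and numeric feature
#'   columns.
#' @param label Name of the label column (string).
#' @param positive_class Value of `label` to treat as class 1. Required when
#'   the label has two non-numeric levels; optional otherwise.
#' @return An object of class `feature_table` with elements `X` (numeric
#'   matrix), `y` (integer 0/1 vector) and `feature_names`.
#' @examples
#' df <- data.frame(a = c(1, 2, 3), b = c(4, 2, 0), dx = c(0, 1, 1))
#' ft <- as_feature_table(df, label = "dx")
#' ft$y
#' @export
as_feature_table <- function(data, label = "class", positive_class = NULL) {
  if (inherits(data, "feature_table")) return(data)
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!is.character(label) || length(label) != 1L) {
    abort("`label` must be a single column name.")
  }
  if (!label %in% names(data)) {
    abort(sprintf("Label column '%s' not found in the data.", label))
  }
  y <- coerce_labels(data[[label]], positive_class)
  feat_names <- names(data)[names(data) != label]
  if (anyDuplicated(feat_names)) {
    abort(sprintf("Duplicate feature names: %s.",
                  paste(unique(feat_names[duplicated(feat_names)]),
                        collapse = ", ")))
  }
  feat <- data[feat_names]
  if (ncol(feat) < 1L) abort("At least one feature column is required.")
  if (nrow(feat) < 2L) abort("At least two samples are required.")
  for (nm in names(feat)) {
    col <- feat[[nm]]
    if (!is.numeric(col)) {
      abort(sprintf("Feature column '%s' is not numeric.", nm))
    }
    if (anyNA(col)) {
      abort(sprintf("Missing value in feature column '%s', row %d.",
                    nm, which(is.na(col))[1L]))
    }
  }
  X <- as.matrix(feat)
  rownames(X) <- NULL
  new_feature_table(X, y, colnames(X))
}

new_feature_table <- function(X, y, feature_names) {
  structure(list(X = X, y = as.integer(y), feature_names = feature_names),
            class = "feature_table")
}

coerce_labels <- function(y, positive_class = NULL) {
  if (anyNA(y)) abort("Missing values in the label column.")
  if (!is.null(positive_class)) {
    out <- as.integer(y == positive_class)
    if (sum(out) == 0L || sum(out) == length(out)) {
      if (length(unique(y)) > 2L) {
        abort("Label column must have exactly two levels.")
      }
    }
    return(out)
  }
  if (is.logical(y)) return(as.integer(y))
  if (is.numeric(y)) {
    u <- sort(unique(y))
    if (all(u %in% c(0, 1))) return(as.integer(y))
    if (all(u %in% c(-1, 1))) return(as.integer(y == 1))
    abort("Numeric labels must be coded {0,1} or {-1,+1}.")
  }
  u <- unique(as.character(y))
  if (length(u) != 2L) abort("Label column must have exactly two levels.")
  abort(paste0("Labels have levels '", u[1L], "' and '", u[2L],
               "'; supply `positive_class` to pick the class-1 level."))
}

#' Read a feature table from delimited text
#'
#' Reads a CSV/TSV file with a header row of feature names and one label
#' column. The delimiter is auto-detected from the header (comma vs tab)
#' unless given explicitly. Missing or non-numeric feature cells are
#' errors that name the offending row and column.
#'
#' @param path Path to a delimited text file.
#' @param label Name of the label column.
#' @param positive_class See [as_feature_table()].
#' @param delim Field delimiter; `NULL` (default) auto-detects `","` vs
#'   `"\t"` from the header line.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path, label = "class", positive_class = NULL,
                               delim = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  # base strtod parsing is correctly rounded, so numeric round trips are
  # bit-exact
  raw <- utils::read.delim(path, sep = delim, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!label %in% names(raw)) {
    abort(sprintf("Label column '%s' not found in %s.", label, path))
  }
  for (nm in setdiff(names(raw), label)) {
    col <- raw[[nm]]
    if (anyNA(col)) {
      abort(sprintf("Missing or non-numeric value in column '%s', row %d of %s.",
                    nm, which(is.na(col))[1L], path))
    }
    if (!is.numeric(col)) {
      abort(sprintf("Non-numeric value in column '%s' of %s.", nm, path))
    }
  }
  as_feature_table(as.data.frame(raw), label = label,
                   positive_class = positive_class)
}

#' Write a feature table to delimited text
#'
#' Inverse of [read_feature_table()]: features in column order plus the
#' label column. A read back of the written file reproduces the feature
#' matrix exactly.
#'
#' @param ft A `feature_table`.
#' @param path Output path.
#' @param label Name to use for the label column.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, label = "class", delim = ",") {
  ft <- as_feature_table(ft)
  # %.17g guarantees a bit-exact read-back of every double
  df <- tibble::as_tibble(lapply(as.data.frame(ft$X),
                                 function(x) sprintf("%.17g", x)))
  df[[label]] <- ft$y
  readr::write_delim(df, path, delim = delim, quote = "none")
  invisible(path)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features; %d cases / %d controls\n",
              nrow(x$X), ncol(x$X), sum(x$y == 1L), sum(x$y == 0L)))
  cat("features:", paste(head(x$feature_names, 6L), collapse = ", "),
      if (length(x$feature_names) > 6L) "...", "\n")
  invisible(x)
}

#' @export
as.data.frame.feature_table <- function(x, ..., label = "class") {
  df <- as.data.frame(x$X)
  df[[label]] <- x$y
  df
}

# tibble view: samples in rows, features + label
#' @export
tidy.feature_table <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$X))
  out$class <- x$y
  out
}
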