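#' Outcome classes of the four-level tumor diagnosis
#'
#' The four mutually exclusive histological outcome events, in their
#' canonical order: benign, borderline, primary invasive, metastatic.
#'
#' @return Character vector of length four.
#' @export
tumor_classes <- function() {
  c("benign", "borderline", "primary_invasive", "metastatic")
}

#' Construct a validated case-level dataset
#'
#' A \code{risk_dataset} is a data frame of one row per patient together with
#' a typed predictor schema and a polytomous outcome column. Predictor kinds
#' are \code{"continuous"} (finite nonnegative real, e.g. diameters in mm or
#' age in years), \code{"ordinal"} (nonnegative integer counts) and
#' \code{"binary"} (0/1).
#'
#' @param data Data frame containing the predictor columns, the outcome
#'   column and optionally a center label column.
#' @param schema Named character vector mapping predictor names to kinds
#'   (\code{"continuous"}, \code{"ordinal"}, \code{"binary"}).
#' @param outcome Name of the outcome column. Default \code{"outcome"}.
#' @param classes Allowed outcome labels, default \code{tumor_classes()}.
#' @param center Optional name of a center label column (used for stratified
#'   splitting), or \code{NULL}.
#'
#' @return An object of class \code{risk_dataset}: a list with elements
#'   \code{data}, \code{schema}, \code{outcome}, \code{classes},
#'   \code{center}.
#' @export
risk_dataset <- function(data, schema, outcome = "outcome",
                         classes = tumor_classes(), center = NULL) {
  if (!is.data.frame(data)) stop_("`data` must be a data frame")
  if (!outcome %in% names(data))
    stop_("outcome column '%s' not found in data", outcome)
  if (!is.null(center) && !center %in% names(data))
    stop_("center column '%s' not found in data", center)
  if (is.null(names(schema)) || any(!nzchar(names(schema))))
    stop_("`schema` must be a named character vector")
  bad_kind <- setdiff(unique(schema), c("continuous", "ordinal", "binary"))
  if (length(bad_kind))
    stop_("unknown predictor kind(s): %s", paste(bad_kind, collapse = ", "))
  missing_cols <- setdiff(names(schema), names(data))
  if (length(missing_cols))
    stop_("schema column(s) absent from data: %s",
          paste(missing_cols, collapse = ", "))

  y <- data[[outcome]]
  if (anyNA(y)) stop_("outcome missing for row(s) %s",
                      paste(utils::head(which(is.na(y)), 5), collapse = ", "))
  y <- as.character(y)
  bad <- which(!y %in% classes)
  if (length(bad))
    stop_("unknown outcome label '%s' in row %d of column '%s'",
          y[bad[1]], bad[1], outcome)
  data[[outcome]] <- factor(y, levels = classes)

  for (v in names(schema)) {
    x <- data[[v]]
    if (!is.numeric(x))
      stop_("column '%s' must be numeric (kind %s)", v, schema[[v]])
    if (anyNA(x) || any(!is.finite(x)))
      stop_("column '%s' contains missing or non-finite values in row %d",
            v, which(is.na(x) | !is.finite(x))[1])
    ok <- switch(schema[[v]],
      continuous = TRUE,
      ordinal    = all(x >= 0 & x == round(x)),
      binary     = is_binary01(x))
    if (!isTRUE(ok)) {
      bad <- switch(schema[[v]],
        ordinal = which(!(x >= 0 & x == round(x)))[1],
        binary  = which(!x %in% c(0, 1))[1])
      stop_("column '%s' violates kind '%s' in row %d (value %s)",
            v, schema[[v]], bad, format(x[bad]))
    }
  }

  structure(list(data = data, schema = schema, outcome = outcome,
                 classes = classes, center = center),
            class = "risk_dataset")
}

#' @export
print.risk_dataset <- function(x, ...) {
  cat(sprintf("risk_dataset: %d cases, %d predictors\n",
              nrow(x$data), length(x$schema)))
  cc <- class_counts(x)
  cat("outcome counts:\n")
  print(cc)
  invisible(x)
}

#' Per-class case counts of a dataset
#'
#' @param ds A \code{risk_dataset}.
#' @return Named integer vector over the dataset's outcome classes
#'   (N1..N4 in the four-class case).
#' @export
class_counts <- function(ds) {
  stopifnot(inherits(ds, "risk_dataset"))
  table(ds$data[[ds$outcome]])
}

#' Outcome labels of a dataset
#' @param ds A \code{risk_dataset}.
#' @return Factor of per-case outcome labels.
#' @export
outcomes <- function(ds) {
  stopifnot(inherits(ds, "risk_dataset"))
  ds$data[[ds$outcome]]
}

#' Predictor matrix of a dataset
#'
#' @param ds A \code{risk_dataset}.
#' @param variables Optional subset of predictor names; default all schema
#'   columns in schema order.
#' @return Numeric matrix, one row per case.
#' @export
predictor_matrix <- function(ds, variables = NULL) {
  stopifnot(inherits(ds, "risk_dataset"))
  variables <- variables %||% names(ds$schema)
  missing <- setdiff(variables, names(ds$schema))
  if (length(missing))
    stop_("unknown predictor column(s): %s", paste(missing, collapse = ", "))
  as.matrix(ds$data[variables])
}

#' Read a case-level dataset from CSV
#'
#' Comma-separated, UTF-8, header row required, "." decimal. Column types are
#' validated against the schema; the outcome labels must all belong to
#' \code{classes}. Row order is preserved.
#'
#' @inheritParams risk_dataset
#' @param path Path to a CSV file.
#' @return A \code{risk_dataset}.
#' @export
read_dataset <- function(path, schema, outcome = "outcome",
                         classes = tumor_classes(), center = NULL) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  risk_dataset(df, schema = schema, outcome = outcome, classes = classes,
               center = center)
}

#' Write a case-level dataset to CSV
#'
#' @param ds A \code{risk_dataset}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "risk_dataset"))
  utils::write.csv(ds$data, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Subset the cases of a dataset by a predicate on its columns
#'
#' Keeps every case for which the predicate evaluates to \code{TRUE}; the
#' schema is unchanged. Useful for subgroup evaluation (e.g. patients
#' without ascites).
#'
#' @param ds A \code{risk_dataset}.
#' @param predicate An unquoted logical expression in the dataset's columns,
#'   e.g. \code{ascites == 0}.
#' @return A \code{risk_dataset} with the matching cases.
#' @export
filter_cases <- function(ds, predicate) {
  stopifnot(inherits(ds, "risk_dataset"))
  expr <- substitute(predicate)
  used <- all.vars(expr)
  unknown <- setdiff(used, names(ds$data))
  if (length(unknown))
    stop_("predicate references unknown column(s): %s",
          paste(unknown, collapse = ", "))
  keep <- eval(expr, envir = ds$data, enclos = parent.frame())
  if (!is.logical(keep) || length(keep) != nrow(ds$data))
    stop_("predicate must yield one logical per case")
  out <- ds
  out$data <- ds$data[which(keep), , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

#' Stratified training/test split
#'
#' Splits the dataset into training and test parts. Within each stratum
#' (cross-classification of the stratifying columns) the training count is
#' round-half-up of \code{fraction} times the stratum size; which cases go to
#' training is randomized under \code{seed}. This mirrors a development/
#' internal-validation split stratified for center and outcome.
#'
#' @param ds A \code{risk_dataset}.
#' @param fraction Training fraction, strictly between 0 and 1.
#' @param strata Character vector of stratifying column names; default the
#'   outcome column (plus the center column when present).
#' @param seed Integer seed controlling the randomized assignment.
#' @return An object of class \code{split_result}: list with \code{train} and
#'   \code{test} (\code{risk_dataset}s), \code{fraction}, \code{strata},
#'   \code{seed}.
#' @export
stratified_split <- function(ds, fraction, strata = NULL, seed) {
  stopifnot(inherits(ds, "risk_dataset"))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1)
    stop_("`fraction` must lie strictly between 0 and 1")
  strata <- strata %||% c(ds$outcome, ds$center)
  missing <- setdiff(strata, names(ds$data))
  if (length(missing))
    stop_("stratum column(s) absent: %s", paste(missing, collapse = ", "))

  key <- interaction(ds$data[strata], drop = TRUE)
  idx_train <- integer(0)
  with_seed(seed, {
    for (lev in levels(key)) {
      rows <- which(key == lev)
      n_tr <- round_half_up(fraction * length(rows))
      n_tr <- max(0L, min(length(rows), n_tr))
      if (n_tr > 0)
        idx_train <- c(idx_train, sort(sample(rows, n_tr)))
    }
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_len(nrow(ds$data)), idx_train)

  take <- function(idx) {
    out <- ds
    out$data <- ds$data[idx, , drop = FALSE]
    rownames(out$data) <- NULL
    out
  }
  structure(list(train = take(idx_train), test = take(idx_test),
                 fraction = fraction, strata = strata, seed = seed,
                 train_index = idx_train, test_index = idx_test),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("stratified split: %d training / %d test (fraction %.2f)\n",
              nrow(x$train$data), nrow(x$test$data), x$fraction))
  invisible(x)
}
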