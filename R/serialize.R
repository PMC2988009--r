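# JSON model documents. Every fitted object in the package is a plain list
# of atomic fields, matrices and sub-models, so one recursive encoder covers
# the whole model zoo. Numeric payloads are serialized at full precision so
# a re-loaded model reproduces predictions to machine accuracy.

SERIALIZABLE <- c("logit_fit", "mnlogit_fit", "lssvm_fit", "klr_fit",
                  "mklr_fit", "kernel_spec", "ovo_ensemble",
                  "polyrisk_model", "risk_dataset", "class_profile",
                  "candidate_set", "selection_trace", "criteria_report")

encode_obj <- function(x) {
  if (is.null(x)) return(NULL)
  cls <- class(x)[1]
  if (cls %in% SERIALIZABLE && !is.data.frame(x)) {
    fields <- unclass(x)
    # the bordered system inverse is large and re-derivable; drop it
    if (cls == "lssvm_fit") fields$Minv <- NULL
    return(list(`.class` = class(x),
                fields = lapply(fields, encode_obj)))
  }
  if (is.data.frame(x))
    return(list(`.df` = TRUE, `.class` = class(x),
                columns = lapply(as.list(x), encode_obj)))
  if (is.matrix(x))
    return(list(`.matrix` = TRUE, dim = dim(x), dimnames = dimnames(x),
                data = as.vector(x)))
  if (is.factor(x))
    return(list(`.factor` = TRUE, levels = levels(x),
                values = as.character(x)))
  if (is.table(x))
    return(list(`.table` = TRUE, names = names(x), values = as.vector(x)))
  if (is.list(x)) return(lapply(x, encode_obj))
  if (is.atomic(x) && (length(x) != 1 || !is.null(names(x))))
    return(list(`.vector` = TRUE, names = as.list(names(x)),
                values = as.list(unname(x))))
  x
}

decode_obj <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.list(x)) {
    if (isTRUE(x$`.df`)) {
      df <- as.data.frame(lapply(x$columns, decode_obj),
                          stringsAsFactors = FALSE, optional = TRUE)
      class(df) <- unlist(x$`.class`)
      return(df)
    }
    if (!is.null(x$`.class`)) {
      obj <- lapply(x$fields, decode_obj)
      class(obj) <- unlist(x$`.class`)
      return(obj)
    }
    if (isTRUE(x$`.matrix`)) {
      v <- unlist(x$data)
      if (is.null(v)) v <- numeric(0)
      m <- matrix(v, nrow = x$dim[[1]], ncol = x$dim[[2]])
      if (!is.null(x$dimnames)) dimnames(m) <- x$dimnames
      return(m)
    }
    if (isTRUE(x$`.factor`))
      return(factor(unlist(x$values), levels = unlist(x$levels)))
    if (isTRUE(x$`.table`)) {
      v <- unlist(x$values); names(v) <- unlist(x$names)
      return(as.table(v))
    }
    if (isTRUE(x$`.vector`)) {
      v <- unlist(x$values)
      if (is.null(v)) v <- logical(0)
      if (length(x$names)) names(v) <- unlist(x$names)
      return(v)
    }
    return(lapply(x, decode_obj))
  }
  x
}

#' Serialize / restore fitted models as JSON documents
#'
#' Writes any of the package's fitted model objects (dichotomous or
#' polytomous, including one-versus-one ensembles with their stored
#' training matrices) to a structured JSON document, and restores an
#' equivalent object that predicts identically to machine precision.
#'
#' @param model A fitted model object from this package.
#' @param path File path.
#' @return \code{write_model} returns \code{path} invisibly;
#'   \code{read_model} returns the restored object.
#' @export
write_model <- function(model, path) {
  if (!class(model)[1] %in% SERIALIZABLE)
    stop_("cannot serialize objects of class '%s'", class(model)[1])
  jsonlite::write_json(encode_obj(model), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop_("model file not found: %s", path)
  decode_obj(jsonlite::read_json(path, simplifyVector = FALSE))
}
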