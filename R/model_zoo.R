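# The model zoo: one fit/predict contract over the eight named methods.
#
#   MLR       multinomial logistic regression (all-at-once)
#   LR-PC     pairwise coupling of 1-vs-1 logistic regressions,
#             coordinated logistic CV selection (10-variable budget)
#   LR-PC2    as LR-PC but variables from R1U rankings (11-variable budget)
#   MKLR      multinomial kernel logistic regression on the union of the
#             R1U variables
#   KLR-PC    pairwise coupling of 1-vs-1 kernel logistic regressions
#   LSSVM-PC  pairwise coupling of 1-vs-1 Bayesian LS-SVMs
#   stepLR-PC pairwise coupling of 1-vs-1 logistic regressions with
#             automatic stepwise selection (p = 0.05 entry/removal)
#   nested-LR sequential tree: benign|malignant, then borderline|invasive,
#             then primary|metastatic

POLYRISK_METHODS <- c("MLR", "LR-PC", "LR-PC2", "MKLR", "KLR-PC",
                      "LSSVM-PC", "stepLR-PC", "nested-LR")

#' Fit a polytomous ovarian-tumor risk model
#'
#' Single front end over the package's eight methods: true polytomous models
#' (multinomial logistic regression, multinomial kernel logistic
#' regression), pairwise coupling of one-versus-one dichotomous models
#' (logistic regression, kernel logistic regression, Bayesian LS-SVMs), the
#' automatic-stepwise comparator, and a nested tree of sequential
#' dichotomies. Each method carries its own variable-selection track; a
#' user-fixed variable list bypasses selection.
#'
#' @param data Training data: a \code{risk_dataset} with all classes
#'   present.
#' @param method One of \code{"MLR"}, \code{"LR-PC"}, \code{"LR-PC2"},
#'   \code{"MKLR"}, \code{"KLR-PC"}, \code{"LSSVM-PC"}, \code{"stepLR-PC"},
#'   \code{"nested-LR"}.
#' @param variables Fixed variable list: a character vector (used for every
#'   component) or, for pairwise methods, a named list with one character
#'   vector per pair (names as in \code{\link{decompose_1v1}}). \code{NULL}
#'   (default) runs the method's selection track.
#' @param kernel \code{"linear"} (default) or \code{"gaussian"} for the
#'   kernel-based methods.
#' @param sigma_grid Bandwidth grid for the Gaussian kernel; default the
#'   median-distance grid.
#' @param gamma_grid,lambda_grid Regularization grids for LS-SVM / KLR.
#' @param budget Total distinct variables across the six pairs for
#'   coordinated selection; defaults: 10 (LR-PC), 11 (R1U-based methods).
#' @param min_per_pair Minimum variables per pair during coordinated
#'   selection, default 3.
#' @param select_runs CV repetitions inside coordinated selection, default
#'   5.
#' @param tune_folds CV folds for hyperparameter tuning, default 5.
#' @param seed Integer seed governing every random element (fold draws).
#' @return Object of class \code{polyrisk_model} with elements
#'   \code{method}, \code{classes}, \code{variables} (per component),
#'   \code{components} (the fitted building blocks), \code{selection}
#'   (traces where applicable), \code{seed}, \code{n_class}.
#' @export
polyrisk <- function(data, method = POLYRISK_METHODS, variables = NULL,
                     kernel = c("linear", "gaussian"), sigma_grid = NULL,
                     gamma_grid = default_gamma_grid(),
                     lambda_grid = default_lambda_grid(),
                     budget = NULL, min_per_pair = 3, select_runs = 5,
                     tune_folds = 5, seed = 1) {
  stopifnot(inherits(data, "risk_dataset"))
  method <- match.arg(method)
  kernel <- match.arg(kernel)
  cc <- class_counts(data)
  if (any(cc == 0))
    stop_("training data misses class '%s'", names(cc)[which(cc == 0)[1]])
  lev <- data$classes
  all_vars <- names(data$schema)

  kern_for <- function(X) {
    if (kernel == "linear") list(spec0 = kernel_spec("linear"),
                                 sigmas = NA_real_)
    else {
      sg <- sigma_grid %||% default_sigma_grid(X)
      list(spec0 = NULL, sigmas = sg)
    }
  }

  selection_info <- list()

  ## ----- resolve per-component variable lists -----
  pair_names <- names(decompose_1v1(data))
  fixed_list <- function(defaults) {
    if (is.null(variables)) return(NULL)
    if (is.character(variables))
      return(stats::setNames(rep(list(variables), length(defaults)),
                             defaults))
    if (is.list(variables)) {
      if (!setequal(names(variables), defaults))
        stop_("per-pair variable list must be named: %s",
              paste(defaults, collapse = ", "))
      return(variables[defaults])
    }
    stop_("`variables` must be a character vector or named list")
  }

  r1u_pair_sets <- function() {
    tasks <- decompose_1v1(data)
    per_pair_cap <- 5L
    pools <- lapply(tasks, function(task) {
      y <- droplevels(outcomes(task$data))
      X <- predictor_matrix(task$data)
      tr <- r1u_forward(X, y, max_vars = min(per_pair_cap, ncol(X)),
                        gamma_grid = gamma_grid,
                        positive = task$pair[1])
      selection_info[[paste0("r1u_", paste(task$pair, collapse = "_vs_"))]] <<-
        tr
      as.character(tr$variable)
    })
    sets <- coordinate_1v1_selection(
      data, pools = pools, budget = budget %||% 11L,
      min_per_pair = min_per_pair, runs = select_runs, seed = seed)
    selection_info[["coordinated"]] <<- sets
    lapply(sets, function(s) s$variables)
  }

  lr_pair_sets <- function() {
    sets <- coordinate_1v1_selection(
      data, budget = budget %||% 10L, min_per_pair = min_per_pair,
      runs = select_runs, seed = seed)
    selection_info[["coordinated"]] <<- sets
    lapply(sets, function(s) s$variables)
  }

  mlr_variables <- function() {
    # candidate sets from one-vs-rest stepwise/backward unions plus the
    # full set, judged by repeated-CV per-event c-index (mean over events)
    y <- outcomes(data)
    X <- predictor_matrix(data)
    union_of <- function(f) {
      unique(unlist(lapply(lev, function(e) {
        yy <- factor(ifelse(y == e, e, "rest"), levels = c("rest", e))
        f(X, yy)$variables
      })))
    }
    cands <- list(stepwise = union_of(function(X, yy)
                    suppressWarnings(stepwise_select(X, yy))),
                  backward = union_of(function(X, yy)
                    suppressWarnings(backward_select(X, yy))),
                  full = all_vars)
    cands <- Filter(length, cands)
    reports <- lapply(cands, function(v)
      evaluate_candidate(v, data, runs = select_runs, folds = tune_folds,
                         seeds = seed + seq_len(select_runs)))
    selection_info[["mlr_candidates"]] <<- reports
    means <- vapply(reports, function(r) mean(r$cv_c_index), numeric(1))
    sizes <- vapply(cands, length, integer(1))
    cands[[order(-means, sizes)[1]]]
  }

  ## ----- tuned dichotomous fitters -----
  tune_grid <- function(X, par_name, par_grid) {
    kf <- kern_for(X)
    if (is.na(kf$sigmas[1]))
      stats::setNames(data.frame(par_grid), par_name)
    else
      stats::setNames(expand.grid(par_grid, kf$sigmas),
                      c(par_name, "sigma"))
  }
  spec_from <- function(best) {
    if (!is.null(best$sigma) && !is.na(best$sigma))
      kernel_spec("gaussian", best$sigma)
    else kernel_spec("linear")
  }

  fit_pair <- function(task, vars, family) {
    y <- droplevels(outcomes(task$data))
    X <- predictor_matrix(task$data, vars)
    pos <- task$pair[1]
    if (family == "logit")
      return(suppressWarnings(logit_fit(X, y, positive = pos)))
    if (family == "klr") {
      tn <- tune_cv(X, y, family = "klr",
                    grid = tune_grid(X, "lambda", lambda_grid),
                    folds = tune_folds, seed = seed, positive = pos)
      return(klr_fit(X, y, lambda = tn$best$lambda,
                     kernel = spec_from(tn$best), positive = pos))
    }
    tn <- tune_cv(X, y, family = "lssvm",
                  grid = tune_grid(X, "gamma", gamma_grid),
                  folds = tune_folds, seed = seed, positive = pos)
    lssvm_fit(X, y, gamma = tn$best$gamma, kernel = spec_from(tn$best),
              positive = pos)
  }

  build_ensemble <- function(pair_vars, family) {
    tasks <- decompose_1v1(data)
    models <- lapply(names(tasks), function(q)
      fit_pair(tasks[[q]], pair_vars[[q]], family))
    ovo_ensemble(models, lapply(tasks, `[[`, "pair"), classes = lev)
  }

  ## ----- per-method development -----
  components <- NULL
  used_vars <- NULL
  if (method == "MLR") {
    v <- if (!is.null(variables)) {
      if (!is.character(variables)) stop_("MLR takes a character vector")
      variables
    } else mlr_variables()
    components <- mnlogit_fit(predictor_matrix(data, v), outcomes(data))
    used_vars <- v
  } else if (method == "MKLR") {
    v <- if (!is.null(variables)) {
      if (!is.character(variables)) stop_("MKLR takes a character vector")
      variables
    } else unique(unlist(r1u_pair_sets()))
    X <- predictor_matrix(data, v)
    y <- outcomes(data)
    tn <- tune_cv(X, y, family = "mklr",
                  grid = tune_grid(X, "lambda", lambda_grid),
                  folds = tune_folds, seed = seed)
    components <- mklr_fit(X, y, lambda = tn$best$lambda,
                           kernel = spec_from(tn$best))
    used_vars <- v
  } else if (method == "nested-LR") {
    v <- if (is.null(variables)) all_vars else {
      if (!is.character(variables))
        stop_("nested-LR takes a character vector")
      variables
    }
    y <- outcomes(data)
    X <- predictor_matrix(data, v)
    mal <- y != lev[1]
    inv <- y %in% lev[3:4]
    y1 <- factor(ifelse(mal, "malignant", lev[1]),
                 levels = c("malignant", lev[1]))
    m1 <- suppressWarnings(logit_fit(X, y1, positive = lev[1]))
    y2 <- factor(ifelse(y[mal] == lev[2], lev[2], "invasive"),
                 levels = c("invasive", lev[2]))
    m2 <- suppressWarnings(logit_fit(X[mal, , drop = FALSE], y2,
                                     positive = lev[2]))
    m3 <- suppressWarnings(logit_fit(X[inv, , drop = FALSE],
                                     droplevels(factor(y[inv])),
                                     positive = lev[3]))
    components <- list(m1, m2, m3)
    used_vars <- v
  } else {
    # one-versus-one + pairwise coupling families
    pair_vars <- fixed_list(pair_names)
    if (is.null(pair_vars)) {
      pair_vars <- switch(method,
        "LR-PC" = lr_pair_sets(),
        "LR-PC2" = , "KLR-PC" = , "LSSVM-PC" = r1u_pair_sets(),
        "stepLR-PC" = {
          tasks <- decompose_1v1(data)
          lapply(tasks, function(task) {
            y <- droplevels(outcomes(task$data))
            X <- predictor_matrix(task$data)
            suppressWarnings(
              stepwise_select(X, y)$variables)
          })
        })
    }
    family <- switch(method,
      "LR-PC" = , "LR-PC2" = , "stepLR-PC" = "logit",
      "KLR-PC" = "klr", "LSSVM-PC" = "lssvm")
    components <- build_ensemble(pair_vars, family)
    used_vars <- pair_vars
  }

  structure(list(method = method, classes = lev, variables = used_vars,
                 components = components, selection = selection_info,
                 seed = seed, n_class = as.integer(cc)),
            class = "polyrisk_model")
}

#' @export
print.polyrisk_model <- function(x, ...) {
  cat(sprintf("polyrisk model: %s (classes: %s)\n", x$method,
              paste(x$classes, collapse = ", ")))
  if (is.character(x$variables))
    cat("variables:", paste(x$variables, collapse = ", "), "\n")
  else {
    cat("variables per pair:\n")
    for (q in names(x$variables))
      cat(sprintf("  %s: %s\n", q, paste(x$variables[[q]],
                                         collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.polyrisk_model <- function(object, ...) {
  print(object)
  nv <- length(unique(unlist(object$variables)))
  cat(sprintf("%d distinct predictors; training class counts: %s\n", nv,
              paste(object$n_class, collapse = "/")))
  invisible(object)
}

#' Predicted polytomous probabilities
#'
#' @param object A \code{polyrisk_model}.
#' @param newdata Cases to score (\code{risk_dataset}, data frame or
#'   matrix with the model's predictor columns).
#' @param ... Unused.
#' @return Matrix of per-case event probabilities; rows on the simplex,
#'   columns in class order.
#' @export
predict.polyrisk_model <- function(object, newdata, ...) {
  P <- switch(object$method,
    "MLR" = predict(object$components, newdata)[, object$classes,
                                                drop = FALSE],
    "MKLR" = predict(object$components, newdata)[, object$classes,
                                                 drop = FALSE],
    "nested-LR" = predict_nested_tree(object$components, newdata,
                                      classes = object$classes),
    predict_coupled(object$components, newdata))
  rownames(P) <- NULL
  P
}

#' Validate a fitted polytomous model on a dataset
#'
#' Computes the polytomous c-index (optionally with a stratified bootstrap
#' CI), the six pairwise c-indexes (from the pair models' own outputs for
#' one-versus-one ensembles, from renormalized coupled probabilities
#' otherwise), the benign-versus-malignant c-index, and one loess
#' calibration curve per event.
#'
#' @param m A \code{polyrisk_model}.
#' @param ds Evaluation data (\code{risk_dataset} with all classes present
#'   for the polytomous index).
#' @param bootstrap Number of bootstrap resamples for the CI of the
#'   polytomous c-index (0 = no CI), default 0.
#' @param level CI level, default 0.95.
#' @param span Loess span for calibration curves, default 0.75.
#' @param seed Seed for the bootstrap.
#' @return Object of class \code{polyrisk_report}.
#' @export
validate_model <- function(m, ds, bootstrap = 0, level = 0.95,
                           span = 0.75, seed = 1) {
  stopifnot(inherits(m, "polyrisk_model"), inherits(ds, "risk_dataset"))
  y <- outcomes(ds)
  P <- predict(m, ds)
  poly <- polytomous_c_index(P, y)
  if (bootstrap > 0) {
    poly$ci <- bootstrap_ci(function(ix)
      polytomous_c_index(P[ix, , drop = FALSE], y[ix])$estimate,
      n = length(y), strata = y, B = bootstrap, level = level, seed = seed)
  }
  pairwise <- if (inherits(m$components, "ovo_ensemble"))
    pairwise_c_indexes_ovo(m$components, ds)
  else pairwise_c_indexes(P, y)
  bvm <- benign_vs_malignant_c(P, y)
  calib <- lapply(m$classes, function(e)
    tryCatch(calibration_curve(P[, e], as.numeric(y == e), span = span),
             error = function(err) NULL))
  names(calib) <- m$classes
  structure(list(method = m$method, n = length(y),
                 polytomous = poly, pairwise = pairwise,
                 benign_vs_malignant = bvm, calibration = calib),
            class = "polyrisk_report")
}

#' @export
print.polyrisk_report <- function(x, ...) {
  cat(sprintf("validation of %s on %d cases\n", x$method, x$n))
  print(x$polytomous)
  cat("pairwise c-indexes:\n")
  for (q in names(x$pairwise))
    cat(sprintf("  %-40s %.3f\n", q, x$pairwise[[q]]$estimate))
  cat(sprintf("benign vs malignant c-index: %.3f\n",
              x$benign_vs_malignant$estimate))
  invisible(x)
}

#' Flatten a validation report to one data-frame row
#'
#' @param report A \code{polyrisk_report}.
#' @return One-row data frame: method, n, polytomous c-index (+ CI when
#'   present), the six pairwise c-indexes, benign-vs-malignant c-index.
#' @export
report_row <- function(report) {
  stopifnot(inherits(report, "polyrisk_report"))
  row <- data.frame(method = report$method, n = report$n,
                    polytomous_c = report$polytomous$estimate)
  if (!is.null(report$polytomous$ci)) {
    row$ci_lower <- report$polytomous$ci$lower
    row$ci_upper <- report$polytomous$ci$upper
  }
  for (q in names(report$pairwise))
    row[[q]] <- report$pairwise[[q]]$estimate
  row$benign_vs_malignant <- report$benign_vs_malignant$estimate
  row
}
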