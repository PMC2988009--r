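# Cross-validated hyperparameter tuning for the kernel models.

#' Default hyperparameter grids
#'
#' The regularization grids are log-spaced over 10^-3..10^3 (13 points); the
#' Gaussian bandwidth grid is log-spaced around the median pairwise distance
#' heuristic (7 points).
#'
#' @return Numeric vector of grid values.
#' @export
default_gamma_grid <- function() 10^seq(-3, 3, length.out = 13)

#' @rdname default_gamma_grid
#' @export
default_lambda_grid <- function() 10^seq(-3, 3, length.out = 13)

#' @rdname default_gamma_grid
#' @param X Case matrix used for the median-distance heuristic.
#' @export
default_sigma_grid <- function(X) {
  median_pairwise_distance(X) * 10^seq(-1.5, 1.5, length.out = 7)
}

# stratified fold assignment; errors if any class is thinner than the folds
cv_folds <- function(y, folds, seed) {
  y <- factor(y)
  if (any(table(y) < folds))
    stop_("class '%s' has fewer cases than folds; cannot stratify",
          names(which(table(y) < folds))[1])
  fold <- integer(length(y))
  with_seed(seed, {
    for (lev in levels(y)) {
      ix <- sample(which(y == lev))
      fold[ix] <- rep_len(seq_len(folds), length(ix))
    }
  })
  fold
}

#' Tune kernel-model hyperparameters by stratified cross-validation
#'
#' Evaluates every grid point with k-fold stratified CV and returns the one
#' maximizing the mean held-out c-index (dichotomous c-index on the latent
#' output for LS-SVM, on the predicted probability for KLR; polytomous
#' c-index for MKLR). Exact ties are broken towards the most regularized
#' point (smallest \code{gamma} / largest \code{lambda}), then the largest
#' \code{sigma}.
#'
#' @param x Predictor matrix or \code{risk_dataset}.
#' @param y Labels (binary for \code{lssvm}/\code{klr}, multi-class factor
#'   for \code{mklr}); defaults to the dataset outcome.
#' @param family \code{"lssvm"}, \code{"klr"} or \code{"mklr"}.
#' @param grid Data frame of candidate hyperparameters: column \code{gamma}
#'   (lssvm) or \code{lambda} (klr/mklr), optional column \code{sigma} for
#'   the Gaussian kernel (absent or NA = linear kernel).
#' @param folds Number of CV folds, default 5.
#' @param seed Integer seed for the fold assignment.
#' @param positive,reference Passed to the fitters.
#' @return List with \code{best} (named list of the selected
#'   hyperparameters) and \code{table} (the grid with the mean CV metric).
#' @export
tune_cv <- function(x, y = NULL, family = c("lssvm", "klr", "mklr"),
                    grid, folds = 5, seed = 1, positive = NULL,
                    reference = NULL) {
  family <- match.arg(family)
  if (inherits(x, "risk_dataset")) {
    if (is.null(y)) y <- outcomes(x)
    x <- predictor_matrix(x)
  }
  x <- as.matrix(x)
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0) stop_("hyperparameter grid is empty")
  yf <- droplevels(factor(y))
  fold <- cv_folds(yf, folds, seed)

  metric_for <- function(row) {
    sigma <- if ("sigma" %in% names(grid)) row$sigma else NA_real_
    kern <- if (is.na(sigma)) kernel_spec("linear")
            else kernel_spec("gaussian", sigma)
    vals <- vapply(seq_len(folds), function(f) {
      tr <- fold != f; te <- !tr
      if (family == "lssvm") {
        m <- lssvm_fit(x[tr, , drop = FALSE], yf[tr], gamma = row$gamma,
                       kernel = kern, positive = positive)
        s <- predict(m, x[te, , drop = FALSE], type = "latent")
        c_index(s, factor(yf[te], levels = m$labels),
                positive = m$positive)$estimate
      } else if (family == "klr") {
        m <- klr_fit(x[tr, , drop = FALSE], yf[tr], lambda = row$lambda,
                     kernel = kern, positive = positive)
        s <- predict(m, x[te, , drop = FALSE])
        c_index(s, factor(yf[te], levels = m$labels),
                positive = m$positive)$estimate
      } else {
        m <- mklr_fit(x[tr, , drop = FALSE], yf[tr], lambda = row$lambda,
                      kernel = kern, reference = reference)
        P <- predict(m, x[te, , drop = FALSE])
        polytomous_c_index(P[, levels(yf), drop = FALSE],
                           yf[te])$estimate
      }
    }, numeric(1))
    mean(vals)
  }

  metrics <- vapply(seq_len(nrow(grid)), function(i)
    suppressWarnings(metric_for(grid[i, , drop = FALSE])), numeric(1))
  tab <- cbind(grid, cv_metric = metrics)

  reg_key <- if (family == "lssvm") tab$gamma else -tab$lambda
  sig_key <- if ("sigma" %in% names(tab))
    ifelse(is.na(tab$sigma), -Inf, -tab$sigma) else rep(0, nrow(tab))
  ord <- order(-metrics, reg_key, sig_key)
  best <- as.list(grid[ord[1], , drop = FALSE])
  list(best = best, table = tab)
}
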