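# Variable selection. Two tracks mirror the study design: (1) logistic
# regression candidate sets from stepwise/backward/manual procedures, judged
# by AIC, BIC and the average per-event c-index over repeated stratified
# cross-validation; (2) for linear-kernel LS-SVMs, fast forward selection
# (R1U) that scores each candidate variable by the exact leave-one-out
# c-index, obtained through rank-one updates of the kernel system inverse
# rather than refits, with the regularization parameter re-tuned on a grid
# at every step. A greedy coordination procedure controls the total number
# of variables across the six one-versus-one problems.

#' Candidate variable set
#'
#' @param variables Character vector of predictor names (no duplicates).
#' @param provenance One of \code{"stepwise"}, \code{"backward"},
#'   \code{"manual"}, \code{"r1u"}.
#' @return Object of class \code{candidate_set}.
#' @export
candidate_set <- function(variables,
                          provenance = c("manual", "stepwise", "backward",
                                         "r1u")) {
  provenance <- match.arg(provenance)
  variables <- as.character(variables)
  if (anyDuplicated(variables)) stop_("duplicate variable names")
  structure(list(variables = variables, provenance = provenance),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate set (%s): %s\n", x$provenance,
              if (length(x$variables)) paste(x$variables, collapse = ", ")
              else "<empty>"))
  invisible(x)
}

# likelihood-ratio p-value for nested logistic models
lrt_pvalue <- function(ll_full, ll_reduced, df = 1) {
  stat <- max(2 * (ll_full - ll_reduced), 0)
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

fit_ll <- function(x, y, vars) {
  if (length(vars) == 0) {
    n <- length(y); p1 <- mean(y)
    return(n * (p1 * log(max(p1, 1e-300)) +
                (1 - p1) * log(max(1 - p1, 1e-300))))
  }
  suppressWarnings(logit_fit(x[, vars, drop = FALSE], y))$logLik
}

resolve_selection_xy <- function(x, y) {
  if (inherits(x, "risk_dataset")) {
    if (is.null(y)) y <- outcomes(x)
    x <- predictor_matrix(x)
  }
  x <- as.matrix(x)
  if (ncol(x) > 0 && is.null(colnames(x)))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  yf <- droplevels(factor(y))
  if (nlevels(yf) != 2) stop_("selection requires a binary outcome")
  yy <- as.integer(yf == levels(yf)[2])
  list(x = x, y = yy)
}

#' Forward stepwise selection with removal, on likelihood-ratio p-values
#'
#' The classic automatic procedure used as a comparator: at each cycle the
#' candidate with the smallest likelihood-ratio p-value enters if below
#' \code{p_enter}; then included variables with p-value above
#' \code{p_remove} are dropped (largest first). Deterministic given data.
#'
#' @param x Predictor matrix/data frame or \code{risk_dataset}.
#' @param y Binary outcome (defaults to the dataset outcome; must have two
#'   levels).
#' @param p_enter,p_remove Entry and removal thresholds, default 0.05.
#' @return A \code{candidate_set} with provenance \code{"stepwise"}.
#' @export
stepwise_select <- function(x, y = NULL, p_enter = 0.05, p_remove = 0.05) {
  r <- resolve_selection_xy(x, y)
  pool <- colnames(r$x)
  sel <- character(0)
  repeat {
    changed <- FALSE
    cand <- setdiff(pool, sel)
    if (length(cand)) {
      ll0 <- fit_ll(r$x, r$y, sel)
      ps <- vapply(cand, function(v)
        lrt_pvalue(fit_ll(r$x, r$y, c(sel, v)), ll0), numeric(1))
      if (min(ps) < p_enter) {
        sel <- c(sel, cand[which.min(ps)])
        changed <- TRUE
      }
    }
    # removal pass
    repeat {
      if (length(sel) == 0) break
      llf <- fit_ll(r$x, r$y, sel)
      ps <- vapply(sel, function(v)
        lrt_pvalue(llf, fit_ll(r$x, r$y, setdiff(sel, v))), numeric(1))
      if (max(ps) > p_remove) {
        sel <- setdiff(sel, sel[which.max(ps)])
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  candidate_set(sel, "stepwise")
}

#' Backward elimination on likelihood-ratio p-values
#'
#' Starts from the full model and repeatedly drops the variable with the
#' largest likelihood-ratio p-value until all remaining p-values are at or
#' below \code{p_remove}.
#'
#' @inheritParams stepwise_select
#' @return A \code{candidate_set} with provenance \code{"backward"}.
#' @export
backward_select <- function(x, y = NULL, p_remove = 0.05) {
  r <- resolve_selection_xy(x, y)
  sel <- colnames(r$x)
  repeat {
    if (length(sel) == 0) break
    llf <- fit_ll(r$x, r$y, sel)
    ps <- vapply(sel, function(v)
      lrt_pvalue(llf, fit_ll(r$x, r$y, setdiff(sel, v))), numeric(1))
    if (max(ps) > p_remove) sel <- setdiff(sel, sel[which.max(ps)])
    else break
  }
  candidate_set(sel, "backward")
}

#' Judge a candidate set by information criteria and repeated-CV c-indexes
#'
#' Fits the polytomous multinomial model on the full data for AIC and BIC,
#' and estimates the discrimination of each event by the average one-versus-
#' rest c-index of out-of-fold multinomial predictions over \code{runs}
#' independent runs of stratified \code{folds}-fold cross-validation.
#'
#' @param set A \code{candidate_set} (or character vector of variables).
#' @param ds A \code{risk_dataset}.
#' @param runs Number of independent CV runs, default 20.
#' @param folds Folds per run, default 5.
#' @param seeds Integer seeds, one per run; default \code{1:runs}.
#' @return Object of class \code{criteria_report}: \code{aic}, \code{bic},
#'   \code{cv_c_index} (named per-event means), \code{per_run} matrix,
#'   \code{runs}, \code{folds}, \code{seeds}.
#' @export
evaluate_candidate <- function(set, ds, runs = 20, folds = 5,
                               seeds = seq_len(runs)) {
  stopifnot(inherits(ds, "risk_dataset"))
  vars <- if (inherits(set, "candidate_set")) set$variables
          else as.character(set)
  if (length(seeds) != runs) stop_("need one seed per run")
  y <- outcomes(ds)
  lev <- levels(y)
  X <- predictor_matrix(ds)

  fit_full <- if (length(vars))
    mnlogit_fit(X[, vars, drop = FALSE], y)
  else mnlogit_fit(matrix(numeric(0), nrow(X), 0), y)

  per_run <- matrix(NA_real_, runs, length(lev),
                    dimnames = list(NULL, lev))
  for (r in seq_len(runs)) {
    fold <- cv_folds(y, folds, seeds[r])
    P <- matrix(NA_real_, nrow(X), length(lev),
                dimnames = list(NULL, lev))
    for (f in seq_len(folds)) {
      tr <- fold != f
      m <- if (length(vars))
        mnlogit_fit(X[tr, vars, drop = FALSE], y[tr])
      else mnlogit_fit(matrix(numeric(0), sum(tr), 0), y[tr])
      P[!tr, ] <- predict(m, if (length(vars))
        X[!tr, vars, drop = FALSE]
        else matrix(numeric(0), sum(!tr), 0))[, lev]
    }
    per_run[r, ] <- vapply(lev, function(e)
      c_index(P[, e], y == e)$estimate, numeric(1))
  }
  structure(list(set = vars, aic = aic(fit_full), bic = bic(fit_full),
                 cv_c_index = colMeans(per_run), per_run = per_run,
                 runs = runs, folds = folds, seeds = seeds),
            class = "criteria_report")
}

#' @export
print.criteria_report <- function(x, ...) {
  cat(sprintf("candidate {%s}\n", paste(x$set, collapse = ", ")))
  cat(sprintf("AIC %.2f, BIC %.2f\n", x$aic, x$bic))
  cat(sprintf("mean CV c-index (%d x %d-fold):\n", x$runs, x$folds))
  print(round(x$cv_c_index, 4))
  invisible(x)
}

#' Sherman-Morrison rank-one inverse update
#'
#' Given \code{A_inv} = \eqn{A^{-1}}, returns \eqn{(A + c\,uu^T)^{-1}}.
#'
#' @param A_inv Inverse of a nonsingular square matrix.
#' @param u Update vector.
#' @param c Scalar weight; \code{1 + c * t(u) A_inv u} must not vanish.
#' @return Updated inverse matrix.
#' @export
rank_one_inverse_update <- function(A_inv, u, c) {
  Au <- drop(A_inv %*% u)
  denom <- 1 + c * sum(u * Au)
  if (abs(denom) < 1e-12)
    stop_("rank-one update denominator numerically zero")
  A_inv - (c / denom) * tcrossprod(Au)
}

# leave-one-out c-index from a system inverse and its solution
loo_cindex_from_inverse <- function(Minv, y) {
  n <- length(y)
  z <- drop(Minv %*% c(y, 0))
  d <- diag(Minv)[seq_len(n)]
  if (any(abs(d) < 1e-12)) return(NA_real_)
  floo <- y - z[seq_len(n)] / d
  c_index(floo, y == 1)$estimate
}

#' Fast forward selection for linear-kernel LS-SVMs (R1U)
#'
#' Adds one variable per step. Every remaining variable is scored by the
#' exact leave-one-out c-index of the linear-kernel LS-SVM that includes
#' it: adding variable v changes the kernel by the rank-one matrix
#' \eqn{x_v x_v^T}, so the bordered system inverse is updated by the
#' Sherman-Morrison identity instead of refitting, and the leave-one-out
#' outputs follow from the inverse's diagonal. The regularization parameter
#' is re-tuned over \code{gamma_grid} at every step (the value with maximal
#' leave-one-out c-index). Ties break towards the higher c-index, then the
#' smaller (more regularized) gamma, then the earlier column. The result is
#' identical to naive forward selection with full refits.
#'
#' @param x Predictor matrix/data frame or \code{risk_dataset}.
#' @param y Binary labels.
#' @param max_vars Number of forward steps (at most \code{ncol(x)}).
#' @param gamma_grid Candidate regularization values; default
#'   \code{\link{default_gamma_grid}()}.
#' @param positive Label treated as the positive event.
#' @param standardize Standardize columns first (recommended); default TRUE.
#' @return Object of class \code{selection_trace}: data frame with columns
#'   \code{step}, \code{variable}, \code{loo_c_index}, \code{gamma}.
#' @export
r1u_forward <- function(x, y = NULL, max_vars,
                        gamma_grid = default_gamma_grid(),
                        positive = NULL, standardize = TRUE) {
  r <- resolve_xy_binary(x, y, positive)
  if (is.null(colnames(r$x))) colnames(r$x) <- paste0("V", seq_len(ncol(r$x)))
  ys <- ifelse(r$y == 1, 1, -1)
  Xs <- if (standardize) apply_standardizer(standardizer(r$x), r$x)
        else as.matrix(r$x)
  n <- nrow(Xs); pvars <- colnames(Xs)
  if (max_vars > ncol(Xs))
    stop_("max_vars (%d) exceeds available variables (%d)",
          max_vars, ncol(Xs))
  if (length(gamma_grid) == 0 || any(gamma_grid <= 0))
    stop_("gamma_grid must be positive")

  # per-gamma inverse of the bordered system for the current variable set
  base_M <- function(gamma) {
    M <- rbind(cbind(diag(1 / gamma, n), 1), c(rep(1, n), 0))
    solve(M)
  }
  Minvs <- lapply(gamma_grid, base_M)
  remaining <- pvars
  selected <- character(0)
  trace <- data.frame(step = integer(0), variable = character(0),
                      loo_c_index = numeric(0), gamma = numeric(0))

  for (step in seq_len(max_vars)) {
    best <- NULL
    for (v in remaining) {
      u <- c(Xs[, v], 0)
      for (g in seq_along(gamma_grid)) {
        Mtry <- rank_one_inverse_update(Minvs[[g]], u, 1)
        ci <- loo_cindex_from_inverse(Mtry, ys)
        if (is.na(ci)) next
        if (is.null(best) || ci > best$ci + 1e-15 ||
            (abs(ci - best$ci) <= 1e-15 &&
             (gamma_grid[g] < best$gamma - 1e-15 ||
              (abs(gamma_grid[g] - best$gamma) <= 1e-15 &&
               match(v, pvars) < match(best$v, pvars))))) {
          best <- list(v = v, g = g, gamma = gamma_grid[g], ci = ci)
        }
      }
    }
    if (is.null(best)) stop_("no admissible variable at step %d", step)
    u <- c(Xs[, best$v], 0)
    Minvs <- lapply(Minvs, rank_one_inverse_update, u = u, c = 1)
    selected <- c(selected, best$v)
    remaining <- setdiff(remaining, best$v)
    trace <- rbind(trace, data.frame(step = step, variable = best$v,
                                     loo_c_index = best$ci,
                                     gamma = best$gamma))
  }
  structure(trace, class = c("selection_trace", "data.frame"))
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("R1U forward selection trace\n")
  print.data.frame(x)
  invisible(x)
}

#' Greedy coordinated variable selection across the six pairwise problems
#'
#' Formalizes the intertwined selection that keeps the total number of
#' variables across all one-versus-one models under control: repeatedly
#' grant the single (pair, variable) addition with the largest mean
#' cross-validated c-index gain, preferring additions that do not grow the
#' union once the budget of distinct variables is reached, until every pair
#' has at least \code{min_per_pair} variables and no further addition is
#' allowed. Gains are measured on dichotomous logistic models by
#' \code{runs} x \code{folds}-fold stratified CV.
#'
#' @param ds A \code{risk_dataset} with all classes present.
#' @param pools Optional named list (one entry per pair, names as in
#'   \code{\link{decompose_1v1}}) of candidate variable pools; default all
#'   schema variables for every pair.
#' @param budget Maximum number of distinct variables across all pairs
#'   (>= 3).
#' @param min_per_pair Minimum variables per pair, default 3.
#' @param runs CV repetitions per evaluation, default 5.
#' @param folds CV folds, default 5.
#' @param seed Base seed; run r of an evaluation uses \code{seed + r}.
#' @return Named list of \code{candidate_set} (provenance "r1u"), one per
#'   pair.
#' @export
coordinate_1v1_selection <- function(ds, pools = NULL, budget,
                                     min_per_pair = 3, runs = 5, folds = 5,
                                     seed = 1) {
  stopifnot(inherits(ds, "risk_dataset"))
  if (budget < min_per_pair) stop_("budget must be at least %d", min_per_pair)
  tasks <- decompose_1v1(ds)
  pools <- pools %||% stats::setNames(
    rep(list(names(ds$schema)), length(tasks)), names(tasks))
  if (!setequal(names(pools), names(tasks)))
    stop_("pools must be named by pair")

  cv_c <- function(task, vars) {
    if (length(vars) == 0) return(0.5)
    y <- droplevels(outcomes(task$data))
    X <- predictor_matrix(task$data, vars)
    vals <- vapply(seq_len(runs), function(r) {
      fold <- cv_folds(y, folds, seed + r)
      s <- numeric(length(y))
      for (f in seq_len(folds)) {
        tr <- fold != f
        m <- suppressWarnings(logit_fit(X[tr, , drop = FALSE], y[tr],
                                        positive = task$pair[1]))
        s[!tr] <- predict(m, X[!tr, , drop = FALSE])
      }
      c_index(s, y, positive = task$pair[1])$estimate
    }, numeric(1))
    mean(vals)
  }

  sets <- stats::setNames(rep(list(character(0)), length(tasks)),
                          names(tasks))
  score <- vapply(names(tasks), function(q) 0.5, numeric(1))
  repeat {
    union_vars <- unique(unlist(sets))
    union_full <- length(union_vars) >= budget
    need <- vapply(sets, length, integer(1)) < min_per_pair
    # enumerate admissible moves
    moves <- list()
    for (q in names(tasks)) {
      cand <- setdiff(pools[[q]], sets[[q]])
      if (union_full) cand <- intersect(cand, union_vars)
      for (v in cand) moves[[length(moves) + 1]] <- list(q = q, v = v)
    }
    if (!length(moves)) break
    if (!any(need) && union_full) break
    gains <- vapply(moves, function(mv)
      cv_c(tasks[[mv$q]], c(sets[[mv$q]], mv$v)) - score[[mv$q]],
      numeric(1))
    # ties: larger gain, then pair order, then column order
    ord <- order(-gains,
                 vapply(moves, function(mv) match(mv$q, names(tasks)),
                        numeric(1)),
                 vapply(moves, function(mv) match(mv$v, names(ds$schema)),
                        numeric(1)))
    mv <- moves[[ord[1]]]
    sets[[mv$q]] <- c(sets[[mv$q]], mv$v)
    score[[mv$q]] <- score[[mv$q]] + gains[ord[1]]
  }
  lapply(sets, candidate_set, provenance = "r1u")
}
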