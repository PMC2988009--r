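# Maximum-likelihood dichotomous and multinomial logistic regression by
# Newton/IRLS, with explicit convergence and separation diagnostics. These
# are the building blocks of the one-versus-one ensembles and the true
# polytomous multinomial model; no shrinkage or penalty is applied here
# (penalization lives in the kernel models).

MAX_IRLS_ITER <- 100L
SCORE_TOL <- 1e-8
SEPARATION_COEF <- 15

# design matrix with intercept column first
add_intercept <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  cbind("(Intercept)" = 1, x)
}

resolve_xy_binary <- function(x, y, positive) {
  if (inherits(x, "risk_dataset")) {
    if (is.null(y)) y <- outcomes(x)
    x <- predictor_matrix(x)
  }
  x <- as.matrix(x)
  if (is.numeric(y) && is_binary01(y)) {
    labels <- c("0", "1")
    pos <- as.character(positive %||% "1")
    if (!pos %in% labels) stop_("positive label '%s' not among labels", pos)
    yy <- as.integer(y == as.numeric(pos))
  } else {
    y <- factor(y)
    y <- droplevels(y)
    labels <- levels(y)
    if (length(labels) != 2) stop_("y must have exactly two labels")
    pos <- positive %||% labels[2]
    if (!pos %in% labels) stop_("positive label '%s' not among labels", pos)
    yy <- as.integer(y == pos)
  }
  if (all(yy == 1) || all(yy == 0))
    stop_("both labels must be present to fit a dichotomous model")
  list(x = x, y = yy, labels = labels, positive = pos)
}

#' Dichotomous logistic regression by Newton-Raphson maximum likelihood
#'
#' Standard unpenalized logistic regression fitted by iteratively reweighted
#' least squares. Convergence is declared when the maximum absolute score
#' (gradient of the log-likelihood) drops below \code{1e-8}; the iteration
#' cap is 100. If the cap is hit with any coefficient exceeding 15 in
#' absolute value the fit is flagged as (quasi-)separated -- with very rare
#' event classes one-versus-one problems can separate -- and the capped fit
#' remains usable for prediction.
#'
#' @param x Predictor matrix or data frame (or a \code{risk_dataset}, in
#'   which case \code{y} defaults to its outcome).
#' @param y Binary labels: 0/1 numeric or a two-level factor.
#' @param positive The label modelled as the event; default the second
#'   factor level (or 1).
#' @return Object of class \code{logit_fit} with elements
#'   \code{coefficients} (intercept first), \code{logLik}, \code{n},
#'   \code{iterations}, \code{converged}, \code{separation},
#'   \code{labels}, \code{positive}, \code{variables}.
#' @export
logit_fit <- function(x, y = NULL, positive = NULL) {
  r <- resolve_xy_binary(x, y, positive)
  X <- add_intercept(r$x)
  fit <- irls_binomial(X, r$y)
  structure(c(fit, list(labels = r$labels, positive = r$positive,
                        variables = var_names(r$x))),
            class = "logit_fit")
}

irls_binomial <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  beta <- numeric(p)
  # intercept start at empirical logit
  beta[1] <- stats::qlogis(mean(y) * 0.998 + 0.001)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(MAX_IRLS_ITER)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < SCORE_TOL) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, score), error = function(e) {
      solve(H + diag(1e-10 * (sum(diag(H)) / p + 1), p), score)
    })
    beta <- beta + step
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  # under (quasi-)separation the score still vanishes as the coefficients
  # diverge, so flag on magnitude rather than on convergence failure alone
  separation <- any(abs(beta) > SEPARATION_COEF)
  if (separation)
    warn_("possible separation: diverging coefficients; fit kept usable")
  names(beta) <- colnames(X)
  list(coefficients = beta, logLik = ll, n = n, iterations = it,
       converged = converged, separation = separation)
}

#' @export
coef.logit_fit <- function(object, ...) object$coefficients

#' @export
logLik.logit_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("logistic regression (%s vs %s; event = %s)\n",
              x$labels[1], x$labels[2], x$positive))
  print(round(x$coefficients, 4))
  cat(sprintf("logLik %.4f on %d cases; %sconverged in %d iterations%s\n",
              x$logLik, x$n, if (x$converged) "" else "NOT ",
              x$iterations,
              if (x$separation) " [separation flagged]" else ""))
  invisible(x)
}

newdata_matrix <- function(object, newdata) {
  vars <- object$variables
  if (inherits(newdata, "risk_dataset"))
    return(predictor_matrix(newdata, vars))
  nd <- as.matrix(newdata)
  if (is.null(vars)) return(nd)  # unnamed training matrix: positional
  if (length(vars) == 0)
    return(matrix(numeric(0), nrow(nd), 0))
  if (is.null(colnames(nd))) {
    if (ncol(nd) != length(vars))
      stop_("newdata has %d columns; model expects %d",
            ncol(nd), length(vars))
    colnames(nd) <- vars
  }
  missing <- setdiff(vars, colnames(nd))
  if (length(missing))
    stop_("newdata lacks predictor column(s): %s",
          paste(missing, collapse = ", "))
  nd[, vars, drop = FALSE]
}

#' Predicted event probabilities from a logistic model
#'
#' @param object A \code{logit_fit}.
#' @param newdata Predictor matrix, data frame or \code{risk_dataset}
#'   containing the model's predictor columns.
#' @param ... Unused.
#' @return Numeric vector of event probabilities in (0, 1).
#' @export
predict.logit_fit <- function(object, newdata, ...) {
  X <- add_intercept(newdata_matrix(object, newdata))
  drop(stats::plogis(X %*% object$coefficients))
}

## ---- multinomial ----

#' Multinomial logistic regression by Newton maximum likelihood
#'
#' All-at-once polytomous model with softmax link anchored at a reference
#' class (default the first outcome level, benign in the packaged four-class
#' problem). Fitted by full Newton iteration on the multinomial
#' log-likelihood; convergence and separation handling as in
#' \code{\link{logit_fit}}.
#'
#' @param x Predictor matrix/data frame or \code{risk_dataset}.
#' @param y Factor of class labels (>= 2 levels); defaults to the dataset
#'   outcome when \code{x} is a \code{risk_dataset}.
#' @param reference Reference class label; default the first level.
#' @return Object of class \code{mnlogit_fit}: \code{coefficients} is a
#'   (p+1) x (k-1) matrix (intercept row first), columns named by
#'   non-reference class.
#' @export
mnlogit_fit <- function(x, y = NULL, reference = NULL) {
  if (inherits(x, "risk_dataset")) {
    if (is.null(y)) y <- outcomes(x)
    x <- predictor_matrix(x)
  }
  y <- droplevels(factor(y))
  lev <- levels(y)
  k <- length(lev)
  if (k < 2) stop_("y must have at least two classes")
  if (any(table(y) == 0)) stop_("every class must have at least one case")
  reference <- reference %||% lev[1]
  if (!reference %in% lev) stop_("reference '%s' not among labels", reference)
  lev <- c(reference, setdiff(lev, reference))
  X <- add_intercept(as.matrix(x))
  n <- nrow(X); p <- ncol(X); m <- k - 1
  Y <- matrix(0, n, m)  # indicators of non-reference classes
  for (c in seq_len(m)) Y[, c] <- as.numeric(y == lev[c + 1])

  B <- matrix(0, p, m)
  prev <- as.numeric(table(factor(y, levels = lev))) / n
  B[1, ] <- log(pmax(prev[-1], 1e-6) / max(prev[1], 1e-6))
  converged <- FALSE
  it <- 0L
  softmax_ref <- function(Eta) {
    # anchored softmax, guarded against overflow at extreme predictors
    M <- pmax(apply(Eta, 1, max), 0)
    P <- exp(cbind(0, Eta) - M)
    P / rowSums(P)
  }
  for (it in seq_len(MAX_IRLS_ITER)) {
    P <- softmax_ref(X %*% B)     # n x k, col 1 = reference
    Pm <- P[, -1, drop = FALSE]
    G <- crossprod(X, Y - Pm)     # p x m score
    if (max(abs(G)) < SCORE_TOL) { converged <- TRUE; break }
    H <- matrix(0, p * m, p * m)
    for (c in seq_len(m)) for (d in seq_len(c)) {
      w <- if (c == d) Pm[, c] * (1 - Pm[, c]) else -Pm[, c] * Pm[, d]
      blk <- crossprod(X * w, X)
      rc <- (c - 1) * p + seq_len(p); rd <- (d - 1) * p + seq_len(p)
      H[rc, rd] <- blk
      if (c != d) H[rd, rc] <- blk
    }
    step <- tryCatch(solve(H, as.vector(G)), error = function(e) {
      solve(H + diag(1e-10 * (sum(diag(H)) / nrow(H) + 1), nrow(H)),
            as.vector(G))
    })
    B <- B + matrix(step, p, m)
  }
  P <- softmax_ref(X %*% B)
  Yfull <- cbind(1 - rowSums(Y), Y)
  ll <- sum(Yfull * log(pmax(P, 1e-300)))
  separation <- any(abs(B) > SEPARATION_COEF)
  if (separation)
    warn_("possible separation: diverging coefficients; fit kept usable")
  rownames(B) <- colnames(X)
  colnames(B) <- lev[-1]
  structure(list(coefficients = B, logLik = ll, n = n, iterations = it,
                 converged = converged, separation = separation,
                 levels = lev, reference = reference,
                 variables = var_names(x)),
            class = "mnlogit_fit")
}

#' @export
coef.mnlogit_fit <- function(object, ...) object$coefficients

#' @export
logLik.mnlogit_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
print.mnlogit_fit <- function(x, ...) {
  cat(sprintf("multinomial logistic regression (reference = %s)\n",
              x$reference))
  print(round(x$coefficients, 4))
  cat(sprintf("logLik %.4f on %d cases; %sconverged in %d iterations%s\n",
              x$logLik, x$n, if (x$converged) "" else "NOT ",
              x$iterations,
              if (x$separation) " [separation flagged]" else ""))
  invisible(x)
}

#' Predicted class probabilities from a multinomial model
#'
#' @param object A \code{mnlogit_fit}.
#' @param newdata Predictor matrix, data frame or \code{risk_dataset}.
#' @param ... Unused.
#' @return Matrix of per-case class probabilities, one column per class in
#'   the order reference-first used at fit time, rows summing to 1.
#' @export
predict.mnlogit_fit <- function(object, newdata, ...) {
  X <- add_intercept(newdata_matrix(object, newdata))
  Eta <- X %*% object$coefficients
  # guard against overflow at extreme linear predictors
  M <- pmax(apply(Eta, 1, max), 0)
  P <- exp(cbind(0, Eta) - M)
  P <- P / rowSums(P)
  colnames(P) <- object$levels
  P
}

#' Information criteria for fitted models
#'
#' \code{aic(m)} returns \eqn{-2\hat L + 2p} and \code{bic(m)} returns
#' \eqn{-2\hat L + p\,\log n}, with \eqn{\hat L} the maximized
#' log-likelihood and \eqn{p} the number of free parameters. Thin wrappers
#' over \code{stats::AIC}/\code{BIC} via the models' \code{logLik} methods.
#'
#' @param m A fitted model with a \code{logLik} method.
#' @return Numeric scalar.
#' @export
aic <- function(m) stats::AIC(m)

#' @rdname aic
#' @export
bic <- function(m) stats::BIC(m)
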