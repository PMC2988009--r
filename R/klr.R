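# Kernel logistic regression (dichotomous) and its multinomial extension.
# Both minimize a penalized negative log-likelihood over a kernel expansion
#   f(x) = sum_j beta_j K(x_j, x) + b,   penalty (lambda/2) beta' K beta,
# by iteratively re-weighted least squares in which every iteration solves a
# linear system with the structure of an LS-SVM:
#   [ K + lambda W^-1   1 ] [beta]   [z]
#   [ 1'                0 ] [b   ] = [0],   z = f + W^-1 (y - p).
# Step-halving on the true penalized objective guarantees monotone descent.

KLR_MAX_ITER <- 100L
KLR_OBJ_TOL <- 1e-8

# solve [[A, 1], [1', 0]] [beta; b] = [z; 0] by block elimination:
# b = (1' A^-1 z) / (1' A^-1 1), beta = A^-1 (z - b 1). Much better scaled
# than the bordered matrix when the working weights are extreme.
solve_lssvm_structured <- function(A, z) {
  S <- tryCatch(solve(A, cbind(z, 1)), error = function(e) {
    solve(A + diag(1e-10 * max(abs(diag(A))), nrow(A)), cbind(z, 1))
  })
  b <- sum(S[, 1]) / sum(S[, 2])
  list(beta = S[, 1] - b * S[, 2], b = b)
}

klr_objective <- function(K, beta, b, y) {
  f <- drop(K %*% beta) + b
  p <- stats::plogis(f)
  nll <- -sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  list(f = f, p = p, nll = nll)
}

#' Kernel logistic regression by penalized IRLS
#'
#' Dichotomous regularized logistic regression in a kernel-induced feature
#' space. Unlike the LS-SVM it directly outputs probabilities. The penalty
#' weight \code{lambda} plays the role of the inverse of the LS-SVM's
#' \code{gamma}: large \code{lambda} shrinks towards the intercept-only
#' model, whose probabilities are the class prevalence.
#'
#' @inheritParams lssvm_fit
#' @param lambda Penalty parameter, > 0.
#' @return Object of class \code{klr_fit} with dual coefficients
#'   \code{beta}, bias \code{b}, the stored (standardized) training matrix,
#'   convergence metadata, and the penalized objective trace.
#' @export
klr_fit <- function(x, y = NULL, lambda, kernel = kernel_spec("linear"),
                    positive = NULL, standardize = TRUE) {
  if (!is.numeric(lambda) || lambda <= 0) stop_("lambda must be > 0")
  r <- resolve_xy_binary(x, y, positive)
  std <- if (standardize) standardizer(r$x) else NULL
  Xs <- if (standardize) apply_standardizer(std, r$x) else as.matrix(r$x)
  n <- nrow(Xs)
  K <- kernel_matrix(Xs, Xs, kernel)
  diag(K) <- diag(K) + kernel_jitter(K)
  yy <- r$y

  beta <- numeric(n)
  b <- stats::qlogis(mean(yy) * 0.998 + 0.001)
  st <- klr_objective(K, beta, b, yy)
  obj <- st$nll + lambda / 2 * drop(crossprod(beta, K %*% beta))
  trace <- obj
  converged <- FALSE
  it <- 0L
  for (it in seq_len(KLR_MAX_ITER)) {
    w <- pmax(st$p * (1 - st$p), 1e-10)
    z <- st$f + (yy - st$p) / w
    sol <- solve_lssvm_structured(K + diag(lambda / w, n), z)
    beta_new <- sol$beta; b_new <- sol$b
    # step-halving against the true penalized objective
    t_step <- 1
    repeat {
      bt <- beta + t_step * (beta_new - beta)
      bbt <- b + t_step * (b_new - b)
      st_new <- klr_objective(K, bt, bbt, yy)
      obj_new <- st_new$nll + lambda / 2 * drop(crossprod(bt, K %*% bt))
      if (obj_new <= obj + 1e-12 || t_step < 1e-4) break
      t_step <- t_step / 2
    }
    beta <- bt; b <- bbt; st <- st_new
    delta <- obj - obj_new
    obj <- obj_new
    trace <- c(trace, obj)
    if (abs(delta) < KLR_OBJ_TOL) { converged <- TRUE; break }
  }
  if (!converged) warn_("kernel logistic regression hit the iteration cap")
  structure(list(beta = beta, b = b, lambda = lambda, kernel = kernel,
                 X = Xs, std = std, p_train = st$p, objective = obj,
                 trace = trace, iterations = it, converged = converged,
                 labels = r$labels, positive = r$positive,
                 variables = var_names(r$x)),
            class = "klr_fit")
}

#' @export
print.klr_fit <- function(x, ...) {
  cat(sprintf("kernel logistic regression (%s vs %s; event = %s), lambda = %g, ",
              x$labels[1], x$labels[2], x$positive, x$lambda))
  print(x$kernel)
  cat(sprintf("%d training cases; %sconverged in %d iterations\n",
              nrow(x$X), if (x$converged) "" else "NOT ", x$iterations))
  invisible(x)
}

#' Predicted event probabilities from kernel logistic regression
#'
#' @param object A \code{klr_fit}.
#' @param newdata Predictor matrix, data frame or \code{risk_dataset}.
#' @param ... Unused.
#' @return Vector of event probabilities.
#' @export
predict.klr_fit <- function(object, newdata, ...) {
  nd <- newdata_matrix(object, newdata)
  if (!is.null(object$std)) nd <- apply_standardizer(object$std, nd)
  Kstar <- kernel_matrix(nd, object$X, object$kernel)
  drop(stats::plogis(Kstar %*% object$beta + object$b))
}

## ---- multinomial kernel logistic regression ----

mklr_objective <- function(K, B, b, Yind, lambda) {
  Eta <- K %*% B
  Eta <- sweep(Eta, 2, b, "+")
  M <- pmax(apply(Eta, 1, max), 0)
  P <- exp(cbind(0, Eta) - M)
  P <- P / rowSums(P)
  nll <- -sum(Yind * log(pmax(P, 1e-300)))
  pen <- lambda / 2 * sum(vapply(seq_len(ncol(B)), function(c)
    drop(crossprod(B[, c], K %*% B[, c])), numeric(1)))
  list(P = P, obj = nll + pen)
}

#' Multinomial kernel logistic regression by penalized IRLS
#'
#' Polytomous extension of \code{\link{klr_fit}}: a regularized multinomial
#' logistic model in a kernel feature space, anchored at a reference class.
#' The penalized multinomial negative log-likelihood is minimized by cycling
#' blockwise Newton updates over the non-reference classes, each update
#' solving an LS-SVM-structured linear system, with step-halving on the true
#' objective. With two classes it coincides with \code{klr_fit}.
#'
#' @inheritParams klr_fit
#' @param y Factor of class labels (2 or more levels).
#' @param reference Reference class; default the first level.
#' @return Object of class \code{mklr_fit}; \code{beta} is an n x (k-1)
#'   matrix of dual coefficients, \code{b} the non-reference biases.
#' @export
mklr_fit <- function(x, y = NULL, lambda, kernel = kernel_spec("linear"),
                     reference = NULL, standardize = TRUE) {
  if (!is.numeric(lambda) || lambda <= 0) stop_("lambda must be > 0")
  if (inherits(x, "risk_dataset")) {
    if (is.null(y)) y <- outcomes(x)
    x <- predictor_matrix(x)
  }
  y <- droplevels(factor(y))
  lev <- levels(y)
  if (length(lev) < 2) stop_("y must have at least two classes")
  reference <- reference %||% lev[1]
  if (!reference %in% lev) stop_("reference '%s' not among labels", reference)
  lev <- c(reference, setdiff(lev, reference))
  k <- length(lev); m <- k - 1
  std <- if (standardize) standardizer(x) else NULL
  Xs <- if (standardize) apply_standardizer(std, x) else as.matrix(x)
  n <- nrow(Xs)
  K <- kernel_matrix(Xs, Xs, kernel)
  diag(K) <- diag(K) + kernel_jitter(K)
  Yind <- matrix(0, n, k)
  for (c in seq_len(k)) Yind[, c] <- as.numeric(y == lev[c])

  B <- matrix(0, n, m)
  prev <- colMeans(Yind)
  b <- log(pmax(prev[-1], 1e-6) / max(prev[1], 1e-6))
  st <- mklr_objective(K, B, b, Yind, lambda)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(KLR_MAX_ITER)) {
    obj_start <- st$obj
    for (c in seq_len(m)) {
      pc <- st$P[, c + 1]
      yc <- Yind[, c + 1]
      w <- pmax(pc * (1 - pc), 1e-10)
      fc <- drop(K %*% B[, c]) + b[c]
      z <- fc + (yc - pc) / w
      sol <- solve_lssvm_structured(K + diag(lambda / w, n), z)
      bn <- sol$beta; bb <- sol$b
      t_step <- 1
      repeat {
        Bt <- B; Bt[, c] <- B[, c] + t_step * (bn - B[, c])
        bt <- b; bt[c] <- b[c] + t_step * (bb - b[c])
        st_new <- mklr_objective(K, Bt, bt, Yind, lambda)
        if (st_new$obj <= st$obj + 1e-12 || t_step < 1e-4) break
        t_step <- t_step / 2
      }
      B <- Bt; b <- bt; st <- st_new
    }
    if (abs(obj_start - st$obj) < KLR_OBJ_TOL) { converged <- TRUE; break }
  }
  if (!converged)
    warn_("multinomial kernel logistic regression hit the iteration cap")
  structure(list(beta = B, b = b, lambda = lambda, kernel = kernel,
                 X = Xs, std = std, objective = st$obj, iterations = it,
                 converged = converged, levels = lev, reference = reference,
                 variables = var_names(x)),
            class = "mklr_fit")
}

#' @export
print.mklr_fit <- function(x, ...) {
  cat(sprintf("multinomial kernel logistic regression (reference = %s), lambda = %g, ",
              x$reference, x$lambda))
  print(x$kernel)
  cat(sprintf("%d training cases; %sconverged in %d sweeps\n",
              nrow(x$X), if (x$converged) "" else "NOT ", x$iterations))
  invisible(x)
}

#' Predicted class probabilities from multinomial kernel logistic regression
#'
#' @param object A \code{mklr_fit}.
#' @param newdata Predictor matrix, data frame or \code{risk_dataset}.
#' @param ... Unused.
#' @return Matrix of class probabilities (columns in reference-first level
#'   order), rows summing to 1.
#' @export
predict.mklr_fit <- function(object, newdata, ...) {
  nd <- newdata_matrix(object, newdata)
  if (!is.null(object$std)) nd <- apply_standardizer(object$std, nd)
  Kstar <- kernel_matrix(nd, object$X, object$kernel)
  Eta <- Kstar %*% object$beta
  Eta <- sweep(Eta, 2, object$b, "+")
  M <- pmax(apply(Eta, 1, max), 0)
  P <- exp(cbind(0, Eta) - M)
  P <- P / rowSums(P)
  colnames(P) <- object$levels
  P
}
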