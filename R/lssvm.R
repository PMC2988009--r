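# Least squares support vector machine classifier. The fit solves one
# linear system (the KKT conditions of the squared-slack margin problem):
#   [ 0   y^T          ] [b]   [0]
#   [ y   Omega + I/g  ] [a] = [1],   Omega_ij = y_i y_j K(x_i, x_j).
# Internally the equivalent "beta form" is used (beta_i = a_i y_i):
#   [ K + I/g   1 ] [beta]   [y]
#   [ 1^T       0 ] [b   ] = [0],
# whose bordered inverse also yields exact leave-one-out outputs without
# refitting. Probabilistic output is obtained by modelling the latent value
# with class-conditional Gaussians combined with prior event probabilities.

#' Fit a least squares support vector machine
#'
#' @param x Predictor matrix/data frame or \code{risk_dataset}.
#' @param y Binary labels (two-level factor or 0/1); mapped internally to
#'   -1/+1 with \code{positive} mapped to +1.
#' @param gamma Regularization parameter, > 0 (larger = less regularized).
#' @param kernel A \code{\link{kernel_spec}}; default linear.
#' @param positive Label treated as the positive event.
#' @param standardize Standardize predictors to zero mean / unit variance
#'   (computed on the training data and stored); default \code{TRUE}.
#' @return Object of class \code{lssvm_fit} holding the dual coefficients
#'   \code{alpha} (and \code{beta = alpha * y}), bias \code{b}, the stored
#'   (standardized) training matrix, latent training outputs and their
#'   class-conditional summaries, prior event probabilities, and the
#'   bordered system inverse used for fast leave-one-out.
#' @export
lssvm_fit <- function(x, y = NULL, gamma, kernel = kernel_spec("linear"),
                      positive = NULL, standardize = TRUE) {
  if (!is.numeric(gamma) || gamma <= 0) stop_("gamma must be > 0")
  r <- resolve_xy_binary(x, y, positive)
  ys <- ifelse(r$y == 1, 1, -1)
  std <- if (standardize) standardizer(r$x) else NULL
  Xs <- if (standardize) apply_standardizer(std, r$x) else as.matrix(r$x)
  K <- kernel_matrix(Xs, Xs, kernel)
  sol <- lssvm_solve(K, ys, gamma)
  f <- drop(K %*% sol$beta) + sol$b
  pos <- ys == 1
  latent <- list(
    mean = c(neg = mean(f[!pos]), pos = mean(f[pos])),
    sd = c(neg = stats::sd(f[!pos]), pos = stats::sd(f[pos])))
  priors <- c(neg = mean(!pos), pos = mean(pos))
  structure(list(beta = sol$beta, alpha = sol$beta * ys, b = sol$b,
                 gamma = gamma, kernel = kernel, y = ys,
                 X = Xs, std = std, latent = latent, priors = priors,
                 f_train = f, Minv = sol$Minv,
                 labels = r$labels, positive = r$positive,
                 variables = var_names(r$x)),
            class = "lssvm_fit")
}

# solve the bordered system; returns beta, b and the full inverse
lssvm_solve <- function(K, y, gamma) {
  n <- length(y)
  Q <- K + diag(1 / gamma + kernel_jitter(K), n)
  M <- rbind(cbind(Q, 1), c(rep(1, n), 0))
  Minv <- tryCatch(solve(M), error = function(e) {
    solve(M + diag(1e-8 * (sum(abs(diag(M))) / (n + 1)), n + 1))
  })
  z <- drop(Minv %*% c(y, 0))
  list(beta = z[seq_len(n)], b = z[n + 1], Minv = Minv)
}

#' @export
print.lssvm_fit <- function(x, ...) {
  cat(sprintf("LS-SVM (%s vs %s; event = %s), gamma = %g, ",
              x$labels[1], x$labels[2], x$positive, x$gamma))
  print(x$kernel)
  cat(sprintf("%d training cases, %d predictors\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

lssvm_latent <- function(object, newdata) {
  nd <- newdata_matrix(object, newdata)
  if (!is.null(object$std)) nd <- apply_standardizer(object$std, nd)
  Kstar <- kernel_matrix(nd, object$X, object$kernel)
  drop(Kstar %*% object$beta) + object$b
}

#' Predictions from an LS-SVM
#'
#' @param object An \code{lssvm_fit}.
#' @param newdata Predictor matrix, data frame or \code{risk_dataset}.
#' @param type \code{"probability"} (Bayesian posterior for the positive
#'   event, see \code{\link{lssvm_posterior}}) or \code{"latent"} (raw
#'   latent output \eqn{f(x)}).
#' @param priors Optional prior event probabilities
#'   \code{c(neg = ..., pos = ...)}; default the training prevalences.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.lssvm_fit <- function(object, newdata,
                              type = c("probability", "latent"),
                              priors = NULL, ...) {
  type <- match.arg(type)
  f <- lssvm_latent(object, newdata)
  if (type == "latent") return(f)
  lssvm_posterior(object, newdata, priors = priors, latent = f)
}

#' Bayesian probabilistic output of an LS-SVM
#'
#' Converts the non-probabilistic LS-SVM latent output into a posterior
#' event probability by Bayes' rule: the latent value is modelled with
#' class-conditional Gaussian densities (means/SDs of the training latent
#' outputs per class), combined with prior event probabilities -- by default
#' the outcome distribution of the development data.
#'
#' @param m A fitted \code{lssvm_fit}.
#' @param newdata Cases to score.
#' @param priors Named numeric \code{c(neg, pos)} in (0,1), summing to 1;
#'   default the training prevalences stored in the model.
#' @param latent Optional precomputed latent outputs for \code{newdata}.
#' @return Vector of posterior probabilities of the positive event.
#' @export
lssvm_posterior <- function(m, newdata, priors = NULL, latent = NULL) {
  stopifnot(inherits(m, "lssvm_fit"))
  priors <- priors %||% m$priors
  if (is.null(names(priors))) names(priors) <- c("neg", "pos")
  if (any(priors <= 0) || any(priors >= 1) || abs(sum(priors) - 1) > 1e-8)
    stop_("priors must lie in (0,1) and sum to 1")
  f <- latent %||% lssvm_latent(m, newdata)
  sds <- m$latent$sd
  if (any(!is.finite(sds)) || any(sds <= 1e-12)) {
    warn_("degenerate latent spread; falling back to hard assignment")
    return(as.numeric(f > mean(m$latent$mean)))
  }
  d_pos <- stats::dnorm(f, m$latent$mean["pos"], sds["pos"])
  d_neg <- stats::dnorm(f, m$latent$mean["neg"], sds["neg"])
  num <- priors["pos"] * d_pos
  den <- num + priors["neg"] * d_neg
  p <- ifelse(den > 0, num / den,
              # both densities underflow far in a tail: assign by nearer
              # class mean in SD units
              as.numeric(abs(f - m$latent$mean["pos"]) / sds["pos"] <
                         abs(f - m$latent$mean["neg"]) / sds["neg"]))
  pmin(pmax(unname(p), 1e-12), 1 - 1e-12)
}

#' Exact leave-one-out latent outputs of an LS-SVM
#'
#' Computes the leave-one-out latent output for every training case from the
#' inverse of the full bordered KKT system, without refitting: the
#' leave-one-out residual is \code{y_i - f_loo_i = beta_i / Minv_ii}, the
#' bordered analogue of the hat-matrix identity
#' \eqn{e_{i,-i} = e_i/(1-h_{ii})}. Exact (to solver precision) relative to
#' n separate refits.
#'
#' @param m A fitted \code{lssvm_fit}.
#' @return Numeric vector of leave-one-out latent outputs, one per training
#'   case.
#' @export
loo_lssvm <- function(m) {
  stopifnot(inherits(m, "lssvm_fit"))
  n <- length(m$y)
  if (n < 3) stop_("leave-one-out undefined below 3 cases")
  if (is.null(m$Minv)) {
    # deserialized model: rebuild the bordered inverse
    K <- kernel_matrix(m$X, m$X, m$kernel)
    m$Minv <- lssvm_solve(K, m$y, m$gamma)$Minv
  }
  d <- diag(m$Minv)[seq_len(n)]
  if (any(abs(d) < 1e-12))
    stop_("leave-one-out breakdown: effective leverage of a case is 1")
  m$y - m$beta / d
}
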