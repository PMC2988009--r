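#' Kernel specification
#'
#' @param kind \code{"linear"} (inner product \eqn{x^T z}) or
#'   \code{"gaussian"} (\eqn{\exp(-\|x-z\|^2/\sigma^2)}).
#' @param sigma Gaussian bandwidth, finite and positive; ignored for the
#'   linear kernel.
#' @return Object of class \code{kernel_spec}.
#' @export
kernel_spec <- function(kind = c("linear", "gaussian"), sigma = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    if (is.null(sigma) || !is.finite(sigma) || sigma <= 0)
      stop_("gaussian kernel requires finite sigma > 0")
  }
  structure(list(kind = kind, sigma = sigma), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  if (x$kind == "linear") cat("linear kernel\n")
  else cat(sprintf("gaussian kernel, sigma = %g\n", x$sigma))
  invisible(x)
}

#' Kernel (Gram) matrix between two case matrices
#'
#' @param X,Z Numeric matrices with equal column counts; rows are cases.
#' @param spec A \code{\link{kernel_spec}}.
#' @return \code{nrow(X)} by \code{nrow(Z)} matrix with
#'   \code{K[i,j] = k(X[i,], Z[j,])}.
#' @export
kernel_matrix <- function(X, Z = X, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (ncol(X) != ncol(Z))
    stop_("dimension mismatch: %d vs %d columns", ncol(X), ncol(Z))
  if (spec$kind == "linear") return(tcrossprod(X, Z))
  d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * tcrossprod(X, Z)
  d2[d2 < 0] <- 0
  exp(-d2 / spec$sigma^2)
}

#' Median-distance bandwidth heuristic
#'
#' Median Euclidean distance between distinct case pairs, the conventional
#' center for a Gaussian bandwidth grid.
#'
#' @param X Case matrix (rows = cases).
#' @param max_cases Subsample cap for the pairwise distance computation.
#' @param seed Seed for the subsample.
#' @return Positive scalar.
#' @export
median_pairwise_distance <- function(X, max_cases = 500, seed = 1) {
  X <- as.matrix(X)
  if (nrow(X) > max_cases)
    X <- with_seed(seed, X[sample.int(nrow(X), max_cases), , drop = FALSE])
  d <- stats::dist(X)
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

# column standardization stored with kernel models (Gaussian kernels are
# scale-sensitive); zero-variance columns are centered only
standardizer <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(std, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

kernel_jitter <- function(K) {
  n <- nrow(K)
  1e-10 * (sum(diag(K)) / n + 1)
}
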