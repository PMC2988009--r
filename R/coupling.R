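# One-versus-one decomposition of the four-class problem and pairwise
# coupling. Each unordered pair of events gets its own dichotomous model,
# trained only on the cases of those two events but applied to every case.
# The six pairwise conditional probability estimates
#   phat_ij = P(event i | case, event in {i, j})
# are recombined into a full probability vector pi by solving the linear
# system
#   pi_i = sum_{j != i} phat_ij (pi_i + pi_j) / (k - 1),  for all i,
# subject to sum(pi) = 1 and pi >= 0. The unconstrained least-squares
# solution is exact whenever the phat are consistent (phat_ij =
# pi_i/(pi_i+pi_j)); if it leaves the simplex, the nonnegativity-constrained
# least-squares solution is returned (exact active-set enumeration, cheap
# for k = 4).

#' Validate a pairwise probability matrix
#'
#' @param pp k x k numeric matrix with \code{pp[i,j]} the estimated
#'   probability of event i given the case belongs to events \{i, j\};
#'   diagonal ignored. Must satisfy \code{pp[i,j] + pp[j,i] = 1} within
#'   1e-8 and entries in [0, 1].
#' @return The matrix, with the complement filled in where only one
#'   triangle was given (NA entries).
#' @export
pairwise_prob_matrix <- function(pp) {
  pp <- as.matrix(pp)
  k <- nrow(pp)
  if (ncol(pp) != k || k < 2) stop_("pp must be a square matrix, k >= 2")
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- pp[i, j]; b <- pp[j, i]
    if (is.na(a) && is.na(b)) stop_("pair (%d,%d) missing", i, j)
    if (is.na(b)) pp[j, i] <- b <- 1 - a
    if (is.na(a)) pp[i, j] <- a <- 1 - b
    if (a < -1e-12 || a > 1 + 1e-12)
      stop_("pp[%d,%d] outside [0,1]", i, j)
    if (abs(a + b - 1) > 1e-8)
      stop_("pp[%d,%d] + pp[%d,%d] = %g differs from 1", i, j, j, i, a + b)
  }
  diag(pp) <- NA_real_
  pp
}

# least squares for the coupling system restricted to free set S
couple_ls <- function(A, b, free) {
  kf <- length(free)
  Af <- A[, free, drop = FALSE]
  G <- rbind(cbind(2 * crossprod(Af), 1), c(rep(1, kf), 0))
  rhs <- c(2 * drop(crossprod(Af, b)), 1)
  sol <- tryCatch(solve(G, rhs), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  pi_f <- sol[seq_len(kf)]
  list(pi_f = pi_f, obj = sum((Af %*% pi_f - b)^2))
}

#' Combine pairwise probabilities into polytomous probabilities
#'
#' @param pp A pairwise probability matrix (see
#'   \code{\link{pairwise_prob_matrix}}).
#' @return Numeric probability vector of length k: nonnegative, summing
#'   to 1. When the pairwise estimates are consistent with some positive
#'   simplex vector, that vector is recovered exactly.
#' @export
couple <- function(pp) {
  pp <- pairwise_prob_matrix(pp)
  k <- nrow(pp)
  # rows: (k-1) pi_i - sum_j phat_ij (pi_i + pi_j) = 0
  A <- matrix(0, k, k)
  for (i in seq_len(k)) {
    off <- setdiff(seq_len(k), i)
    A[i, i] <- (k - 1) - sum(pp[i, off])
    A[i, off] <- -pp[i, off]
  }
  b <- rep(0, k)
  # stack the normalization row and solve by least squares
  pi_ls <- tryCatch(qr.solve(rbind(A, rep(1, k)), c(b, 1)),
                    error = function(e) NULL)
  if (!is.null(pi_ls) && all(pi_ls >= -1e-10)) {
    pi_ <- pmax(pi_ls, 0)
    return(pi_ / sum(pi_))
  }
  # constrained: enumerate active sets (zeroed coordinates)
  best <- NULL
  for (mask in seq_len(2^k - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    sol <- couple_ls(A, b, free)
    if (is.null(sol) || any(sol$pi_f < -1e-10)) next
    if (is.null(best) || sol$obj < best$obj - 1e-14) {
      best <- sol; best$free <- free
    }
  }
  if (is.null(best)) stop_("coupling system has no feasible solution")
  pi_ <- numeric(k)
  pi_[best$free] <- pmax(best$pi_f, 0)
  pi_ / sum(pi_)
}

#' Decompose a dataset into the six one-versus-one training subsets
#'
#' @param ds A \code{risk_dataset} with all classes present.
#' @return Named list over unordered class pairs; each element has
#'   \code{pair} (the two class labels, first = positive event) and
#'   \code{data} (the \code{risk_dataset} restricted to those classes).
#' @export
decompose_1v1 <- function(ds) {
  stopifnot(inherits(ds, "risk_dataset"))
  cc <- class_counts(ds)
  if (any(cc == 0))
    stop_("class '%s' has no cases", names(cc)[which(cc == 0)[1]])
  lev <- ds$classes
  pairs <- utils::combn(length(lev), 2)
  out <- vector("list", ncol(pairs))
  nm <- character(ncol(pairs))
  y <- outcomes(ds)
  for (q in seq_len(ncol(pairs))) {
    li <- lev[pairs[1, q]]; lj <- lev[pairs[2, q]]
    sub <- ds
    sub$data <- ds$data[y %in% c(li, lj), , drop = FALSE]
    rownames(sub$data) <- NULL
    out[[q]] <- list(pair = c(li, lj), data = sub)
    nm[q] <- paste0(li, "_vs_", lj)
  }
  names(out) <- nm
  out
}

#' One-versus-one ensemble of dichotomous models
#'
#' @param models List of six fitted dichotomous models (any family with a
#'   \code{predict} method returning the probability of the pair's first
#'   event), in the pair order of \code{\link{decompose_1v1}}.
#' @param pairs List of length-2 character vectors naming each model's
#'   event pair (first = the event whose probability the model returns).
#' @param classes The k class labels.
#' @return Object of class \code{ovo_ensemble}.
#' @export
ovo_ensemble <- function(models, pairs, classes = tumor_classes()) {
  k <- length(classes)
  expected <- utils::combn(k, 2)
  if (length(models) != ncol(expected) || length(pairs) != ncol(expected))
    stop_("need exactly %d pair models", ncol(expected))
  seen <- vapply(pairs, function(p) paste(sort(match(p, classes)),
                                          collapse = "-"), character(1))
  want <- apply(expected, 2, paste, collapse = "-")
  if (!setequal(seen, want) || anyDuplicated(seen))
    stop_("pair tags must cover every unordered class pair exactly once")
  structure(list(models = models, pairs = pairs, classes = classes),
            class = "ovo_ensemble")
}

#' @export
print.ovo_ensemble <- function(x, ...) {
  cat(sprintf("one-versus-one ensemble over %d classes (%d pair models)\n",
              length(x$classes), length(x$models)))
  for (q in seq_along(x$models))
    cat(sprintf("  %s vs %s: %s\n", x$pairs[[q]][1], x$pairs[[q]][2],
                class(x$models[[q]])[1]))
  invisible(x)
}

# n x 6 matrix of pair-model outputs phat_ij (probability of pair's first
# event), applied to every case
predict_pairwise_raw <- function(ens, newdata) {
  cols <- lapply(ens$models, function(m) {
    p <- stats::predict(m, newdata)
    if (is.matrix(p)) stop_("pair model must return a probability vector")
    p
  })
  out <- do.call(cbind, cols)
  colnames(out) <- vapply(ens$pairs, function(p) paste0(p[1], "_vs_", p[2]),
                          character(1))
  out
}

#' Polytomous probabilities from a one-versus-one ensemble
#'
#' Every pair model is applied to every case (including cases of events
#' outside its pair, taken at face value) and the six outputs are combined
#' per case by \code{\link{couple}}.
#'
#' @param ens An \code{ovo_ensemble}.
#' @param newdata Cases to score.
#' @return Matrix of per-case event probabilities (columns = classes),
#'   rows on the simplex.
#' @export
predict_coupled <- function(ens, newdata) {
  stopifnot(inherits(ens, "ovo_ensemble"))
  raw <- predict_pairwise_raw(ens, newdata)
  k <- length(ens$classes)
  pair_idx <- lapply(ens$pairs, function(p) match(p, ens$classes))
  out <- matrix(NA_real_, nrow(raw), k, dimnames = list(NULL, ens$classes))
  pp <- matrix(NA_real_, k, k)
  for (r in seq_len(nrow(raw))) {
    pp[] <- NA_real_
    for (q in seq_along(pair_idx)) {
      ij <- pair_idx[[q]]
      pp[ij[1], ij[2]] <- min(max(raw[r, q], 0), 1)
    }
    out[r, ] <- couple(pp)
  }
  out
}

#' @export
predict.ovo_ensemble <- function(object, newdata, ...) {
  predict_coupled(object, newdata)
}

#' Pairwise c-indexes of a one-versus-one ensemble
#'
#' Scores each event pair with the pair's own model output (rather than the
#' coupled probabilities), restricted to the cases of the two events.
#'
#' @param ens An \code{ovo_ensemble}.
#' @param ds A \code{risk_dataset} containing the evaluation cases.
#' @return Named list of \code{c_index_result} in pair order.
#' @export
pairwise_c_indexes_ovo <- function(ens, ds) {
  stopifnot(inherits(ens, "ovo_ensemble"), inherits(ds, "risk_dataset"))
  y <- outcomes(ds)
  raw <- predict_pairwise_raw(ens, ds)
  out <- vector("list", length(ens$models))
  nm <- character(length(ens$models))
  for (q in seq_along(ens$models)) {
    pr <- ens$pairs[[q]]
    sel <- y %in% pr
    out[[q]] <- c_index(raw[sel, q], factor(as.character(y[sel]),
                                            levels = pr),
                        positive = pr[1])
    nm[q] <- paste0(pr[1], "_vs_", pr[2])
  }
  names(out) <- nm
  out
}

#' Polytomous probabilities from a nested tree of dichotomies
#'
#' Sequential decomposition: first benign versus malignant, then borderline
#' versus invasive among malignant, finally primary versus metastatic among
#' invasive. With stage probabilities p1, p2, p3 the event probabilities are
#' \code{(p1, (1-p1) p2, (1-p1)(1-p2) p3, (1-p1)(1-p2)(1-p3))}, which sum
#' to 1 identically.
#'
#' @param models List of three fitted dichotomous models in tree order; each
#'   \code{predict} must return the probability of the stage's first branch
#'   (benign; borderline; primary invasive).
#' @param newdata Cases to score.
#' @param classes Class labels in canonical order.
#' @return Matrix of per-case event probabilities.
#' @export
predict_nested_tree <- function(models, newdata,
                                classes = tumor_classes()) {
  if (length(models) != 3 || any(vapply(models, is.null, logical(1))))
    stop_("the nested tree needs its three stage models")
  p1 <- stats::predict(models[[1]], newdata)
  p2 <- stats::predict(models[[2]], newdata)
  p3 <- stats::predict(models[[3]], newdata)
  out <- cbind(p1,
               (1 - p1) * p2,
               (1 - p1) * (1 - p2) * p3,
               (1 - p1) * (1 - p2) * (1 - p3))
  colnames(out) <- classes
  out
}
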