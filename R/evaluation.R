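# Discrimination and calibration metrics. The polytomous c-index extends
# the ROC area to four events: over sets of four cases, one per event, it
# averages the number of events whose own-event predicted probability is
# strictly largest for the case of that event, divided by 4. 0.25 is chance,
# 1 is perfect. It is computed by a factorization over events (each event's
# strict-exceedance counts against every other event's cases), identical to
# brute-force enumeration of all quadruples.

#' Dichotomous c-index (area under the ROC curve)
#'
#' Mann-Whitney estimate: over all positive/negative case pairs, credit 1
#' when the positive case scores strictly higher and 0.5 on ties.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels: logical, 0/1, or a two-level factor (second
#'   level positive unless \code{positive} is given).
#' @param positive Label counted as positive.
#' @return Object of class \code{c_index_result}: list with
#'   \code{estimate}, \code{n_positive}, \code{n_negative},
#'   \code{tied_pairs}.
#' @export
c_index <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores) || anyNA(labels)) stop_("missing values in input")
  if (is.logical(labels)) pos <- labels
  else if (is.numeric(labels) && is_binary01(labels)) {
    pos <- labels == (as.numeric(positive %||% 1))
  } else {
    labels <- droplevels(factor(labels))
    if (nlevels(labels) != 2) stop_("labels must have exactly two levels")
    pos <- labels == (positive %||% levels(labels)[2])
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop_("both labels must be present")
  r <- rank(scores)            # midranks handle ties as 0.5 credit
  est <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  tab <- table(scores)
  tied <- sum(vapply(names(tab)[tab > 1], function(v) {
    eq <- scores == as.numeric(v)
    sum(eq & pos) * sum(eq & !pos)
  }, numeric(1)))
  structure(list(estimate = est, n_positive = n1, n_negative = n0,
                 tied_pairs = tied),
            class = "c_index_result")
}

#' @export
print.c_index_result <- function(x, ...) {
  cat(sprintf("c-index %.4f (%d positive / %d negative cases",
              x$estimate, x$n_positive, x$n_negative))
  if (!is.null(x$ci))
    cat(sprintf("; %d%% CI %.3f-%.3f", round(100 * x$ci$level),
                x$ci$lower, x$ci$upper))
  cat(")\n")
  invisible(x)
}

check_prob_matrix <- function(probs, labels) {
  probs <- as.matrix(probs)
  if (!is.factor(labels)) labels <- factor(labels)
  # declared levels are kept: an empty event is an error, not dropped
  k <- nlevels(labels)
  if (ncol(probs) != k)
    stop_("probability matrix has %d columns but %d classes", ncol(probs), k)
  if (nrow(probs) != length(labels))
    stop_("probability rows (%d) must match labels (%d)",
          nrow(probs), length(labels))
  if (!is.null(colnames(probs))) {
    if (!setequal(colnames(probs), levels(labels)))
      stop_("probability columns do not match class labels")
    probs <- probs[, levels(labels), drop = FALSE]
  } else colnames(probs) <- levels(labels)
  list(probs = probs, labels = labels)
}

#' Polytomous c-index
#'
#' The four-event extension of the ROC area: the probability of correctly
#' identifying the case from a randomly chosen event within a set of four
#' cases, one per event. Equal to the average over all quadruples of
#' \eqn{C(n_1,n_2,n_3,n_4)/4}, where C counts the events whose own
#' predicted probability is strictly largest for the case with that event.
#' Ties earn no credit (with continuous model outputs ties have measure
#' zero). Chance level is 0.25.
#'
#' @param probs Matrix of per-case event probabilities (one column per
#'   event; column names, if present, must match the class labels).
#' @param labels Factor of true events; every event must be present.
#' @param mode \code{"factorized"} (default; exact, fast),
#'   \code{"brute"} (explicit enumeration of all case quadruples -- the
#'   reference implementation, only feasible for small counts).
#' @return Object of class \code{poly_c_index_result}: \code{estimate},
#'   \code{counts} (cases per event), \code{mode}.
#' @export
polytomous_c_index <- function(probs, labels,
                               mode = c("factorized", "brute")) {
  mode <- match.arg(mode)
  cp <- check_prob_matrix(probs, labels)
  probs <- cp$probs; labels <- cp$labels
  lev <- levels(labels)
  counts <- table(labels)
  if (any(counts == 0)) stop_("every event needs at least one case")
  idx <- lapply(lev, function(l) which(labels == l))
  k <- length(lev)

  est <- if (mode == "factorized") {
    per_event <- vapply(seq_len(k), function(e) {
      se <- probs[idx[[e]], e]
      frac <- rep(1, length(se))
      for (f in seq_len(k)[-e]) {
        sf <- sort(probs[idx[[f]], e])
        # strict count of event-f cases with smaller own-event-e probability
        n_lt <- findInterval(se, sf, left.open = TRUE)
        frac <- frac * n_lt / length(sf)
      }
      mean(frac)
    }, numeric(1))
    mean(per_event)
  } else {
    # enumerate every set of one case per event (vectorized over sets)
    grid <- as.matrix(expand.grid(lapply(idx, seq_along)))
    cases <- vapply(seq_len(k), function(e) idx[[e]][grid[, e]],
                    integer(nrow(grid)))
    if (is.null(dim(cases))) cases <- matrix(cases, nrow = 1)
    total <- 0
    for (e in seq_len(k)) {
      own <- probs[cases[, e], e]
      other <- do.call(pmax, lapply(seq_len(k)[-e], function(f)
        probs[cases[, f], e]))
      total <- total + sum(own > other)
    }
    total / (k * nrow(grid))
  }
  structure(list(estimate = est, counts = counts, mode = mode),
            class = "poly_c_index_result")
}

#' @export
print.poly_c_index_result <- function(x, ...) {
  cat(sprintf("polytomous c-index %.4f (%s; events: %s",
              x$estimate, x$mode,
              paste(sprintf("%s=%d", names(x$counts), x$counts),
                    collapse = ", ")))
  if (!is.null(x$ci))
    cat(sprintf("; %d%% CI %.3f-%.3f", round(100 * x$ci$level),
                x$ci$lower, x$ci$upper))
  cat(")\n")
  invisible(x)
}

#' All pairwise dichotomous c-indexes of a polytomous classifier
#'
#' For each unordered pair of events \{i, j\} the cases of those two events
#' are scored and the standard c-index computed. For a polytomous
#' probability matrix the score for event i within the pair is the
#' renormalized conditional probability \eqn{\pi_i/(\pi_i+\pi_j)}; a
#' one-versus-one ensemble instead supplies each pair's own model output
#' (see \code{\link{predict_pairwise}}).
#'
#' @param probs Per-case event probability matrix.
#' @param labels Factor of true events.
#' @return Named list of \code{c_index_result}, in pair order
#'   (1,2),(1,3),(1,4),(2,3),(2,4),(3,4) of the class levels, names
#'   \code{"i_vs_j"}.
#' @export
pairwise_c_indexes <- function(probs, labels) {
  cp <- check_prob_matrix(probs, labels)
  probs <- cp$probs; labels <- cp$labels
  lev <- levels(labels)
  pairs <- utils::combn(length(lev), 2)
  out <- vector("list", ncol(pairs))
  nm <- character(ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    sel <- labels %in% lev[c(i, j)]
    if (!any(labels[sel] == lev[i]) || !any(labels[sel] == lev[j]))
      stop_("pair %s vs %s has an empty class", lev[i], lev[j])
    pi_ <- probs[sel, i]; pj <- probs[sel, j]
    s <- ifelse(pi_ + pj > 0, pi_ / (pi_ + pj), 0.5)
    out[[q]] <- c_index(s, factor(labels[sel], levels = lev[c(i, j)]),
                        positive = lev[i])
    nm[q] <- paste0(lev[i], "_vs_", lev[j])
  }
  names(out) <- nm
  out
}

#' Benign-versus-malignant c-index of a polytomous classifier
#'
#' Collapses the three malignant events and scores the dichotomy with
#' 1 - P(benign), allowing direct comparison with classical dichotomous
#' ovarian tumor models.
#'
#' @param probs Per-case event probability matrix (must contain a column for
#'   the benign class).
#' @param labels Factor of true events.
#' @param benign Name of the benign class; default the first level.
#' @return A \code{c_index_result}.
#' @export
benign_vs_malignant_c <- function(probs, labels, benign = NULL) {
  cp <- check_prob_matrix(probs, labels)
  probs <- cp$probs; labels <- cp$labels
  benign <- benign %||% levels(labels)[1]
  if (!benign %in% levels(labels)) stop_("unknown benign class '%s'", benign)
  is_mal <- labels != benign
  if (!any(is_mal) || all(is_mal)) stop_("both benign and malignant needed")
  c_index(1 - probs[, benign], is_mal)
}

#' Loess calibration curve
#'
#' Relates predicted probabilities to actual (observed) event frequencies by
#' local-linear loess smoothing with tricube weights, evaluated on a
#' 100-point grid spanning the observed predictions and clipped to [0, 1].
#' A well calibrated model tracks the identity line.
#'
#' @param p Predicted event probabilities.
#' @param y Observed event indicator (0/1 or logical).
#' @param span Loess span; default 0.75.
#' @return Object of class \code{calibration_curve}: data frame with
#'   \code{predicted} and \code{observed} columns plus attributes
#'   \code{span} and \code{n}.
#' @export
calibration_curve <- function(p, y, span = 0.75) {
  y <- as.numeric(y)
  stopifnot(length(p) == length(y))
  if (length(p) < 10) stop_("calibration needs at least 10 cases")
  if (!is_binary01(y)) stop_("y must be a 0/1 event indicator")
  if (max(p) - min(p) < 1e-12)
    stop_("predicted probabilities are constant; no calibration curve")
  # near-singularity warnings from saturated probability clusters are
  # expected and harmless here
  fit <- suppressWarnings(
    stats::loess(y ~ p, span = span, degree = 1, family = "gaussian",
                 control = stats::loess.control(surface = "direct")))
  grid <- seq(min(p), max(p), length.out = 100)
  obs <- pmin(pmax(suppressWarnings(
    stats::predict(fit, data.frame(p = grid))), 0), 1)
  structure(data.frame(predicted = grid, observed = obs),
            span = span, n = length(p), class = c("calibration_curve",
                                                  "data.frame"))
}

#' @export
plot.calibration_curve <- function(x, ...) {
  plot(x$predicted, x$observed, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "predicted probability", ylab = "observed proportion", ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

## ---- bootstrap ----

resample_stratified <- function(n, strata) {
  unlist(lapply(split(seq_len(n), strata), function(ix)
    ix[sample.int(length(ix), length(ix), replace = TRUE)]),
    use.names = FALSE)
}

#' Stratified percentile bootstrap confidence interval
#'
#' Case-resampling percentile interval for an arbitrary scalar metric,
#' resampling within strata (typically the outcome event, so no resample
#' loses an event class). Resamples on which the metric fails are redrawn,
#' up to \code{10 * B} attempts.
#'
#' @param statistic Function taking integer case indices and returning a
#'   scalar (e.g. \code{function(ix) c_index(s[ix], y[ix])$estimate}).
#' @param n Number of cases.
#' @param strata Factor of length \code{n} defining resampling strata, or
#'   \code{NULL} for plain resampling.
#' @param B Number of bootstrap resamples, >= 100.
#' @param level Confidence level, default 0.95.
#' @param seed Integer seed.
#' @return List with \code{lower}, \code{upper}, \code{level}, \code{B},
#'   \code{seed}, \code{replicates}.
#' @export
bootstrap_ci <- function(statistic, n, strata = NULL, B = 1000,
                         level = 0.95, seed = 1) {
  if (B < 100) stop_("B must be at least 100")
  strata <- if (is.null(strata)) factor(rep(1, n)) else factor(strata)
  reps <- numeric(B)
  with_seed(seed, {
    b <- 1; attempts <- 0
    while (b <= B) {
      attempts <- attempts + 1
      if (attempts > 10 * B) stop_("bootstrap: too many failed resamples")
      ix <- resample_stratified(n, strata)
      val <- tryCatch(statistic(ix), error = function(e) NA_real_)
      if (is.finite(val)) { reps[b] <- val; b <- b + 1 }
    }
  })
  alpha <- (1 - level) / 2
  qs <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(lower = qs[1], upper = qs[2], level = level, B = B, seed = seed,
       replicates = reps)
}

#' Bootstrap confidence interval for a paired difference of two metrics
#'
#' Applies both metrics to the same stratified resample so the interval
#' reflects the paired difference (metric A minus metric B), as used to
#' compare a model against the best model.
#'
#' @param statistic_a,statistic_b Functions of integer case indices
#'   returning scalars.
#' @inheritParams bootstrap_ci
#' @return As \code{\link{bootstrap_ci}}, for the difference A - B.
#' @export
bootstrap_diff_ci <- function(statistic_a, statistic_b, n, strata = NULL,
                              B = 1000, level = 0.95, seed = 1) {
  bootstrap_ci(function(ix) statistic_a(ix) - statistic_b(ix),
               n = n, strata = strata, B = B, level = level, seed = seed)
}
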