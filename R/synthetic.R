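# Class-conditional generative profile and synthetic cohort generator.
#
# The packaged default profile transcribes the per-class descriptive
# statistics of the selected ultrasound/clinical variables in a multi-center
# ovarian tumor development cohort: continuous variables are summarized by
# their class medians, the ordinal papillation count by its class mean, and
# binary markers by their class percentages. Only these marginals are known,
# so the generator fills in distributional shape by documented convention
# (log-normal continuous, truncated-Poisson ordinal, Bernoulli binary,
# independence within class).

#' Construct a class-conditional generative profile
#'
#' @param prevalence Named numeric vector of class prevalences over
#'   \code{classes}; nonnegative, summing to 1.
#' @param variables Named list of per-variable parameter blocks. Each block
#'   is a list with a \code{kind} field and per-class parameter vectors (in
#'   the order of \code{classes}):
#'   \describe{
#'     \item{continuous}{\code{median} (target medians, >= 0), optional
#'       \code{sdlog} (log-scale dispersion, default 0.5), optional
#'       \code{zero_prob} (structural-zero mass per class, default 0) and
#'       \code{pos_median} (median of the positive part where
#'       \code{zero_prob > 0}; defaults to \code{median}).}
#'     \item{ordinal}{\code{mean} (target means) and \code{max} (truncation
#'       point of the count distribution, default 4).}
#'     \item{binary}{\code{prop} (target proportions in [0,1]).}
#'   }
#' @param classes Outcome labels, default \code{tumor_classes()}.
#' @return An object of class \code{class_profile}.
#' @export
class_profile <- function(prevalence, variables,
                          classes = tumor_classes()) {
  k <- length(classes)
  if (length(prevalence) != k)
    stop_("`prevalence` must have one entry per class")
  if (is.null(names(prevalence))) names(prevalence) <- classes
  prevalence <- prevalence[classes]
  if (anyNA(prevalence) || any(prevalence < 0) ||
      abs(sum(prevalence) - 1) > 1e-8)
    stop_("prevalences must be nonnegative and sum to 1")

  for (v in names(variables)) {
    blk <- variables[[v]]
    kind <- blk$kind
    if (is.null(kind) || !kind %in% c("continuous", "ordinal", "binary"))
      stop_("variable '%s': invalid kind", v)
    chk <- function(field, lo = 0, hi = Inf, required = TRUE) {
      val <- blk[[field]]
      if (is.null(val)) {
        if (required) stop_("variable '%s': missing field '%s'", v, field)
        return(invisible())
      }
      if (length(val) != k || anyNA(val) || any(val < lo | val > hi))
        stop_("variable '%s': field '%s' must be %d values in [%g, %g]",
              v, field, k, lo, hi)
    }
    switch(kind,
      continuous = { chk("median"); chk("zero_prob", 0, 1, FALSE)
                     chk("pos_median", required = FALSE) },
      ordinal    = chk("mean"),
      binary     = chk("prop", 0, 1))
    variables[[v]] <- blk
  }
  structure(list(prevalence = prevalence, variables = variables,
                 classes = classes),
            class = "class_profile")
}

#' @export
print.class_profile <- function(x, ...) {
  cat(sprintf("class_profile: %d classes, %d variables\n",
              length(x$classes), length(x$variables)))
  cat("prevalence:", paste(sprintf("%s=%.3f", x$classes, x$prevalence),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Packaged default class profile for the ovarian tumor cohort
#'
#' Transcribes the per-class descriptive statistics of the twelve selected
#' variables in the development cohort: class prevalences 75/5/16/4%
#' (benign/borderline/primary invasive/metastatic), continuous medians,
#' the papillation-count mean and binary percentages. The benign solid-part
#' diameter has printed median 0 and is modelled as zero-inflated with a
#' structural-zero mass of 0.6 and a positive-part median of 12 mm.
#'
#' @return A \code{class_profile}.
#' @export
default_class_profile <- function() {
  class_profile(
    prevalence = c(benign = 0.75, borderline = 0.05,
                   primary_invasive = 0.16, metastatic = 0.04),
    variables = list(
      age = list(kind = "continuous",
                 median = c(42, 52.5, 58, 59)),
      lesion_diameter = list(kind = "continuous",
                             median = c(63, 108, 98, 73)),
      solid_diameter = list(kind = "continuous",
                            median = c(0, 22, 51, 54),
                            zero_prob = c(0.6, 0, 0, 0),
                            pos_median = c(12, 22, 51, 54)),
      papillation_count = list(kind = "ordinal",
                               mean = c(0.35, 1.70, 1.43, 0.93), max = 4),
      ascites = list(kind = "binary",
                     prop = c(0.032, 0.125, 0.504, 0.400)),
      solid_tumor = list(kind = "binary",
                         prop = c(0.066, 0.075, 0.322, 0.567)),
      irregular_walls = list(kind = "binary",
                             prop = c(0.336, 0.675, 0.884, 0.833)),
      ovarian_cancer_history = list(kind = "binary",
                                    prop = c(0.009, 0.050, 0.008, 0.100)),
      bilateral = list(kind = "binary",
                       prop = c(0.176, 0.125, 0.413, 0.333)),
      papillation_flow = list(kind = "binary",
                              prop = c(0.068, 0.475, 0.430, 0.233)),
      acoustic_shadows = list(kind = "binary",
                              prop = c(0.130, 0.025, 0.000, 0.033)),
      unilocular = list(kind = "binary",
                        prop = c(0.403, 0.025, 0.000, 0.000))
    ))
}

#' Predictor schema implied by a class profile
#' @param profile A \code{class_profile}.
#' @return Named character vector (variable -> kind).
#' @export
profile_schema <- function(profile) {
  stopifnot(inherits(profile, "class_profile"))
  vapply(profile$variables, function(b) b$kind, character(1))
}

# rate of a Poisson truncated to {0, ..., max} with given mean, by root
# finding on the monotone mean-vs-rate map
truncated_poisson_rate <- function(target_mean, max) {
  if (target_mean <= 0) return(0)
  if (target_mean >= max) stop_("ordinal target mean must be < max")
  trunc_mean <- function(lam) {
    p <- stats::dpois(0:max, lam)
    sum((0:max) * p) / sum(p)
  }
  stats::uniroot(function(l) trunc_mean(l) - target_mean,
                 lower = 1e-9, upper = max * 50, tol = 1e-10)$root
}

r_truncated_poisson <- function(n, rate, max) {
  if (rate == 0) return(integer(n))
  p <- stats::dpois(0:max, rate)
  sample(0:max, n, replace = TRUE, prob = p)
}

draw_variable <- function(blk, class_index, n) {
  i <- class_index
  switch(blk$kind,
    continuous = {
      zp <- (blk$zero_prob %||% rep(0, length(blk$median)))[i]
      med <- if (zp > 0) (blk$pos_median %||% blk$median)[i] else
        blk$median[i]
      sdlog <- (blk$sdlog %||% 0.5)
      if (length(sdlog) > 1) sdlog <- sdlog[i]
      if (med <= 0 && zp <= 0)
        stop_("continuous median must be positive unless zero-inflated")
      x <- if (med > 0)
        stats::rlnorm(n, meanlog = log(med), sdlog = sdlog) else numeric(n)
      if (zp > 0) x[stats::runif(n) < zp] <- 0
      x
    },
    ordinal = {
      mx <- blk$max %||% 4
      rate <- truncated_poisson_rate(blk$mean[i], mx)
      r_truncated_poisson(n, rate, mx)
    },
    binary = stats::rbinom(n, 1, blk$prop[i]))
}

#' Simulate a synthetic cohort from a class profile
#'
#' Class counts follow exact largest-remainder allocation of the prevalence
#' vector (or multinomial sampling when \code{allocation = "multinomial"}).
#' Within each class, continuous variables are drawn from a log-normal whose
#' theoretical median equals the profile median (zero-inflated where the
#' profile specifies a structural-zero mass), ordinal counts from a truncated
#' Poisson moment-matched to the profile mean, and binaries as Bernoulli at
#' the profile proportion. Predictors are independent within class. All
#' randomness flows through \code{seed}.
#'
#' @param profile A \code{class_profile}; default the packaged cohort
#'   profile.
#' @param n Number of cases; must be at least the number of classes.
#' @param seed Integer seed.
#' @param allocation \code{"largest_remainder"} (default, deterministic class
#'   counts) or \code{"multinomial"}.
#' @return A \code{risk_dataset} with the profile's schema.
#' @export
simulate_cohort <- function(profile = default_class_profile(), n, seed,
                            allocation = c("largest_remainder",
                                           "multinomial")) {
  stopifnot(inherits(profile, "class_profile"))
  allocation <- match.arg(allocation)
  k <- length(profile$classes)
  if (n < k) stop_("n must be at least the number of classes (%d)", k)

  with_seed(seed, {
    counts <- if (allocation == "largest_remainder")
      largest_remainder(n, profile$prevalence)
    else as.integer(stats::rmultinom(1, n, profile$prevalence))
    cols <- lapply(names(profile$variables), function(v) {
      blk <- profile$variables[[v]]
      unlist(lapply(seq_len(k), function(i) draw_variable(blk, i, counts[i])))
    })
    names(cols) <- names(profile$variables)
    df <- as.data.frame(cols)
    df$outcome <- factor(rep(profile$classes, counts),
                         levels = profile$classes)
    # shuffle so row order carries no class information
    df <- df[sample.int(nrow(df)), , drop = FALSE]
    rownames(df) <- NULL
    risk_dataset(df, schema = profile_schema(profile),
                 classes = profile$classes)
  })
}

#' Simulate only the cases of one class
#'
#' Convenience wrapper drawing \code{n} cases from a single class of the
#' profile (e.g. for calibration checks of the generator).
#'
#' @inheritParams simulate_cohort
#' @param class One of the profile's class labels.
#' @return A \code{risk_dataset} whose cases all carry \code{class}.
#' @export
simulate_class <- function(profile = default_class_profile(), class, n,
                           seed) {
  stopifnot(inherits(profile, "class_profile"))
  i <- match(class, profile$classes)
  if (is.na(i)) stop_("unknown class '%s'", class)
  with_seed(seed, {
    cols <- lapply(profile$variables, draw_variable, class_index = i, n = n)
    df <- as.data.frame(cols)
    df$outcome <- factor(rep(profile$classes[i], n),
                         levels = profile$classes)
    risk_dataset(df, schema = profile_schema(profile),
                 classes = profile$classes)
  })
}

#' Read / write a class profile as JSON
#'
#' @param path File path.
#' @return \code{read_profile} returns a \code{class_profile};
#'   \code{write_profile} returns \code{path} invisibly.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop_("profile file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  prev <- unlist(obj$prevalence)
  vars <- lapply(obj$variables, function(b) {
    b <- as.list(b)
    b
  })
  class_profile(prevalence = prev, variables = vars,
                classes = obj$classes %||% tumor_classes())
}

#' @rdname read_profile
#' @param profile A \code{class_profile}.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "class_profile"))
  jsonlite::write_json(
    list(classes = profile$classes,
         prevalence = as.list(profile$prevalence),
         variables = profile$variables),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
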