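# Shared fixtures built in code. All randomness goes through explicit seeds.

CLS <- tumor_classes()

# small hand-written cohort with a typed schema
toy_schema <- c(age = "continuous", solid_diameter = "continuous",
                papillation_count = "ordinal", ascites = "binary")

toy_dataset <- function() {
  df <- data.frame(
    age = c(35, 42, 61, 58, 47, 52, 66, 39, 44, 70),
    solid_diameter = c(0, 0, 55, 40, 12, 20, 60, 0, 5, 48),
    papillation_count = c(0L, 1L, 2L, 3L, 0L, 1L, 4L, 0L, 0L, 2L),
    ascites = c(0, 0, 1, 1, 0, 0, 1, 0, 0, 1),
    outcome = c("benign", "benign", "primary_invasive", "metastatic",
                "benign", "borderline", "primary_invasive", "benign",
                "borderline", "metastatic"))
  risk_dataset(df, schema = toy_schema)
}

# seeded logistic-model data for recovery / oracle tests
sim_logistic <- function(n, beta, intercept = 0, seed = 1) {
  with_seed_test(seed, {
    X <- matrix(rnorm(n * length(beta)), n,
                dimnames = list(NULL, paste0("x", seq_along(beta))))
    p <- stats::plogis(intercept + drop(X %*% beta))
    list(X = X, y = rbinom(n, 1, p))
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# naive leave-one-out for an LS-SVM: n full refits
naive_loo_lssvm <- function(m) {
  n <- length(m$y)
  vapply(seq_len(n), function(i) {
    yi <- factor(ifelse(m$y[-i] == 1, "pos", "neg"),
                 levels = c("neg", "pos"))
    mi <- lssvm_fit(m$X[-i, , drop = FALSE], yi, gamma = m$gamma,
                    kernel = m$kernel, standardize = FALSE)
    predict(mi, m$X[i, , drop = FALSE], type = "latent")
  }, numeric(1))
}

# naive forward selection for linear-kernel LS-SVMs: refit every candidate
# system from scratch (no rank-one updates), same tie-breaking as r1u
naive_r1u <- function(X, y, max_vars, gamma_grid) {
  Xs <- apply_std(X)
  ys <- ifelse(y == levels(factor(y))[2], 1, -1)
  n <- nrow(Xs)
  sel <- character(0); rem <- colnames(X)
  out <- data.frame(step = integer(0), variable = character(0),
                    loo_c_index = numeric(0), gamma = numeric(0))
  for (s in seq_len(max_vars)) {
    best <- NULL
    for (v in rem) for (g in gamma_grid) {
      K <- tcrossprod(Xs[, c(sel, v), drop = FALSE])
      M <- rbind(cbind(K + diag(1 / g, n), 1), c(rep(1, n), 0))
      Minv <- solve(M)
      z <- drop(Minv %*% c(ys, 0))
      floo <- ys - z[seq_len(n)] / diag(Minv)[seq_len(n)]
      ci <- c_index(floo, ys == 1)$estimate
      if (is.null(best) || ci > best$ci + 1e-15 ||
          (abs(ci - best$ci) <= 1e-15 &&
           (g < best$g - 1e-15 ||
            (abs(g - best$g) <= 1e-15 &&
             match(v, colnames(X)) < match(best$v, colnames(X)))))) {
        best <- list(v = v, g = g, ci = ci)
      }
    }
    sel <- c(sel, best$v); rem <- setdiff(rem, best$v)
    out <- rbind(out, data.frame(step = s, variable = best$v,
                                 loo_c_index = best$ci, gamma = best$g))
  }
  out
}

apply_std <- function(X) {
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  scl[scl < 1e-12] <- 1
  sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
}

# well-separated four-class data: one indicator variable per class plus
# noise, so class membership is (nearly) recoverable
block_design <- function(n_per_class = 8, seed = 1, noise = 0) {
  with_seed_test(seed, {
    k <- 4
    y <- factor(rep(CLS, each = n_per_class), levels = CLS)
    X <- matrix(0, length(y), k, dimnames = list(NULL, paste0("d", 1:k)))
    for (c in seq_len(k)) X[y == CLS[c], c] <- 1
    if (noise > 0) X <- X + matrix(rnorm(length(X), sd = noise), nrow(X))
    list(X = X, y = y)
  })
}
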