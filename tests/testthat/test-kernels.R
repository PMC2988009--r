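test_that("kernel matrices follow their definitions", {
  X <- diag(3)
  expect_equal(kernel_matrix(X, X, kernel_spec("linear")), diag(3))
  x <- matrix(c(0, 0), 1); z <- matrix(c(1, 1), 1)
  expect_equal(kernel_matrix(x, z, kernel_spec("gaussian", sqrt(2)))[1, 1],
               exp(-1), tolerance = 1e-12)
  X <- with_seed_test(3, matrix(rnorm(40), 10, 4))
  K <- kernel_matrix(X, X, kernel_spec("gaussian", 1.5))
  expect_equal(diag(K), rep(1, 10))
  expect_equal(K, t(K))
  expect_gt(min(eigen(K, symmetric = TRUE)$values), -1e-8)
  expect_error(kernel_matrix(X, X[, 1:2], kernel_spec("linear")),
               "dimension")
  expect_error(kernel_spec("gaussian", -1), "sigma")
})

test_that("LS-SVM solves its KKT system", {
  # two symmetric cases: zero bias, correct signs
  m2 <- lssvm_fit(matrix(c(-1, 1), 2, 1), factor(c("a", "b")), gamma = 1,
                  standardize = FALSE)
  expect_lt(abs(m2$b), 1e-10)
  f <- predict(m2, matrix(c(-1, 1), 2, 1), type = "latent")
  expect_true(f[2] > 0 && f[1] < 0)

  # KKT residual on random problems, stated in the alpha formulation
  for (seed in 1:3) {
    d <- with_seed_test(seed, {
      X <- matrix(rnorm(60), 30, 2)
      list(X = X, y = factor(sample(c("a", "b"), 30, TRUE)))
    })
    m <- lssvm_fit(d$X, d$y, gamma = 3,
                   kernel = kernel_spec("gaussian", 2))
    n <- length(m$y)
    K <- kernel_matrix(m$X, m$X, m$kernel)
    Omega <- outer(m$y, m$y) * K
    lhs <- rbind(c(0, m$y), cbind(m$y, Omega + diag(1 / m$gamma, n)))
    res <- lhs %*% c(m$b, m$alpha) - c(0, rep(1, n))
    expect_lt(max(abs(res)) / max(abs(c(m$alpha, 1))), 1e-8)
    expect_lt(abs(sum(m$alpha * m$y)), 1e-10)
  }

  # XOR with a Gaussian kernel: all four training points on the right side
  Xx <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  yx <- factor(c("n", "n", "p", "p"))
  mx <- lssvm_fit(Xx, yx, gamma = 10, kernel = kernel_spec("gaussian", 1),
                  standardize = FALSE)
  expect_equal(sign(predict(mx, Xx, type = "latent")), c(-1, -1, 1, 1))
})

test_that("Bayesian posterior combines latent densities with priors", {
  stub <- structure(list(
    latent = list(mean = c(neg = -1, pos = 1), sd = c(neg = 1, pos = 1)),
    priors = c(neg = 0.25, pos = 0.75), kernel = kernel_spec("linear"),
    std = NULL, X = matrix(0, 1, 1), beta = 0, b = 0, y = c(-1, 1),
    variables = NULL), class = "lssvm_fit")
  # equal densities at f = 0: posterior equals the prior
  expect_equal(lssvm_posterior(stub, NULL, latent = 0), 0.75,
               tolerance = 1e-12)
  # symmetric latents, equal priors: 0.5 at the midpoint
  expect_equal(lssvm_posterior(stub, NULL, priors = c(.5, .5), latent = 0),
               0.5, tolerance = 1e-12)
  # hand Bayes at f = 0.5
  num <- 0.75 * dnorm(0.5, 1, 1)
  expect_equal(lssvm_posterior(stub, NULL, latent = 0.5),
               num / (num + 0.25 * dnorm(0.5, -1, 1)), tolerance = 1e-12)
  # degenerate latent spread falls back to hard assignment with a warning
  stub$latent$sd <- c(neg = 0, pos = 0)
  expect_warning(p <- lssvm_posterior(stub, NULL, latent = c(-2, 2)),
                 "degenerate")
  expect_equal(p, c(0, 1))
  expect_error(lssvm_posterior(stub, NULL, priors = c(0.7, 0.7),
                               latent = 0), "priors")
})

test_that("fast leave-one-out equals naive refits", {
  d <- with_seed_test(17, {
    X <- matrix(rnorm(40), 20, 2)
    list(X = X, y = factor(sample(c("a", "b"), 20, TRUE)))
  })
  for (kern in list(kernel_spec("linear"), kernel_spec("gaussian", 2))) {
    m <- lssvm_fit(d$X, d$y, gamma = 2, kernel = kern)
    expect_lt(max(abs(loo_lssvm(m) - naive_loo_lssvm(m))), 1e-8)
  }
  # invariance under case reordering
  m <- lssvm_fit(d$X, d$y, gamma = 2)
  perm <- with_seed_test(1, sample(20))
  mp <- lssvm_fit(d$X[perm, ], d$y[perm], gamma = 2)
  expect_equal(loo_lssvm(mp), loo_lssvm(m)[perm], tolerance = 1e-9)
  # too few cases is a defined error
  expect_error(
    loo_lssvm(lssvm_fit(matrix(c(-1, 1), 2, 1), factor(c("a", "b")),
                        gamma = 1, standardize = FALSE)),
    "leave-one-out")
})

test_that("KLR honors its limits and descends monotonically", {
  d <- sim_logistic(120, c(0.8, -0.6), intercept = 0.4, seed = 3)
  # lambda -> infinity: prevalences
  m_inf <- klr_fit(d$X, d$y, lambda = 1e8)
  expect_lt(max(abs(predict(m_inf, d$X) - mean(d$y))), 1e-4)
  # linear kernel, tiny lambda: unpenalized logistic regression
  m_0 <- klr_fit(d$X, d$y, lambda = 1e-7, standardize = FALSE)
  ml <- logit_fit(d$X, d$y)
  expect_lt(max(abs(predict(m_0, d$X) - predict(ml, d$X))), 1e-3)
  # penalized objective decreases across IRLS steps
  m <- klr_fit(d$X, d$y, lambda = 0.5, kernel = kernel_spec("gaussian", 2))
  expect_true(all(diff(m$trace) <= 1e-9))
  expect_true(m$converged)
  # regularization path: training c-index non-increasing in lambda
  cis <- vapply(c(0.01, 1, 100, 1e4), function(l) {
    mm <- klr_fit(d$X, d$y, lambda = l)
    c_index(predict(mm, d$X), d$y)$estimate
  }, numeric(1))
  expect_true(all(diff(cis) <= 0.02))
})

test_that("MKLR reduces to KLR and normalizes", {
  d <- sim_logistic(100, c(1, -0.4), seed = 6)
  mk <- klr_fit(d$X, d$y, lambda = 0.5)
  mm <- mklr_fit(d$X, factor(d$y), lambda = 0.5)
  expect_lt(max(abs(predict(mm, d$X)[, 2] - predict(mk, d$X))), 1e-6)

  bd <- block_design(10, noise = 0.3, seed = 8)
  m4 <- mklr_fit(bd$X, bd$y, lambda = 1)
  P <- predict(m4, bd$X)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  expect_true(all(P >= 0))
  m4i <- mklr_fit(bd$X, bd$y, lambda = 1e8)
  expect_lt(max(abs(predict(m4i, bd$X) - 0.25)), 1e-3)
})

test_that("cross-validated tuning picks sensible grid points", {
  # a single grid point is returned as-is
  d <- sim_logistic(60, c(2), seed = 4)
  yf <- factor(ifelse(d$y == 1, "pos", "neg"), levels = c("neg", "pos"))
  tn <- tune_cv(d$X, yf, family = "lssvm", grid = data.frame(gamma = 7),
                seed = 1)
  expect_equal(tn$best$gamma, 7)

  # constant-zero predictors: identical metric everywhere, so the tie rule
  # picks the most regularized point (largest lambda)
  X0 <- matrix(0, 60, 1, dimnames = list(NULL, "z"))
  tn0 <- tune_cv(X0, yf, family = "klr",
                 grid = data.frame(lambda = c(0.1, 10, 1)), seed = 1)
  expect_equal(tn0$best$lambda, 10)
  expect_equal(length(unique(round(tn0$table$cv_metric, 12))), 1L)

  # with real signal the tuned gamma beats the degenerate endpoint
  d2 <- sim_logistic(150, c(2.5, 2), seed = 10)
  y2 <- factor(ifelse(d2$y == 1, "pos", "neg"), levels = c("neg", "pos"))
  tr <- 1:100; te <- 101:150
  tn2 <- tune_cv(d2$X[tr, ], y2[tr], family = "lssvm",
                 grid = data.frame(gamma = default_gamma_grid()), seed = 2)
  fit_best <- lssvm_fit(d2$X[tr, ], y2[tr], gamma = tn2$best$gamma)
  fit_worst <- lssvm_fit(d2$X[tr, ], y2[tr], gamma = 1e-6)
  cb <- c_index(predict(fit_best, d2$X[te, ], type = "latent"),
                y2[te])$estimate
  cw <- c_index(predict(fit_worst, d2$X[te, ], type = "latent"),
                y2[te])$estimate
  expect_gte(cb, cw - 0.02)
  expect_error(tune_cv(d$X, yf, family = "lssvm",
                       grid = data.frame(gamma = numeric(0))), "empty")
})
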