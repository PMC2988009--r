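test_that("stepwise selection finds strong signals and guards type I", {
  # one overwhelming predictor (log-odds 3 per unit, i.e. OR ~ 20)
  d <- with_seed_test(41, {
    X <- matrix(rnorm(500 * 4), 500, 4,
                dimnames = list(NULL, c("strong", "n1", "n2", "n3")))
    list(X = X, y = rbinom(500, 1, plogis(X[, "strong"] * 3)))
  })
  cs <- suppressWarnings(stepwise_select(d$X, factor(d$y)))
  expect_equal(cs$variables[1], "strong")
  expect_equal(cs$provenance, "stepwise")

  # pure noise: per-variable selection rate near the 5% entry level
  rate <- with_seed_test(17, {
    picks <- 0
    for (r in 1:150) {
      X <- matrix(rnorm(200 * 3), 200, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
      y <- rbinom(200, 1, 0.4)
      picks <- picks +
        length(suppressWarnings(stepwise_select(X, factor(y)))$variables)
    }
    picks / (150 * 3)
  })
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.12)

  # empty candidate pool
  expect_equal(
    stepwise_select(matrix(numeric(0), 50, 0),
                    factor(rep(c("a", "b"), 25)))$variables,
    character(0))
})

test_that("backward elimination keeps true predictors, drops noise", {
  d <- with_seed_test(23, {
    X <- matrix(rnorm(400 * 3), 400, 3,
                dimnames = list(NULL, c("true", "z1", "z2")))
    list(X = X, y = rbinom(400, 1, plogis(1.5 * X[, "true"])))
  })
  cs <- suppressWarnings(backward_select(d$X, factor(d$y)))
  expect_true("true" %in% cs$variables)
  # p_remove = 1 keeps everything
  cs_full <- suppressWarnings(backward_select(d$X, factor(d$y),
                                              p_remove = 1))
  expect_setequal(cs_full$variables, colnames(d$X))
  # all-noise fixture mostly collapses to (near) nothing
  kept <- with_seed_test(29, {
    tot <- 0
    for (r in 1:40) {
      X <- matrix(rnorm(200 * 3), 200, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
      y <- rbinom(200, 1, 0.5)
      tot <- tot +
        length(suppressWarnings(backward_select(X, factor(y)))$variables)
    }
    tot / (40 * 3)
  })
  expect_lt(kept, 0.15)
})

test_that("candidate evaluation reports AIC/BIC and repeated-CV c-index", {
  ds <- with_seed_test(3, simulate_cohort(n = 240, seed = 19))
  r0 <- evaluate_candidate(character(0), ds, runs = 3, folds = 4,
                           seeds = 1:3)
  expect_true(all(abs(r0$cv_c_index - 0.5) < 0.05))
  r1 <- suppressWarnings(
    evaluate_candidate(c("solid_diameter", "ascites"), ds, runs = 3,
                       folds = 4, seeds = 1:3))
  expect_gt(mean(r1$cv_c_index), mean(r0$cv_c_index))
  expect_lt(r1$aic, r0$aic)
  # reproducible under fixed seeds
  r1b <- suppressWarnings(
    evaluate_candidate(c("solid_diameter", "ascites"), ds, runs = 3,
                       folds = 4, seeds = 1:3))
  expect_identical(r1$cv_c_index, r1b$cv_c_index)
  # more runs shrink the run-to-run spread of the mean
  r_many <- suppressWarnings(
    evaluate_candidate(c("solid_diameter"), ds, runs = 8,
                       folds = 4, seeds = 1:8))
  expect_equal(nrow(r_many$per_run), 8)
  expect_true(all(r_many$per_run >= 0 & r_many$per_run <= 1))
})

test_that("Sherman-Morrison updates match direct inversion", {
  with_seed_test(10, {
    A <- crossprod(matrix(rnorm(9), 3)) + diag(3)
    u <- rnorm(3)
    A_inv <- solve(A)
    expect_equal(rank_one_inverse_update(A_inv, u, 0), A_inv)
    up <- rank_one_inverse_update(A_inv, u, 0.7)
    expect_lt(max(abs(up - solve(A + 0.7 * tcrossprod(u)))), 1e-10)
    # update followed by downdate restores the original inverse
    down <- rank_one_inverse_update(up, u, -0.7)
    expect_lt(max(abs(down - A_inv)), 1e-10)
    # singular denominator is refused
    B_inv <- diag(2)
    expect_error(rank_one_inverse_update(B_inv, c(1, 0), -1),
                 "denominator")
  })
})

test_that("rank-one update of the linear kernel adds the variable's outer
           product", {
  X <- with_seed_test(2, matrix(rnorm(30), 10, 3))
  K12 <- tcrossprod(X[, 1:2])
  K123 <- tcrossprod(X[, 1:3])
  expect_equal(K12 + tcrossprod(X[, 3]), K123, tolerance = 1e-12)
})

test_that("R1U forward selection equals naive refit-everything selection", {
  gg <- 10^seq(-2, 2, length.out = 5)
  for (seed in c(9, 101, 202)) {
    d <- with_seed_test(seed, {
      X <- matrix(rnorm(25 * 6), 25, 6,
                  dimnames = list(NULL, paste0("v", 1:6)))
      eta <- X[, 2] * 2 - X[, 5]
      list(X = X, y = factor(ifelse(rbinom(25, 1, plogis(eta)) == 1,
                                    "pos", "neg"),
                             levels = c("neg", "pos")))
    })
    fast <- r1u_forward(d$X, d$y, max_vars = 3, gamma_grid = gg)
    naive <- naive_r1u(d$X, d$y, max_vars = 3, gamma_grid = gg)
    expect_equal(fast$variable, naive$variable)
    expect_equal(fast$gamma, naive$gamma)
    expect_lt(max(abs(fast$loo_c_index - naive$loo_c_index)), 1e-8)
  }
  expect_error(r1u_forward(matrix(rnorm(20), 10, 2),
                           factor(rep(c("a", "b"), 5)), max_vars = 5),
               "exceeds")
})

test_that("a planted informative variable is picked first", {
  hits <- with_seed_test(55, {
    h <- 0
    for (r in 1:20) {
      X <- matrix(rnorm(60 * 5), 60, 5,
                  dimnames = list(NULL, paste0("v", 1:5)))
      y <- factor(rep(c("neg", "pos"), each = 30),
                  levels = c("neg", "pos"))
      X[y == "pos", 3] <- X[y == "pos", 3] + 2   # 2 SD shift
      tr <- r1u_forward(X, y, max_vars = 1,
                        gamma_grid = 10^seq(-2, 2, length.out = 5))
      if (tr$variable[1] == "v3") h <- h + 1
    }
    h
  })
  expect_gte(hits, 18)
})

test_that("selection traces serialize and round-trip", {
  d <- with_seed_test(77, {
    X <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
    list(X = X, y = factor(rep(c("n", "p"), 15), levels = c("n", "p")))
  })
  tr <- r1u_forward(d$X, d$y, max_vars = 2, gamma_grid = c(0.1, 1, 10))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(tr, f, digits = NA)
  tr2 <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(tr2$variable, tr$variable)
  expect_equal(tr2$loo_c_index, tr$loo_c_index, tolerance = 1e-12)
})

test_that("coordinated pairwise selection respects the variable budget", {
  ds <- with_seed_test(1, simulate_cohort(n = 280, seed = 61))
  sets <- coordinate_1v1_selection(ds, budget = 4, min_per_pair = 2,
                                   runs = 1, folds = 3, seed = 2)
  expect_named(sets, names(decompose_1v1(ds)))
  expect_lte(length(unique(unlist(lapply(sets, `[[`, "variables")))), 4)
  expect_true(all(vapply(sets, function(s) length(s$variables),
                         numeric(1)) >= 2))
  expect_error(coordinate_1v1_selection(ds, budget = 1, min_per_pair = 3),
               "budget")
})

test_that("a universally helpful variable is granted to every pair", {
  # one variable separates all classes monotonically; the rest is noise
  d <- with_seed_test(31, {
    y <- factor(rep(CLS, each = 15), levels = CLS)
    n <- length(y)
    df <- data.frame(
      u = as.integer(y) * 2 + rnorm(n, sd = 0.3),
      w1 = rnorm(n), w2 = rnorm(n), outcome = y)
    risk_dataset(df, schema = c(u = "continuous", w1 = "continuous",
                                w2 = "continuous"))
  })
  sets <- coordinate_1v1_selection(d, budget = 2, min_per_pair = 1,
                                   runs = 1, folds = 3, seed = 5)
  expect_true(all(vapply(sets, function(s) "u" %in% s$variables,
                         logical(1))))
})
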