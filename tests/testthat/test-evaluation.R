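test_that("dichotomous c-index counts concordant pairs", {
  expect_equal(c_index(c(10, 2, 9, 1), c(1, 0, 1, 0))$estimate, 1)
  expect_equal(c_index(rep(3, 6), rep(c(1, 0), 3))$estimate, 0.5)
  # exhaustive pair checks from first principles
  expect_equal(c_index(c(3, 1, 2),
                       factor(c("p", "n", "p"), levels = c("n", "p")),
                       positive = "p")$estimate, 1)
  expect_equal(c_index(c(1, 2, 3),
                       factor(c("p", "n", "p"), levels = c("n", "p")),
                       positive = "p")$estimate, 0.5)
  r <- c_index(c(1, 1, 2), c(1, 0, 1))
  expect_equal(r$tied_pairs, 1)
  expect_error(c_index(1:3, c(1, 1, 1)), "both labels")
})

test_that("polytomous c-index: anchors and the tie rule", {
  # perfect indicator probabilities
  y <- factor(rep(CLS, each = 3), levels = CLS)
  P <- diag(4)[as.integer(y), ]
  colnames(P) <- CLS
  expect_equal(polytomous_c_index(P, y)$estimate, 1)
  # uniform rows: every comparison ties, strict rule gives zero credit
  y1 <- factor(CLS, levels = CLS)
  P1 <- matrix(0.25, 4, 4, dimnames = list(NULL, CLS))
  expect_equal(polytomous_c_index(P1, y1)$estimate, 0)
  # two cases per event with distinct hand-chosen probabilities: the
  # factorized algorithm equals enumeration of all 16 quadruples
  with_seed_test(12, {
    y2 <- factor(rep(CLS, each = 2), levels = CLS)
    P2 <- matrix(runif(32), 8, 4, dimnames = list(NULL, CLS))
    a <- polytomous_c_index(P2, y2, mode = "factorized")$estimate
    b <- polytomous_c_index(P2, y2, mode = "brute")$estimate
    expect_equal(a, b, tolerance = 1e-12)
  })
  expect_error(polytomous_c_index(P1[, 1:3], y1), "columns")
  expect_error(polytomous_c_index(P1, factor(rep("benign", 4),
                                             levels = CLS)),
               "at least one case")
})

test_that("factorized polytomous c-index equals brute force (property)", {
  with_seed_test(99, {
    for (i in 1:25) {
      counts <- sample(1:6, 4, replace = TRUE)
      y <- factor(rep(CLS, counts), levels = CLS)
      P <- matrix(runif(length(y) * 4), ncol = 4,
                  dimnames = list(NULL, CLS))
      # occasionally inject ties to exercise the strict rule
      if (i %% 5 == 0) P[, 1] <- round(P[, 1], 1)
      expect_equal(polytomous_c_index(P, y, mode = "factorized")$estimate,
                   polytomous_c_index(P, y, mode = "brute")$estimate,
                   tolerance = 1e-12)
    }
  })
})

test_that("two-event reduction is consistent with the dichotomous c-index", {
  with_seed_test(4, {
    y <- factor(rep(c("benign", "borderline"), each = 10),
                levels = c("benign", "borderline"))
    s <- runif(20)  # continuous, no ties
    P <- cbind(benign = s, borderline = 1 - s)
    expect_equal(polytomous_c_index(P, y)$estimate,
                 c_index(s, y == "benign")$estimate, tolerance = 1e-12)
  })
})

test_that("label-independent probabilities score near chance", {
  with_seed_test(8, {
    y <- factor(rep(CLS, each = 100), levels = CLS)
    vals <- vapply(1:10, function(i) {
      P <- matrix(rgamma(1600, 1), 400, 4)
      P <- P / rowSums(P); colnames(P) <- CLS
      polytomous_c_index(P, y)$estimate
    }, numeric(1))
    expect_lt(abs(mean(vals) - 0.25), 0.02)
  })
})

test_that("pairwise c-indexes use the conditional probability ratio", {
  y <- factor(rep(CLS, each = 3), levels = CLS)
  P <- diag(4)[as.integer(y), ] * 0.9 + 0.025
  colnames(P) <- CLS
  res <- pairwise_c_indexes(P, y)
  expect_named(res, c("benign_vs_borderline", "benign_vs_primary_invasive",
                      "benign_vs_metastatic",
                      "borderline_vs_primary_invasive",
                      "borderline_vs_metastatic",
                      "primary_invasive_vs_metastatic"))
  expect_true(all(vapply(res, function(r) r$estimate, numeric(1)) == 1))
  # uniform probabilities: all ties, credit one half
  Pu <- matrix(0.25, 12, 4, dimnames = list(NULL, CLS))
  resu <- pairwise_c_indexes(Pu, y)
  expect_true(all(vapply(resu, function(r) r$estimate, numeric(1)) == 0.5))
  # composition oracle on a small fixture
  with_seed_test(5, {
    P3 <- matrix(runif(48), 12, 4); P3 <- P3 / rowSums(P3)
    colnames(P3) <- CLS
    res3 <- pairwise_c_indexes(P3, y)
    sel <- y %in% c("benign", "borderline")
    manual <- c_index(P3[sel, 1] / (P3[sel, 1] + P3[sel, 2]),
                      y[sel] == "benign")$estimate
    expect_equal(res3$benign_vs_borderline$estimate, manual)
  })
  # label-permutation equivariance: relabelling events relabels the pair
  # c-indexes without changing their values
  perm <- c(2, 1, 4, 3)   # swap benign<->borderline, primary<->metastatic
  yp <- factor(CLS[perm][as.integer(y)], levels = CLS)
  with_seed_test(5, {
    P3 <- matrix(runif(48), 12, 4); P3 <- P3 / rowSums(P3)
    colnames(P3) <- CLS
    a <- pairwise_c_indexes(P3, y)
    Pp <- P3[, order(perm)]; colnames(Pp) <- CLS
    b <- pairwise_c_indexes(Pp, yp)
    expect_equal(b$benign_vs_borderline$estimate,
                 a$benign_vs_borderline$estimate)
    expect_equal(b$primary_invasive_vs_metastatic$estimate,
                 a$primary_invasive_vs_metastatic$estimate)
  })
})

test_that("benign-versus-malignant collapses the malignant events", {
  y <- factor(rep(CLS, each = 2), levels = CLS)
  P <- diag(4)[as.integer(y), ]; colnames(P) <- CLS
  expect_equal(benign_vs_malignant_c(P, y)$estimate, 1)
  Pc <- matrix(0.25, 8, 4, dimnames = list(NULL, CLS))
  expect_equal(benign_vs_malignant_c(Pc, y)$estimate, 0.5)
  # equals c_index on the collapsed labels
  with_seed_test(3, {
    Pr <- matrix(runif(32), 8, 4); Pr <- Pr / rowSums(Pr)
    colnames(Pr) <- CLS
    expect_equal(benign_vs_malignant_c(Pr, y)$estimate,
                 c_index(1 - Pr[, "benign"], y != "benign")$estimate)
  })
})

test_that("calibration curves track observed frequencies", {
  with_seed_test(21, {
    p <- runif(10000)
    y <- rbinom(10000, 1, p)
    cc <- calibration_curve(p, y)
    interior <- cc$predicted > 0.05 & cc$predicted < 0.95
    expect_lt(max(abs(cc$observed - cc$predicted)[interior]), 0.05)
    # sharp threshold outcome: low grid points near 0, high near 1
    y2 <- as.numeric(p > 0.5)
    cc2 <- calibration_curve(p, y2)
    expect_lt(max(cc2$observed[cc2$predicted < 0.3]), 0.3)
    expect_gt(min(cc2$observed[cc2$predicted > 0.7]), 0.7)
  })
  # constant outcome gives the constant curve
  ccl <- calibration_curve(seq(0, 1, length.out = 50), rep(1, 50))
  expect_equal(ccl$observed, rep(1, 100), tolerance = 1e-8)
  expect_error(calibration_curve(rep(0.4, 50), rbinom(50, 1, 0.4)),
               "constant")
  expect_error(calibration_curve(runif(5), rbinom(5, 1, 0.5)),
               "at least 10")
})

test_that("stratified percentile bootstrap behaves", {
  # constant metric: zero-width interval
  ci <- bootstrap_ci(function(ix) 0.5, n = 40, B = 100, seed = 1)
  expect_equal(ci$lower, 0.5)
  expect_equal(ci$upper, 0.5)
  # interval contains the point estimate across random fixtures
  with_seed_test(6, {
    for (i in 1:25) {
      x <- rnorm(40)
      ci <- bootstrap_ci(function(ix) mean(x[ix]), n = 40, B = 200,
                         seed = i)
      expect_true(ci$lower <= mean(x) && mean(x) <= ci$upper)
    }
  })
  # paired difference of identical metrics is identically zero
  x <- rnorm(30)
  dci <- bootstrap_diff_ci(function(ix) mean(x[ix]),
                           function(ix) mean(x[ix]), n = 30, B = 100,
                           seed = 2)
  expect_equal(dci$lower, 0)
  expect_equal(dci$upper, 0)
  expect_error(bootstrap_ci(function(ix) 1, n = 10, B = 50), "at least 100")
})

test_that("bootstrap coverage for a normal mean is near nominal", {
  with_seed_test(13, {
    hits <- 0; nsim <- 300
    for (i in 1:nsim) {
      x <- rnorm(40, mean = 1)
      ci <- bootstrap_ci(function(ix) mean(x[ix]), n = 40, B = 200,
                         seed = i)
      if (ci$lower <= 1 && 1 <= ci$upper) hits <- hits + 1
    }
    expect_gt(hits / nsim, 0.88)
    expect_lt(hits / nsim, 0.99)
  })
})
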