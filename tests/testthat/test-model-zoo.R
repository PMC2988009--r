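fit_fixture <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$sp)) {
      ds <- simulate_cohort(n = 360, seed = 71)
      cache$sp <- stratified_split(ds, 0.71, seed = 72)
    }
    cache$sp
  }
})

VARS3 <- c("solid_diameter", "ascites", "age")

test_that("fixed-variable development honors the requested lists", {
  sp <- fit_fixture()
  m <- polyrisk(sp$train, method = "MLR", variables = VARS3, seed = 1)
  expect_equal(m$variables, VARS3)
  expect_s3_class(m$components, "mnlogit_fit")

  m2 <- suppressWarnings(polyrisk(sp$train, method = "LR-PC",
                                  variables = VARS3, seed = 1))
  expect_s3_class(m2$components, "ovo_ensemble")
  expect_length(m2$components$models, 6)
  expect_true(all(vapply(m2$variables, identical, logical(1), VARS3)))
})

test_that("prediction delegates to the component models", {
  sp <- fit_fixture()
  m <- polyrisk(sp$train, method = "MLR", variables = VARS3, seed = 1)
  P <- predict(m, sp$test)
  direct <- predict(m$components, sp$test)[, m$classes]
  expect_equal(unname(P), unname(direct))

  m2 <- suppressWarnings(polyrisk(sp$train, method = "LR-PC",
                                  variables = VARS3, seed = 1))
  P2 <- predict(m2, sp$test)
  expect_equal(unname(P2), unname(predict_coupled(m2$components, sp$test)))
  expect_lt(max(abs(rowSums(P2) - 1)), 1e-10)
  expect_true(all(P2 >= -1e-12))

  m3 <- suppressWarnings(polyrisk(sp$train, method = "nested-LR",
                                  variables = VARS3, seed = 1))
  P3 <- predict(m3, sp$test)
  expect_equal(unname(rowSums(P3)), rep(1, nrow(P3)), tolerance = 1e-12)
})

test_that("development is reproducible end to end under a seed", {
  sp <- fit_fixture()
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  m1 <- suppressWarnings(polyrisk(sp$train, method = "LR-PC", budget = 4,
                                  min_per_pair = 2, select_runs = 1,
                                  seed = 5))
  m2 <- suppressWarnings(polyrisk(sp$train, method = "LR-PC", budget = 4,
                                  min_per_pair = 2, select_runs = 1,
                                  seed = 5))
  write_model(m1, f1); write_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("serialized models predict identically after reload", {
  sp <- fit_fixture()
  for (mth in c("MLR", "LSSVM-PC", "KLR-PC")) {
    m <- suppressWarnings(polyrisk(sp$train, method = mth,
                                   variables = VARS3,
                                   gamma_grid = c(0.1, 1, 10),
                                   lambda_grid = c(0.1, 1, 10), seed = 1))
    f <- withr::local_tempfile(fileext = ".json")
    write_model(m, f)
    m2 <- read_model(f)
    expect_equal(predict(m2, sp$test), predict(m, sp$test),
                 tolerance = 1e-12)
  }
})

test_that("validation reports every metric of the evaluation suite", {
  sp <- fit_fixture()
  m <- suppressWarnings(polyrisk(sp$train, method = "LR-PC",
                                 variables = VARS3, seed = 1))
  rep <- validate_model(m, sp$test, bootstrap = 100, seed = 3)
  expect_s3_class(rep, "polyrisk_report")
  expect_true(rep$polytomous$estimate >= 0 && rep$polytomous$estimate <= 1)
  expect_length(rep$pairwise, 6)
  expect_false(is.null(rep$polytomous$ci))
  expect_lte(rep$polytomous$ci$lower, rep$polytomous$estimate)
  expect_gte(rep$polytomous$ci$upper, rep$polytomous$estimate)
  expect_length(rep$calibration, 4)
  row <- report_row(rep)
  expect_true(all(c("polytomous_c", "benign_vs_malignant",
                    "benign_vs_borderline") %in% names(row)))
})

test_that("a perfect classifier scores 1.0 and a prevalence-only
           classifier no better than chance", {
  bd <- block_design(6)
  df <- as.data.frame(bd$X)
  df$outcome <- bd$y
  ds <- risk_dataset(df, schema = stats::setNames(
    rep("binary", 4), colnames(bd$X)))
  m <- suppressWarnings(polyrisk(ds, method = "MLR",
                                 variables = colnames(bd$X), seed = 1))
  rep <- validate_model(m, ds)
  expect_equal(rep$polytomous$estimate, 1)
  expect_true(all(vapply(rep$pairwise, function(r) r$estimate,
                         numeric(1)) == 1))

  # intercept-only model: constant rows carry no discrimination, and under
  # the strict tie rule score 0 (a continuous random classifier scores
  # 0.25, the chance anchor)
  sp <- fit_fixture()
  m0 <- polyrisk(sp$train, method = "MLR", variables = character(0),
                 seed = 1)
  rep0 <- validate_model(m0, sp$test)
  expect_lte(rep0$polytomous$estimate, 0.25)
})

test_that("pair-specific signals favor the one-versus-one decomposition", {
  # a variable that only separates borderline from metastatic, on top of
  # a weak shared signal: the coupled ensemble can use it where it helps
  d <- with_seed_test(83, {
    y <- factor(rep(CLS, c(120, 40, 60, 40)), levels = CLS)
    n <- length(y)
    shared <- as.integer(y %in% CLS[3:4]) * 0.8 + rnorm(n)
    pairv <- ifelse(y == "borderline", 1.5, ifelse(y == "metastatic",
                                                   -1.5, 0)) + rnorm(n)
    df <- data.frame(shared = shared, pairv = pairv, outcome = y)
    risk_dataset(df, schema = c(shared = "continuous",
                                pairv = "continuous"))
  })
  sp <- stratified_split(d, 0.6, seed = 9)
  m_pc <- suppressWarnings(polyrisk(sp$train, method = "LR-PC",
                                    variables = c("shared", "pairv"),
                                    seed = 1))
  r_pc <- validate_model(m_pc, sp$test)
  expect_gt(r_pc$pairwise$borderline_vs_metastatic$estimate, 0.7)
})
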