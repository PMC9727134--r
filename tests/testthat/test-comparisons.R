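test_that("welch_ttest matches the closed-form worked example", {
  res <- welch_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t_statistic, -3.674235, tolerance = 1e-6)
  expect_equal(res$degrees_of_freedom, 4, tolerance = 1e-10)
  expect_equal(res$p_value, 0.021312, tolerance = 1e-4)
  expect_equal(unname(res$group_means), c(2, 5))
  expect_equal(unname(res$group_ses), rep(sqrt(1 / 3), 2), tolerance = 1e-12)
})

test_that("welch_ttest null identity and degenerate conventions", {
  x <- c(3, 1, 4, 1, 5)
  res <- welch_ttest(x, x)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  # both constant and equal -> t = 0, p = 1 by convention
  eq <- welch_ttest(rep(2, 3), rep(2, 4))
  expect_equal(eq$t_statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_true(eq$degenerate)
  # both constant and unequal -> flagged non-finite
  ne <- welch_ttest(rep(30, 3), rep(40, 3))
  expect_true(ne$degenerate)
  expect_true(is.infinite(ne$t_statistic) && ne$t_statistic < 0)
  expect_true(is.na(ne$p_value))
  expect_error(welch_ttest(1, c(1, 2)), ">= 2")
})

test_that("welch_ttest properties: antisymmetry and df bound", {
  set.seed(51)
  for (i in 1:50) {
    nx <- sample(2:15, 1); ny <- sample(2:15, 1)
    x <- rnorm(nx, sd = runif(1, 0.5, 3))
    y <- rnorm(ny, sd = runif(1, 0.5, 3))
    a <- welch_ttest(x, y); b <- welch_ttest(y, x)
    expect_equal(a$t_statistic, -b$t_statistic, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    expect_lte(a$degrees_of_freedom, nx + ny - 2 + 1e-9)
    expect_gt(a$degrees_of_freedom, min(nx, ny) - 1 - 1e-9)
  }
  # equality case of the df bound: equal variances and sizes
  x <- c(1, 2, 3, 4); y <- c(11, 12, 13, 14)
  expect_equal(welch_ttest(x, y)$degrees_of_freedom, 6, tolerance = 1e-10)
})

test_that("welch_ttest agrees with the independent oracle on random instances", {
  set.seed(52)
  for (i in 1:50) {
    x <- rnorm(sample(3:20, 1), mean = runif(1, -2, 2), sd = runif(1, 0.3, 3))
    y <- rnorm(sample(3:20, 1), mean = runif(1, -2, 2), sd = runif(1, 0.3, 3))
    mine <- welch_ttest(x, y)
    ref <- oracle_welch(x, y)
    expect_equal(mine$t_statistic, ref$t, tolerance = 1e-10)
    expect_equal(mine$degrees_of_freedom, ref$df, tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p, tolerance = 1e-10)
  }
})

test_that("regression_fit: exact-fit and flat-response conventions", {
  x <- c(20, 30, 40, 50)
  perfect <- regression_fit(x, x)
  expect_equal(perfect$slope, 1)
  expect_equal(perfect$intercept, 0)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$adjusted_r_squared, 1)
  expect_equal(perfect$slope_p_value, 0)
  flat <- regression_fit(x, rep(33, 4))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_true(flat$degenerate)
  expect_error(regression_fit(c(30, 30, 30), c(1, 2, 3)), "constant chronological")
  expect_error(regression_fit(c(1, 2), c(1, 2)), "n >= 3")
})

test_that("regression_fit agrees with the least-squares oracle", {
  # frozen worked case
  fit <- regression_fit(c(20, 30, 40, 50), c(22, 29, 41, 49))
  ref <- oracle_ols(c(20, 30, 40, 50), c(22, 29, 41, 49))
  expect_equal(fit$slope, ref$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, ref$intercept, tolerance = 1e-10)
  expect_equal(fit$r_squared, ref$r2, tolerance = 1e-10)
  expect_equal(fit$adjusted_r_squared, ref$adj_r2, tolerance = 1e-10)
  expect_equal(fit$slope_p_value, ref$p, tolerance = 1e-10)
  # random instances + invariants
  set.seed(53)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    x <- runif(n, 18, 60)
    y <- 0.8 * x + rnorm(n, sd = runif(1, 0.5, 5))
    fit <- regression_fit(x, y)
    ref <- oracle_ols(x, y)
    expect_equal(fit$slope, ref$slope, tolerance = 1e-8)
    expect_equal(fit$r_squared, ref$r2, tolerance = 1e-8)
    expect_equal(fit$adjusted_r_squared, ref$adj_r2, tolerance = 1e-8)
    expect_equal(fit$slope_p_value, ref$p, tolerance = 1e-8)
    # r2 equals squared Pearson correlation
    expect_equal(fit$r_squared, cor(x, y)^2, tolerance = 1e-12)
    # adjusted r2 identity and sample-order invariance
    expect_equal(fit$adjusted_r_squared,
                 1 - (1 - fit$r_squared) * (n - 1) / (n - 2), tolerance = 1e-12)
    o <- sample(n)
    expect_equal(regression_fit(x[o], y[o])$slope, fit$slope, tolerance = 1e-12)
  }
})

test_that("glad_group_test validates tissue and groups", {
  b <- generate_cohort(light_config(seed = 54))
  res <- analyze_cohort(b)
  expect_error(glad_group_test(res$glad, "muscle"), "unknown tissue")
  sub <- res$glad[res$glad$group == "normozoospermic", ]
  expect_error(glad_group_test(sub, "sperm"), "group absent")
  tst <- glad_group_test(res$glad, "sperm")
  expect_s3_class(tst, "tsage_test")
  expect_equal(unname(tst$n), c(10, 24))
})

test_that("run_comparisons assembles all six components", {
  b <- generate_cohort(light_config(seed = 55))
  res <- analyze_cohort(b)
  rep_ <- res$report
  expect_s3_class(rep_, "comparison_report")
  for (nm in c("sperm_glad_test", "blood_glad_test", "predicted_difference_test",
               "age_confound")) {
    expect_s3_class(rep_[[nm]], "tsage_test")
  }
  expect_s3_class(rep_$sperm_regression, "tsage_regression")
  expect_s3_class(rep_$blood_regression, "tsage_regression")
  df <- as.data.frame(rep_)
  expect_equal(nrow(df), 6)
  expect_true(all(df$p[!is.na(df$p)] >= 0 & df$p[!is.na(df$p)] <= 1))
})

test_that("run_comparisons: partial inputs and minimal-n path", {
  b <- generate_cohort(light_config(seed = 56, n_oligo = 2, n_normo = 2))
  res <- analyze_cohort(b)
  expect_s3_class(res$report$sperm_glad_test, "tsage_test")
  # missing blood predictions -> dependent components marked not-evaluated
  b2 <- generate_cohort(light_config(seed = 57))
  preds <- apply_clock(b2$true_sperm_clock, b2$sperm_betas, sheet = b2$sheet)
  glad <- glad_table(preds, b2$sheet)
  rep2 <- run_comparisons(glad, preds, b2$sheet)
  expect_s3_class(rep2$blood_glad_test, "tsage_not_evaluated")
  expect_s3_class(rep2$predicted_difference_test, "tsage_not_evaluated")
  expect_s3_class(rep2$blood_regression, "tsage_not_evaluated")
  expect_s3_class(rep2$sperm_glad_test, "tsage_test")
})

test_that("bonferroni option reports adjusted p alongside raw", {
  b <- generate_cohort(light_config(seed = 58))
  res <- analyze_cohort(b)
  rep_ <- run_comparisons(res$glad, res$predictions, b$sheet, bonferroni = TRUE)
  expect_equal(rep_$sperm_glad_test$p_bonferroni,
               min(1, rep_$sperm_glad_test$p_value * 4))
})

test_that("report writers emit JSON, markdown and TSV", {
  b <- generate_cohort(light_config(seed = 59))
  res <- analyze_cohort(b)
  prefix <- file.path(tempfile(), "report")
  dir.create(dirname(prefix))
  paths <- write_comparison_report(res$report, prefix)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[1])
  expect_equal(js$sperm_glad_test$p_value, res$report$sperm_glad_test$p_value,
               tolerance = 1e-12)
  unlink(dirname(prefix), recursive = TRUE)
})
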