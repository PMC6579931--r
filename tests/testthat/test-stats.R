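test_that("Spearman matrix recovers monotone relationships exactly", {
  d <- tibble::tibble(x = c(3, 1, 4, 1.5, 9, 2.6), y = 2 * c(3, 1, 4, 1.5, 9, 2.6))
  d$z <- -d$x^3
  cm <- spearman_matrix(d)
  expect_equal(cm$rho["x", "y"], 1)
  expect_equal(cm$rho["x", "z"], -1)
})

test_that("Spearman coefficients match the textbook rank formula", {
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    cm <- spearman_matrix(tibble::tibble(x = x, y = y))
    expect_equal(cm$rho["x", "y"], oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("Bonferroni correction never increases the significant count", {
  set.seed(8)
  d <- as.data.frame(matrix(rnorm(40 * 6), 40))
  d$V7 <- d$V1 + rnorm(40, 0, 0.3)
  cm <- spearman_matrix(d)
  expect_lte(sum(cm$significant_corrected), sum(cm$significant_raw))
  td <- tidy(cm)
  expect_equal(nrow(td), choose(7, 2))
  expect_true(all(td$p_bonferroni >= td$p_raw, na.rm = TRUE))
  expect_true(all(td$p_bonferroni <= 1, na.rm = TRUE))
})

test_that("constant variables give NA correlations, invariant under monotone maps", {
  d <- tibble::tibble(x = rnorm(20), y = rnorm(20), k = rep(1, 20))
  cm <- spearman_matrix(d)
  expect_true(is.na(cm$rho["x", "k"]))
  d2 <- d
  d2$x <- exp(d$x)  # strictly monotone transform
  cm2 <- spearman_matrix(d2)
  expect_equal(cm$rho["x", "y"], cm2$rho["x", "y"], tolerance = 1e-12)
})

test_that("a perfect log-log line gives R^2 = 1 and partial eta^2 = 1", {
  d <- tibble::tibble(x = seq(90, 130, length.out = 20))
  d$y <- exp(2 * log(d$x) - 5)
  f <- suppressWarnings(fit_baseline_regression(d, "y", "x"))
  expect_equal(unname(f$partial_eta_sq[1]), 1, tolerance = 1e-9)
  expect_equal(suppressWarnings(glance(f))$r_squared, 1, tolerance = 1e-9)
  expect_true(f$transform_applied)
})

test_that("partial eta^2 equals the squared correlation for one predictor", {
  set.seed(11)
  d <- tibble::tibble(x = exp(rnorm(60, 4.6, 0.1)))
  d$y <- exp(0.5 * log(d$x) + rnorm(60, 0, 0.2))
  f <- fit_baseline_regression(d, "y", "x")
  expect_equal(unname(f$partial_eta_sq[1]), cor(log(d$x), log(d$y))^2,
               tolerance = 1e-12)
})

test_that("the regression F-test holds its nominal size under permutation", {
  set.seed(21)
  n <- 40
  x <- exp(rnorm(n, 4.6, 0.12))
  y <- exp(rnorm(n, 3.4, 0.5))
  rejections <- vapply(1:1000, function(i) {
    d <- tibble::tibble(x = sample(x), y = y)
    f <- fit_baseline_regression(d, "y", "x")
    f$f_stats$p[1] <= 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.015)
})

test_that("log transform rejects non-positive values with subject ids", {
  d <- tibble::tibble(subject_id = c("a", "b", "c", rep("x", 9)),
                      y = c(-1, 2, 3, rep(4, 9)), x = rep(2, 12))
  err <- tryCatch(fit_baseline_regression(d, "y", "x"),
                  error = function(e) e)
  expect_s3_class(err, "cvcreact_transform_error")
  expect_match(conditionMessage(err), "a")
})

test_that("stepwise selection finds a strong single signal and stays sparse under the null", {
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    d <- as.data.frame(matrix(rnorm(100 * 4), 100))
    names(d) <- paste0("b", 1:4)
    d$y <- 1.2 * d$b3 + rnorm(100, 0, 0.8)
    sel <- stepwise_branch_selection(d, "y", paste0("b", 1:4))$selected
    "b3" %in% sel
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  sizes <- vapply(1:50, function(s) {
    set.seed(s + 300)
    d <- as.data.frame(matrix(rnorm(100 * 4), 100))
    names(d) <- paste0("b", 1:4)
    d$y <- rnorm(100)
    length(stepwise_branch_selection(d, "y", paste0("b", 1:4))$selected)
  }, numeric(1))
  expect_lte(median(sizes), 1)
})

test_that("stepwise keeps exactly one of two duplicated predictors", {
  set.seed(9)
  d <- tibble::tibble(b1 = rnorm(80))
  d$b2 <- d$b1  # perfectly collinear duplicate
  d$b3 <- rnorm(80)
  d$y <- d$b1 + rnorm(80, 0, 0.5)
  sel <- stepwise_branch_selection(d, "y", c("b1", "b2", "b3"))$selected
  expect_equal(sum(c("b1", "b2") %in% sel), 1)
})

test_that("LASSO screening recovers signal covariates and shrinks noise away", {
  hits <- vapply(1:30, function(s) {
    set.seed(s)
    d <- tibble::tibble(age = rnorm(100), gender = sample(c("f", "m"), 100, TRUE),
                        caffeine = sample(c("no", "yes"), 100, TRUE),
                        time_of_day = runif(100, 8, 18))
    d$y <- 0.8 * d$age + rnorm(100)
    scr <- lasso_covariate_screen(d, "y", c("gender", "age", "caffeine",
                                            "time_of_day"), seed = s)
    "age" %in% scr$selected
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  null_sizes <- vapply(1:30, function(s) {
    set.seed(s + 900)
    d <- tibble::tibble(age = rnorm(100), gender = sample(c("f", "m"), 100, TRUE),
                        caffeine = sample(c("no", "yes"), 100, TRUE),
                        time_of_day = runif(100, 8, 18), y = rnorm(100))
    length(lasso_covariate_screen(d, "y", c("gender", "age", "caffeine",
                                            "time_of_day"), seed = s)$selected)
  }, numeric(1))
  expect_lte(mean(null_sizes), 0.5)
})

test_that("LASSO screening is skipped with a warning below 20 subjects", {
  d <- tibble::tibble(age = rnorm(10), y = rnorm(10),
                      gender = sample(c("f", "m"), 10, TRUE))
  expect_warning(scr <- lasso_covariate_screen(d, "y", c("age", "gender")),
                 "skipped")
  expect_length(scr$selected, 0)
})
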