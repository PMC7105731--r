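test_that("ols_fit agrees with lm on a random table", {
  tab <- random_table(80, seed = 2)
  fit <- ols_fit(tab, "sv", c("df", "ps", "filament"))
  ref <- lm(sv ~ df + ps + filament, data = tab)
  expect_equal(fit$coefficients$B, unname(coef(ref)[-1]), tolerance = 1e-10)
  expect_equal(fit$intercept[["B"]], unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(fit$model$R2, summary(ref)$r.squared, tolerance = 1e-10)
  expect_equal(fit$model$adjR2, summary(ref)$adj.r.squared, tolerance = 1e-10)
  expect_equal(fit$coefficients$SE,
               unname(summary(ref)$coefficients[-1, 2]), tolerance = 1e-10)
})

test_that("fit_from_summary reproduces ols_fit from the table's own moments", {
  tab <- random_table(60, seed = 5)
  preds <- c("apd", "df", "ps")
  direct <- ols_fit(tab, "amptens", preds)
  s <- summary_stats(colMeans(tab), vapply(tab, sd, numeric(1)),
                     pearson_matrix(tab)$r, n = nrow(tab))
  fromsum <- fit_from_summary(s, "amptens", preds)
  expect_equal(fromsum$coefficients$beta, direct$coefficients$beta,
               tolerance = 1e-8)
  expect_equal(fromsum$coefficients$B, direct$coefficients$B,
               tolerance = 1e-8)
  expect_equal(fromsum$model$R2, direct$model$R2, tolerance = 1e-8)
  expect_equal(fromsum$coefficients$VIF, direct$coefficients$VIF,
               tolerance = 1e-8)
})

test_that("VIF equals 1 / (1 - R2) of each predictor on the others", {
  tab <- random_table(100, seed = 7)
  preds <- c("apd", "df", "ps", "filament")
  fit <- ols_fit(tab, "sv", preds)
  manual <- vapply(preds, function(p) {
    r2 <- summary(lm(stats::reformulate(setdiff(preds, p), p),
                     data = tab))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(fit$coefficients$VIF, unname(manual), tolerance = 1e-8)
  expect_equal(fit$coefficients$tolerance, unname(1 / manual),
               tolerance = 1e-8)
})

test_that("summary_stats validates dimensions and names", {
  m <- c(a = 1, b = 2); s <- c(a = 1, b = 1)
  r <- diag(2); dimnames(r) <- list(c("a", "b"), c("a", "b"))
  expect_s3_class(summary_stats(m, s, r, n = 10), "vt_summary_stats")
  expect_error(summary_stats(m, s[1], r, n = 10))
  expect_error(summary_stats(m, s, r[1, , drop = FALSE], n = 10))
  expect_error(summary_stats(m, s, r, n = 1))
})

test_that("pearson_matrix agrees with cor()", {
  tab <- random_table(50, seed = 3)
  pm <- pearson_matrix(tab)
  expect_equal(pm$r, cor(tab), tolerance = 1e-12)
})

test_that("analyze on the packaged summary includes the anchor comparison", {
  a <- analyze(printed_summary())
  expect_s3_class(a, "vt_analysis")
  expect_equal(a$dropped, "apd")
  expect_true(a$full$flagged)
  expect_s3_class(a$reproduction, "vt_reproduction")
  expect_setequal(a$screened$predictors, c("df", "ps", "filament"))
})

test_that("analyze drops all-NA columns with a note and still fits", {
  tab <- gen_correlated_table(100, seed = 8)
  tab$filament <- NA_real_
  a <- analyze(tab)
  expect_true(any(grepl("filament", a$notes)))
  expect_false("filament" %in% colnames(a$summary$r))
})
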