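## Regression engine: Pearson correlation tables, OLS with standardized
## coefficients and collinearity diagnostics (tolerance/VIF), ANOVA F,
## Durbin-Watson, and a closed form that fits the same models directly from
## summary statistics (means, SDs, correlation matrix) so that printed
## regression tables can be reproduced without the raw 48-case dataset.

.vt_vars <- c("apd", "df", "ps", "filament", "sv", "amptens")

#' Summary statistics container
#'
#' Per-variable means and sample SDs plus a Pearson correlation matrix; the
#' sufficient statistics for every model fitted by [fit_from_summary()].
#'
#' @param mean,sd named numeric vectors (same names, same order).
#' @param r symmetric correlation matrix with unit diagonal, dimnames matching.
#' @param n number of cases the statistics summarize.
#' @param p optional matrix of two-sided correlation p-values.
#' @return an object of class `vt_summary_stats`.
#' @export
summary_stats <- function(mean, sd, r, n, p = NULL) {
  v <- names(mean)
  stopifnot(!is.null(v), identical(names(sd), v),
            identical(rownames(r), v), identical(colnames(r), v))
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must be <= 1")
  if (max(abs(r - t(r))) > 1e-12) stop("correlation matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-12) stop("correlation matrix diagonal must be 1")
  if (any(sd <= 0)) stop("SDs must be positive")
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n < 2)
    stop("n must be a single sample size of at least 2")
  structure(list(mean = mean, sd = sd, r = r, p = p, n = n),
            class = "vt_summary_stats")
}

#' @export
print.vt_summary_stats <- function(x, digits = 3, ...) {
  cat("<vt_summary_stats> n =", x$n, "\n")
  m <- rbind(mean = x$mean, sd = x$sd)
  print(round(m, digits))
  cat("Pearson correlation matrix:\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Pearson correlation matrix with p-values and marginal moments
#'
#' Pairwise Pearson correlations with two-sided p-values from the t
#' distribution on n - 2 degrees of freedom, plus per-column means and sample
#' SDs (divisor n - 1).
#'
#' @param table data frame of numeric columns (a feature table).
#' @return a [summary_stats()] object.
#' @export
pearson_matrix <- function(table) {
  num <- table[vapply(table, is.numeric, logical(1))]
  n <- nrow(num)
  if (n < 3) stop("need at least 3 cases")
  sds <- vapply(num, sd, numeric(1))
  if (any(sds == 0))
    stop("undefined correlation: zero-variance column(s): ",
         paste(names(num)[sds == 0], collapse = ", "))
  r <- cor(as.matrix(num))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- NA
  summary_stats(mean = colMeans(num), sd = sds, r = r, n = n, p = p)
}

.fit_report <- function(response, predictors, n, B, SE, beta, tval, pval,
                        tol, vif, b0, se0, t0, p0, R2, se_est, dw = NA_real_,
                        method = "raw") {
  p <- length(predictors)
  df2 <- n - p - 1
  Fstat <- (R2 / p) / ((1 - R2) / df2)
  out <- list(
    response = response, predictors = predictors, n = n, method = method,
    coefficients = data.frame(
      term = predictors, B = B, SE = SE, beta = beta, t = tval, p = pval,
      tolerance = tol, VIF = vif, row.names = NULL),
    intercept = c(B = b0, SE = se0, t = t0, p = p0),
    model = list(R = sqrt(R2), R2 = R2,
                 adjR2 = 1 - (1 - R2) * (n - 1) / df2,
                 se_est = se_est, F = Fstat, df1 = p, df2 = df2,
                 pF = pf(Fstat, p, df2, lower.tail = FALSE),
                 durbin_watson = dw))
  class(out) <- "vt_fit"
  out
}

#' @export
print.vt_fit <- function(x, digits = 3, ...) {
  cat("<vt_fit> ", x$response, " ~ ", paste(x$predictors, collapse = " + "),
      "   (", x$method, ", n = ", x$n, ")\n", sep = "")
  cf <- x$coefficients
  cf[-1] <- lapply(cf[-1], signif, digits + 1)
  print(cf, row.names = FALSE)
  cat(sprintf("intercept B = %.4g (SE %.3g, t %.3g, p %.3g)\n",
              x$intercept["B"], x$intercept["SE"], x$intercept["t"],
              x$intercept["p"]))
  m <- x$model
  cat(sprintf("R = %.3f  R2 = %.3f  adjR2 = %.3f  SE = %.5g  F(%d,%d) = %.3f  p = %.3g",
              m$R, m$R2, m$adjR2, m$se_est, m$df1, m$df2, m$F, m$pF))
  if (is.finite(m$durbin_watson)) cat(sprintf("  DW = %.3f", m$durbin_watson))
  cat("\n")
  invisible(x)
}

#' Ordinary least squares with standardized coefficients and collinearity
#' diagnostics
#'
#' Fits `response ~ predictors` by OLS with intercept ("enter" method: all
#' predictors simultaneously) and reports, per predictor, the unstandardized
#' coefficient B with its SE, the standardized beta (B s_x / s_y), t and p,
#' and tolerance/VIF (VIF_j = 1 / (1 - R2_j) from regressing predictor j on
#' the remaining predictors). The model block carries R, R-squared, adjusted
#' R-squared, the SE of the estimate, the ANOVA F with its degrees of freedom
#' and p-value, and the Durbin-Watson statistic computed on residuals in table
#' row order.
#'
#' @param table data frame holding the variables.
#' @param response name of the dependent variable.
#' @param predictors character vector of predictor names.
#' @return a `vt_fit` report.
#' @export
ols_fit <- function(table, response, predictors) {
  n <- nrow(table)
  y <- table[[response]]
  X <- as.matrix(table[predictors])
  if (qr(cbind(1, X))$rank < ncol(X) + 1) {
    stop("singular design: linearly dependent columns among: ",
         paste(predictors, collapse = ", "))
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(sprintf("`%s`", predictors), collapse = "+")))
  fit <- lm(fml, data = table)
  sm <- summary(fit)
  cf <- sm$coefficients
  B <- cf[-1, 1]; SE <- cf[-1, 2]; tval <- cf[-1, 3]; pval <- cf[-1, 4]
  sy <- sd(y); sx <- apply(X, 2, sd)
  beta <- B * sx / sy
  p <- length(predictors)
  if (p > 1) {
    vif <- vapply(seq_len(p), function(j) {
      r2j <- summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
      1 / (1 - r2j)
    }, numeric(1))
  } else vif <- 1
  e <- stats::residuals(fit)
  dw <- if (sum(e^2) < 1e-25) NA_real_ else sum(diff(e)^2) / sum(e^2)
  .fit_report(response, predictors, n, B, SE, beta, tval, pval,
              1 / vif, vif, cf[1, 1], cf[1, 2], cf[1, 3], cf[1, 4],
              sm$r.squared, sm$sigma, dw, method = "raw")
}

#' Fit a regression model from summary statistics alone
#'
#' Closed-form OLS from means, SDs and the correlation matrix: standardized
#' coefficients beta = Rxx^-1 rxy, R2 = rxy' beta, VIF_j = the j-th diagonal
#' of Rxx^-1, B_j = beta_j s_y / s_x_j, intercept = ybar - sum B_j xbar_j,
#' SE(beta_j) = sqrt((1 - R2) [Rxx^-1]_jj / (n - p - 1)). Durbin-Watson needs
#' case ordering and is unavailable from summaries.
#'
#' @param summary a [summary_stats()] object (e.g. [printed_summary()]).
#' @param response,predictors variable names present in the summary.
#' @param n number of cases; defaults to the summary's own n.
#' @return a `vt_fit` report with `method = "summary"`.
#' @export
fit_from_summary <- function(summary, response, predictors, n = summary$n) {
  stopifnot(inherits(summary, "vt_summary_stats"))
  v <- c(response, predictors)
  miss <- setdiff(v, names(summary$mean))
  if (length(miss)) stop("variables not in summary: ", paste(miss, collapse = ", "))
  Rxx <- summary$r[predictors, predictors, drop = FALSE]
  rxy <- summary$r[predictors, response]
  if (kappa(Rxx, exact = TRUE) > 1e8)
    stop("collinearity: predictor correlation matrix is numerically singular")
  Rinv <- solve(Rxx)
  beta <- drop(Rinv %*% rxy)
  R2 <- sum(rxy * beta)
  p <- length(predictors); df2 <- n - p - 1
  vif <- diag(Rinv)
  sy <- summary$sd[response]; sx <- summary$sd[predictors]
  B <- beta * sy / sx
  se_beta <- sqrt((1 - R2) * vif / df2)
  tval <- beta / se_beta
  pval <- 2 * pt(-abs(tval), df2)
  SE <- se_beta * sy / sx
  se_est <- sy * sqrt((1 - R2) * (n - 1) / df2)
  xbar <- summary$mean[predictors]
  b0 <- summary$mean[response] - sum(B * xbar)
  # var(b0) = s^2 (1/n + xbar' [(n-1) Sxx]^-1 xbar), Sxx = D Rxx D
  Dm <- diag(sx, p)
  Sxx_inv <- solve(Dm %*% Rxx %*% Dm)
  se0 <- se_est * sqrt(1 / n + drop(t(xbar) %*% Sxx_inv %*% xbar) / (n - 1))
  t0 <- b0 / se0
  .fit_report(response, predictors, n, unname(B), unname(SE), unname(beta),
              unname(tval), unname(pval), unname(1 / vif), unname(vif),
              unname(b0), unname(se0), unname(t0),
              unname(2 * pt(-abs(t0), df2)), R2, unname(se_est),
              NA_real_, method = "summary")
}

## ------------------------------------------------------------------------
## Packaged printed constants: the 48-case correlation matrix and marginal
## moments of the six features, transcribed from the published summary.

#' Printed summary statistics of the 48-case tachyarrhythmia dataset
#'
#' The published correlation matrix and per-variable means/SDs of the six
#' features (APD ms, dominant frequency Hz, phase-singularity count, filament
#' count, stroke volume mL, tension amplitude kPa) across the 48 simulated
#' tachyarrhythmia cases. These are sufficient statistics for every
#' summary-derivable quantity of the printed regression tables.
#'
#' @return a [summary_stats()] object over variables
#'   `apd, df, ps, filament, sv, amptens` with n = 48.
#' @export
printed_summary <- function() {
  v <- .vt_vars
  r <- matrix(c(
    #  apd      df      ps   filament   sv   amptens
     1.000, -0.991,  0.284,  0.577,  0.859,  0.930,
    -0.991,  1.000, -0.268, -0.533, -0.809, -0.907,
     0.284, -0.268,  1.000,  0.795,  0.305,  0.146,
     0.577, -0.533,  0.795,  1.000,  0.713,  0.507,
     0.859, -0.809,  0.305,  0.713,  1.000,  0.887,
     0.930, -0.907,  0.146,  0.507,  0.887,  1.000), 6, 6,
    dimnames = list(v, v))
  summary_stats(
    mean = c(apd = 131.02, df = 5.59, ps = 49.98, filament = 12401.1,
             sv = 0.38, amptens = 0.41),
    sd = c(apd = 50.47, df = 1.15, ps = 24.49, filament = 7902.9,
           sv = 0.56, amptens = 0.38),
    r = r, n = 48)
}

# Printed regression anchors (single-variable models and the two admissible
# 3-predictor models) used by reproduce_printed_stats().
.printed_anchors <- function() {
  list(
    single = data.frame(
      model = c("A1", "A2", "A3", "A4", "B1", "B2", "B3"),
      response = c(rep("sv", 4), rep("amptens", 3)),
      predictor = c("apd", "df", "ps", "filament", "apd", "df", "filament"),
      B = c(0.010, -0.393, 0.007, 5.059e-5, 0.007, -0.299, 2.441e-5),
      beta = c(0.859, -0.809, 0.305, 0.713, 0.930, -0.907, 0.507),
      R2 = c(0.738, 0.655, 0.093, 0.509, 0.866, 0.822, 0.257),
      F = c(129.7, 87.4, 4.7, 47.6, 296.8, 212.9, 15.90)),
    multi = list(
      model2 = list(response = "sv", predictors = c("df", "ps", "filament"),
                    beta = c(df = -0.490, ps = -0.505, filament = 0.853),
                    VIF = c(df = 1.539, ps = 2.992, filament = 3.881),
                    tolerance = c(df = 0.650, ps = 0.334, filament = 0.258),
                    R2 = 0.851, adjR2 = 0.841),
      model4 = list(response = "amptens", predictors = c("df", "ps", "filament"),
                    beta = c(df = -0.813, ps = -0.353, filament = 0.354),
                    VIF = c(df = 1.539, ps = 2.992, filament = 3.881),
                    tolerance = c(df = 0.650, ps = 0.334, filament = 0.258),
                    R2 = 0.865, adjR2 = 0.856)))
}

#' Recompute printed regression quantities from the packaged summary statistics
#'
#' Fits every summary-derivable model of the printed regression tables (the
#' seven single-variable models and the two admissible 3-predictor models)
#' through [fit_from_summary()] using only the packaged correlation matrix and
#' means/SDs, and tabulates computed versus printed values with relative
#' deviations. The 4-predictor models are also fitted and their collinearity
#' flag reported, but their coefficients are numerically fragile (printed
#' inputs are 3-decimal rounded and the APD-DF correlation is -0.991) and are
#' not tabulated as anchors.
#'
#' @return a data frame of class `vt_reproduction` with columns `model`,
#'   `quantity`, `computed`, `printed`, `rel_dev`.
#' @export
reproduce_printed_stats <- function() {
  s <- printed_summary()
  an <- .printed_anchors()
  rows <- list()
  add <- function(model, quantity, computed, printed)
    rows[[length(rows) + 1]] <<- data.frame(
      model = model, quantity = quantity, computed = computed,
      printed = printed, rel_dev = (computed - printed) / abs(printed))
  for (i in seq_len(nrow(an$single))) {
    a <- an$single[i, ]
    f <- fit_from_summary(s, a$response, a$predictor)
    add(a$model, "B", f$coefficients$B, a$B)
    add(a$model, "beta", f$coefficients$beta, a$beta)
    add(a$model, "R2", f$model$R2, a$R2)
    add(a$model, "F", f$model$F, a$F)
  }
  for (nm in names(an$multi)) {
    a <- an$multi[[nm]]
    f <- fit_from_summary(s, a$response, a$predictors)
    for (j in seq_along(a$predictors)) {
      pj <- a$predictors[j]
      add(nm, paste0("beta(", pj, ")"), f$coefficients$beta[j], a$beta[[pj]])
      add(nm, paste0("VIF(", pj, ")"), f$coefficients$VIF[j], a$VIF[[pj]])
      add(nm, paste0("tolerance(", pj, ")"), f$coefficients$tolerance[j],
          a$tolerance[[pj]])
    }
    add(nm, "R2", f$model$R2, a$R2)
    add(nm, "adjR2", f$model$adjR2, a$adjR2)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("vt_reproduction", "data.frame")
  out
}

#' @export
print.vt_reproduction <- function(x, ...) {
  y <- x
  y$computed <- signif(y$computed, 5)
  y$rel_dev <- sprintf("%+.2f%%", 100 * y$rel_dev)
  NextMethod(object = y)
  cat(sprintf("max |relative deviation| = %.3f%%\n", 100 * max(abs(x$rel_dev))))
  invisible(x)
}
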