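# Wrap an lm into the package's fit container: per-term F tests (sequential
# sums of squares), partial eta-squared, information criteria, and residual
# diagnostics (skewness, kurtosis, Breusch-Pagan heteroscedasticity test).
as_cvc_fit <- function(fit, transform_applied = FALSE) {
  a <- anova(fit)
  terms_tab <- a[rownames(a) != "Residuals", , drop = FALSE]
  ss_res <- a["Residuals", "Sum Sq"]
  f_stats <- tibble(
    term = rownames(terms_tab),
    f = terms_tab[["F value"]],
    df1 = terms_tab[["Df"]],
    df2 = a["Residuals", "Df"],
    p = terms_tab[["Pr(>F)"]]
  )
  eta <- setNames(terms_tab[["Sum Sq"]] / (terms_tab[["Sum Sq"]] + ss_res),
                  rownames(terms_tab))
  cf <- summary(fit)$coefficients
  r <- resid(fit)
  diagnostics <- list(
    skewness = if (length(r) > 2) e1071::skewness(r) else NA_real_,
    kurtosis = if (length(r) > 3) e1071::kurtosis(r) else NA_real_,
    shapiro_p = if (length(r) >= 3 && length(r) <= 5000 && sd(r) > 0)
      stats::shapiro.test(r)$p.value else NA_real_,
    breusch_pagan_p = if (length(coef(fit)) > 1 && sd(r) > 0)
      tryCatch(lmtest::bptest(fit)$p.value, error = function(e) NA_real_)
      else NA_real_
  )
  structure(
    list(
      fit = fit,
      formula = deparse(stats::formula(fit)),
      coefficients = tibble(term = rownames(cf), estimate = cf[, 1], se = cf[, 2]),
      f_stats = f_stats,
      partial_eta_sq = eta,
      aic = AIC(fit),
      log_lik = as.numeric(logLik(fit)),
      n = length(r),
      transform_applied = transform_applied,
      diagnostics = diagnostics
    ),
    class = "cvc_fit"
  )
}

#' Baseline regression of a cardiac metric on an EI score
#'
#' Ordinary least squares of (optionally log-transformed) outcome on
#' (optionally log-transformed) predictor, with the predictor's F test,
#' partial eta-squared (`SS_effect / (SS_effect + SS_error)`), and residual
#' assumption diagnostics (skewness, kurtosis, Shapiro-Wilk, Breusch-Pagan).
#'
#' @param data A data frame with one row per subject.
#' @param outcome,predictor Column names (strings).
#' @param log_transform Log both variables before fitting (both must then be
#'   strictly positive).
#' @return A `cvc_fit`; see [tidy()] and [glance()].
#' @export
fit_baseline_regression <- function(data, outcome, predictor,
                                    log_transform = TRUE) {
  for (v in c(outcome, predictor)) {
    if (!v %in% names(data)) abort_config(sprintf("column '%s' not in data.", v))
  }
  df <- data.frame(y = data[[outcome]], x = data[[predictor]])
  ids <- if ("subject_id" %in% names(data)) data$subject_id else
    as.character(seq_len(nrow(data)))
  keep <- complete.cases(df)
  df <- df[keep, ]; ids <- ids[keep]
  if (nrow(df) < 10L) abort_insufficient("baseline regression needs n >= 10.")
  if (log_transform) {
    bad <- df$y <= 0 | df$x <= 0
    if (any(bad)) {
      abort(sprintf("non-positive values under log transform for subject(s): %s.",
                    paste(ids[bad], collapse = ", ")),
            class = "cvcreact_transform_error")
    }
    df$y <- log(df$y); df$x <- log(df$x)
  }
  names(df) <- c(outcome, predictor)
  fit <- lm(as.formula(paste0("`", outcome, "` ~ `", predictor, "`")), data = df)
  as_cvc_fit(fit, transform_applied = log_transform)
}

#' Stepwise selection among EI subscale predictors
#'
#' Bidirectional stepwise regression minimising AIC, starting from the
#' intercept-only model, used to pick which EI branch or composite scores
#' carry an association while limiting multicollinearity. Ties are broken
#' deterministically by candidate order. If no candidate improves AIC the
#' intercept-only model is returned.
#'
#' @param data A data frame with one row per subject.
#' @param outcome Outcome column name.
#' @param candidates Character vector (>= 2) of candidate predictor columns.
#' @param log_outcome Log-transform the outcome first.
#' @return A list with `fit` (a `cvc_fit` of the final model) and `selected`
#'   (character vector of retained candidates).
#' @export
stepwise_branch_selection <- function(data, outcome, candidates,
                                      log_outcome = FALSE) {
  if (length(candidates) < 2L) abort_config("need at least two candidate predictors.")
  cols <- c(outcome, candidates)
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    abort_config(sprintf("column(s) not in data: %s.", paste(miss, collapse = ", ")))
  }
  df <- data[cols]
  df <- df[complete.cases(df), ]
  if (log_outcome) df[[outcome]] <- log(df[[outcome]])
  null_fit <- lm(as.formula(paste0("`", outcome, "` ~ 1")), data = df)
  upper <- as.formula(paste0("~ ", paste0("`", candidates, "`", collapse = " + ")))
  final <- MASS::stepAIC(null_fit, scope = list(lower = ~1, upper = upper),
                         direction = "both", trace = 0)
  selected <- intersect(candidates, all.vars(stats::formula(final))[-1])
  list(fit = as_cvc_fit(final, transform_applied = log_outcome),
       selected = selected)
}

#' @export
tidy.cvc_fit <- function(x, ...) x$coefficients

#' @export
glance.cvc_fit <- function(x, ...) {
  s <- tryCatch(summary(x$fit), error = function(e) NULL)
  tibble(
    r_squared = if (!is.null(s) && !is.null(s$r.squared)) s$r.squared else NA_real_,
    aic = x$aic, log_lik = x$log_lik, n = x$n,
    transform_applied = x$transform_applied
  )
}

#' @exportS3Method base::print
print.cvc_fit <- function(x, ...) {
  cat("Model:", x$formula,
      if (x$transform_applied) "(log-transformed variables)" else "", "\n")
  cat(sprintf("n = %d, AIC = %.2f, logLik = %.2f\n", x$n, x$aic, x$log_lik))
  for (i in seq_len(nrow(x$f_stats))) {
    r <- x$f_stats[i, ]
    eta <- x$partial_eta_sq[[r$term]] %||% NA_real_
    cat(sprintf("  %s: F(%d,%d) = %.2f, p = %.3g, partial eta^2 = %.3f\n",
                r$term, r$df1, r$df2, r$f, r$p, eta))
  }
  invisible(x)
}

#' Scatter plot of a baseline regression
#'
#' @param x A `cvc_fit` from [fit_baseline_regression()].
#' @return A ggplot of the (transformed) data with the fitted line and 95%
#'   confidence band.
#' @export
plot_baseline_regression <- function(x) {
  df <- x$fit$model
  nm <- names(df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[nm[2]]], y = .data[[nm[1]]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, level = 0.95,
                         colour = "#2166AC") +
    ggplot2::labs(
      x = if (x$transform_applied) paste0("log(", nm[2], ")") else nm[2],
      y = if (x$transform_applied) paste0("log(", nm[1], ")") else nm[1]
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cvc_fit <- function(object, ...) plot_baseline_regression(object)
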