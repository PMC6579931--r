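#' Repeated-measures GLS across protocol conditions
#'
#' Fits a generalized-least-squares model for the three-condition repeated
#' measurement with homogeneous residual variance and an unstructured
#' (separately estimated) within-subject correlation, by REML. Marginal F
#' tests are reported per fixed-effect term. If the unstructured correlation
#' fails to converge, the model falls back to compound symmetry with a
#' warning. Heterogeneous per-condition variances and compound symmetry are
#' also available for sensitivity analysis.
#'
#' @param data Long-format data frame with one row per subject x condition.
#' @param formula Fixed-effects formula, e.g. `log(rmssd) ~ condition` or
#'   `log(rmssd) ~ condition * msceit_total`.
#' @param subject Name of the subject-identifier column.
#' @param condition Name of the condition column (3 levels per subject).
#' @param correlation `"unstructured"` (default) or `"compound_symmetry"`.
#' @param variance `"homogeneous"` (default) or `"heterogeneous"`.
#' @param method `"REML"` (default) or `"ML"`.
#' @return A `cvc_gls` object; see [tidy()], [glance()], and
#'   [compare_models()].
#' @export
fit_gls_repeated <- function(data, formula = log(rmssd) ~ condition,
                             subject = "subject_id", condition = "condition",
                             correlation = c("unstructured", "compound_symmetry"),
                             variance = c("homogeneous", "heterogeneous"),
                             method = "REML") {
  correlation <- match.arg(correlation)
  variance <- match.arg(variance)
  for (v in c(subject, condition)) {
    if (!v %in% names(data)) abort_config(sprintf("column '%s' not in data.", v))
  }
  df <- as.data.frame(data)
  df[[condition]] <- factor(df[[condition]],
                            levels = intersect(.cvc_conditions,
                                               unique(as.character(df[[condition]]))))
  df <- df[order(df[[subject]], as.integer(df[[condition]])), ]
  counts <- table(df[[subject]])
  n_cond <- nlevels(df[[condition]])
  if (any(counts != n_cond)) {
    abort_config("every subject must contribute one row per condition.")
  }
  if (length(counts) < 20L) {
    abort_insufficient("repeated-measures GLS needs at least 20 subjects.")
  }
  df$.cond_idx <- as.integer(df[[condition]])
  grp <- as.formula(paste0("~ .cond_idx | ", subject))
  wts <- if (variance == "heterogeneous")
    nlme::varIdent(form = as.formula(paste0("~ 1 | ", condition))) else NULL
  cor_struct <- function(kind) {
    if (kind == "unstructured") nlme::corSymm(form = grp)
    else nlme::corCompSymm(form = grp)
  }
  fit_once <- function(kind) {
    nlme::gls(model = formula, data = df, correlation = cor_struct(kind),
              weights = wts, method = method, na.action = stats::na.fail)
  }
  used <- correlation
  fit <- tryCatch(fit_once(correlation), error = function(e) e)
  if (inherits(fit, "error") && correlation == "unstructured") {
    warn(paste("unstructured within-subject correlation failed to converge;",
               "falling back to compound symmetry:", conditionMessage(fit)))
    used <- "compound_symmetry"
    fit <- tryCatch(fit_once("compound_symmetry"), error = function(e) e)
  }
  if (inherits(fit, "error")) {
    abort_fit(paste("GLS fit failed:", conditionMessage(fit)),
              trace = conditionMessage(fit))
  }
  a <- anova(fit, type = "marginal")
  f_stats <- tibble(
    term = rownames(a),
    f = a[["F-value"]],
    df1 = a[["numDF"]],
    df2 = fit$dims$N - fit$dims$p,
    p = a[["p-value"]]
  )
  cf <- summary(fit)$tTable
  structure(
    list(
      fit = fit,
      formula = deparse(formula),
      coefficients = tibble(term = rownames(cf), estimate = cf[, 1], se = cf[, 2]),
      f_stats = f_stats[f_stats$term != "(Intercept)", ],
      within_correlation = coef(fit$modelStruct$corStruct, unconstrained = FALSE),
      correlation = used,
      variance = variance,
      aic = AIC(fit),
      log_lik = as.numeric(logLik(fit)),
      n_subjects = length(counts),
      n = nrow(df),
      method = method,
      args = list(formula = formula, data = df, subject = subject,
                  condition = condition, correlation = used,
                  variance = variance)
    ),
    class = c("cvc_gls", "cvc_fit")
  )
}

#' @export
glance.cvc_gls <- function(x, ...) {
  tibble(aic = x$aic, log_lik = x$log_lik, n = x$n,
         n_subjects = x$n_subjects, method = x$method,
         correlation = x$correlation)
}

#' @exportS3Method base::print
print.cvc_gls <- function(x, ...) {
  cat("Repeated-measures GLS:", x$formula, "\n")
  cat(sprintf("  %s correlation, %s variance, %s; n = %d subjects\n",
              x$correlation, x$variance, x$method, x$n_subjects))
  cat(sprintf("  AIC = %.2f, logLik = %.2f\n", x$aic, x$log_lik))
  for (i in seq_len(nrow(x$f_stats))) {
    r <- x$f_stats[i, ]
    cat(sprintf("  %s: F(%d,%d) = %.2f, p = %.4g\n", r$term, r$df1, r$df2, r$f, r$p))
  }
  invisible(x)
}

refit_ml <- function(x) {
  if (x$method == "ML") return(x$fit)
  nlme::gls(model = x$args$formula, data = x$args$data,
            correlation = if (x$args$correlation == "unstructured")
              nlme::corSymm(form = as.formula(paste0("~ .cond_idx | ", x$args$subject)))
            else
              nlme::corCompSymm(form = as.formula(paste0("~ .cond_idx | ", x$args$subject))),
            weights = if (x$args$variance == "heterogeneous")
              nlme::varIdent(form = as.formula(paste0("~ 1 | ", x$args$condition)))
            else NULL,
            method = "ML")
}

fixed_terms <- function(x) {
  f <- if (inherits(x, "cvc_fit")) stats::formula(x$fit) else stats::formula(x)
  attr(terms(f), "term.labels")
}

#' Penalized-likelihood comparison of two models
#'
#' Reports the AIC difference and, for nested models, the likelihood-ratio
#' statistic `L.Ratio = 2 * (logLik_complex - logLik_simple)` with a
#' chi-squared p-value on the parameter-count difference. GLS models whose
#' fixed effects differ are refit by maximum likelihood first, since REML
#' likelihoods are not comparable across fixed-effect structures. For
#' non-nested models only the AIC difference is reported, with a warning.
#'
#' @param fit_simple,fit_complex Two `cvc_fit` / `cvc_gls` models of the same
#'   data.
#' @return A tibble with `delta_aic` (simple minus complex; positive favours
#'   the complex model), `l_ratio`, `df`, and `p`.
#' @export
compare_models <- function(fit_simple, fit_complex) {
  if (!inherits(fit_simple, "cvc_fit") || !inherits(fit_complex, "cvc_fit")) {
    abort_config("compare_models() expects two cvc_fit/cvc_gls objects.")
  }
  if (fit_simple$n != fit_complex$n) {
    abort_config("models were fitted to different numbers of observations.")
  }
  get_ml <- function(x) {
    if (inherits(x, "cvc_gls")) refit_ml(x) else x$fit
  }
  ms <- get_ml(fit_simple); mc <- get_ml(fit_complex)
  lls <- logLik(ms); llc <- logLik(mc)
  df_diff <- attr(llc, "df") - attr(lls, "df")
  delta_aic <- AIC(ms) - AIC(mc)
  nested <- all(fixed_terms(fit_simple) %in% fixed_terms(fit_complex)) &&
    df_diff >= 0
  if (!nested) {
    warn("models are not nested; likelihood-ratio p-value suppressed.")
    return(tibble(delta_aic = delta_aic, l_ratio = NA_real_, df = NA_integer_,
                  p = NA_real_))
  }
  l_ratio <- max(0, 2 * (as.numeric(llc) - as.numeric(lls)))
  p <- if (df_diff == 0) 1 else pchisq(l_ratio, df_diff, lower.tail = FALSE)
  tibble(delta_aic = delta_aic, l_ratio = l_ratio, df = as.integer(df_diff), p = p)
}
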