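#' LASSO screening of nuisance covariates
#'
#' Coordinate-descent LASSO of baseline RMSSD (or any outcome) on candidate
#' covariates, with the penalty chosen by seeded k-fold cross-validation at
#' the one-standard-error rule. Categorical covariates are dummy-coded and all
#' columns standardized; a covariate is selected when any of its dummies has a
#' nonzero coefficient at the chosen penalty.
#'
#' @param data A data frame with one row per subject.
#' @param outcome Outcome column name.
#' @param covariates Character vector of candidate covariate columns.
#' @param nfolds Number of cross-validation folds.
#' @param seed Integer seed for fold assignment.
#' @param rule `"1se"` (default) or `"min"`.
#' @return An object of class `cvc_lasso`: `selected` (character), `lambda`,
#'   `coefficients` tibble at the chosen penalty, and the underlying
#'   `cv.glmnet` fit. If fewer than 20 complete cases are available, screening
#'   is skipped with a warning and nothing is selected.
#' @export
lasso_covariate_screen <- function(data, outcome = "rmssd_baseline",
                                   covariates = c("gender", "age", "caffeine",
                                                  "time_of_day"),
                                   nfolds = 10, seed = 1L,
                                   rule = c("1se", "min")) {
  rule <- match.arg(rule)
  cols <- c(outcome, covariates)
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    abort_config(sprintf("column(s) not in data: %s.", paste(miss, collapse = ", ")))
  }
  df <- as.data.frame(data[cols])
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < 20L) {
    warn("fewer than 20 complete cases; covariate screening skipped.")
    return(structure(list(selected = character(0), lambda = NA_real_,
                          coefficients = tibble(term = character(),
                                                estimate = numeric()),
                          cv_fit = NULL, n = nrow(df)),
                     class = "cvc_lasso"))
  }
  for (v in covariates) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  mm <- model.matrix(
    as.formula(paste0("~ ", paste0("`", covariates, "`", collapse = " + "))),
    data = df
  )
  x <- mm[, -1, drop = FALSE]
  col_term <- attr(mm, "assign")[-1]  # maps each dummy column to its covariate
  y <- df[[outcome]]
  foldid <- withr::with_seed(seed,
    sample(rep(seq_len(nfolds), length.out = length(y))))
  cv <- glmnet::cv.glmnet(x, y, foldid = foldid, standardize = TRUE)
  lam <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
  b <- as.matrix(coef(cv, s = lam))
  nz_cols <- which(abs(b[-1, 1]) > 0)
  sel_cov <- unique(covariates[col_term[nz_cols]])
  structure(
    list(selected = sel_cov, lambda = lam,
         coefficients = tibble(term = rownames(b), estimate = b[, 1]),
         cv_fit = cv, n = length(y)),
    class = "cvc_lasso"
  )
}

#' @export
tidy.cvc_lasso <- function(x, ...) x$coefficients

#' @exportS3Method base::print
print.cvc_lasso <- function(x, ...) {
  if (is.null(x$cv_fit)) {
    cat("LASSO covariate screen skipped (n =", x$n, ")\n")
  } else {
    cat(sprintf("LASSO covariate screen (n = %d, lambda = %.4g)\n", x$n, x$lambda))
    cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
        else "(none)", "\n")
  }
  invisible(x)
}
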