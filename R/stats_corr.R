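#' Spearman correlation matrix with Bonferroni correction
#'
#' Pairwise-complete Spearman rank correlations (average ranks for ties) with
#' two-sided p-values from the t approximation, and Bonferroni-adjusted
#' p-values over all unique pairs tested. Constant variables yield `NA`
#' correlations for their pairs.
#'
#' @param data A data frame of subjects.
#' @param vars Character vector of numeric columns to correlate; defaults to
#'   every numeric column.
#' @param alpha Two-tailed significance level.
#' @return An object of class `cvc_corr` with matrices `rho`, `p_raw`,
#'   `p_bonferroni`, `n`, and logical matrices `significant_raw`,
#'   `significant_corrected`. Use [tidy()] for a long tibble.
#' @export
spearman_matrix <- function(data, vars = NULL, alpha = 0.05) {
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    abort_config(sprintf("variable(s) not in data: %s.", paste(miss, collapse = ", ")))
  }
  k <- length(vars)
  if (k < 2L) abort_config("need at least two variables to correlate.")
  rho <- p_raw <- nmat <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(rho) <- 1; diag(p_raw) <- NA
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      x <- data[[vars[i]]]; y <- data[[vars[j]]]
      ok <- is.finite(x) & is.finite(y)
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 4L || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
      ct <- suppressWarnings(
        cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
      )
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p_raw[i, j] <- p_raw[j, i] <- ct$p.value
    }
  }
  m <- sum(!is.na(rho[upper.tri(rho)]))
  p_bonf <- pmin(p_raw * m, 1)  # argument order keeps the matrix shape
  structure(
    list(variables = vars, rho = rho, p_raw = p_raw, p_bonferroni = p_bonf,
         n = nmat, n_tests = m, alpha = alpha,
         significant_raw = !is.na(p_raw) & p_raw <= alpha,
         significant_corrected = !is.na(p_bonf) & p_bonf <= alpha),
    class = "cvc_corr"
  )
}

#' @export
tidy.cvc_corr <- function(x, ...) {
  ut <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble(
    var1 = x$variables[ut[, 1]],
    var2 = x$variables[ut[, 2]],
    rho = x$rho[ut],
    n = x$n[ut],
    p_raw = x$p_raw[ut],
    p_bonferroni = x$p_bonferroni[ut],
    significant_raw = x$significant_raw[ut],
    significant_corrected = x$significant_corrected[ut]
  )
}

#' @exportS3Method base::print
print.cvc_corr <- function(x, digits = 2, ...) {
  cat(sprintf("Spearman correlation matrix (%d variables, %d tests, alpha = %g)\n",
              length(x$variables), x$n_tests, x$alpha))
  print(round(x$rho, digits))
  cat(sprintf("significant raw: %d; after Bonferroni: %d\n",
              sum(x$significant_raw) / 2, sum(x$significant_corrected) / 2))
  invisible(x)
}

#' Correlation-matrix heat map
#'
#' @param x A `cvc_corr` object.
#' @return A ggplot: coefficients in the upper triangle, significance stars in
#'   the lower.
#' @export
plot_correlation_matrix <- function(x) {
  df <- tidy.cvc_corr(x)
  stars <- function(p) dplyr::case_when(
    is.na(p) ~ "", p < 0.001 ~ "***", p < 0.01 ~ "**", p <= 0.05 ~ "*",
    .default = ""
  )
  lv <- x$variables
  upper <- df |> mutate(row = .data$var1, col = .data$var2,
                        label = sprintf("%.2f", .data$rho))
  lower <- df |> mutate(row = .data$var2, col = .data$var1,
                        label = stars(.data$p_raw))
  both <- bind_rows(upper, lower) |>
    mutate(row = factor(.data$row, levels = rev(lv)),
           col = factor(.data$col, levels = lv))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "white", high = "#B2182B",
                                  na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "rho") +
    ggplot2::theme_minimal()
}
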