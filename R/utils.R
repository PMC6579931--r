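# Condition labels recognised throughout the package, in protocol order.
.cvc_conditions <- c("baseline", "stress", "recovery")

# Interval flag levels.
.cvc_flags <- c("clean", "ectopic", "missed", "extra", "erroneous")

abort_config <- function(message, field = NULL) {
  abort(message, class = "cvcreact_config_error", field = field)
}

abort_format <- function(message, line = NULL) {
  abort(message, class = "cvcreact_format_error", line = line)
}

abort_insufficient <- function(message) {
  abort(message, class = "cvcreact_insufficient_data_error")
}

abort_coverage <- function(message) {
  abort(message, class = "cvcreact_coverage_error")
}

abort_quality <- function(message) {
  abort(message, class = "cvcreact_quality_error")
}

abort_fit <- function(message, trace = NULL) {
  abort(message, class = "cvcreact_fit_error", trace = trace)
}

check_number <- function(x, field, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config(sprintf("`%s` must be a single finite number.", field), field)
  }
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    abort_config(sprintf(
      "`%s` = %g is outside its valid range %s%g, %g%s.", field, x,
      if (strict_min) "(" else "[", min, max, if (strict_max) ")" else "]"
    ), field)
  }
  x
}

#' Derive a reproducible child seed
#'
#' Counter-based seed derivation so that each subject (or replicate) gets its
#' own RNG stream that does not depend on the order in which other subjects
#' are generated. All arithmetic stays below 2^53 so the result is exact.
#'
#' @param seed Integer master seed.
#' @param counter Non-negative integer stream index.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, counter = 0L) {
  seed <- check_number(seed, "seed")
  counter <- check_number(counter, "counter", min = 0)
  m <- 2147483647
  as.integer(((seed %% m) * 48271 + (counter %% m) * 69621) %% (m - 1) + 1)
}
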