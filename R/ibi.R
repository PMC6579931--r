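#' Interbeat-interval series as a tibble
#'
#' The package represents an IBI (RR-interval) series as a tibble with one row
#' per interval: `subject_id`, `time_s` (the time of the interval's *second*
#' beat, seconds), `ibi_ms` (interval length, milliseconds), and `flag`
#' (`"clean"`, `"ectopic"`, `"missed"`, `"extra"`, or `"erroneous"`). The time
#' of the opening beat of the recording is `time_s[1] - ibi_ms[1] / 1000`, so a
#' series of n intervals describes n + 1 beats.
#'
#' @param ibi_ms Numeric vector of intervals in milliseconds (all positive).
#' @param subject_id Subject identifier.
#' @param start Time of the first beat in seconds.
#' @param source Free-text provenance note, kept as an attribute.
#' @return An IBI tibble.
#' @examples
#' ibi_from_intervals(c(800, 800, 800))
#' @export
ibi_from_intervals <- function(ibi_ms, subject_id = "s1", start = 0,
                               source = NA_character_) {
  if (!is.numeric(ibi_ms) || length(ibi_ms) < 1L) {
    abort_format("`ibi_ms` must be a non-empty numeric vector.")
  }
  bad <- which(!is.finite(ibi_ms) | ibi_ms <= 0)
  if (length(bad)) {
    abort_format(sprintf("non-positive or missing interval at position %d.", bad[1]),
                 line = bad[1])
  }
  out <- tibble(
    subject_id = as.character(subject_id),
    time_s = start + cumsum(ibi_ms) / 1000,
    ibi_ms = as.numeric(ibi_ms),
    flag = "clean"
  )
  attr(out, "source") <- source
  out
}

#' @rdname ibi_from_intervals
#' @param x A data frame to validate as an IBI series.
#' @export
validate_ibi <- function(x) {
  need <- c("subject_id", "time_s", "ibi_ms", "flag")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort_format(sprintf("IBI series lacks column(s): %s.",
                         paste(miss, collapse = ", ")))
  }
  if (nrow(x) == 0L) abort_format("IBI series has no intervals.")
  if (any(!is.finite(x$ibi_ms) | x$ibi_ms <= 0)) {
    abort_format("all intervals must be positive and finite.")
  }
  if (is.unsorted(x$time_s, strictly = TRUE)) {
    abort_format("beat times must be strictly increasing.")
  }
  if (!all(x$flag %in% .cvc_flags)) {
    abort_format("interval flags must be one of: clean, ectopic, missed, extra, erroneous.")
  }
  gap <- abs(diff(x$time_s) * 1000 - x$ibi_ms[-1])
  if (any(gap > 0.5)) {
    abort_format("intervals disagree with beat-time differences by more than 0.5 ms.")
  }
  invisible(x)
}

# Beat times (length n + 1) implied by an IBI tibble.
ibi_beat_times <- function(x) {
  c(x$time_s[1] - x$ibi_ms[1] / 1000, x$time_s)
}

# Recompute time_s from a first-beat time and intervals.
rebuild_ibi <- function(ibi_ms, first_beat, subject_id, flag = "clean") {
  tibble(
    subject_id = subject_id,
    time_s = first_beat + cumsum(ibi_ms) / 1000,
    ibi_ms = ibi_ms,
    flag = flag
  )
}

#' Read and write interbeat-interval files
#'
#' Two plain-text dialects are supported: `"intervals"`, one millisecond value
#' per line (beat times are synthesized by cumulative sum from 0); and
#' `"beats"`, an RFC-4180 CSV with columns `time_s` (second beat of each
#' interval) and `ibi_ms`. `dialect = "auto"` picks `"beats"` for files whose
#' first line contains a comma.
#'
#' @param path File path.
#' @param dialect One of `"auto"`, `"intervals"`, `"beats"`.
#' @param subject_id Subject identifier to attach.
#' @return `read_ibi()` returns an IBI tibble; `write_ibi()` returns `path`
#'   invisibly.
#' @export
read_ibi <- function(path, dialect = c("auto", "intervals", "beats"),
                     subject_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "auto") {
    first <- readr::read_lines(path, n_max = 1L)
    dialect <- if (length(first) && grepl(",", first[1])) "beats" else "intervals"
  }
  if (dialect == "intervals") {
    lines <- readr::read_lines(path)
    keep <- which(nzchar(trimws(lines)))
    vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
    if (anyNA(vals)) {
      ln <- keep[which(is.na(vals))[1]]
      abort_format(sprintf("unparseable interval on line %d of %s.", ln, path),
                   line = ln)
    }
    bad <- which(vals <= 0)
    if (length(bad)) {
      ln <- keep[bad[1]]
      abort_format(sprintf("non-positive interval on line %d of %s.", ln, path),
                   line = ln)
    }
    return(ibi_from_intervals(vals, subject_id = subject_id, source = path))
  }
  # base read.csv parses doubles with strtod, which round-trips %.17g exactly
  df <- utils::read.csv(path)
  if (!all(c("time_s", "ibi_ms") %in% names(df))) {
    abort_format(sprintf("%s must have columns time_s and ibi_ms.", path))
  }
  bad <- which(!is.finite(df$ibi_ms) | df$ibi_ms <= 0)
  if (length(bad)) {
    abort_format(sprintf("non-positive interval on line %d of %s.", bad[1] + 1L, path),
                 line = bad[1] + 1L)
  }
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    ln <- which(diff(df$time_s) <= 0)[1] + 2L
    abort_format(sprintf("non-monotone beat time on line %d of %s.", ln, path),
                 line = ln)
  }
  out <- tibble(subject_id = as.character(subject_id),
                time_s = df$time_s, ibi_ms = df$ibi_ms, flag = "clean")
  attr(out, "source") <- path
  validate_ibi(out)
  out
}

#' @rdname read_ibi
#' @param x An IBI tibble.
#' @export
write_ibi <- function(x, path, dialect = c("beats", "intervals")) {
  dialect <- match.arg(dialect)
  validate_ibi(x)
  if (dialect == "intervals") {
    readr::write_lines(sprintf("%.17g", x$ibi_ms), path)
  } else {
    # %.17g guarantees a bit-exact double round trip
    readr::write_lines(
      c("time_s,ibi_ms", sprintf("%.17g,%.17g", x$time_s, x$ibi_ms)), path)
  }
  invisible(path)
}

#' Read and write condition-segment annotations
#'
#' Segments are stored as CSV with columns `label` (baseline, stress or
#' recovery), `start_s` and `end_s`; they must be ordered and non-overlapping.
#'
#' @param path File path.
#' @return `read_segments()` returns a tibble with columns `label`, `start`,
#'   `end`.
#' @export
read_segments <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("label", "start_s", "end_s") %in% names(df))) {
    abort_format(sprintf("%s must have columns label, start_s, end_s.", path))
  }
  out <- tibble(label = as.character(df$label), start = df$start_s, end = df$end_s)
  validate_segments(out)
  out
}

#' @rdname read_segments
#' @param segments A segments tibble (`label`, `start`, `end`).
#' @export
write_segments <- function(segments, path) {
  validate_segments(segments)
  readr::write_csv(
    tibble(label = segments$label, start_s = segments$start, end_s = segments$end),
    path
  )
  invisible(path)
}

validate_segments <- function(segments) {
  need <- c("label", "start", "end")
  if (!all(need %in% names(segments))) {
    abort_config("segments need columns label, start, end.")
  }
  if (!all(segments$label %in% .cvc_conditions)) {
    abort_config(sprintf("segment labels must be one of: %s.",
                         paste(.cvc_conditions, collapse = ", ")), "label")
  }
  if (any(segments$end <= segments$start)) {
    abort_config("each segment must have end > start.")
  }
  if (nrow(segments) > 1L) {
    if (any(segments$start[-1] < segments$end[-nrow(segments)])) {
      abort_config("segments must be ordered and non-overlapping.")
    }
  }
  invisible(segments)
}
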