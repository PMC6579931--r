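#' Detect beat artifacts in an IBI series
#'
#' A seeded, reproducible stand-in for manual beat correction. Each interval
#' is compared against a running median `m` (9-interval window):
#'
#' * `missed`: interval longer than `long_factor * m` (two beats merged);
#' * `extra`: interval shorter than `short_factor * m` (a spurious detection
#'   split one beat);
#' * `ectopic`: relative deviation score above `rel_threshold`, where the
#'   score is the larger of the interval's deviation from `m` and half its
#'   largest successive difference (an ectopic beat shifts one beat time,
#'   deflecting two adjacent intervals in opposite directions).
#'
#' @param series An IBI tibble with at least 5 intervals.
#' @param rel_threshold Relative-deviation threshold for ectopic/erroneous
#'   intervals.
#' @param long_factor,short_factor Multiples of the running median defining
#'   missed-beat and extra-beat intervals.
#' @return The series with its `flag` column populated.
#' @export
detect_artifacts <- function(series, rel_threshold = 0.25, long_factor = 1.8,
                             short_factor = 0.5) {
  validate_ibi(series)
  v <- series$ibi_ms
  n <- length(v)
  if (n < 5L) abort_insufficient("artifact detection needs at least 5 intervals.")
  k <- min(9L, if (n %% 2L == 1L) n else n - 1L)
  m <- runmed(v, k, endrule = "median")
  long <- v > long_factor * m
  short <- v < short_factor * m
  # ectopic score: deviation from the running median, backed up by the smaller
  # of the two adjacent successive differences (an ectopic beat deflects BOTH
  # neighbouring intervals, a clean neighbour of an artifact only one). Diffs
  # that involve a missed/extra interval are masked so its neighbours stay
  # clean.
  dev <- abs(v - m)
  d <- abs(diff(v))
  d[long[-n] | short[-n] | long[-1] | short[-1]] <- 0
  back <- c(0, d)
  fwd <- c(d, 0)
  # an ectopic beat deflects both adjacent intervals in opposite directions;
  # the jump between them (twice the displacement) makes even small ectopics
  # stand far out of the successive-difference noise floor. The flag must
  # also be an outlier against the subject's OWN beat-to-beat variability
  # (3.5 robust SDs of the successive differences), so that high-HRV subjects
  # whose natural differences approach the relative threshold are not
  # shredded as artifacts.
  score_ms <- pmax(dev, back, fwd)
  own_scale <- 3.5 * mad(diff(v))
  flag <- rep("clean", n)
  flag[score_ms / m > rel_threshold & score_ms > own_scale] <- "ectopic"
  flag[short] <- "extra"
  flag[long] <- "missed"
  series$flag <- flag
  series
}

#' Correct flagged beat artifacts
#'
#' Every run of consecutive flagged intervals is re-beat under one
#' conservation rule: the run's elapsed time divided by the local median
#' interval tells how many true beats it spans, so the run is replaced by
#' `k = round(sum / m)` intervals whose values follow a cubic spline through
#' the surrounding clean intervals, rescaled so the run's elapsed time is
#' preserved exactly. This merges extra-beat splits (`k = 1`), re-inserts
#' missed beats at local-median spacing (`k = 2` for one merged pair), and
#' redistributes the interval pair deflected by a moved (ectopic) beat
#' (`k = 2`). A run is first extended by one adjacent clean interval when that
#' better completes a whole number of median beats — the situation where only
#' one of the two intervals deflected by an ectopic beat was flagged.
#'
#' @param series An IBI tibble whose `flag` column has been populated, e.g. by
#'   [detect_artifacts()].
#' @param max_flag_fraction Records with more than this fraction of flagged
#'   intervals are rejected as unusable.
#' @return A corrected IBI tibble with all flags `"clean"`.
#' @export
correct_artifacts <- function(series, max_flag_fraction = 0.2) {
  validate_ibi(series)
  if (all(series$flag == "clean")) return(series)
  frac <- mean(series$flag != "clean")
  if (frac > max_flag_fraction) {
    abort_quality(sprintf(
      "record rejected: %.1f%% of intervals flagged (limit %.0f%%).",
      100 * frac, 100 * max_flag_fraction))
  }
  first_beat <- ibi_beat_times(series)[1]
  v <- series$ibi_ms
  flag <- series$flag
  if (sum(flag == "clean") < 4L) {
    abort_quality("too few clean intervals to interpolate over artifacts.")
  }
  global_m <- median(v[flag == "clean"])

  bad <- which(flag != "clean")
  runs <- split(bad, cumsum(c(1, diff(bad) != 1)))
  # process right to left so earlier indices stay valid while splicing
  for (run in rev(runs)) {
    a <- run[1]; b <- run[length(run)]
    win <- max(1L, a - 6L):min(length(v), b + 6L)
    nb <- v[win][flag[win] == "clean"]
    m_loc <- if (length(nb) >= 3L) median(nb) else global_m
    resid <- function(s) {
      k <- max(1, round(s / m_loc))
      abs(s / m_loc - k)
    }
    # optionally absorb one clean neighbour (a half-detected ectopic pair)
    cand <- list(c(a, b))
    if (a > 1L && flag[a - 1L] == "clean") cand <- c(cand, list(c(a - 1L, b)))
    if (b < length(v) && flag[b + 1L] == "clean") cand <- c(cand, list(c(a, b + 1L)))
    res_vals <- vapply(cand, function(ab) resid(sum(v[ab[1]:ab[2]])), numeric(1))
    best <- which(res_vals < res_vals[1] - 0.1)
    if (length(best)) {
      ab <- cand[[best[which.min(res_vals[best])]]]
      a <- ab[1]; b <- ab[2]
    }
    s <- sum(v[a:b])
    k <- max(1L, as.integer(round(s / m_loc)))
    clean_idx <- setdiff(which(flag == "clean"), a:b)
    near <- clean_idx[abs(clean_idx - (a + b) / 2) <= 10]
    repl <- if (length(near) >= 4L) {
      spline(near, v[near], method = "natural",
             xout = seq(a, b, length.out = k))$y
    } else {
      rep(s / k, k)
    }
    repl <- pmax(repl, 1)
    repl <- repl * s / sum(repl)  # exact conservation of elapsed time
    v <- c(v[seq_len(a - 1L)], repl,
           if (b < length(v)) v[(b + 1L):length(v)])
    flag <- c(flag[seq_len(a - 1L)], rep("clean", k),
              if (b < length(flag)) flag[(b + 1L):length(flag)])
  }

  res <- rebuild_ibi(v, first_beat, series$subject_id[1])
  attr(res, "source") <- attr(series, "source")
  validate_ibi(res)
  res
}

#' Split an IBI series by protocol condition
#'
#' An interval belongs to the segment that contains its *second* beat, with
#' half-open `[start, end)` segment windows; intervals outside every segment
#' are dropped. A tolerance of 1.5 median intervals is allowed at the tail of
#' the recording, since a recording necessarily stops at its last detected
#' beat.
#'
#' @param series An IBI tibble.
#' @param segments A segments tibble (`label`, `start`, `end`), e.g. from a
#'   [session_protocol()] or [read_segments()].
#' @return The series restricted to the segments, with a `condition` factor
#'   column added.
#' @export
segment_by_condition <- function(series, segments) {
  validate_ibi(series)
  validate_segments(segments)
  beats <- ibi_beat_times(series)
  tol <- 1.5 * median(series$ibi_ms) / 1000
  if (segments$start[1] < beats[1] - tol ||
      segments$end[nrow(segments)] > beats[length(beats)] + tol) {
    abort_coverage("recording does not span the annotated segments.")
  }
  idx <- findInterval(series$time_s, segments$start)
  inside <- idx >= 1L & series$time_s < segments$end[pmax(idx, 1L)]
  out <- series[inside, , drop = FALSE]
  out$condition <- factor(segments$label[idx[inside]],
                          levels = unique(segments$label))
  empty <- setdiff(segments$label, as.character(out$condition))
  if (length(empty)) {
    abort_coverage(sprintf("segment(s) with no beats: %s.",
                           paste(empty, collapse = ", ")))
  }
  attr(out, "source") <- attr(series, "source")
  out
}
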