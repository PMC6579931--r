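#' Configuration of an end-to-end pipeline run
#'
#' Exactly one of `simulation` (a [population_config()]) or `input` (paths to
#' recorded data) must be supplied.
#'
#' @param simulation A [population_config()], or `NULL` when reading files.
#' @param input `NULL`, or a list with `subjects` (CSV path of the subject
#'   table), `ibi_dir` (directory of per-subject IBI files named
#'   `<subject_id>.csv`) and `segments` (CSV path of shared condition
#'   segments).
#' @param window_length,window_step Moving-window geometry, s.
#' @param filter_taps,filter_low,filter_high Respiratory-band FIR parameters.
#' @param alpha Two-tailed significance level for the statistical stages.
#' @param stages Character vector of analysis stages to run; any subset of
#'   `"correlations"`, `"baseline_regression"`, `"stepwise"`, `"gls"`,
#'   `"lasso"`, `"clustering"`.
#' @param seed Integer seed governing all randomness of the run.
#' @param output_dir Directory where artifacts are written.
#' @return A validated `cvc_run_config`.
#' @export
run_config <- function(simulation = population_config(), input = NULL,
                       window_length = 30, window_step = 3,
                       filter_taps = 241, filter_low = 0.12, filter_high = 0.40,
                       alpha = 0.05,
                       stages = c("correlations", "baseline_regression",
                                  "stepwise", "gls", "lasso", "clustering"),
                       seed = 1L, output_dir = tempfile("cvc_run_")) {
  if (!is.null(simulation) && !is.null(input)) {
    abort_config("provide either a simulation config or input paths, not both.")
  }
  if (is.null(simulation) && is.null(input)) {
    abort_config("one of `simulation` or `input` is required.")
  }
  if (!is.null(simulation) && !inherits(simulation, "population_config")) {
    simulation <- do.call(population_config, simulation)
  }
  if (!is.null(input)) {
    need <- c("subjects", "ibi_dir", "segments")
    miss <- setdiff(need, names(input))
    if (length(miss)) {
      abort_config(sprintf("input lacks element(s): %s.", paste(miss, collapse = ", ")))
    }
  }
  check_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE,
               strict_max = TRUE)
  known <- c("correlations", "baseline_regression", "stepwise", "gls", "lasso",
             "clustering")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    abort_config(sprintf("unknown stage(s): %s.", paste(bad, collapse = ", ")))
  }
  structure(
    list(simulation = simulation, input = input,
         window_length = window_length, window_step = window_step,
         filter_taps = filter_taps, filter_low = filter_low,
         filter_high = filter_high, alpha = alpha, stages = stages,
         seed = as.integer(seed), output_dir = output_dir),
    class = "cvc_run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file mirrors the arguments of [run_config()]; `simulation:` and
#' `input:` blocks map to [population_config()] fields and input paths.
#'
#' @param path Path to a YAML file.
#' @return A `cvc_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("simulation", "input"))]
  if (!is.null(y$simulation)) args$simulation <- do.call(population_config, y$simulation)
  else args$simulation <- NULL
  args$input <- y$input
  do.call(run_config, args)
}

#' Validate recorded input files
#'
#' Checks each IBI file for parseability, monotone beat times, positive
#' intervals, and a plausible millisecond unit (a median interval below 10
#' suggests seconds); checks the segment annotations for coverage of all three
#' protocol conditions.
#'
#' @param ibi_paths Character vector of IBI file paths.
#' @param segments_path Optional path to a segment-annotation CSV.
#' @return A tibble with one row per check: `file`, `check`, `pass`,
#'   `message`.
#' @export
validate_inputs <- function(ibi_paths, segments_path = NULL) {
  rows <- purrr::map_dfr(ibi_paths, function(p) {
    res <- tryCatch(read_ibi(p), error = function(e) e)
    if (inherits(res, "error")) {
      return(tibble(file = p, check = "parse", pass = FALSE,
                    message = conditionMessage(res)))
    }
    out <- tibble(file = p, check = "parse", pass = TRUE, message = "ok")
    if (median(res$ibi_ms) < 10) {
      out <- bind_rows(out, tibble(
        file = p, check = "units", pass = FALSE,
        message = "median interval < 10; intervals look like seconds, expected ms."))
    } else {
      out <- bind_rows(out, tibble(file = p, check = "units", pass = TRUE,
                                   message = "ok"))
    }
    if (!is.null(segments_path)) {
      seg <- tryCatch(read_segments(segments_path), error = function(e) NULL)
      if (!is.null(seg)) {
        cov <- tryCatch({segment_by_condition(res, seg); TRUE},
                        error = function(e) conditionMessage(e))
        out <- bind_rows(out, tibble(
          file = p, check = "coverage", pass = isTRUE(cov),
          message = if (isTRUE(cov)) "ok" else cov))
      }
    }
    out
  })
  if (!is.null(segments_path)) {
    seg_res <- tryCatch({
      seg <- read_segments(segments_path)
      miss <- setdiff(.cvc_conditions, seg$label)
      if (length(miss)) sprintf("missing condition(s): %s", paste(miss, collapse = ", "))
      else TRUE
    }, error = function(e) conditionMessage(e))
    rows <- bind_rows(rows, tibble(
      file = segments_path, check = "conditions", pass = isTRUE(seg_res),
      message = if (isTRUE(seg_res)) "ok" else seg_res))
  }
  rows
}

read_input_data <- function(input) {
  subjects <- readr::read_csv(input$subjects, show_col_types = FALSE,
                              progress = FALSE)
  if (!"subject_id" %in% names(subjects)) {
    abort_format("subject table must have a subject_id column.")
  }
  subjects$subject_id <- as.character(subjects$subject_id)
  segments <- read_segments(input$segments)
  sessions <- tibble(
    subject_id = subjects$subject_id,
    ibi = purrr::map(subjects$subject_id, function(id) {
      p <- file.path(input$ibi_dir, paste0(id, ".csv"))
      if (!file.exists(p)) p <- file.path(input$ibi_dir, paste0(id, ".txt"))
      read_ibi(p, subject_id = id)
    }),
    segments = purrr::map(subjects$subject_id, function(id) segments)
  )
  list(subjects = subjects, sessions = sessions)
}

write_json_result <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

#' Run the full CVC reactivity pipeline
#'
#' Simulates (or reads) the study data, preprocesses every IBI series
#' (artifact detection and correction), computes moving-window cardiac metrics
#' per condition, runs the configured statistical stages, and writes the
#' artifact set to `output_dir`: `metrics.csv`, `subjects.csv`, per-stage
#' JSON results, `clusters.csv`, a markdown `report.md`, and a JSON-lines
#' `run_log.jsonl` carrying the seed, package version, and a config hash.
#' Re-running with an identical config reproduces every numeric output.
#'
#' @param config A [run_config()].
#' @return A `cvc_run` list with the in-memory results and output paths,
#'   invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "cvc_run_config")) abort_config("expected a run_config().")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run_log.jsonl")
  log_line <- function(stage, status, detail = NULL) {
    rec <- list(stage = stage, status = status, detail = detail)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), "\n",
        file = log_path, append = TRUE, sep = "")
  }
  unlink(log_path)
  log_line("start", "ok", list(
    package_version = as.character(utils::packageVersion("cvcreact")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "output_dir")])
  ))

  if (!is.null(config$simulation)) {
    # the run seed governs the simulation, whatever the block's own seed was
    sim <- do.call(population_config, utils::modifyList(
      unclass(config$simulation), list(seed = config$seed)))
    data <- simulate_population(sim)
  } else {
    data <- read_input_data(config$input)
  }
  subjects <- data$subjects
  sessions <- data$sessions
  log_line("data", "ok", list(n_subjects = nrow(subjects)))

  h <- design_band_filter(config$filter_taps, config$filter_low,
                          config$filter_high)
  results <- list()
  failures <- character(0)

  metrics <- purrr::map_dfr(seq_len(nrow(sessions)), function(i) {
    ser <- sessions$ibi[[i]]
    ser <- suppressWarnings(detect_artifacts(ser))
    ser <- correct_artifacts(ser)
    suppressWarnings(
      condition_summary(ser, sessions$segments[[i]],
                        window_length = config$window_length,
                        window_step = config$window_step, filter = h)
    )
  })
  readr::write_csv(metrics, file.path(config$output_dir, "metrics.csv"))
  readr::write_csv(subjects, file.path(config$output_dir, "subjects.csv"))
  results$metrics <- metrics
  log_line("metrics", "ok", list(rows = nrow(metrics)))

  profiles <- reactivity_profiles(metrics)
  wide <- subjects |> left_join(profiles, by = "subject_id")
  wide$rmssd_reactivity <- wide$rmssd_stress - wide$rmssd_baseline
  wide$rmssd_recovery_change <- wide$rmssd_recovery - wide$rmssd_stress
  long <- metrics |>
    select("subject_id", "condition", "rmssd") |>
    left_join(subjects, by = "subject_id")

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      failures <<- c(failures, name)
      log_line(name, "error", conditionMessage(res))
      NULL
    } else {
      log_line(name, "ok")
      res
    }
  }

  results$correlations <- run_stage("correlations", function() {
    basemet <- metrics |> filter(.data$condition == "baseline") |>
      select("subject_id", "rmssd", "hrv", "hr") |>
      dplyr::rename(rmssd_baseline_m = "rmssd", hrv_baseline = "hrv",
                    hr_baseline = "hr")
    cm <- spearman_matrix(
      wide |> left_join(basemet, by = "subject_id"),
      vars = c("age", "msceit_total", "eqi_total", "rmssd_baseline",
               "hrv_baseline", "hr_baseline", "rmssd_reactivity",
               "rmssd_recovery_change"),
      alpha = config$alpha
    )
    write_json_result(tidy(cm), file.path(config$output_dir, "correlations.json"))
    cm
  })

  results$baseline_regression <- run_stage("baseline_regression", function() {
    fits <- list(
      ability = fit_baseline_regression(wide, "rmssd_baseline", "msceit_total"),
      mixed = fit_baseline_regression(wide, "rmssd_baseline", "eqi_total")
    )
    write_json_result(
      purrr::map(fits, function(f) list(
        formula = f$formula, f_stats = f$f_stats,
        partial_eta_sq = as.list(f$partial_eta_sq),
        aic = f$aic, n = f$n, diagnostics = f$diagnostics)),
      file.path(config$output_dir, "baseline_regression.json"))
    fits
  })

  results$stepwise <- run_stage("stepwise", function() {
    sel <- list(
      ability = stepwise_branch_selection(
        wide, "rmssd_baseline",
        c("msceit_perceiving", "msceit_using", "msceit_understanding",
          "msceit_managing"), log_outcome = TRUE),
      mixed = stepwise_branch_selection(
        wide, "rmssd_baseline",
        c("eqi_self_perception", "eqi_self_expression", "eqi_interpersonal",
          "eqi_decision_making", "eqi_stress_management"), log_outcome = TRUE)
    )
    write_json_result(purrr::map(sel, function(s) list(
      selected = s$selected, formula = s$fit$formula, aic = s$fit$aic)),
      file.path(config$output_dir, "stepwise.json"))
    sel
  })

  results$gls <- run_stage("gls", function() {
    base_fit <- fit_gls_repeated(long, log(rmssd) ~ condition)
    main_fit <- fit_gls_repeated(long,
      log(rmssd) ~ condition + msceit_total + eqi_total)
    inter_fit <- fit_gls_repeated(long,
      log(rmssd) ~ condition * (msceit_total + eqi_total))
    out <- list(
      condition = base_fit,
      ei_main = main_fit,
      ei_interaction = inter_fit,
      main_vs_condition = compare_models(base_fit, main_fit),
      interaction_vs_main = compare_models(main_fit, inter_fit)
    )
    write_json_result(list(
      condition_f = base_fit$f_stats,
      within_correlation = unname(base_fit$within_correlation),
      main_vs_condition = out$main_vs_condition,
      interaction_vs_main = out$interaction_vs_main),
      file.path(config$output_dir, "gls.json"))
    out
  })

  results$lasso <- run_stage("lasso", function() {
    scr <- lasso_covariate_screen(wide, outcome = "rmssd_baseline",
                                  covariates = c("gender", "age", "caffeine",
                                                 "time_of_day"),
                                  seed = derive_seed(config$seed, 9000L))
    write_json_result(list(selected = scr$selected, lambda = scr$lambda,
                           n = scr$n),
                      file.path(config$output_dir, "lasso.json"))
    scr
  })

  results$clustering <- run_stage("clustering", function() {
    cl <- cluster_reactivity(profiles)
    readr::write_csv(
      cl$assignments |> dplyr::rename(cluster_k3 = "cluster"),
      file.path(config$output_dir, "clusters.csv"))
    joined <- cl$assignments |>
      dplyr::rename(cvc_responder = "responder") |>
      left_join(subjects, by = "subject_id")
    tests <- list(
      msceit_total = mann_whitney(joined$msceit_total, joined$cvc_responder),
      eqi_total = mann_whitney(joined$eqi_total, joined$cvc_responder)
    )
    write_json_result(list(
      explained_variance = cl$pca$explained_variance,
      cluster_summary = cl$cluster_summary,
      group_sizes = as.list(cl$group_sizes),
      mann_whitney = tests),
      file.path(config$output_dir, "clustering.json"))
    list(clusters = cl, tests = tests)
  })

  report_path <- file.path(config$output_dir, "report.md")
  write_run_report(report_path, config, subjects, metrics, results, failures)
  log_line("report", "ok", list(failures = failures))

  invisible(structure(
    list(config = config, subjects = subjects, metrics = metrics,
         results = results, failures = failures,
         output_dir = config$output_dir),
    class = "cvc_run"
  ))
}

# Markdown run report with descriptive (Table-1 style), regression (Fig-2
# style) and cluster (Tables 2/3 style) sections.
write_run_report <- function(path, config, subjects, metrics, results,
                             failures) {
  fmt_tbl <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.3f", x))
    header <- paste("|", paste(names(df), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
    rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
    paste(c(header, sep, rows), collapse = "\n")
  }
  desc <- metrics |>
    group_by(.data$condition) |>
    summarise(across(c("rmssd", "hrv", "hr"),
                     list(mean = ~mean(.x, na.rm = TRUE),
                          sd = ~sd(.x, na.rm = TRUE))),
              rsa_valid_pct = 100 * mean(.data$rsa_valid), .groups = "drop")
  lines <- c(
    "# CVC reactivity pipeline report", "",
    sprintf("- subjects: %d", nrow(subjects)),
    sprintf("- seed: %d", config$seed),
    sprintf("- stages failed: %s",
            if (length(failures)) paste(failures, collapse = ", ") else "none"),
    "", "## Descriptive statistics by condition", "", fmt_tbl(desc)
  )
  if (!is.null(results$baseline_regression)) {
    br <- results$baseline_regression
    lines <- c(lines, "", "## Baseline EI regressions", "",
               purrr::imap_chr(br, function(f, nm) {
                 r <- f$f_stats[1, ]
                 sprintf("- %s EI: F(%d,%d) = %.2f, p = %.3g, partial eta^2 = %.3f",
                         nm, r$df1, r$df2, r$f, r$p, f$partial_eta_sq[[1]])
               }))
  }
  if (!is.null(results$clustering)) {
    cl <- results$clustering$clusters
    lines <- c(lines, "", "## Reactivity clusters", "",
               sprintf("Two components explain %.2f%% of profile variance.",
                       100 * sum(cl$pca$explained_variance[1:2])),
               "", fmt_tbl(cl$cluster_summary), "",
               sprintf("Responders: %d, non-responders: %d.",
                       cl$group_sizes[["responders"]],
                       cl$group_sizes[["non_responders"]]))
  }
  readr::write_lines(lines, path)
  invisible(path)
}
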