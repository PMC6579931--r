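#' Principal components of RMSSD reactivity profiles
#'
#' Correlation-matrix PCA (centred, scaled) of the per-subject
#' baseline/stress/recovery RMSSD triple, by default on the log scale: RMSSD
#' is approximately lognormal across subjects and vagal withdrawal is
#' multiplicative, so log profiles make within-subject reactivity additive and
#' comparable across resting levels. The sign of each component is fixed so
#' that its largest-magnitude loading is positive.
#'
#' @param profiles A tibble with `subject_id`, `rmssd_baseline`,
#'   `rmssd_stress`, `rmssd_recovery` (see [reactivity_profiles()]).
#' @param log_scale Analyse `log(RMSSD)` (default) rather than raw ms.
#' @return An object of class `cvc_pca`: `scores` tibble, `loadings` matrix,
#'   `sdev`, and `explained_variance` fractions (non-increasing, summing
#'   to 1).
#' @export
pca_profiles <- function(profiles, log_scale = TRUE) {
  cols <- c("rmssd_baseline", "rmssd_stress", "rmssd_recovery")
  miss <- setdiff(cols, names(profiles))
  if (length(miss)) {
    abort_config(sprintf("profiles lack column(s): %s.", paste(miss, collapse = ", ")))
  }
  if (nrow(profiles) < 10L) abort_insufficient("PCA needs at least 10 subjects.")
  m <- as.matrix(profiles[cols])
  if (any(!is.finite(m)) || any(m <= 0)) {
    abort_config("reactivity profiles must be complete and positive.")
  }
  if (log_scale) m <- log(m)
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  if (any(pc$sdev < 1e-10)) {
    warn(sprintf("rank-deficient profiles: only %d informative component(s).",
                 sum(pc$sdev >= 1e-10)))
  }
  scores <- as_tibble(pc$x)
  scores <- dplyr::bind_cols(tibble(subject_id = profiles$subject_id), scores)
  structure(list(scores = scores, loadings = pc$rotation, sdev = pc$sdev,
                 explained_variance = ev, log_scale = log_scale),
            class = "cvc_pca")
}

#' Ward hierarchical clustering of PC scores
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances by default)
#' over the retained principal-component scores, cut at `k` clusters. By
#' default each retained component is standardized to unit variance before
#' clustering (Mahalanobis geometry): the resting-level component otherwise
#' dominates the distances and masks the reactivity contrast that
#' distinguishes responders. Cluster labels are re-ordered deterministically
#' by ascending mean baseline RMSSD.
#'
#' @param pca A `cvc_pca` from [pca_profiles()], or a data frame of scores
#'   with a `subject_id` column.
#' @param profiles The reactivity profiles (used to order cluster labels).
#' @param k Number of clusters.
#' @param n_components Number of leading components fed to the clustering.
#' @param linkage `"ward"` (default), `"complete"`, or `"single"`.
#' @param standardize Scale retained component scores to unit variance before
#'   clustering (default `TRUE`).
#' @return Integer cluster labels (1 = lowest mean baseline RMSSD).
#' @export
hac_cluster <- function(pca, profiles, k = 3, n_components = 2,
                        linkage = c("ward", "complete", "single"),
                        standardize = TRUE) {
  linkage <- match.arg(linkage)
  scores <- if (inherits(pca, "cvc_pca")) pca$scores else as_tibble(pca)
  sc <- as.matrix(scores[setdiff(names(scores), "subject_id")])
  n_components <- min(n_components, ncol(sc))
  sc <- sc[, seq_len(n_components), drop = FALSE]
  if (standardize) {
    sds <- apply(sc, 2, sd)
    keep <- sds > 1e-10
    sc[, keep] <- sweep(sc[, keep, drop = FALSE], 2, sds[keep], "/")
    sc[, !keep] <- 0
  }
  if (k > nrow(sc)) abort_config("k cannot exceed the number of subjects.", "k")
  method <- c(ward = "ward.D2", complete = "complete", single = "single")[[linkage]]
  raw <- cutree(hclust(dist(sc), method = method), k = k)
  base_means <- tapply(profiles$rmssd_baseline, raw, mean)
  as.integer(order(order(base_means))[raw])  # 1 = lowest mean baseline RMSSD
}

#' Collapse clusters into responders and non-responders
#'
#' A cluster is *responsive* when its mean stress RMSSD is below its mean
#' baseline RMSSD and its mean recovery RMSSD is above its mean stress RMSSD
#' (vagal withdrawal followed by rebound), each by more than a small relative
#' `margin` so that a flat cluster whose means differ only by estimation noise
#' is never classified responsive. All responsive clusters collapse to
#' responders; the rest are non-responders. If no cluster is responsive, all
#' subjects are flagged non-responders with a warning.
#'
#' @param labels Integer cluster labels from [hac_cluster()].
#' @param profiles The reactivity profiles.
#' @param margin Relative practical-equivalence margin for the cluster-mean
#'   comparisons (default 2%).
#' @return Logical responder flag per subject.
#' @export
collapse_to_responders <- function(labels, profiles, margin = 0.05) {
  if (length(labels) != nrow(profiles)) {
    abort_config("labels and profiles must have the same length.")
  }
  means <- profiles |>
    mutate(.cluster = labels) |>
    group_by(.data$.cluster) |>
    summarise(
      baseline = mean(.data$rmssd_baseline),
      stress = mean(.data$rmssd_stress),
      recovery = mean(.data$rmssd_recovery),
      .groups = "drop"
    ) |>
    mutate(responsive = .data$stress < (1 - margin) * .data$baseline &
             .data$recovery > (1 + margin) * .data$stress)
  if (!any(means$responsive)) {
    warn("no cluster shows the withdrawal-rebound pattern; all flagged non-responders.")
  }
  labels %in% means$.cluster[means$responsive]
}

#' Classify CVC responders by PCA + hierarchical clustering
#'
#' One-call orchestration: correlation PCA of the log RMSSD reactivity
#' profiles, Ward clustering of the two leading (standardized) component
#' scores into `k` groups, and collapse of the responsive clusters into a
#' responder/non-responder split.
#'
#' @inheritParams hac_cluster
#' @inheritParams pca_profiles
#' @param profiles A tibble with `subject_id` and per-condition RMSSD columns.
#' @return An object of class `cvc_clusters`: `assignments` tibble
#'   (`subject_id`, `cluster`, `responder`), the `cvc_pca`, per-cluster
#'   summary means, and `group_sizes`.
#' @export
cluster_reactivity <- function(profiles, k = 3, n_components = 2,
                               linkage = c("ward", "complete", "single"),
                               log_scale = TRUE, standardize = TRUE) {
  linkage <- match.arg(linkage)
  pca <- pca_profiles(profiles, log_scale = log_scale)
  labels <- hac_cluster(pca, profiles, k = k, n_components = n_components,
                        linkage = linkage, standardize = standardize)
  responder <- collapse_to_responders(labels, profiles)
  summary <- profiles |>
    mutate(cluster = labels) |>
    group_by(.data$cluster) |>
    summarise(n = dplyr::n(),
              across(dplyr::starts_with("rmssd_"), mean),
              .groups = "drop")
  structure(
    list(
      assignments = tibble(subject_id = profiles$subject_id,
                           cluster = labels, responder = responder),
      pca = pca,
      cluster_summary = summary,
      group_sizes = c(responders = sum(responder),
                      non_responders = sum(!responder))
    ),
    class = "cvc_clusters"
  )
}

#' @export
tidy.cvc_clusters <- function(x, ...) x$assignments

#' @export
glance.cvc_clusters <- function(x, ...) {
  tibble(
    k = nrow(x$cluster_summary),
    pc1_variance = x$pca$explained_variance[1],
    pc2_cumulative = sum(x$pca$explained_variance[1:2]),
    responders = x$group_sizes[["responders"]],
    non_responders = x$group_sizes[["non_responders"]]
  )
}

#' @exportS3Method base::print
print.cvc_clusters <- function(x, ...) {
  cat(sprintf("CVC reactivity clusters (k = %d); 2 PCs explain %.2f%% of variance\n",
              nrow(x$cluster_summary), 100 * sum(x$pca$explained_variance[1:2])))
  print(x$cluster_summary)
  cat(sprintf("responders: %d, non-responders: %d\n",
              x$group_sizes[["responders"]], x$group_sizes[["non_responders"]]))
  invisible(x)
}

#' Mann-Whitney U test between responder groups
#'
#' Rank-sum test in the convention of [stats::wilcox.test()]: the reported `W`
#' is the U statistic of the first group (sum of its ranks minus its minimum).
#' The p-value is exact for combined n <= 20 without ties, and otherwise uses
#' the normal approximation with tie and continuity corrections.
#'
#' @param values Numeric outcome (e.g. an EI total score).
#' @param group Two-level grouping. A logical vector puts the `TRUE` group
#'   (e.g. responders) first; a factor uses its level order.
#' @return A tibble with `w`, `p`, `n1`, `n2`, and `method`.
#' @export
mann_whitney <- function(values, group) {
  if (is.logical(group)) {
    group <- factor(group, levels = c("TRUE", "FALSE"))
  } else {
    group <- factor(group)
  }
  if (nlevels(group) != 2L) abort_config("`group` must have exactly two levels.")
  ok <- is.finite(values) & !is.na(group)
  values <- values[ok]; group <- group[ok]
  x <- values[group == levels(group)[1]]
  y <- values[group == levels(group)[2]]
  if (length(x) < 3L || length(y) < 3L) {
    abort(sprintf("both groups need at least 3 members (got %d and %d).",
                  length(x), length(y)), class = "cvcreact_test_error")
  }
  ties <- anyDuplicated(values) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, alternative = "two.sided")
  )
  tibble(w = unname(wt$statistic), p = wt$p.value,
         n1 = length(x), n2 = length(y),
         method = if (exact) "exact" else "normal approximation")
}

#' Violin plot of reactivity profiles by group
#'
#' @param profiles Reactivity profiles tibble.
#' @param group Grouping vector (cluster labels or responder flags).
#' @param group_name Legend/facet title.
#' @return A ggplot of per-condition RMSSD distributions per group.
#' @export
plot_reactivity_profiles <- function(profiles, group,
                                     group_name = "group") {
  long <- profiles |>
    mutate(.group = as.factor(group)) |>
    tidyr::pivot_longer(dplyr::starts_with("rmssd_"),
                        names_to = "condition", values_to = "rmssd",
                        names_prefix = "rmssd_") |>
    mutate(condition = factor(.data$condition, levels = .cvc_conditions))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$rmssd,
                                     fill = .data$.group)) +
    ggplot2::geom_violin(position = ggplot2::position_dodge(width = 0.8),
                         alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "RMSSD (ms)", fill = group_name) +
    ggplot2::theme_minimal()
}
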