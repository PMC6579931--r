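test_that("PCA of perfectly correlated profiles is rank one", {
  base <- exp(rnorm(20, 3.4, 0.4))
  prof <- tibble::tibble(subject_id = as.character(1:20),
                         rmssd_baseline = base,
                         rmssd_stress = base * 0.8,
                         rmssd_recovery = base * 1.1)
  expect_warning(pca <- pca_profiles(prof), "rank-deficient")
  expect_equal(pca$explained_variance[1], 1, tolerance = 1e-9)
  expect_equal(sum(pca$explained_variance), 1, tolerance = 1e-12)
})

test_that("component signs follow the largest-loading-positive convention", {
  prof <- simulate_reactivity_profiles(50, seed = 31)
  pca <- pca_profiles(prof)
  for (j in seq_len(ncol(pca$loadings))) {
    l <- pca$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
  expect_equal(sum(pca$explained_variance), 1, tolerance = 1e-12)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
})

test_that("well-separated three-group mixtures are recovered by Ward clustering", {
  skip_if_not_installed("mclust")
  aris <- vapply(1:10, function(s) {
    prof <- simulate_profile_mixture(n = 102, seed = s)
    cl <- cluster_reactivity(prof)
    mclust::adjustedRandIndex(tidy(cl)$cluster, prof$group)
  }, numeric(1))
  expect_gte(mean(aris), 0.95)
})

test_that("cluster labels are deterministic and ordered by baseline level", {
  prof <- simulate_profile_mixture(n = 60, seed = 9)
  cl1 <- cluster_reactivity(prof)
  cl2 <- cluster_reactivity(prof)
  expect_identical(tidy(cl1), tidy(cl2))
  means <- tapply(prof$rmssd_baseline, tidy(cl1)$cluster, mean)
  expect_true(all(diff(means) > 0))

  # permuting input rows permutes labels identically
  perm <- withr::with_seed(1, sample(nrow(prof)))
  cl3 <- cluster_reactivity(prof[perm, ])
  expect_equal(tidy(cl3)$cluster[order(perm)], tidy(cl1)$cluster)
})

test_that("duplicated points share a label; k = 1 puts everyone together", {
  prof <- simulate_profile_mixture(n = 40, seed = 2)
  prof2 <- prof
  prof2[11, -1] <- prof2[10, -1]  # duplicate one subject's profile
  pca <- suppressWarnings(pca_profiles(prof2))
  lab <- hac_cluster(pca, prof2, k = 3)
  expect_equal(lab[10], lab[11])
  expect_equal(unique(hac_cluster(pca, prof2, k = 1)), 1L)
  expect_error(hac_cluster(pca, prof2, k = 99), class = "cvcreact_config_error")
})

test_that("the collapse rule flags withdrawal-rebound clusters only", {
  prof <- tibble::tibble(
    subject_id = as.character(1:30),
    rmssd_baseline = rep(c(20, 40, 70), each = 10),
    rmssd_stress = rep(c(20.1, 28, 50), each = 10),
    rmssd_recovery = rep(c(19.9, 41, 69), each = 10)
  )
  labels <- rep(1:3, each = 10)
  resp <- collapse_to_responders(labels, prof)
  expect_equal(resp, rep(c(FALSE, TRUE, TRUE), each = 10))

  # flat everywhere: nobody responds, with a warning
  flat <- prof
  flat$rmssd_stress <- flat$rmssd_baseline * 1.001
  flat$rmssd_recovery <- flat$rmssd_baseline * 0.999
  expect_warning(resp2 <- collapse_to_responders(labels, flat), "non-responders")
  expect_true(all(!resp2))

  # all clusters responsive: everyone collapses to responder
  allr <- prof
  allr$rmssd_stress <- allr$rmssd_baseline * 0.6
  allr$rmssd_recovery <- allr$rmssd_baseline
  expect_true(all(collapse_to_responders(labels, allr)))

  # idempotence: collapsing twice changes nothing
  expect_identical(resp, collapse_to_responders(labels, prof))
})

test_that("responder collapse recovers generator ground truth", {
  agree <- vapply(1:10, function(s) {
    prof <- simulate_profile_mixture(n = 102, seed = s)
    cl <- cluster_reactivity(prof)
    mean(tidy(cl)$responder == prof$responder)
  }, numeric(1))
  expect_gte(mean(agree), 0.9)
})

test_that("Mann-Whitney follows the exact conventions of the analysis environment", {
  res <- mann_whitney(c(1, 2, 3, 4, 5, 6), factor(rep(c("a", "b"), each = 3),
                                                  levels = c("a", "b")))
  expect_equal(res$w, 0)
  expect_equal(res$p, 0.1)
  expect_equal(res$method, "exact")

  # identical groups (ties force the corrected normal approximation)
  same <- mann_whitney(rep(c(5, 6, 7), 4), rep(c(TRUE, FALSE), 6))
  expect_equal(same$p, 1, tolerance = 0.05)

  expect_error(mann_whitney(1:5, c(TRUE, TRUE, FALSE, FALSE, FALSE)),
               class = "cvcreact_test_error")
})

test_that("exact Mann-Whitney p equals exhaustive permutation enumeration", {
  set.seed(12)
  for (i in 1:12) {
    m <- sample(3:5, 1); n <- sample(3:5, 1)
    x <- round(rnorm(m, 0, 10), 4)
    y <- round(rnorm(n, 1, 10), 4)
    res <- mann_whitney(c(x, y), rep(c(TRUE, FALSE), c(m, n)))
    expect_equal(res$p, oracle_mw_exact(x, y), tolerance = 1e-12)
  }
})

test_that("logical grouping puts the TRUE group first", {
  x <- c(10, 11, 12, 1, 2, 3)
  grp <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  res <- mann_whitney(x, grp)
  expect_equal(res$w, 9)  # TRUE group ranks highest: U = m*n
  expect_equal(res$n1, 3)
})
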