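test_that("feature tables carry five features and binary labels", {
  prs <- make_profile_cohort(10, 8, seed = 3)
  tab <- build_feature_table(prs, "dir", a = 0.0168)
  expect_s3_class(tab, "feature_table")
  expect_equal(nrow(tab), 18)
  expect_named(tab, c("id", "Tmax", "d", "q", "R", "theta", "label"))
  expect_equal(sum(tab$label), 8)
  expect_false(anyNA(tab))
  expect_error(build_feature_table(prs, "dir", a = 0), "> 0")
  # single class is unusable for CV
  prN <- make_profile_cohort(6, 0, seed = 4)
  expect_error(build_feature_table(prN, "dir", a = 0.0168), "single class")
})

test_that("cross-validation predicts every row once and separates separable clusters", {
  # two far-separated Gaussian clusters in feature space
  set.seed(10)
  n <- 40
  X <- rbind(matrix(rnorm(n / 2 * 5, 0, 0.2), ncol = 5),
             matrix(rnorm(n / 2 * 5, 5, 0.2), ncol = 5))
  tab <- data.frame(id = sprintf("s%02d", 1:n), X)
  names(tab)[2:6] <- c("Tmax", "d", "q", "R", "theta")
  tab$label <- rep(0:1, each = n / 2)
  class(tab) <- c("feature_table", "data.frame")
  cv <- svm_cross_validate(tab, K = 10, seed = 1)
  expect_equal(cv$crc, 100)
  expect_length(cv$predictions, n)
  expect_length(cv$scores, n)
  # each row predicted exactly once, and CRC == accuracy on the same rows
  m <- classification_metrics(cv$predictions, tab$label)
  expect_equal(m$accuracy, cv$crc)
  # duplicating every row leaves a separable problem separable
  tab2 <- rbind(tab, tab)
  class(tab2) <- c("feature_table", "data.frame")
  expect_equal(svm_cross_validate(tab2, K = 10, seed = 1)$crc, 100)
  # K larger than the smaller class is reduced with a warning
  small <- tab[c(1:3, 21:23), ]
  class(small) <- c("feature_table", "data.frame")
  expect_warning(cvs <- svm_cross_validate(small, K = 10, seed = 1),
                 "exceeds")
  expect_equal(cvs$K, 3)
})

test_that("permuted labels drive the classification rate to chance", {
  prs <- make_profile_cohort(12, 10, seed = 8)
  tab <- build_feature_table(prs, "dir", a = 0.0168)
  set.seed(99)
  crcs <- replicate(30, {
    t2 <- tab
    t2$label <- sample(t2$label)
    class(t2) <- c("feature_table", "data.frame")
    tryCatch(suppressWarnings(
      svm_cross_validate(t2, K = 5, seed = 1)$crc),
      error = function(e) NA_real_)
  })
  # mean permuted CRC stays inside a generous chance band, far from
  # the 100% reached with the true labels
  expect_gt(mean(crcs, na.rm = TRUE), 25)
  expect_lt(mean(crcs, na.rm = TRUE), 75)
})

test_that("diagnostic metrics match hand-computed confusion tables", {
  lab <- rep(c(0L, 1L), c(49, 38))
  expect_equal(classification_metrics(lab, lab),
               list(accuracy = 100, sensitivity = 100, specificity = 100))
  # all predicted normal on the 49/38 cohort
  m <- classification_metrics(rep(0L, 87), lab)
  expect_equal(round(m$accuracy, 2), 56.32)
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 100)
  # TP=33, FN=5, TN=47, FP=2
  pred <- c(rep(0L, 47), rep(1L, 2), rep(1L, 33), rep(0L, 5))
  labs <- c(rep(0L, 49), rep(1L, 38))
  m2 <- classification_metrics(pred, labs)
  expect_equal(round(m2$sensitivity, 2), 86.84)
  expect_equal(round(m2$specificity, 2), 95.92)
  expect_equal(round(m2$accuracy, 2), round(100 * 80 / 87, 2))
  expect_error(classification_metrics(pred, rep(0L, 87)), "both classes")
})

test_that("trapezoid AUC equals brute-force concordant-pair counting", {
  # worked example: 3 of 4 pos/neg pairs concordant
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(1:10, rep(c(0, 1), each = 5))$auc, 1)
  expect_equal(roc_auc(10:1, rep(c(0, 1), each = 5))$auc, 0)
  expect_warning(rc <- roc_auc(rep(1, 6), c(0, 0, 0, 1, 1, 1)), "constant")
  expect_equal(rc$auc, 0.5)
  # Mann-Whitney oracle on random instances (ties included)
  set.seed(77)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    labels <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    pairs <- expand.grid(p = which(labels == 1L), n = which(labels == 0L))
    u <- mean(ifelse(scores[pairs$p] > scores[pairs$n], 1,
                     ifelse(scores[pairs$p] == scores[pairs$n], 0.5, 0)))
    expect_equal(suppressWarnings(roc_auc(scores, labels)$auc), u)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  labels <- rep(c(0L, 1L), each = 20)
  scores <- rnorm(40) + labels
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              direction = "<",
                                              levels = c(0, 1),
                                              quiet = TRUE))))
})

test_that("position scan finds a perfectly separating radius on disjoint classes", {
  prs <- make_profile_cohort(12, 10, seed = 21)
  scan <- suppressWarnings(scan_positions(prs, "dir", K = 5, seed = 2))
  expect_s3_class(scan, "roi_position_scan")
  expect_equal(max(scan$results$crc, na.rm = TRUE), 100)
  best <- scan$results[scan$results$a_m == scan$optimal_a, ]
  expect_equal(best$crc, 100)
  expect_equal(best$auc, 1)
  # optimum attains the max with ties broken toward the smallest radius
  expect_equal(scan$optimal_a,
               min(scan$results$a_m[scan$results$crc ==
                                      max(scan$results$crc, na.rm = TRUE)],
                   na.rm = TRUE))
  # single-offset grid returns that offset
  s1 <- scan_positions(prs, "dir", a_grid = 0.0168, K = 5, seed = 2)
  expect_equal(s1$optimal_a, 0.0168)
  expect_output(print(scan), "optimal a")
})

test_that("scan is deterministic and reports byte-identical files", {
  prs <- make_profile_cohort(8, 7, seed = 13)
  grid <- c(0.006, 0.012, 0.0168)
  s1 <- scan_positions(prs, "lorentz", a_grid = grid, K = 5, seed = 7)
  s2 <- scan_positions(prs, "lorentz", a_grid = grid, K = 5, seed = 7)
  expect_identical(s1$results, s2$results)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  report(s1, d1); report(s2, d2)
  for (f in c("crc_by_position.csv", "metrics.csv", "roc.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  met <- utils::read.csv(file.path(d1, "metrics.csv"))
  expect_named(met, c("method", "optimal_a_m", "crc", "accuracy",
                      "sensitivity", "specificity", "auc"))
})
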