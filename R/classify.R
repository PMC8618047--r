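#' Build the cohort feature table at a fixed extraction position
#'
#' Extracts the five-component pattern vector \code{\{Tmax, d, q, R,
#' theta\}} for every profile in a cohort at position \code{a}.
#' Profiles whose extraction fails (e.g. the inversion is singular at
#' that position) are dropped with a message.  Labels are binary:
#' normal = 0, abnormal = 1.
#'
#' @param profiles list of \code{roi_profile} objects carrying labels.
#' @param method \code{"dir"} or \code{"lorentz"}.
#' @param a extraction position in metres (> 0, on the offset grid).
#' @param constants a \code{\link{model_constants}}.
#' @param labels optional explicit label vector (\code{"normal"} /
#'   \code{"abnormal"}) overriding the profiles' own labels.
#' @param lorentz_fits optional list of precomputed
#'   \code{\link{lorentz_fit}} results, parallel to \code{profiles}.
#' @return A data frame (class \code{feature_table}) with columns
#'   \code{id}, \code{Tmax}, \code{d}, \code{q}, \code{R}, \code{theta},
#'   \code{label}; attributes \code{a} and \code{method}.
#' @export
build_feature_table <- function(profiles, method = c("dir", "lorentz"), a,
                                constants = model_constants(),
                                labels = NULL, lorentz_fits = NULL) {
  method <- match.arg(method)
  if (a <= 0) stop("'a' must be > 0")
  if (is.null(labels))
    labels <- vapply(profiles, function(p)
      if (is.null(p$label)) "unknown" else p$label, character(1))
  rows <- vector("list", length(profiles))
  dropped <- character(0)
  for (i in seq_along(profiles)) {
    pid <- if (is.null(profiles[[i]]$id)) sprintf("profile_%03d", i)
           else profiles[[i]]$id
    v <- tryCatch(
      pattern_vector(profiles[[i]], method, a, constants,
                     lorentz = lorentz_fits[[i]]),
      error = function(e) NULL)
    if (is.null(v) || any(!is.finite(v))) { dropped <- c(dropped, pid); next }
    rows[[i]] <- data.frame(id = pid, Tmax = v[["Tmax"]], d = v[["d"]],
                            q = v[["q"]], R = v[["R"]],
                            theta = v[["theta"]],
                            label = as.integer(labels[i] == "abnormal"),
                            stringsAsFactors = FALSE)
  }
  if (length(dropped))
    message("dropped ", length(dropped), " profile(s) with failed ",
            "extraction at a = ", a, ": ", paste(dropped, collapse = ", "))
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab) || nrow(tab) < 2L)
    stop("cohort error: fewer than 2 usable rows at a = ", a)
  if (length(unique(tab$label)) < 2L)
    stop("cohort error: a single class present at a = ", a)
  attr(tab, "a") <- a
  attr(tab, "method") <- method
  class(tab) <- c("feature_table", "data.frame")
  tab
}

feature_cols <- c("Tmax", "d", "q", "R", "theta")

stratified_folds <- function(labels, K, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(K), length(idx))
  }
  fold
}

#' RBF-SVM stratified cross-validation of a feature table
#'
#' C-classification support-vector machine with the radial-basis kernel
#' under stratified K-fold cross-validation.  Features are standardized
#' inside each training fold (centre/scale by the training mean and sd)
#' and the same transform is applied to the held-out fold, so no
#' information leaks across folds; \code{scale = FALSE} reproduces the
#' raw-feature behaviour.  Every row receives exactly one out-of-fold
#' prediction and decision score (oriented so larger = abnormal).
#'
#' @param table a \code{\link{build_feature_table}} result.
#' @param C soft-margin cost (upper bound on the dual weights).
#' @param gamma RBF kernel width; default \code{1 / (5 * var)} with
#'   \code{var} the overall variance of the (standardized) training
#'   features.
#' @param K number of folds (default 10); reduced with a warning if it
#'   exceeds the smaller class count.
#' @param seed fold-assignment seed.
#' @param scale per-fold feature standardization (default TRUE).
#' @return List with \code{predictions} (0/1 integer), \code{scores}
#'   (decision values), \code{crc} (percent correct out-of-fold),
#'   \code{folds}, \code{K}.
#' @export
svm_cross_validate <- function(table, C = 1, gamma = NULL, K = 10L,
                               seed = 1L, scale = TRUE) {
  y <- table$label
  if (length(unique(y)) < 2L) stop("both classes must be present")
  min_class <- min(table(y))
  if (K > min_class) {
    warning("K = ", K, " exceeds the smaller class count (", min_class,
            "); using K = ", min_class)
    K <- min_class
  }
  if (K < 2L) stop("degenerate folds: need K >= 2")
  X <- as.matrix(table[, feature_cols])
  folds <- stratified_folds(y, K, seed)
  pred <- integer(nrow(X))
  score <- numeric(nrow(X))
  yf <- factor(y, levels = c(0L, 1L))
  for (k in seq_len(K)) {
    tr <- folds != k; te <- !tr
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (scale) {
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2L, stats::sd)
      sdv[sdv == 0 | !is.finite(sdv)] <- 1
      Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sdv, "/")
      Xte <- sweep(sweep(Xte, 2L, mu), 2L, sdv, "/")
    }
    g <- if (is.null(gamma)) {
      v <- stats::var(as.vector(Xtr))
      if (!is.finite(v) || v == 0) v <- 1
      1 / (ncol(Xtr) * v)
    } else gamma
    fit <- e1071::svm(Xtr, yf[tr], type = "C-classification",
                      kernel = "radial", cost = C, gamma = g,
                      scale = FALSE)
    pr <- stats::predict(fit, Xte, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # e1071 names the decision column "A/B": positive values favour A
    s <- as.numeric(dv[, 1L])
    if (colnames(dv)[1L] == "0/1") s <- -s  # orient: larger = abnormal
    pred[te] <- as.integer(as.character(pr))
    score[te] <- s
  }
  list(predictions = pred, scores = score,
       crc = 100 * mean(pred == y), folds = folds, K = K)
}

#' Accuracy, sensitivity and specificity
#'
#' Binary diagnostic metrics with abnormal (label 1) as the positive
#' class, expressed as percentages.
#'
#' @param predictions,labels 0/1 vectors.
#' @return Named list \code{accuracy}, \code{sensitivity},
#'   \code{specificity} (percent).
#' @export
classification_metrics <- function(predictions, labels) {
  if (length(unique(labels)) < 2L)
    stop("undefined metric: both classes must be present in 'labels'")
  tp <- sum(predictions == 1L & labels == 1L)
  fn <- sum(predictions == 0L & labels == 1L)
  tn <- sum(predictions == 0L & labels == 0L)
  fp <- sum(predictions == 1L & labels == 0L)
  list(accuracy = 100 * (tp + tn) / length(labels),
       sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp))
}

#' ROC curve and area under the curve
#'
#' Sweeps a decision threshold over the scores (larger score = more
#' abnormal), collects (false-positive rate, true-positive rate) points
#' and integrates the area by the trapezoid rule.
#'
#' @param scores continuous decision values.
#' @param labels 0/1 vector (abnormal = 1, the positive class).
#' @return List with \code{points} (data frame \code{threshold},
#'   \code{fpr}, \code{tpr}) and \code{auc} in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  if (length(unique(labels)) < 2L)
    stop("both classes must be present")
  if (diff(range(scores)) == 0) {
    warning("constant decision scores: ROC is uninformative, AUC = 0.5")
    return(list(points = data.frame(threshold = c(Inf, -Inf),
                                    fpr = c(0, 1), tpr = c(0, 1)),
                auc = 0.5))
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n_neg,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Scan the RoI radial position for the best classification rate
#'
#' For every position on the offset grid, builds the cohort feature
#' table, runs RBF-SVM stratified cross-validation and records the
#' correct-classification rate (CRC, percent); the optimal position is
#' the CRC argmax, ties broken toward the smallest radius.  Full
#' diagnostic metrics and the ROC are reported at every position.
#' Lorentz profiles are fitted once per cohort member and reused across
#' positions (the fit is position-independent by construction).
#'
#' @param profiles list of labeled \code{roi_profile} objects.
#' @param method \code{"dir"} or \code{"lorentz"}.
#' @param a_grid positions to scan, metres; default: every positive
#'   offset shared by all profiles (up to 0.018 m).
#' @param C,gamma,scale SVM settings, see
#'   \code{\link{svm_cross_validate}}.
#' @param K folds.
#' @param seed fold-assignment seed.
#' @param constants a \code{\link{model_constants}}.
#' @return An object of class \code{roi_position_scan}: list with
#'   \code{results} (data frame: a_m, crc, accuracy, sensitivity,
#'   specificity, auc, n_used), \code{optimal_a}, \code{best} (the CV
#'   result at the optimum), \code{roc} (ROC points at the optimum),
#'   \code{method}, \code{seed}.
#' @export
scan_positions <- function(profiles, method = c("dir", "lorentz"),
                           a_grid = NULL, C = 1, gamma = NULL, K = 10L,
                           seed = 1L, scale = TRUE,
                           constants = model_constants()) {
  method <- match.arg(method)
  if (is.null(a_grid)) {
    max_a <- min(vapply(profiles, function(p) max(p$offsets), numeric(1)))
    step <- profiles[[1L]]$pixel_size
    a_grid <- seq(step, min(max_a, 0.018) + 1e-12, by = step)
  }
  if (length(a_grid) == 0L) stop("empty usable position grid")
  lorentz_fits <- if (method == "lorentz")
    lapply(profiles, function(p) tryCatch(lorentz_fit(p),
                                          error = function(e) NULL))
  else vector("list", length(profiles))
  res <- vector("list", length(a_grid))
  cvs <- vector("list", length(a_grid))
  for (i in seq_along(a_grid)) {
    a <- a_grid[i]
    row <- tryCatch({
      tab <- suppressMessages(
        build_feature_table(profiles, method, a, constants,
                            lorentz_fits = lorentz_fits))
      cv <- svm_cross_validate(tab, C = C, gamma = gamma, K = K,
                               seed = seed, scale = scale)
      m <- classification_metrics(cv$predictions, tab$label)
      roc <- suppressWarnings(roc_auc(cv$scores, tab$label))
      cvs[[i]] <- list(cv = cv, table = tab, roc = roc)
      data.frame(a_m = a, crc = cv$crc, accuracy = m$accuracy,
                 sensitivity = m$sensitivity, specificity = m$specificity,
                 auc = roc$auc, n_used = nrow(tab))
    }, error = function(e)
      data.frame(a_m = a, crc = NA_real_, accuracy = NA_real_,
                 sensitivity = NA_real_, specificity = NA_real_,
                 auc = NA_real_, n_used = 0L))
    res[[i]] <- row
  }
  results <- do.call(rbind, res)
  usable <- which(!is.na(results$crc))
  if (length(usable) == 0L) stop("empty usable position grid")
  best_i <- usable[which.max(results$crc[usable])]  # ties -> smallest a
  structure(list(results = results, optimal_a = results$a_m[best_i],
                 best = cvs[[best_i]], method = method, seed = seed,
                 C = C, K = K),
            class = "roi_position_scan")
}

#' @export
print.roi_position_scan <- function(x, ...) {
  b <- x$results[x$results$a_m == x$optimal_a, ]
  cat(sprintf("RoI position scan (%s, %d positions, %d-fold CV)\n",
              if (x$method == "dir") "D-I-R" else "Lorentz",
              nrow(x$results), x$K))
  cat(sprintf("  optimal a = %.4g m: CRC %.2f%%, AUC %.4f\n",
              x$optimal_a, b$crc, b$auc))
  cat(sprintf("  accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
              b$accuracy, b$sensitivity, b$specificity))
  invisible(x)
}

#' @export
summary.roi_position_scan <- function(object, ...) {
  print(object)
  cat("\nCRC by position:\n")
  print(object$results[, c("a_m", "crc", "auc")], row.names = FALSE)
  invisible(object)
}

#' @export
plot.roi_position_scan <- function(x, ...) {
  graphics::plot(x$results$a_m * 100, x$results$crc, type = "b", pch = 16,
                 xlab = "RoI radial position a (cm)",
                 ylab = "correct classification rate (%)",
                 main = "Classification rate across RoI positions", ...)
  graphics::abline(v = x$optimal_a * 100, lty = 2, col = 2)
  invisible(x)
}

#' Write position-scan reports to a directory
#'
#' Emits \code{crc_by_position.csv} (per-position CRC and metrics),
#' \code{metrics.csv} (diagnostic metrics at the optimal position),
#' \code{roc.csv} (ROC points at the optimum) and \code{config.yaml}
#' (run settings echo).  Outputs are deterministic given the scan.
#'
#' @param scan an \code{roi_position_scan}.
#' @param out_dir output directory (created on demand).
#' @return \code{out_dir}, invisibly.
#' @export
report <- function(scan, out_dir) {
  stopifnot(inherits(scan, "roi_position_scan"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(scan$results, file.path(out_dir, "crc_by_position.csv"),
                   row.names = FALSE)
  b <- scan$results[scan$results$a_m == scan$optimal_a, ]
  metrics <- data.frame(method = scan$method, optimal_a_m = scan$optimal_a,
                        crc = b$crc, accuracy = b$accuracy,
                        sensitivity = b$sensitivity,
                        specificity = b$specificity, auc = b$auc)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(scan$best$roc$points, file.path(out_dir, "roc.csv"),
                   row.names = FALSE)
  writeLines(c("# run settings",
               paste0("method: ", scan$method),
               paste0("seed: ", scan$seed),
               paste0("C: ", scan$C),
               paste0("K: ", scan$K),
               paste0("optimal_a_m: ", scan$optimal_a)),
             file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
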