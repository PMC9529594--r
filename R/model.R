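# Imbalance-aware training and evaluation: SMOTE oversampling,
# z-standardization, a boosted-stump (SAMME) classifier, stratified k-fold
# CV, and the confusion-matrix metric suite.

as_feature_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

#' SMOTE minority oversampling
#'
#' Generates synthetic minority-class rows on segments between a minority row
#' and one of its `k_neighbors` nearest minority neighbors (Euclidean):
#' `x_new = x + u * (x_nn - x)`, `u ~ U(0,1)`. Original rows are preserved
#' verbatim; synthetic rows are appended until
#' `minority = target_ratio * majority`.
#'
#' @param x Feature matrix / data frame (rows = epochs).
#' @param y Binary labels (0/1), length `nrow(x)`.
#' @param k_neighbors Number of minority nearest neighbors (default 5);
#'   reduced (with a message) when the minority class is too small.
#' @param target_ratio Minority/majority ratio after resampling (default 1).
#' @param seed Integer seed for the interpolation draws.
#' @return List with `x` (tibble) and `y` (integer vector).
#' @export
smote_oversample <- function(x, y, k_neighbors = 5, target_ratio = 1,
                             seed = 1) {
  m <- as_feature_matrix(x)
  y <- as.integer(y)
  if (length(y) != nrow(m))
    abort("x and y lengths differ.", class = "earpipe_config_error")
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts == 0))
    abort("SMOTE needs both classes present.", class = "earpipe_config_error")
  minority <- as.integer(names(which.min(counts)))
  n_min <- min(counts); n_maj <- max(counts)
  n_new <- round(target_ratio * n_maj) - n_min
  if (n_new <= 0)
    return(list(x = as_tibble(m), y = y))
  if (n_min <= k_neighbors) {
    k_neighbors <- n_min - 1
    inform(sprintf("SMOTE: minority class too small, k reduced to %d.",
                   k_neighbors))
  }
  if (k_neighbors < 1)
    abort("SMOTE needs at least 2 minority rows.",
          class = "earpipe_config_error")
  min_rows <- m[y == minority, , drop = FALSE]
  d <- as.matrix(stats::dist(min_rows))
  diag(d) <- Inf
  nn_idx <- t(apply(d, 1, function(r) order(r)[seq_len(k_neighbors)]))
  synth <- with_seed(seed, {
    base <- sample.int(nrow(min_rows), n_new, replace = TRUE)
    pick <- sample.int(k_neighbors, n_new, replace = TRUE)
    u <- runif(n_new)
    nb <- nn_idx[cbind(base, pick)]
    min_rows[base, , drop = FALSE] +
      u * (min_rows[nb, , drop = FALSE] - min_rows[base, , drop = FALSE])
  })
  list(x = as_tibble(rbind(m, synth)),
       y = c(y, rep(minority, n_new)))
}

#' Z-standardize features with train-only parameters
#'
#' Column means and standard deviations are fitted on the training rows only
#' and applied to both sets, preventing test-set leakage. Constant columns
#' (sd = 0) map to 0 with a warning.
#'
#' @param train_x Training feature matrix / data frame.
#' @param apply_x Optional matrix to transform with the training parameters.
#' @return List with `train_z`, `apply_z` (or `NULL`), `means`, `sds`.
#' @export
zstandardize <- function(train_x, apply_x = NULL) {
  tr <- as_feature_matrix(train_x)
  if (nrow(tr) == 0) abort("Empty training set.", class = "earpipe_config_error")
  means <- colMeans(tr)
  sds <- apply(tr, 2, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero)) {
    warn(sprintf("%d constant feature column(s) mapped to 0.", sum(zero)))
    sds[zero] <- 1
  }
  scale_mat <- function(m) {
    z <- sweep(sweep(m, 2, means), 2, sds, "/")
    z[, zero] <- 0
    as_tibble(z)
  }
  list(train_z = scale_mat(tr),
       apply_z = if (!is.null(apply_x)) scale_mat(as_feature_matrix(apply_x)),
       means = means, sds = sds)
}

stump_control <- function(depth) {
  rpart::rpart.control(maxdepth = depth, cp = -1, minsplit = 2, minbucket = 1,
                       xval = 0, maxcompete = 0, maxsurrogate = 0,
                       usesurrogate = 0)
}

#' Train the boosted-stump bruxism classifier
#'
#' Adaptive boosting (discrete SAMME weighting) of depth-limited decision
#' trees (depth 1 = stumps, fitted with `rpart` under the boosting case
#' weights). Training stops early when a weak learner reaches zero weighted
#' error or no learner better than chance can be found.
#'
#' @param x Feature matrix / data frame.
#' @param y Binary labels (0/1).
#' @param n_estimators Maximum ensemble size (default 100).
#' @param learning_rate Shrinkage on the stage weights (default 1).
#' @param base_depth Depth of each base tree (default 1).
#' @param seed Integer seed (kept for interface determinism; the fit itself
#'   is deterministic).
#' @return Object of class `brux_classifier` with a [predict()] method
#'   (`type = "class"` or `"score"`).
#' @export
train_classifier <- function(x, y, n_estimators = 100, learning_rate = 1,
                             base_depth = 1, seed = 1) {
  m <- as_feature_matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    abort("Training labels contain a single class.",
          class = "earpipe_config_error")
  if (n_estimators < 1)
    abort("n_estimators must be >= 1.", class = "earpipe_config_error")
  df <- as.data.frame(m)
  df$.y <- factor(y, levels = c(0, 1))
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (it in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w * n, method = "class",
                        control = stump_control(base_depth))
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    miss <- pred != y
    err <- sum(w[miss])
    if (err >= 0.5) break  # no better than chance under current weights
    err <- max(err, 1e-12)
    alpha <- learning_rate * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    if (err <= 1e-12) break
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  if (length(stumps) == 0)
    abort("Boosting found no weak learner better than chance.",
          class = "earpipe_fit_error")
  structure(list(stumps = stumps, alphas = alphas,
                 feature_names = colnames(m),
                 n_estimators = n_estimators,
                 learning_rate = learning_rate, base_depth = base_depth,
                 seed = seed),
            class = "brux_classifier")
}

#' @rdname train_classifier
#' @param object A `brux_classifier`.
#' @param newdata Feature matrix / data frame.
#' @param type `"class"` for 0/1 labels, `"score"` for the signed ensemble
#'   vote margin.
#' @param ... Unused.
#' @export
predict.brux_classifier <- function(object, newdata,
                                    type = c("class", "score"), ...) {
  type <- match.arg(type)
  df <- as.data.frame(as_feature_matrix(newdata))
  score <- rep(0, nrow(df))
  for (i in seq_along(object$stumps)) {
    p <- as.integer(as.character(predict(object$stumps[[i]], df,
                                         type = "class")))
    score <- score + object$alphas[i] * (2 * p - 1)
  }
  if (type == "score") score else as.integer(score > 0)
}

#' @export
print.brux_classifier <- function(x, ...) {
  cat(sprintf("<brux_classifier> %d boosted depth-%d trees (requested %d)\n",
              length(x$stumps), x$base_depth, x$n_estimators))
  invisible(x)
}

# Stratified fold ids: within-class shuffles dealt round-robin, the second
# class continuing the cycle so fold sizes also differ by at most one.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  offset <- 0L
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- sample(which(y == cls))
      fold[idx] <- ((seq_along(idx) - 1 + offset) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

#' Stratified k-fold cross-validation with in-fold resampling
#'
#' Splits the training set into `cv_folds` class-stratified folds (per-fold
#' positive counts differ by at most one). For every hyperparameter setting
#' in the grid, each fold is scored by: SMOTE and z-standardization fitted on
#' the training folds only, classifier trained, validation fold predicted.
#' The setting with the best mean F1 is selected.
#'
#' @param x Feature matrix / data frame.
#' @param y Binary labels (0/1).
#' @param cv_folds Number of folds (default 5).
#' @param grid Named list of hyperparameter vectors to search (default
#'   `list(n_estimators = c(50, 100, 200))`).
#' @param k_neighbors,target_ratio SMOTE settings (see [smote_oversample()]).
#' @param learning_rate,base_depth Classifier settings used unless present in
#'   `grid`.
#' @param seed Integer seed (fold assignment + SMOTE draws).
#' @return Object of class `cv_result`: `folds` tibble (one row per fold x
#'   setting with the four metrics), `best` (named list of selected
#'   hyperparameters), `summary` tibble of mean metrics per setting.
#' @export
stratified_cv <- function(x, y, cv_folds = 5,
                          grid = list(n_estimators = c(50, 100, 200)),
                          k_neighbors = 5, target_ratio = 1,
                          learning_rate = 1, base_depth = 1, seed = 1) {
  m <- as_feature_matrix(x)
  y <- as.integer(y)
  if (min(table(y)) < cv_folds)
    abort("Each class must have at least cv_folds members.",
          class = "earpipe_config_error")
  fold <- stratified_folds(y, cv_folds, seed)
  settings <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(settings) == 0) settings <- data.frame(n_estimators = 100)
  rows <- list()
  for (si in seq_len(nrow(settings))) {
    s <- as.list(settings[si, , drop = FALSE])
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      res <- smote_oversample(m[tr, , drop = FALSE], y[tr],
                              k_neighbors = k_neighbors,
                              target_ratio = target_ratio,
                              seed = seed + 97L * f)
      z <- zstandardize(res$x, m[!tr, , drop = FALSE])
      fit <- train_classifier(z$train_z, res$y,
                              n_estimators = s$n_estimators %||% 100,
                              learning_rate = s$learning_rate %||% learning_rate,
                              base_depth = s$base_depth %||% base_depth,
                              seed = seed)
      rep <- evaluate(y[!tr], predict(fit, z$apply_z))
      rows[[length(rows) + 1]] <-
        dplyr::bind_cols(as_tibble(s), tibble(fold = f), glance(rep))
    }
  }
  folds <- dplyr::bind_rows(rows)
  by <- names(settings)
  summ <- folds %>%
    group_by(dplyr::across(dplyr::all_of(by))) %>%
    summarise(dplyr::across(c("precision", "recall", "f1", "mcc"), mean),
              .groups = "drop")
  best <- as.list(summ[which.max(summ$f1), by, drop = FALSE])
  structure(list(folds = folds, summary = summ, best = best,
                 cv_folds = cv_folds, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold stratified CV; best by mean F1: %s\n",
              x$cv_folds,
              paste(names(x$best), unlist(x$best), sep = "=", collapse = ", ")))
  print(x$summary)
  invisible(x)
}

#' Confusion-matrix evaluation of binary predictions
#'
#' Computes TP/FP/FN/TN and precision, recall, F1 and the Matthews
#' correlation coefficient; any 0/0 is defined as 0.
#'
#' @param y_true True 0/1 labels.
#' @param y_pred Predicted 0/1 labels, same length.
#' @return Object of class `eval_report`.
#' @export
evaluate <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    abort("y_true and y_pred lengths differ.", class = "earpipe_config_error")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L)))
    abort("Labels must be binary 0/1.", class = "earpipe_config_error")
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  safe <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  f1 <- safe(2 * precision * recall, precision + recall)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = precision, recall = recall, f1 = f1, mcc = mcc,
                 prevalence = safe(tp + fn, length(y_true)),
                 n = length(y_true)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d (prevalence %.3f)\n", x$n, x$prevalence))
  cat(sprintf("  TP=%d FP=%d FN=%d TN=%d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  precision=%.3f recall=%.3f F1=%.3f MCC=%.3f\n",
              x$precision, x$recall, x$f1, x$mcc))
  invisible(x)
}

#' Permutation null distribution of the F1 score
#'
#' Repeatedly permutes the true labels against fixed predictions and
#' recomputes F1, giving the no-association reference distribution.
#'
#' @param y_true True labels.
#' @param y_pred Fixed predictions.
#' @param n_rep Number of permutations (default 200).
#' @param seed Integer seed.
#' @return Numeric vector of `n_rep` null F1 values.
#' @export
f1_permutation_null <- function(y_true, y_pred, n_rep = 200, seed = 1) {
  y_true <- as.integer(y_true)
  with_seed(seed, vapply(seq_len(n_rep), function(i)
    evaluate(sample(y_true), y_pred)$f1, numeric(1)))
}
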