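make_toy <- function(n_pos = 10, n_neg = 90, p = 4, sep = 3, seed = 24) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_neg * p), n_neg),
             matrix(rnorm(n_pos * p, mean = sep), n_pos))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = c(rep(0L, n_neg), rep(1L, n_pos)))
}

test_that("SMOTE balances classes and preserves originals verbatim", {
  toy <- make_toy()
  out <- smote_oversample(toy$x, toy$y, seed = 1)
  expect_identical(sum(out$y == 1), 90L)
  expect_identical(sum(out$y == 0), 90L)
  expect_equal(as.matrix(out$x[seq_len(100), ]), toy$x, ignore_attr = TRUE)

  balanced <- smote_oversample(toy$x[81:100, ], toy$y[81:100], seed = 1)
  expect_identical(nrow(balanced$x), 20L)
  expect_error(smote_oversample(toy$x, rep(0, 100)),
               class = "earpipe_config_error")
})

test_that("every synthetic SMOTE row lies on a segment between minority rows", {
  toy <- make_toy(n_pos = 8, n_neg = 40, p = 3)
  out <- smote_oversample(toy$x, toy$y, k_neighbors = 3, seed = 2)
  minority <- toy$x[toy$y == 1, ]
  synth <- as.matrix(out$x)[(nrow(toy$x) + 1):nrow(out$x), , drop = FALSE]
  on_segment <- function(z) {
    for (i in seq_len(nrow(minority) - 1)) {
      for (j in (i + 1):nrow(minority)) {
        d <- minority[j, ] - minority[i, ]
        if (sum(d^2) == 0) next
        u <- sum((z - minority[i, ]) * d) / sum(d^2)
        if (u >= -1e-9 && u <= 1 + 1e-9 &&
            sqrt(sum((z - (minority[i, ] + u * d))^2)) < 1e-9)
          return(TRUE)
      }
    }
    FALSE
  }
  expect_true(all(apply(synth, 1, on_segment)))
})

test_that("z-standardization fits on train only", {
  toy <- make_toy()
  shifted <- toy$x + 100
  z <- zstandardize(toy$x, shifted)
  expect_lt(max(abs(colMeans(z$train_z))), 1e-9)
  expect_lt(max(abs(apply(as.matrix(z$train_z), 2, sd) - 1)), 1e-9)
  # the apply set is transformed with TRAIN parameters, not its own
  expect_gt(min(colMeans(as.matrix(z$apply_z))), 50)

  const <- cbind(toy$x, cns = 1)
  expect_warning(zc <- zstandardize(const), "constant")
  expect_true(all(zc$train_z$cns == 0))
})

test_that("boosted stumps separate a separable toy set and are deterministic", {
  toy <- make_toy(sep = 6)
  fit <- train_classifier(toy$x, toy$y, n_estimators = 20)
  expect_identical(predict(fit, toy$x), toy$y)
  fit2 <- train_classifier(toy$x, toy$y, n_estimators = 20)
  expect_identical(predict(fit2, toy$x), predict(fit, toy$x))
  expect_error(train_classifier(toy$x, rep(1, 100)),
               class = "earpipe_config_error")
  td <- tidy(fit)
  expect_true(all(td$alpha > 0))
  expect_identical(nrow(glance(fit)), 1L)
})

test_that("with labels independent of features CV accuracy matches the majority rate", {
  set.seed(25)
  n <- 400
  x <- matrix(rnorm(n * 5), n)
  colnames(x) <- paste0("f", 1:5)
  y <- as.integer(runif(n) < 0.25)
  folds <- 5
  fold <- earpipe:::stratified_folds(y, folds, seed = 3)
  acc <- vapply(seq_len(folds), function(f) {
    fit <- train_classifier(x[fold != f, ], y[fold != f], n_estimators = 30)
    mean(predict(fit, x[fold == f, ]) == y[fold == f])
  }, numeric(1))
  maj <- max(mean(y), 1 - mean(y))
  se <- sqrt(maj * (1 - maj) / n)
  expect_lt(abs(mean(acc) - maj), 3 * se + 0.02)
})

test_that("stratified CV partitions correctly and selects by mean F1", {
  toy <- make_toy(n_pos = 25, n_neg = 100, sep = 2.5)
  cv <- stratified_cv(toy$x, toy$y, cv_folds = 5,
                      grid = list(n_estimators = c(10, 30)), seed = 4)
  folds <- earpipe:::stratified_folds(toy$y, 5, seed = 4)
  sizes <- table(folds)
  expect_lte(diff(range(sizes)), 1)
  pos_counts <- table(folds[toy$y == 1])
  expect_lte(diff(range(pos_counts)), 1)
  expect_equal(sort(unique(folds)), 1:5)
  expect_identical(length(folds), 125L)

  expect_identical(nrow(cv$folds), 10L)
  expect_true(cv$best$n_estimators %in% c(10, 30))
  expect_identical(nrow(glance(cv)), 1L)
  expect_error(stratified_cv(toy$x[1:20, ], c(rep(0, 18), 1, 1), cv_folds = 5),
               class = "earpipe_config_error")
})

test_that("evaluation metrics match direct formula evaluation", {
  perfect <- evaluate(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_identical(c(perfect$precision, perfect$recall, perfect$f1,
                     perfect$mcc), rep(1, 4))

  allneg <- evaluate(c(1, 1, 0, 0), c(0, 0, 0, 0))
  expect_identical(c(allneg$recall, allneg$f1, allneg$mcc, allneg$precision),
                   rep(0, 4))

  tp <- 37; fp <- 14; fn <- 13; tn <- 236
  y_true <- c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn))
  y_pred <- c(rep(1, tp), rep(1, fp), rep(0, fn), rep(0, tn))
  r <- evaluate(y_true, y_pred)
  expect_identical(c(r$tp, r$fp, r$fn, r$tn), c(37L, 14L, 13L, 236L))
  expect_equal(r$precision, 37 / 51)
  expect_equal(r$recall, 37 / 50)
  expect_equal(r$f1, 2 * (37 / 51) * (37 / 50) / (37 / 51 + 37 / 50))
  expect_equal(r$mcc, (37 * 236 - 14 * 13) /
                 sqrt(51 * 50 * 250 * 249))
  expect_error(evaluate(c(1, 0), c(1, 0, 0)), class = "earpipe_config_error")
})

test_that("MCC is symmetric under label flips and metrics stay in bounds", {
  set.seed(26)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    y <- as.integer(runif(n) < runif(1))
    p <- as.integer(runif(n) < runif(1))
    r <- evaluate(y, p)
    rflip <- evaluate(1L - y, 1L - p)
    expect_equal(r$mcc, rflip$mcc)
    expect_true(r$precision >= 0 && r$precision <= 1)
    expect_true(r$recall >= 0 && r$recall <= 1)
    expect_true(r$f1 >= 0 && r$f1 <= 1)
    expect_true(r$mcc >= -1 && r$mcc <= 1)
    expect_identical(r$tp + r$fp + r$fn + r$tn, n)
  }
})

test_that("tidy/glance on eval reports expose all counts and metrics", {
  r <- evaluate(c(1, 0, 1, 0), c(1, 1, 1, 0))
  td <- tidy(r)
  expect_setequal(td$metric, c("tp", "fp", "fn", "tn", "precision", "recall",
                               "f1", "mcc", "prevalence"))
  g <- glance(r)
  expect_identical(g$tp + g$fp + g$fn + g$tn, 4L)
})
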