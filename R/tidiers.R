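# broom-style tidiers and plotting methods for the fitted objects.

#' Tidy an evaluation report
#' @param x An `eval_report` from [evaluate()].
#' @param ... Unused.
#' @return Tibble with one row per metric (`metric`, `value`).
#' @export
tidy.eval_report <- function(x, ...) {
  tibble(metric = c("tp", "fp", "fn", "tn",
                    "precision", "recall", "f1", "mcc", "prevalence"),
         value = c(x$tp, x$fp, x$fn, x$tn,
                   x$precision, x$recall, x$f1, x$mcc, x$prevalence))
}

#' Glance at an evaluation report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row tibble of the four headline metrics plus counts.
#' @export
glance.eval_report <- function(x, ...) {
  tibble(precision = x$precision, recall = x$recall, f1 = x$f1, mcc = x$mcc,
         tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
         prevalence = x$prevalence, n = x$n)
}

#' Tidy a fitted boosted-stump classifier
#'
#' One row per boosting stage: the stage weight (alpha) and, for stumps, the
#' splitting feature and threshold.
#'
#' @param x A `brux_classifier`.
#' @param ... Unused.
#' @return Tibble with `stage`, `alpha`, `feature`, `threshold`.
#' @export
tidy.brux_classifier <- function(x, ...) {
  info <- purrr::map(x$stumps, function(s) {
    fr <- s$frame
    if (nrow(fr) < 2 || fr$var[1] == "<leaf>")
      return(list(feature = NA_character_, threshold = NA_real_))
    list(feature = as.character(fr$var[1]),
         threshold = unname(s$splits[1, "index"]))
  })
  tibble(stage = seq_along(x$stumps),
         alpha = x$alphas,
         feature = purrr::map_chr(info, "feature"),
         threshold = purrr::map_dbl(info, "threshold"))
}

#' Glance at a fitted boosted-stump classifier
#' @param x A `brux_classifier`.
#' @param ... Unused.
#' @return One-row tibble: stages fitted/requested, depth, learning rate.
#' @export
glance.brux_classifier <- function(x, ...) {
  tibble(n_stages = length(x$stumps), n_requested = x$n_estimators,
         base_depth = x$base_depth, learning_rate = x$learning_rate)
}

#' Tidy a cross-validation result
#' @param x A `cv_result` from [stratified_cv()].
#' @param ... Unused.
#' @return The per-fold metrics tibble.
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' Glance at a cross-validation result
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return One-row tibble: selected hyperparameters and their mean metrics.
#' @export
glance.cv_result <- function(x, ...) {
  best_row <- dplyr::inner_join(x$summary, as_tibble(x$best),
                                by = names(x$best))
  dplyr::bind_cols(as_tibble(x$best),
                   best_row[c("precision", "recall", "f1", "mcc")])
}

#' @export
tidy.pipeline_result <- function(x, ...) tidy(x$report)

#' @export
glance.pipeline_result <- function(x, ...) glance(x$report)

#' Plot an evaluation report as a metric bar chart
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidy(object) %>%
    filter(.data$metric %in% c("precision", "recall", "f1", "mcc"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Held-out session performance") +
    ggplot2::theme_minimal()
}

#' Plot per-channel feature distributions by class
#'
#' @param features Feature tibble from [extract_features()].
#' @param feature Which of the seven features to show (default
#'   `"activity"`).
#' @return A ggplot object: per-channel boxplots split by bruxism label.
#' @export
plot_feature_by_class <- function(features, feature = "activity") {
  cols <- grep(paste0("_", feature, "$"), names(features), value = TRUE)
  if (length(cols) == 0)
    abort(sprintf("No columns for feature '%s'.", feature),
          class = "earpipe_config_error")
  long <- tidyr::pivot_longer(features[c("label", cols)],
                              dplyr::all_of(cols),
                              names_to = "channel", values_to = "value")
  long$channel <- sub(paste0("_", feature, "$"), "", long$channel)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$channel, y = .data$value,
                                     fill = factor(.data$label))) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = feature, fill = "bruxism") +
    ggplot2::theme_minimal()
}
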