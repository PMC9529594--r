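# End-to-end chain: preprocess -> epoch + label -> features -> CV-optimize ->
# fit on the pooled training sessions -> predict the held-out session.

#' Features for one annotated session
#'
#' Convenience wrapper running labeling, epoching, preprocessing and feature
#' extraction for a single recording.
#'
#' @param recording An [ear_recording()].
#' @param annotations Annotation tibble.
#' @param preprocess `"epoch"` (mean-center + band-pass + notch per 1 s
#'   epoch) or `"session"` (filter the whole channel once, then epoch).
#' @param band_hz,notch_hz Filter settings.
#' @param shift_s,epoch_s,bruxism_fraction Labeling/epoching settings.
#' @param k_max Higuchi `k_max`.
#' @return Feature tibble from [extract_features()].
#' @export
session_features <- function(recording, annotations,
                             preprocess = c("epoch", "session"),
                             band_hz = c(5, 62), notch_hz = 50,
                             shift_s = 0.350, epoch_s = 1,
                             bruxism_fraction = 0.5, k_max = 10) {
  preprocess <- match.arg(preprocess)
  if (preprocess == "session")
    recording <- preprocess_recording(recording, band_hz, notch_hz)
  epochs <- make_epochs(recording, annotations, epoch_s = epoch_s,
                        bruxism_fraction = bruxism_fraction,
                        shift_s = shift_s)
  if (preprocess == "epoch")
    epochs <- preprocess_epochs(epochs, band_hz, notch_hz)
  extract_features(epochs, k_max = k_max)
}

#' Run the full cross-session bruxism classification pipeline
#'
#' Two (or more) sessions are pooled into a training set; one session is held
#' out for testing. Per session: preprocessing, epoching with the 350 ms
#' shifted labeling rule, feature extraction. On the pooled training set:
#' optional stratified CV over the hyperparameter grid (best mean F1), then
#' SMOTE oversampling and z-standardization fitted on the full training set,
#' a boosted-stump classifier, and prediction of the held-out session.
#'
#' @param study Study tibble from [generate_study()] (columns `session_id`,
#'   `recording`, `annotations`), or a list of `list(recording, annotations)`.
#' @param train_sessions Character vector of training session ids.
#' @param test_session Held-out session id.
#' @param grid Hyperparameter grid for [stratified_cv()], or `NULL` to skip
#'   CV and use `n_estimators` directly.
#' @param cv_folds Number of CV folds (default 5).
#' @param n_estimators,learning_rate,base_depth Classifier defaults.
#' @param k_neighbors,target_ratio SMOTE settings.
#' @param seed Integer seed governing SMOTE and CV fold draws.
#' @inheritParams session_features
#' @return Object of class `pipeline_result`: `report` ([evaluate()] result
#'   on the held-out session), `cv` (a `cv_result` or `NULL`),
#'   `chosen` hyperparameters, `predictions`/`truth` vectors, `model`, and a
#'   `run_log` list of every configuration value and seed.
#' @export
run_pipeline <- function(study, train_sessions, test_session,
                         preprocess = c("epoch", "session"),
                         band_hz = c(5, 62), notch_hz = 50, shift_s = 0.350,
                         epoch_s = 1, bruxism_fraction = 0.5, k_max = 10,
                         grid = list(n_estimators = c(50, 100, 200)),
                         cv_folds = 5, n_estimators = 100, learning_rate = 1,
                         base_depth = 1, k_neighbors = 5, target_ratio = 1,
                         seed = 1) {
  preprocess <- match.arg(preprocess)
  if (!is_tibble(study))
    study <- tibble(
      session_id = purrr::map_chr(study, ~ .x$recording$session_id),
      recording = purrr::map(study, "recording"),
      annotations = purrr::map(study, "annotations"))
  if (test_session %in% train_sessions)
    abort("test_session must not be a training session.",
          class = "earpipe_config_error")
  missing <- setdiff(c(train_sessions, test_session), study$session_id)
  if (length(missing))
    abort(sprintf("Session(s) not in study: %s",
                  paste(missing, collapse = ", ")),
          class = "earpipe_config_error")
  if (length(train_sessions) < 1)
    abort("Need at least one training session.",
          class = "earpipe_config_error")

  feats <- purrr::map(c(train_sessions, test_session), function(sid) {
    i <- match(sid, study$session_id)
    session_features(study$recording[[i]], study$annotations[[i]],
                     preprocess = preprocess, band_hz = band_hz,
                     notch_hz = notch_hz, shift_s = shift_s,
                     epoch_s = epoch_s, bruxism_fraction = bruxism_fraction,
                     k_max = k_max)
  })
  names(feats) <- c(train_sessions, test_session)
  train_tbl <- dplyr::bind_rows(feats[train_sessions])
  test_tbl <- feats[[test_session]]
  fcols <- feature_columns(train_tbl)
  train_x <- train_tbl[fcols]; train_y <- train_tbl$label
  test_x <- test_tbl[fcols]; test_y <- test_tbl$label

  cv <- NULL
  chosen <- list(n_estimators = n_estimators,
                 learning_rate = learning_rate, base_depth = base_depth)
  if (!is.null(grid)) {
    cv <- stratified_cv(train_x, train_y, cv_folds = cv_folds, grid = grid,
                        k_neighbors = k_neighbors,
                        target_ratio = target_ratio,
                        learning_rate = learning_rate,
                        base_depth = base_depth, seed = seed)
    chosen[names(cv$best)] <- cv$best
  }
  res <- smote_oversample(train_x, train_y, k_neighbors = k_neighbors,
                          target_ratio = target_ratio, seed = seed + 7919L)
  z <- zstandardize(res$x, test_x)
  model <- train_classifier(z$train_z, res$y,
                            n_estimators = chosen$n_estimators,
                            learning_rate = chosen$learning_rate,
                            base_depth = chosen$base_depth, seed = seed)
  pred <- predict(model, z$apply_z)
  report <- evaluate(test_y, pred)
  run_log <- list(
    package_version = as.character(packageVersion("earpipe")),
    train_sessions = train_sessions, test_session = test_session,
    preprocess = preprocess, band_hz = band_hz, notch_hz = notch_hz,
    shift_s = shift_s, epoch_s = epoch_s,
    bruxism_fraction = bruxism_fraction, k_max = k_max,
    grid = grid, cv_folds = if (!is.null(grid)) cv_folds else NULL,
    chosen = chosen, k_neighbors = k_neighbors,
    target_ratio = target_ratio, seed = seed,
    n_train_epochs = nrow(train_tbl), n_test_epochs = nrow(test_tbl))
  structure(list(report = report, cv = cv, chosen = chosen,
                 predictions = pred, truth = test_y, model = model,
                 run_log = run_log),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> train: %s | test: %s\n",
              paste(x$run_log$train_sessions, collapse = "+"),
              x$run_log$test_session))
  print(x$report)
  invisible(x)
}
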