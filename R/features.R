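# The seven per-channel time-domain features: Hjorth activity / mobility /
# complexity, absolute-amplitude maximum and sum, Higuchi and Petrosian
# fractal dimensions. On 16 channels this yields the 112-column feature
# matrix the classifier consumes.

FEATURE_NAMES <- c("activity", "complexity", "mobility", "abs_max",
                   "abs_sum", "higuchi_fd", "petrosian_fd")

#' Remove the mean of a signal
#' @param x Numeric vector.
#' @return `x - mean(x)`.
#' @export
mean_center <- function(x) {
  if (length(x) == 0) abort("Empty signal.", class = "earpipe_config_error")
  x - mean(x)
}

pop_var <- function(x) mean((x - mean(x))^2)

#' Hjorth parameters
#'
#' Activity is the (population) variance; mobility the ratio
#' `sqrt(var(dx)/var(x))` -- a mean-frequency proxy; complexity the mobility
#' of the first difference divided by the mobility of the signal -- a
#' bandwidth proxy. A flat signal returns `(0, 0, 0)` by convention.
#'
#' @param x Numeric vector, length >= 3.
#' @return Named numeric vector `activity`, `mobility`, `complexity`.
#' @export
hjorth <- function(x) {
  if (length(x) < 3)
    abort("Hjorth parameters need at least 3 samples.",
          class = "earpipe_config_error")
  v0 <- pop_var(x)
  if (v0 == 0) return(c(activity = 0, mobility = 0, complexity = 0))
  d1 <- diff(x)
  v1 <- pop_var(d1)
  mob <- sqrt(v1 / v0)
  if (v1 == 0) return(c(activity = v0, mobility = mob, complexity = 0))
  v2 <- pop_var(diff(d1))
  c(activity = v0, mobility = mob, complexity = sqrt(v2 / v1) / mob)
}

#' Absolute-amplitude features
#' @param x Numeric vector.
#' @return Named vector `abs_max = max|x|`, `abs_sum = sum|x|`.
#' @export
abs_amplitude <- function(x) {
  if (length(x) == 0) abort("Empty signal.", class = "earpipe_config_error")
  c(abs_max = max(abs(x)), abs_sum = sum(abs(x)))
}

#' Petrosian fractal dimension
#'
#' `PFD = log10(n) / (log10(n) + log10(n / (n + 0.4 * Nd)))` with `Nd` the
#' number of sign changes in the first difference. Exact zeros in the
#' difference are ignored: a change is counted between the nearest nonzero
#' neighbors, so monotone (and flat) signals give `Nd = 0` and `PFD = 1`.
#'
#' @param x Numeric vector, length >= 2.
#' @return The fractal dimension (>= 1).
#' @export
petrosian_fd <- function(x) {
  n <- length(x)
  if (n < 2)
    abort("Petrosian FD needs at least 2 samples.",
          class = "earpipe_config_error")
  s <- sign(diff(x))
  s <- s[s != 0]
  nd <- if (length(s) > 1) sum(s[-1] != s[-length(s)]) else 0
  log10(n) / (log10(n) + log10(n / (n + 0.4 * nd)))
}

#' Higuchi fractal dimension
#'
#' Standard Higuchi construction: average normalized curve lengths `L(k)`
#' over decimation offsets for `k = 1..k_max`, then the FD is the slope of
#' the least-squares fit of `ln L(k)` on `ln(1/k)`. Approaches 1 for smooth
#' curves and 2 for white noise. A constant signal returns 1 by convention.
#'
#' @param x Numeric vector with `length(x) > 2 * k_max`.
#' @param k_max Maximum decimation factor (default 10, suited to ~250-sample
#'   epochs).
#' @return The fractal dimension estimate.
#' @export
higuchi_fd <- function(x, k_max = 10) {
  n <- length(x)
  if (k_max < 2 || n <= 2 * k_max)
    abort("Need 2 <= k_max < length(x)/2.", class = "earpipe_config_error")
  L <- .higuchi_lengths(as.numeric(x), as.integer(k_max))
  if (any(!is.finite(L)) || any(L <= 0)) return(1)
  lk <- log(1 / seq_len(k_max))
  ll <- log(L)
  sum((lk - mean(lk)) * (ll - mean(ll))) / sum((lk - mean(lk))^2)
}

compute_channel_features <- function(x, k_max = 10) {
  x <- mean_center(x)
  hj <- hjorth(x)
  aa <- abs_amplitude(x)
  c(activity = unname(hj["activity"]),
    complexity = unname(hj["complexity"]),
    mobility = unname(hj["mobility"]),
    abs_max = unname(aa["abs_max"]),
    abs_sum = unname(aa["abs_sum"]),
    higuchi_fd = higuchi_fd(x, k_max),
    petrosian_fd = petrosian_fd(x))
}

#' Extract the per-channel feature matrix from an epoch set
#'
#' Mean-centers each epoch channel, then computes the 7 features per channel
#' in fixed order (activity, complexity, mobility, abs_max, abs_sum,
#' higuchi_fd, petrosian_fd). Columns are named `<channel>_<feature>`; with
#' 16 channels this is 112 feature columns.
#'
#' @param epochs An `epoch_set`.
#' @param k_max Higuchi `k_max`.
#' @return Tibble with `session_id`, `epoch`, `activity_label`, `label`
#'   (0/1) and one numeric column per channel-feature pair.
#' @export
extract_features <- function(epochs, k_max = 10) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  n_ep <- d[1]; n_ch <- d[2]
  cols <- as.vector(t(outer(epochs$channel_labels, FEATURE_NAMES, paste,
                            sep = "_")))
  vals <- matrix(NA_real_, n_ep, n_ch * 7, dimnames = list(NULL, cols))
  for (e in seq_len(n_ep)) {
    for (c_i in seq_len(n_ch)) {
      vals[e, ((c_i - 1) * 7 + 1):(c_i * 7)] <-
        compute_channel_features(epochs$data[e, c_i, ], k_max)
    }
  }
  if (!all(is.finite(vals)))
    abort("Non-finite feature values computed.", class = "earpipe_numeric_error")
  dplyr::bind_cols(
    tibble(session_id = epochs$session_id, epoch = seq_len(n_ep),
           activity_label = epochs$activity, label = epochs$labels),
    as_tibble(vals))
}

#' Names of the feature columns in a feature tibble
#' @param features Tibble from [extract_features()].
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(features) {
  setdiff(names(features), c("session_id", "epoch", "activity_label", "label"))
}
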