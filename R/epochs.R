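# Epoch-level labeling: converts annotated recordings into non-overlapping
# 1 s windows with binary bruxism labels.

#' Per-sample binary bruxism labels
#'
#' Sample `i` (0-based) is labeled 1 iff its time `i/fs` falls inside
#' `[onset + shift, offset + shift)` of any bruxism annotation. The shift
#' compensates the wearer's reaction time to the activity cue: both onset and
#' offset are delayed by `shift_s`. Interval-to-sample convention: half-open,
#' start index `ceil(start_s * fs)`. Shifted intervals are clipped to the
#' recording bounds.
#'
#' @param recording An [ear_recording()].
#' @param annotations Annotation tibble (`label`, `is_bruxism`, `onset_s`,
#'   `offset_s`).
#' @param shift_s Onset/offset delay in seconds (default 0.350).
#' @return Integer vector of 0/1, one per sample.
#' @export
label_samples <- function(recording, annotations, shift_s = 0.350) {
  n <- ncol(recording$data)
  fs <- recording$fs
  labels <- integer(n)
  if (nrow(annotations) == 0) return(labels)
  brux <- annotations[annotations$is_bruxism, , drop = FALSE]
  for (k in seq_len(nrow(brux))) {
    i0 <- ceiling((brux$onset_s[k] + shift_s) * fs - 1e-9)   # 0-based, incl.
    i1 <- ceiling((brux$offset_s[k] + shift_s) * fs - 1e-9)  # 0-based, excl.
    i0 <- max(0L, i0); i1 <- min(n, i1)
    if (i1 > i0) labels[(i0 + 1):i1] <- 1L
  }
  labels
}

# Dominant (most-covered) shifted activity per epoch, "rest" where no
# activity covers any sample.
epoch_activities <- function(n_epochs, epoch_samples, fs, annotations,
                             shift_s) {
  out <- rep("rest", n_epochs)
  if (nrow(annotations) == 0) return(out)
  cover <- matrix(0L, n_epochs, nrow(annotations))
  n <- n_epochs * epoch_samples
  for (k in seq_len(nrow(annotations))) {
    i0 <- max(0L, ceiling((annotations$onset_s[k] + shift_s) * fs - 1e-9))
    i1 <- min(n, ceiling((annotations$offset_s[k] + shift_s) * fs - 1e-9))
    if (i1 <= i0) next
    ep <- (i0:(i1 - 1)) %/% epoch_samples + 1
    tab <- table(ep)
    cover[as.integer(names(tab)), k] <- as.integer(tab)
  }
  hit <- which(rowSums(cover) > 0)
  out[hit] <- annotations$label[max.col(cover[hit, , drop = FALSE],
                                        ties.method = "first")]
  out
}

#' Cut a recording into labeled, non-overlapping epochs
#'
#' Epochs tile the session from sample 0 (no alignment to trial onsets,
#' mimicking an online system); the trailing partial window is discarded. An
#' epoch is bruxism-positive iff at least `bruxism_fraction` of its samples
#' carry a positive per-sample label (the boundary is inclusive: exactly 50%
#' counts).
#'
#' @param recording An [ear_recording()].
#' @param annotations Annotation tibble.
#' @param sample_labels Optional precomputed 0/1 vector from
#'   [label_samples()]; computed internally when `NULL`.
#' @param epoch_s Epoch length in seconds (default 1).
#' @param bruxism_fraction Labeled-sample fraction threshold (default 0.5).
#' @param shift_s Labeling shift passed to [label_samples()].
#' @return An object of class `epoch_set`: `data` (epochs x channels x
#'   samples array), `labels` (0/1), `activity` (dominant activity or
#'   `"rest"`), `session_id`, `fs`, `channel_labels`.
#' @export
make_epochs <- function(recording, annotations, sample_labels = NULL,
                        epoch_s = 1, bruxism_fraction = 0.5,
                        shift_s = 0.350) {
  if (bruxism_fraction <= 0 || bruxism_fraction > 1)
    abort("Need 0 < bruxism_fraction <= 1.", class = "earpipe_config_error")
  fs <- recording$fs
  epoch_samples <- round(epoch_s * fs)
  n <- ncol(recording$data)
  if (n < epoch_samples)
    abort("Recording shorter than one epoch.", class = "earpipe_config_error")
  sample_labels <- sample_labels %||%
    label_samples(recording, annotations, shift_s)
  n_epochs <- n %/% epoch_samples
  used <- n_epochs * epoch_samples
  lab_mat <- matrix(sample_labels[seq_len(used)], epoch_samples, n_epochs)
  frac <- colMeans(lab_mat)
  labels <- as.integer(frac >= bruxism_fraction - 1e-12)
  n_ch <- nrow(recording$data)
  data <- array(0, dim = c(n_epochs, n_ch, epoch_samples))
  for (e in seq_len(n_epochs))
    data[e, , ] <- recording$data[, ((e - 1) * epoch_samples + 1):(e * epoch_samples)]
  structure(
    list(data = data, labels = labels,
         activity = epoch_activities(n_epochs, epoch_samples, fs,
                                     annotations, shift_s),
         session_id = recording$session_id, fs = fs,
         channel_labels = recording$channel_labels),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> session %s: %d epochs x %d channels x %d samples; %d bruxism (%.1f%%)\n",
              x$session_id, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              sum(x$labels), 100 * mean(x$labels)))
  invisible(x)
}

#' Preprocess epochs: mean-centering, band-pass, notch
#'
#' Applies, per epoch and channel: (1) mean-centering, (2) 5-62 Hz IIR
#' band-pass, (3) 50 Hz IIR notch. Filters are zero-phase by default, which
#' keeps event energy aligned within the epoch despite the short (1 s)
#' filtering segments.
#'
#' @param epochs An `epoch_set`.
#' @param band_hz Band-pass edges (Hz).
#' @param notch_hz Notch frequency (Hz).
#' @param zero_phase Zero-phase application?
#' @return The preprocessed `epoch_set`.
#' @export
preprocess_epochs <- function(epochs, band_hz = c(5, 62), notch_hz = 50,
                              zero_phase = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  bp <- filter_spec("bandpass_iir", band_hz = band_hz, zero_phase = zero_phase)
  nt <- filter_spec("notch_iir", notch_hz = notch_hz, zero_phase = zero_phase)
  d <- dim(epochs$data)
  for (e in seq_len(d[1])) {
    for (c_i in seq_len(d[2])) {
      x <- epochs$data[e, c_i, ]
      x <- x - mean(x)
      x <- apply_filter(x, epochs$fs, bp)
      x <- apply_filter(x, epochs$fs, nt)
      epochs$data[e, c_i, ] <- x
    }
  }
  epochs
}

#' Preprocess a whole recording before epoching
#'
#' Session-scope alternative to [preprocess_epochs()]: mean-centers and
#' filters each full channel once, avoiding short-segment edge effects.
#'
#' @inheritParams preprocess_epochs
#' @param recording An [ear_recording()].
#' @return The filtered recording.
#' @export
preprocess_recording <- function(recording, band_hz = c(5, 62),
                                 notch_hz = 50, zero_phase = TRUE) {
  bp <- filter_spec("bandpass_iir", band_hz = band_hz, zero_phase = zero_phase)
  nt <- filter_spec("notch_iir", notch_hz = notch_hz, zero_phase = zero_phase)
  for (c_i in seq_len(nrow(recording$data))) {
    x <- recording$data[c_i, ]
    x <- x - mean(x)
    recording$data[c_i, ] <- apply_filter(apply_filter(x, recording$fs, bp),
                                          recording$fs, nt)
  }
  recording
}
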