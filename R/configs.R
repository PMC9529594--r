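#' Default facial-activity catalogue
#'
#' The 28 posed facial activities of the multi-session protocol: 26
#' non-bruxism activities (eye, brow, mouth, head and speech movements of the
#' kind used in facial-gesture studies) plus the two jaw-clenching activities
#' `"clench_short"` and `"clench_long"`, which are the bruxism-positive
#' classes.
#'
#' @return Character vector of 28 activity labels.
#' @export
default_activities <- function() {
  c("clench_short", "clench_long",
    "rest_baseline", "blink_single", "blink_double", "wink_left",
    "wink_right", "eyes_closed", "gaze_left", "gaze_right", "gaze_up",
    "gaze_down", "brow_raise", "brow_furrow", "smile", "frown",
    "mouth_open", "lip_press", "lip_pucker", "cheek_puff", "tongue_press",
    "chew_soft", "swallow", "yawn", "head_nod", "head_shake",
    "speak_word", "speak_sentence")
}

#' Which activity labels count as bruxism
#'
#' @param labels Character vector of activity labels.
#' @return Logical vector, `TRUE` for jaw-clenching (bruxism) activities.
#' @export
is_bruxism_label <- function(labels) {
  labels %in% c("clench_short", "clench_long")
}

#' Protocol configuration for the synthetic study
#'
#' Describes the posed facial-activity experiment that the synthetic-session
#' generator emulates: which activities are posed, how often, for how long,
#' and at what sampling rate. Defaults reproduce a 28-activity protocol with
#' two jaw-clench (bruxism) classes over three sessions; with
#' `trials_per_activity = 29` a session spans ~3306 s, i.e. ~3300
#' non-overlapping one-second epochs, with ~5% of samples inside bruxism
#' events -- the class-imbalance regime the downstream classifier must handle.
#'
#' @param activity_labels Character vector of activity class names.
#' @param trials_per_activity Number of trials of each activity per session.
#' @param activity_duration_s Named numeric vector mapping label to duration
#'   in seconds; labels absent from the map fall back to `default_duration_s`.
#' @param default_duration_s Fallback activity duration (seconds).
#' @param rest_duration_s Rest gap between consecutive trials (seconds).
#' @param n_sessions Number of recording sessions.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return An object of class `protocol_config`.
#' @examples
#' cfg <- protocol_config(trials_per_activity = 1)
#' session_duration_s(cfg)
#' @export
protocol_config <- function(activity_labels = default_activities(),
                            trials_per_activity = 29,
                            activity_duration_s = c(clench_long = 4),
                            default_duration_s = 2,
                            rest_duration_s = 2,
                            n_sessions = 3,
                            sampling_rate_hz = 250) {
  if (trials_per_activity > 0 && length(activity_labels) == 0)
    abort("`activity_labels` is empty but `trials_per_activity` > 0.",
          class = "earpipe_config_error")
  if (anyDuplicated(activity_labels))
    abort("`activity_labels` contains duplicates.",
          class = "earpipe_config_error")
  durations <- rep(default_duration_s, length(activity_labels))
  names(durations) <- activity_labels
  known <- intersect(names(activity_duration_s), activity_labels)
  durations[known] <- activity_duration_s[known]
  if (length(activity_labels) > 0 && any(durations <= 0))
    abort("All activity durations must be > 0.",
          class = "earpipe_config_error")
  if (default_duration_s <= 0 || rest_duration_s < 0 ||
      sampling_rate_hz <= 0 || n_sessions < 1 || trials_per_activity < 0)
    abort("Invalid protocol configuration value.",
          class = "earpipe_config_error")
  structure(
    list(activity_labels = as.character(activity_labels),
         trials_per_activity = as.integer(trials_per_activity),
         activity_duration_s = durations,
         rest_duration_s = rest_duration_s,
         n_sessions = as.integer(n_sessions),
         sampling_rate_hz = sampling_rate_hz),
    class = "protocol_config")
}

#' Total scheduled duration of one session
#'
#' Sum over trials of activity duration plus the rest gap that follows each
#' trial.
#'
#' @param config A [protocol_config()].
#' @return Duration in seconds.
#' @export
session_duration_s <- function(config) {
  stopifnot(inherits(config, "protocol_config"))
  per_round <- sum(config$activity_duration_s + config$rest_duration_s)
  config$trials_per_activity * per_round
}

#' Default cEEGrid-style channel labels
#'
#' Sixteen recording channels, eight around each ear.
#'
#' @return Character vector `L1..L8, R1..R8`.
#' @export
default_channels <- function() {
  c(paste0("L", 1:8), paste0("R", 1:8))
}

#' Default activity-by-channel EMG gain matrix
#'
#' Each posed activity projects a single EMG source onto the 16 channels with
#' a smooth, activity-specific spatial profile (a Gaussian bump whose peak
#' channel varies across activities, emulating differing muscle locations
#' under volume conduction). Jaw clenches project strongly and bilaterally
#' onto the lower electrode positions of both ears (peaks at L6 and R6) with a
#' much larger amplitude, reflecting the large masseter/temporalis EMG seen at
#' the ear; this guarantees the bruxism classes carry more summed channel gain
#' than the median other activity, i.e. that the detection problem is
#' learnable.
#'
#' Gains are in microvolts of RMS burst amplitude per unit-RMS source.
#'
#' @param activity_labels Activity class names.
#' @param channel_labels Channel names (default 16 cEEGrid-style channels).
#' @param bruxism_gain Peak gain for jaw-clench activities (uV).
#' @param other_gain Peak gain for the remaining activities (uV).
#' @return Numeric matrix (activities x channels) with dimnames.
#' @export
default_emg_gains <- function(activity_labels = default_activities(),
                              channel_labels = default_channels(),
                              bruxism_gain = 25,
                              other_gain = 8) {
  n_act <- length(activity_labels)
  n_ch <- length(channel_labels)
  g <- matrix(0, n_act, n_ch, dimnames = list(activity_labels, channel_labels))
  brux <- is_bruxism_label(activity_labels)
  ch <- seq_len(n_ch)
  sigma <- 3
  non_idx <- which(!brux)
  for (j in seq_along(non_idx)) {
    i <- non_idx[j]
    # spread source locations across the montage, activity by activity
    mu <- 1 + (n_ch - 1) * (j - 1) / max(1, length(non_idx) - 1)
    g[i, ] <- other_gain * exp(-((ch - mu)^2) / (2 * sigma^2))
  }
  for (i in which(brux)) {
    # bilateral masseter projection: one bump per ear
    left_peak <- 6
    right_peak <- min(n_ch, 14)
    g[i, ] <- bruxism_gain * (exp(-((ch - left_peak)^2) / (2 * sigma^2)) +
                                exp(-((ch - right_peak)^2) / (2 * sigma^2)))
  }
  g
}

#' Noise and signal-composition configuration for the synthetic generator
#'
#' Amplitudes of the signal components that the generator superimposes:
#' 1/f-shaped EEG background with a 10 Hz alpha component, per-activity EMG
#' bursts, power-line interference (a stationary baseline plus burst-like
#' non-stationary increases, as seen when a wearer touches mains-powered
#' equipment), and slow baseline wander. One channel can be designated an
#' "open" electrode -- taped off from the skin -- which then records the line
#' interference at `open_channel_gain` and the wander, but no physiology, and
#' serves as the reference input of the NLMS adaptive filter.
#'
#' Default amplitudes mirror what ear-electrode recordings with a consumer
#' biosignal amplifier show: ~5 uV RMS background at rest, line noise that is
#' weak continuously and an order of magnitude stronger during bursts, and an
#' open electrode dominated by interference.
#'
#' @param eeg_background_rms RMS of the 1/f EEG background (uV).
#' @param alpha_amplitude Amplitude of the 10 Hz alpha sinusoid (uV).
#' @param line_freq_hz Power-line frequency (Hz).
#' @param line_baseline_amplitude Stationary line-noise amplitude in
#'   recording channels (uV).
#' @param line_burst_amplitude Additional amplitude during bursts (uV).
#' @param line_burst_schedule Two-column matrix or list of `c(onset, offset)`
#'   pairs in seconds, or `NULL` for the default schedule (a 5 s burst every
#'   30 s, starting at 10 s).
#' @param open_channel_gain Multiplier applied to the line signal on the open
#'   electrode (unitless, >> 1).
#' @param open_channel Channel label to render as an open electrode, or
#'   `NULL` for none (all channels record physiology).
#' @param baseline_wander_rms RMS of the < 0.5 Hz drift component (uV).
#' @param emg_band_hz Length-2 vector, EMG burst band edges (Hz).
#' @param emg_gain_matrix Activity-by-channel gain matrix; `NULL` defers to
#'   [default_emg_gains()] at synthesis time.
#' @param emg_gain_scale Global multiplier on the EMG gain matrix (used for
#'   SNR sweeps).
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(eeg_background_rms = 5,
                         alpha_amplitude = 2,
                         line_freq_hz = 50,
                         line_baseline_amplitude = 1,
                         line_burst_amplitude = 10,
                         line_burst_schedule = NULL,
                         open_channel_gain = 20,
                         open_channel = NULL,
                         baseline_wander_rms = 3,
                         emg_band_hz = c(20, 100),
                         emg_gain_matrix = NULL,
                         emg_gain_scale = 1) {
  amps <- c(eeg_background_rms, alpha_amplitude, line_baseline_amplitude,
            line_burst_amplitude, baseline_wander_rms, emg_gain_scale)
  if (any(amps < 0))
    abort("All noise amplitudes must be >= 0.", class = "earpipe_config_error")
  if (length(emg_band_hz) != 2 || emg_band_hz[1] <= 0 ||
      emg_band_hz[2] <= emg_band_hz[1])
    abort("`emg_band_hz` must be an increasing positive pair.",
          class = "earpipe_config_error")
  if (!is.null(line_burst_schedule)) {
    if (is.list(line_burst_schedule))
      line_burst_schedule <- do.call(rbind, lapply(line_burst_schedule,
                                                   function(p) c(p[[1]], p[[2]])))
    line_burst_schedule <- matrix(as.numeric(line_burst_schedule), ncol = 2)
    if (any(line_burst_schedule[, 2] <= line_burst_schedule[, 1]))
      abort("Line-noise burst offsets must exceed onsets.",
            class = "earpipe_config_error")
  }
  structure(
    list(eeg_background_rms = eeg_background_rms,
         alpha_amplitude = alpha_amplitude,
         line_freq_hz = line_freq_hz,
         line_baseline_amplitude = line_baseline_amplitude,
         line_burst_amplitude = line_burst_amplitude,
         line_burst_schedule = line_burst_schedule,
         open_channel_gain = open_channel_gain,
         open_channel = open_channel,
         baseline_wander_rms = baseline_wander_rms,
         emg_band_hz = emg_band_hz,
         emg_gain_matrix = emg_gain_matrix,
         emg_gain_scale = emg_gain_scale),
    class = "noise_config")
}
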