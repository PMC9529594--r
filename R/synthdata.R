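# Synthetic cEEGrid-like session generator.
#
# The generator does not attempt physiological forward modeling; it
# reproduces the statistical structure the analysis chain assumes: 1/f EEG
# background with alpha, band-limited EMG bursts with activity-specific
# spatial gains, stationary + burst-like 50 Hz line interference coupled
# strongly into an optional open electrode, and slow common-mode drift.

#' Build a randomized trial schedule for one session
#'
#' Every activity is posed `trials_per_activity` times; trial order is a
#' seeded random permutation; consecutive trials are separated by the rest
#' gap. Annotations are returned sorted and non-overlapping.
#'
#' @param config A [protocol_config()].
#' @param seed Integer seed controlling the trial permutation.
#' @return Tibble with columns `label`, `is_bruxism`, `onset_s`, `offset_s`.
#' @examples
#' ann <- build_protocol(protocol_config(trials_per_activity = 1), seed = 1)
#' nrow(ann)          # 28 trials
#' sum(ann$is_bruxism)  # 2 jaw-clench trials
#' @export
build_protocol <- function(config, seed = 1) {
  stopifnot(inherits(config, "protocol_config"))
  if (config$trials_per_activity == 0 || length(config$activity_labels) == 0)
    return(tibble(label = character(), is_bruxism = logical(),
                  onset_s = numeric(), offset_s = numeric()))
  trials <- rep(config$activity_labels, times = config$trials_per_activity)
  order <- with_seed(seed, sample.int(length(trials)))
  trials <- trials[order]
  durs <- unname(config$activity_duration_s[trials])
  offsets_end <- cumsum(durs + config$rest_duration_s)
  onsets <- offsets_end - durs - config$rest_duration_s
  tibble(label = trials,
         is_bruxism = is_bruxism_label(trials),
         onset_s = onsets,
         offset_s = onsets + durs)
}

# Unit-RMS Gaussian noise spectrally shaped by power_fn(freq_hz) (relative
# power; zero frequencies where power_fn returns 0). Returns numeric(n).
shaped_noise <- function(n, fs, power_fn) {
  if (n == 0) return(numeric(0))
  freqs <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  freqs <- pmin(freqs, fs - freqs) # two-sided spectrum, mirrored
  amp <- sqrt(pmax(power_fn(freqs), 0))
  x <- fft(rnorm(n)) * amp
  x <- Re(fft(x, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x / s else x
}

pink_power <- function(f) 1 / pmax(f, 1)               # 1/f, floored at 1 Hz
wander_power <- function(f) ifelse(f > 0.01 & f < 0.5, 1 / f^2, 0)
band_power_fn <- function(band) function(f) as.numeric(f >= band[1] & f <= band[2])

# Raised-cosine on/off ramps of ramp_s seconds on an n-sample gate.
cosine_envelope <- function(n, fs, ramp_s = 0.05) {
  env <- rep(1, n)
  r <- min(floor(ramp_s * fs), floor(n / 2))
  if (r > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(r) / r))
    env[seq_len(r)] <- ramp
    env[n - r + seq_len(r)] <- rev(ramp)
  }
  env
}

# Time-varying line-noise amplitude: stationary baseline plus raised-cosine
# gated bursts per the schedule.
line_amplitude <- function(t, noise, duration_s) {
  amp <- rep(noise$line_baseline_amplitude, length(t))
  sched <- noise$line_burst_schedule
  if (is.null(sched) && noise$line_burst_amplitude > 0) {
    onsets <- seq(10, max(10, duration_s - 5), by = 30)
    onsets <- onsets[onsets + 5 <= duration_s]
    if (length(onsets)) sched <- cbind(onsets, onsets + 5)
  }
  if (!is.null(sched) && nrow(sched) > 0) {
    fs <- 1 / (t[2] - t[1])
    for (i in seq_len(nrow(sched))) {
      sel <- which(t >= sched[i, 1] & t < sched[i, 2])
      if (length(sel))
        amp[sel] <- amp[sel] +
          noise$line_burst_amplitude * cosine_envelope(length(sel), fs, 0.1)
    }
  }
  amp
}

#' Synthesize one session recording from an annotation schedule
#'
#' Superimposes, per channel: 1/f EEG background plus a 10 Hz alpha
#' sinusoid; one band-limited EMG burst per annotation, smoothly enveloped
#' (50 ms raised-cosine ramps) and scaled by that activity's row of the EMG
#' gain matrix; a line-noise sinusoid whose amplitude follows the baseline
#' level plus the burst schedule; and slow common-mode baseline wander. The
#' open electrode, when configured, records only the line interference
#' (scaled by `open_channel_gain`) and the wander -- no physiology.
#'
#' @param protocol Annotation tibble from [build_protocol()].
#' @param noise A [noise_config()].
#' @param config The [protocol_config()] used to build `protocol`.
#' @param seed Integer seed; output is fully reproducible from it.
#' @param session_id Session identifier.
#' @return An [ear_recording()].
#' @export
synthesize_recording <- function(protocol, noise, config, seed = 1,
                                 session_id = "S1") {
  stopifnot(inherits(noise, "noise_config"), inherits(config, "protocol_config"))
  fs <- config$sampling_rate_hz
  if (noise$emg_band_hz[2] >= fs / 2)
    warn("EMG band upper edge at/above Nyquist; it will be truncated.")
  duration_s <- max(session_duration_s(config),
                    if (nrow(protocol)) max(protocol$offset_s) else 0)
  n <- round(duration_s * fs)
  if (nrow(protocol) && any(protocol$onset_s < 0 | protocol$offset_s * fs > n + 1e-6))
    abort("Annotation outside session bounds.", class = "earpipe_config_error")
  channels <- default_channels()
  gains <- (noise$emg_gain_matrix %||%
              default_emg_gains(config$activity_labels, channels)) *
    noise$emg_gain_scale
  if (nrow(protocol) && !all(protocol$label %in% rownames(gains)))
    abort("EMG gain matrix lacks rows for some activities.",
          class = "earpipe_config_error")
  t <- (seq_len(n) - 1) / fs
  band <- c(noise$emg_band_hz[1], min(noise$emg_band_hz[2], fs / 2 * 0.999))

  data <- with_seed(seed, {
    X <- matrix(0, length(channels), n, dimnames = list(channels, NULL))
    open_idx <- if (!is.null(noise$open_channel))
      match(noise$open_channel, channels) else NA_integer_
    if (is.na(open_idx)) open_idx <- 0L
    # physiology: background + alpha on every non-open channel
    for (c_i in seq_along(channels)) {
      if (c_i == open_idx) next
      if (noise$eeg_background_rms > 0)
        X[c_i, ] <- X[c_i, ] +
          noise$eeg_background_rms * shaped_noise(n, fs, pink_power)
      if (noise$alpha_amplitude > 0)
        X[c_i, ] <- X[c_i, ] +
          noise$alpha_amplitude * sin(2 * pi * 10 * t + runif(1, 0, 2 * pi))
    }
    # EMG bursts: one source per trial, projected through the gain row
    if (nrow(protocol)) {
      for (k in seq_len(nrow(protocol))) {
        i0 <- floor(protocol$onset_s[k] * fs) + 1
        i1 <- min(n, ceiling(protocol$offset_s[k] * fs))
        m <- i1 - i0 + 1
        if (m < 4) next
        g <- gains[protocol$label[k], ]
        if (all(g == 0)) next
        src <- shaped_noise(m, fs, band_power_fn(band)) *
          cosine_envelope(m, fs, 0.05)
        for (c_i in seq_along(channels)) {
          if (c_i == open_idx || g[c_i] == 0) next
          X[c_i, i0:i1] <- X[c_i, i0:i1] + g[c_i] * src
        }
      }
    }
    # line interference: coherent across channels, amplified on the open one
    if (n > 1 &&
        (noise$line_baseline_amplitude > 0 || noise$line_burst_amplitude > 0)) {
      carrier <- sin(2 * pi * noise$line_freq_hz * t + runif(1, 0, 2 * pi))
      line <- line_amplitude(t, noise, duration_s) * carrier
      for (c_i in seq_along(channels))
        X[c_i, ] <- X[c_i, ] +
          line * (if (c_i == open_idx) noise$open_channel_gain else 1)
    }
    # slow common-mode drift (shared by recording and open electrodes)
    if (noise$baseline_wander_rms > 0 && n > 1) {
      wander <- noise$baseline_wander_rms * shaped_noise(n, fs, wander_power)
      X <- sweep(X, 2, wander, `+`)
    }
    X
  })
  ear_recording(data, fs, channels, session_id = session_id,
                open_channel = noise$open_channel)
}

#' Generate a multi-session synthetic study
#'
#' Runs the full protocol `n_sessions` times with independently re-randomized
#' trial orders, emulating repeated recording days.
#'
#' @param config A [protocol_config()].
#' @param noise A [noise_config()].
#' @param seeds Integer vector, one seed per session.
#' @return Tibble with columns `session_id`, `recording` (list of
#'   [ear_recording()]), `annotations` (list of annotation tibbles).
#' @export
generate_study <- function(config, noise = noise_config(),
                           seeds = seq_len(config$n_sessions)) {
  stopifnot(inherits(config, "protocol_config"))
  if (length(seeds) != config$n_sessions)
    abort(sprintf("Need %d seeds (one per session), got %d.",
                  config$n_sessions, length(seeds)),
          class = "earpipe_config_error")
  if (anyDuplicated(seeds))
    warn("Duplicate session seeds: sessions will be correlated.")
  sessions <- purrr::map(seq_len(config$n_sessions), function(i) {
    sid <- paste0("S", i)
    ann <- build_protocol(config, seed = seeds[i])
    rec <- synthesize_recording(ann, noise, config, seed = seeds[i] + 1000003L,
                                session_id = sid)
    list(session_id = sid, recording = rec, annotations = ann)
  })
  tibble(session_id = purrr::map_chr(sessions, "session_id"),
         recording = purrr::map(sessions, "recording"),
         annotations = purrr::map(sessions, "annotations"))
}
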