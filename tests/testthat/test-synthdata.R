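test_that("default protocol enumerates 28 activities with 2 bruxism classes", {
  labels <- default_activities()
  expect_length(labels, 28)
  expect_identical(sum(is_bruxism_label(labels)), 2L)

  ann <- build_protocol(protocol_config(trials_per_activity = 1), seed = 1)
  expect_identical(nrow(ann), 28L)
  expect_identical(sum(ann$is_bruxism), 2L)
  expect_setequal(ann$label, labels)
})

test_that("protocol construction is deterministic, sorted and non-overlapping", {
  cfg <- protocol_config(trials_per_activity = 3)
  a1 <- build_protocol(cfg, seed = 42)
  a2 <- build_protocol(cfg, seed = 42)
  expect_identical(a1, a2)
  expect_false(identical(a1$label, build_protocol(cfg, seed = 43)$label))
  expect_true(all(diff(a1$onset_s) > 0))
  expect_true(all(a1$onset_s[-1] >= a1$offset_s[-nrow(a1)]))
  # consecutive trials separated by exactly the rest gap
  expect_equal(a1$onset_s[-1] - a1$offset_s[-nrow(a1)],
               rep(cfg$rest_duration_s, nrow(a1) - 1))
})

test_that("degenerate protocol configs behave per contract", {
  expect_identical(nrow(build_protocol(protocol_config(trials_per_activity = 0))),
                   0L)
  expect_error(protocol_config(activity_labels = character(),
                               trials_per_activity = 1),
               class = "earpipe_config_error")
  expect_error(protocol_config(default_duration_s = 0),
               class = "earpipe_config_error")
})

test_that("session duration equals sum of trials x (activity + rest)", {
  cfg <- protocol_config(trials_per_activity = 2)
  expect_equal(session_duration_s(cfg),
               2 * sum(cfg$activity_duration_s + cfg$rest_duration_s))
  ann <- build_protocol(cfg, seed = 1)
  expect_equal(max(ann$offset_s) + cfg$rest_duration_s,
               session_duration_s(cfg))
})

test_that("all-zero noise amplitudes with an empty protocol give a silent recording", {
  cfg <- protocol_config(trials_per_activity = 0)
  quiet <- noise_config(eeg_background_rms = 0, alpha_amplitude = 0,
                        line_baseline_amplitude = 0, line_burst_amplitude = 0,
                        baseline_wander_rms = 0)
  # zero-length protocol still spans the (empty) session; use 1 trial of
  # everything with zero gains instead to get a nonempty recording
  cfg1 <- protocol_config(trials_per_activity = 1)
  quiet1 <- noise_config(eeg_background_rms = 0, alpha_amplitude = 0,
                         line_baseline_amplitude = 0,
                         line_burst_amplitude = 0, baseline_wander_rms = 0,
                         emg_gain_scale = 0)
  rec <- synthesize_recording(build_protocol(cfg1, 1), quiet1, cfg1, seed = 1)
  expect_true(all(rec$data == 0))
  expect_identical(dim(rec$data)[1], 16L)
})

test_that("line-noise-only config puts the open channel's PSD peak at 50 Hz", {
  cfg <- protocol_config(trials_per_activity = 1)
  line_only <- noise_config(eeg_background_rms = 0, alpha_amplitude = 0,
                            baseline_wander_rms = 0, emg_gain_scale = 0,
                            open_channel = "L7")
  rec <- synthesize_recording(build_protocol(cfg, 1), line_only, cfg, seed = 3)
  psd <- welch_psd(get_channel(rec, "L7"), rec$fs)
  expect_equal(psd$freq[which.max(psd$psd)], 50)
  # and a recording channel carries it too, at much lower amplitude
  psd_l3 <- welch_psd(get_channel(rec, "L3"), rec$fs)
  expect_equal(psd_l3$freq[which.max(psd_l3$psd)], 50)
  expect_gt(max(psd$psd), 50 * max(psd_l3$psd))
})

test_that("a clench trial raises 20-100 Hz band power over a flanking rest segment", {
  labels <- default_activities()
  cfg <- protocol_config(trials_per_activity = 1)
  ann <- tibble::tibble(label = "clench_long", is_bruxism = TRUE,
                        onset_s = 5, offset_s = 7)
  rec <- synthesize_recording(ann, noise_config(), cfg, seed = 9)
  ch <- get_channel(rec, "L6") # gain-positive channel for clenches
  fs <- rec$fs
  inside <- ch[(5 * fs + 1):(7 * fs)]
  flank <- ch[(9 * fs + 1):(11 * fs)]
  expect_gt(band_power_fft(inside, fs, 20, 100),
            band_power_fft(flank, fs, 20, 100))
})

test_that("generate_study produces the configured number of independent sessions", {
  study <- small_study()
  expect_identical(nrow(study), 3L)
  expect_identical(study$session_id, c("S1", "S2", "S3"))
  orders <- lapply(study$annotations, function(a) a$label)
  expect_false(identical(orders[[1]], orders[[2]]))
  expect_false(identical(orders[[1]], orders[[3]]))
  expect_false(identical(orders[[2]], orders[[3]]))

  one <- generate_study(protocol_config(trials_per_activity = 1,
                                        n_sessions = 1),
                        noise_config(), seeds = 5)
  expect_identical(nrow(one), 1L)
  expect_error(generate_study(small_protocol_config(), noise_config(),
                              seeds = 1:2),
               class = "earpipe_config_error")
  expect_warning(generate_study(protocol_config(trials_per_activity = 1,
                                                n_sessions = 2),
                                noise_config(
                                  eeg_background_rms = 0, alpha_amplitude = 0,
                                  baseline_wander_rms = 0,
                                  line_burst_amplitude = 0,
                                  emg_gain_scale = 0),
                                seeds = c(4, 4)),
                 "Duplicate")
})

test_that("study generation is byte-identical under identical seeds", {
  cfg <- protocol_config(trials_per_activity = 1)
  s1 <- generate_study(cfg, noise_config(), seeds = c(8, 9, 10))
  s2 <- generate_study(cfg, noise_config(), seeds = c(8, 9, 10))
  expect_identical(s1$recording[[2]]$data, s2$recording[[2]]$data)
  expect_identical(s1$annotations, s2$annotations)
})

test_that("bruxism samples are a small minority of the session", {
  study <- small_study()
  for (i in 1:3) {
    ann <- study$annotations[[i]]
    frac <- sum(ann$offset_s[ann$is_bruxism] - ann$onset_s[ann$is_bruxism]) /
      recording_duration_s(study$recording[[i]])
    expect_lt(frac, 0.15)
    expect_gt(frac, 0)
  }
})

test_that("EEG background has 1/f spectral shape above 15 Hz", {
  cfg <- protocol_config(trials_per_activity = 1)
  bg_only <- noise_config(alpha_amplitude = 0, line_baseline_amplitude = 0,
                          line_burst_amplitude = 0, baseline_wander_rms = 0,
                          emg_gain_scale = 0)
  rec <- synthesize_recording(build_protocol(cfg, 1), bg_only, cfg, seed = 4)
  for (ch in c("L1", "R5")) {
    psd <- welch_psd(get_channel(rec, ch), rec$fs)
    sel <- psd$freq > 15 & psd$freq < 120
    slope <- coef(lm(log(psd$psd[sel]) ~ log(psd$freq[sel])))[2]
    expect_lt(slope, 0)
  }
})

test_that("bruxism activities carry more summed EMG gain than the median activity", {
  g <- default_emg_gains()
  sums <- rowSums(g)
  brux <- is_bruxism_label(rownames(g))
  expect_true(all(sums[brux] > median(sums[!brux])))
})
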