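fs <- 250

test_that("band-pass behaves at stop-band, pass-band and zero input", {
  spec <- filter_spec("bandpass_iir")
  t <- (0:(20 * fs - 1)) / fs
  steady <- (5 * fs):(15 * fs) # avoid edges
  rms <- function(x) sqrt(mean(x^2))

  expect_identical(apply_filter(numeric(500), fs, spec), numeric(500))

  low <- sin(2 * pi * 2 * t)
  expect_lt(20 * log10(rms(apply_filter(low, fs, spec)[steady]) /
                         rms(low[steady])), -20)

  mid <- sin(2 * pi * 20 * t)
  expect_lt(abs(20 * log10(rms(apply_filter(mid, fs, spec)[steady]) /
                             rms(mid[steady]))), 1)
})

test_that("filters are linear and reject invalid configs", {
  set.seed(3)
  x <- rnorm(1000)
  for (kind in c("bandpass_iir", "notch_iir", "notch_fir")) {
    spec <- filter_spec(kind)
    y1 <- apply_filter(3.7 * x, fs, spec)
    y2 <- 3.7 * apply_filter(x, fs, spec)
    expect_lt(max(abs(y1 - y2)) / max(abs(y2)), 1e-9)
  }
  expect_error(apply_filter(x, fs, filter_spec("bandpass_iir",
                                               band_hz = c(5, 130))),
               class = "earpipe_config_error")
  expect_error(apply_filter(rnorm(10), fs, filter_spec("bandpass_iir")),
               class = "earpipe_config_error")
})

test_that("Welch PSD: zero input, sinusoid peak location, Parseval", {
  expect_true(all(welch_psd(numeric(1000), fs)$psd == 0))

  t <- (0:(10 * fs - 1)) / fs
  psd <- welch_psd(sin(2 * pi * 10 * t), fs)
  expect_equal(psd$freq[which.max(psd$psd)], 10)
  expect_true(all(psd$psd >= 0))
  expect_equal(range(psd$freq), c(0, fs / 2))

  set.seed(4)
  x <- rnorm(60 * fs)
  psd <- welch_psd(x, fs)
  df <- psd$freq[2] - psd$freq[1]
  expect_lt(abs(sum(psd$psd) * df - var(x)) / var(x), 0.1)

  expect_error(welch_psd(rnorm(100), fs, window_s = 1),
               class = "earpipe_config_error")
  expect_error(welch_psd(rnorm(1000), fs, overlap_s = 1.5),
               class = "earpipe_config_error")
})

test_that("NLMS passes primary through when the reference is silent", {
  set.seed(5)
  x <- rnorm(2000)
  out <- nlms_clean(x, numeric(2000), fs)
  expect_identical(out$cleaned, x)
  expect_identical(out$estimate, numeric(2000))
})

test_that("NLMS self-cancels when primary equals the reference", {
  r <- sin(2 * pi * 50 * (0:4999) / fs) * (1 + 0.3 * sin(2 * pi * 0.2 * (0:4999) / fs))
  out <- nlms_clean(r, r, fs, mu = 1)
  lastpart <- 4501:5000
  expect_lt(mean(abs(out$cleaned[lastpart])), 0.01 * sqrt(mean(r^2)))
})

test_that("NLMS matches the naive per-sample oracle to 1e-10", {
  set.seed(7)
  prim <- rnorm(1000)
  ref <- 0.8 * prim + rnorm(1000)
  for (mode_reset in list(c(0, 0), c(1, 500))) {
    out <- nlms_clean(prim, ref, fs, window_s = 0.1, mu = 0.7, eps = 1e-8,
                      mode = if (mode_reset[1]) "rolling" else "full",
                      rolling_window_s = 2)
    orc <- oracle_nlms(prim, ref, n_taps = round(0.1 * fs), mu = 0.7,
                       eps = 1e-8, reset_every = mode_reset[2])
    expect_lt(max(abs(out$cleaned - orc$cleaned)), 1e-10)
    expect_lt(max(abs(out$estimate - orc$estimate)), 1e-10)
  }
})

test_that("NLMS input validation", {
  expect_error(nlms_clean(rnorm(10), rnorm(9), fs),
               class = "earpipe_config_error")
  expect_error(nlms_clean(rnorm(100), rnorm(100), fs, mu = 3),
               class = "earpipe_config_error")
  expect_error(nlms_clean(rnorm(10), rnorm(10), fs),
               class = "earpipe_config_error") # shorter than window
})

test_that("slow-adaptation NLMS removes a 50 Hz tone without touching 5-40 Hz", {
  set.seed(8)
  n <- 40 * fs
  t <- (0:(n - 1)) / fs
  s <- apply_filter(rnorm(n), fs, filter_spec("bandpass_iir",
                                              band_hz = c(5, 40)))
  prim <- s + 0.5 * sin(2 * pi * 50 * t)
  ref <- sin(2 * pi * 50 * t + 1.1)
  out <- nlms_clean(prim, ref, fs, mu = 0.1)
  keep <- (fs + 1):n
  p_raw <- welch_psd(prim[keep], fs)
  p_cln <- welch_psd(out$cleaned[keep], fs)
  at50 <- function(p) p$psd[which.min(abs(p$freq - 50))]
  expect_lt(10 * log10(at50(p_cln) / at50(p_raw)), -20)
  bp <- function(p) sum(p$psd[p$freq >= 5 & p$freq <= 40])
  expect_lt(abs(10 * log10(bp(p_cln) / bp(p_raw))), 1)
  # energy is not inflated in the slow-adaptation regime
  expect_lt(mean(out$cleaned^2), 1.05 * mean(prim^2))
})

test_that("cleaned energy stays bounded across slow-adaptation fixtures", {
  set.seed(9)
  for (mu in c(0.05, 0.1, 0.2)) {
    n <- 10 * fs
    t <- (0:(n - 1)) / fs
    prim <- rnorm(n) + 2 * sin(2 * pi * 50 * t)
    ref <- sin(2 * pi * 50 * t + runif(1, 0, 2 * pi))
    out <- nlms_clean(prim, ref, fs, mu = mu)
    expect_lt(mean(out$cleaned^2), 1.05 * mean(prim^2))
  }
})

test_that("notch and NLMS both remove line power; NLMS leaves no band hole", {
  rec <- contaminated_recording()
  cmpr <- compare_line_noise_removal(get_channel(rec, "L3"),
                                     get_channel(rec, "L7"), rec$fs)
  s <- cmpr$summary
  raw <- s[s$method == "raw", ]
  notch <- s[s$method == "notch_fir", ]
  nlms <- s[s$method == "nlms", ]
  expect_lt(notch$line_bin_power, raw$line_bin_power)
  expect_lt(10 * log10(notch$line_bin_power / raw$line_bin_power), -20)
  expect_lt(10 * log10(nlms$line_bin_power / raw$line_bin_power), -20)
  expect_gt(nlms$band_mean_45_55, notch$band_mean_49_51)
})

test_that("a clean channel with a silent reference is unchanged by all methods", {
  set.seed(10)
  x <- apply_filter(rnorm(20 * fs), fs,
                    filter_spec("bandpass_iir", band_hz = c(5, 40)))
  cmpr <- compare_line_noise_removal(x, numeric(length(x)), fs)
  wide <- tidyr::pivot_wider(cmpr$psd, names_from = "method",
                             values_from = "psd")
  sel <- wide$freq >= 5 & wide$freq <= 40
  expect_lt(max(abs(10 * log10(wide$nlms[sel] / wide$raw[sel]))), 0.01)
  # FIR notch only reshapes its stop band; pass band equal within 1 dB
  pass <- wide$freq >= 5 & wide$freq <= 40
  expect_lt(max(abs(10 * log10(wide$notch_fir[pass] / wide$raw[pass]))), 1)
})
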