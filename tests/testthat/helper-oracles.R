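# Independent straight-loop oracles: deliberately naive per-sample
# implementations, kept free of any code path used by the package.

oracle_var <- function(x) {
  m <- 0
  for (v in x) m <- m + v
  m <- m / length(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  s / length(x)
}

oracle_hjorth <- function(x) {
  v0 <- oracle_var(x)
  if (v0 == 0) return(c(0, 0, 0))
  d1 <- numeric(length(x) - 1)
  for (i in 2:length(x)) d1[i - 1] <- x[i] - x[i - 1]
  v1 <- oracle_var(d1)
  mob <- sqrt(v1 / v0)
  if (v1 == 0) return(c(v0, mob, 0))
  d2 <- numeric(length(d1) - 1)
  for (i in 2:length(d1)) d2[i - 1] <- d1[i] - d1[i - 1]
  mob_d <- sqrt(oracle_var(d2) / v1)
  c(v0, mob, mob_d / mob)
}

oracle_abs <- function(x) {
  mx <- 0; sm <- 0
  for (v in x) {
    if (abs(v) > mx) mx <- abs(v)
    sm <- sm + abs(v)
  }
  c(mx, sm)
}

oracle_petrosian <- function(x) {
  n <- length(x)
  signs <- c()
  for (i in 2:n) {
    d <- x[i] - x[i - 1]
    if (d != 0) signs <- c(signs, sign(d))
  }
  nd <- 0
  if (length(signs) > 1)
    for (i in 2:length(signs)) if (signs[i] != signs[i - 1]) nd <- nd + 1
  log10(n) / (log10(n) + log10(n / (n + 0.4 * nd)))
}

oracle_higuchi <- function(x, k_max = 10) {
  n <- length(x)
  Lk <- numeric(k_max)
  for (k in 1:k_max) {
    Lm <- c()
    for (m in 1:k) {
      nm <- floor((n - m) / k)
      if (nm < 1) next
      s <- 0
      for (i in 1:nm) s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      Lm <- c(Lm, s * (n - 1) / (nm * k^2))
    }
    Lk[k] <- mean(Lm)
  }
  if (any(Lk <= 0)) return(1)
  xs <- log(1 / (1:k_max)); ys <- log(Lk)
  b <- sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
  b
}

oracle_features <- function(x, k_max = 10) {
  x <- x - mean(x)
  hj <- oracle_hjorth(x)
  aa <- oracle_abs(x)
  c(activity = hj[1], complexity = hj[3], mobility = hj[2],
    abs_max = aa[1], abs_sum = aa[2],
    higuchi_fd = oracle_higuchi(x, k_max),
    petrosian_fd = oracle_petrosian(x))
}

# Naive per-sample NLMS, direct transliteration of the update equations.
oracle_nlms <- function(primary, reference, n_taps, mu, eps,
                        reset_every = 0) {
  n <- length(primary)
  w <- rep(0, n_taps)
  est <- numeric(n); cleaned <- numeric(n)
  for (i in seq_len(n)) {
    if (reset_every > 0 && i > 1 && ((i - 1) %% reset_every) == 0)
      w <- rep(0, n_taps)
    if (i < n_taps + 1) {
      est[i] <- 0; cleaned[i] <- primary[i]
      next
    }
    r <- reference[i:(i - n_taps + 1)]
    est[i] <- sum(w * r)
    e <- primary[i] - est[i]
    cleaned[i] <- e
    w <- w + mu * e * r / (sum(r^2) + eps)
  }
  list(cleaned = cleaned, estimate = est)
}

band_power_fft <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sum(sp[f >= lo & f <= hi & f <= fs / 2])
}
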