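# Shared fixtures. The small study is expensive enough to build that tests
# reuse one cached copy (never mutated in place).

.fixture_cache <- new.env(parent = emptyenv())

small_protocol_config <- function(trials = 2) {
  protocol_config(trials_per_activity = trials)
}

# Three short sessions at the default noise conditions.
small_study <- function() {
  if (is.null(.fixture_cache$study))
    .fixture_cache$study <- generate_study(small_protocol_config(2),
                                           noise_config(),
                                           seeds = c(101, 202, 303))
  .fixture_cache$study
}

# One short contaminated session with an open reference electrode.
contaminated_recording <- function() {
  if (is.null(.fixture_cache$contaminated)) {
    cfg <- small_protocol_config(2)
    .fixture_cache$contaminated <- synthesize_recording(
      build_protocol(cfg, seed = 7), noise_config(open_channel = "L7"),
      cfg, seed = 7)
  }
  .fixture_cache$contaminated
}

random_epoch_set <- function(n_epochs = 3, n_channels = 16, n_samples = 250,
                             seed = 1, fs = 250) {
  set.seed(seed)
  rec <- ear_recording(matrix(rnorm(n_channels * n_epochs * n_samples),
                              n_channels),
                       fs, paste0("ch", seq_len(n_channels)))
  make_epochs(rec, annotations = tibble::tibble(
    label = character(), is_bruxism = logical(),
    onset_s = numeric(), offset_s = numeric()))
}
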