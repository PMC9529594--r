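#' Construct a multichannel recording object
#'
#' The container every pipeline stage transforms: a channels-by-samples
#' numeric matrix in microvolts plus sampling rate, channel labels, a session
#' id, and optionally the label of an "open" (taped-off) electrode usable as
#' artifact reference.
#'
#' @param data Numeric matrix, `n_channels x n_samples`, in uV.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of `data`.
#' @param session_id Session identifier string.
#' @param open_channel Optional label of the artifact-reference channel.
#' @return An object of class `ear_recording`.
#' @export
ear_recording <- function(data, fs, channel_labels = default_channels(),
                          session_id = "S1", open_channel = NULL) {
  data <- as.matrix(data)
  if (nrow(data) != length(channel_labels))
    abort(sprintf("`data` has %d rows but %d channel labels.",
                  nrow(data), length(channel_labels)),
          class = "earpipe_format_error")
  if (nrow(data) > 0 && ncol(data) > 0 && !all(is.finite(data)))
    abort("Recording contains non-finite samples.",
          class = "earpipe_format_error")
  if (!is.null(open_channel) && !open_channel %in% channel_labels)
    abort(sprintf("open_channel '%s' is not a channel label.", open_channel),
          class = "earpipe_format_error")
  if (fs <= 0) abort("`fs` must be positive.", class = "earpipe_config_error")
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = as.character(channel_labels),
         session_id = session_id, open_channel = open_channel),
    class = "ear_recording")
}

#' @export
print.ear_recording <- function(x, ...) {
  cat(sprintf("<ear_recording> session %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$session_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  if (!is.null(x$open_channel))
    cat(sprintf("  open (reference) electrode: %s\n", x$open_channel))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording An [ear_recording()].
#' @return Seconds.
#' @export
recording_duration_s <- function(recording) {
  ncol(recording$data) / recording$fs
}

#' Extract one channel of a recording
#' @param recording An [ear_recording()].
#' @param channel Channel label.
#' @return Numeric vector of samples (uV).
#' @export
get_channel <- function(recording, channel) {
  if (!channel %in% recording$channel_labels)
    abort(sprintf("No channel named '%s'.", channel),
          class = "earpipe_format_error")
  recording$data[channel, ]
}

#' Convert a recording to a long tibble
#'
#' @param x An [ear_recording()].
#' @param ... Unused.
#' @return Tibble with columns `time_s`, `channel`, `value_uv`, `session_id`.
#' @export
as_tibble.ear_recording <- function(x, ...) {
  n <- ncol(x$data)
  tibble(
    time_s = rep((seq_len(n) - 1) / x$fs, each = nrow(x$data)),
    channel = rep(x$channel_labels, times = n),
    value_uv = as.vector(x$data),
    session_id = x$session_id)
}
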