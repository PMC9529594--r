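#' Recording file format specification
#'
#' Two dialects are understood: `"openbci_gui_txt"` -- the plain-text export
#' of the OpenBCI GUI, with `%`-prefixed comment header lines, comma-separated
#' values, a leading sample-index column (counting modulo 256) and optional
#' trailing auxiliary columns (accelerometer, timestamps) -- and
#' `"plain_csv"`, a headered CSV with one column per channel.
#'
#' @param dialect `"openbci_gui_txt"` or `"plain_csv"`.
#' @param expected_channels Number of data channels the file must contain.
#' @param fs_hz Sampling rate in Hz to stamp on the recording.
#' @return An object of class `recording_file_spec`.
#' @export
recording_file_spec <- function(dialect = c("plain_csv", "openbci_gui_txt"),
                                expected_channels = 16, fs_hz = 250) {
  dialect <- match.arg(dialect)
  if (expected_channels < 1 || fs_hz <= 0)
    abort("expected_channels and fs_hz must be positive.",
          class = "earpipe_config_error")
  structure(list(dialect = dialect,
                 expected_channels = as.integer(expected_channels),
                 fs_hz = fs_hz),
            class = "recording_file_spec")
}

# Parse a character matrix of numeric fields, reporting 1-based file line
# numbers for non-numeric cells.
parse_numeric_fields <- function(fields, file_lines) {
  suppressWarnings(num <- matrix(as.numeric(fields), nrow = nrow(fields)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-numeric value '%s' at line %d, column %d.",
                  fields[bad[1], bad[2]], file_lines[bad[1]], bad[2]),
          class = "earpipe_parse_error")
  }
  num
}

#' Read a multichannel recording from disk
#'
#' Values are taken as microvolts with no rescaling. For the OpenBCI dialect,
#' the sample-index column and any auxiliary columns beyond the data channels
#' are parsed but stored in the `aux` attribute, separate from the channel
#' data.
#'
#' @param path File path.
#' @param spec A [recording_file_spec()].
#' @param channel_labels Labels to assign (defaults to the file header for
#'   `plain_csv`, `L1..R8`-style labels otherwise).
#' @param session_id Session id to stamp on the recording.
#' @return An [ear_recording()].
#' @export
read_recording <- function(path, spec = recording_file_spec(),
                           channel_labels = NULL, session_id = "S1") {
  if (!file.exists(path))
    abort(sprintf("File not found: %s", path), class = "earpipe_io_error")
  lines <- readLines(path, warn = FALSE)
  lines_idx <- seq_along(lines)
  keep <- !startsWith(lines, "%") & nzchar(trimws(lines))
  header <- NULL
  if (spec$dialect == "plain_csv" && any(keep)) {
    first <- which(keep)[1]
    header <- strsplit(lines[first], ",", fixed = TRUE)[[1]]
    keep[first] <- FALSE
  }
  body <- lines[keep]
  body_lines <- lines_idx[keep]
  if (length(body) == 0) {
    labels <- channel_labels %||% header %||%
      paste0("ch", seq_len(spec$expected_channels))
    if (length(labels) != spec$expected_channels)
      abort(sprintf("Expected %d channels, header names %d.",
                    spec$expected_channels, length(labels)),
            class = "earpipe_format_error")
    return(ear_recording(matrix(0, spec$expected_channels, 0), spec$fs_hz,
                         labels, session_id = session_id))
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  ncols <- lengths(parts)
  if (length(unique(ncols)) != 1)
    abort(sprintf("Ragged file: rows have %s columns.",
                  paste(unique(ncols), collapse = "/")),
          class = "earpipe_format_error")
  ncol <- ncols[1]
  fields <- matrix(trimws(unlist(parts)), nrow = length(parts), byrow = TRUE)

  if (spec$dialect == "openbci_gui_txt") {
    min_cols <- spec$expected_channels + 1 # sample index + channels
    if (ncol < min_cols)
      abort(sprintf("Expected at least %d columns (index + %d channels), found %d.",
                    min_cols, spec$expected_channels, ncol),
            class = "earpipe_format_error")
    num <- parse_numeric_fields(fields, body_lines)
    data <- t(num[, 1 + seq_len(spec$expected_channels), drop = FALSE])
    aux <- cbind(sample_index = num[, 1],
                 if (ncol > min_cols) num[, (min_cols + 1):ncol, drop = FALSE])
    labels <- channel_labels %||% default_channels()[seq_len(spec$expected_channels)]
  } else {
    if (ncol != spec$expected_channels)
      abort(sprintf("Expected %d channel columns, found %d.",
                    spec$expected_channels, ncol),
            class = "earpipe_format_error")
    num <- parse_numeric_fields(fields, body_lines)
    data <- t(num)
    aux <- NULL
    labels <- channel_labels %||% header %||%
      paste0("ch", seq_len(spec$expected_channels))
  }
  if (length(labels) != spec$expected_channels)
    abort(sprintf("Expected %d channel labels, got %d.",
                  spec$expected_channels, length(labels)),
          class = "earpipe_format_error")
  rec <- ear_recording(data, spec$fs_hz, labels, session_id = session_id)
  attr(rec, "aux") <- aux
  rec
}

#' Write a recording to disk
#'
#' Inverse of [read_recording()]: deterministic column order, microvolt
#' values at full double precision. A zero-sample recording yields a
#' header-only file.
#'
#' @param recording An [ear_recording()].
#' @param path Output path.
#' @param spec A [recording_file_spec()]; its channel count must match.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, spec = recording_file_spec()) {
  if (nrow(recording$data) != spec$expected_channels)
    abort(sprintf("Recording has %d channels but spec expects %d.",
                  nrow(recording$data), spec$expected_channels),
          class = "earpipe_format_error")
  n <- ncol(recording$data)
  if (spec$dialect == "openbci_gui_txt") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("%OpenBCI Raw EEG Data",
                 sprintf("%%Number of channels = %d", nrow(recording$data)),
                 sprintf("%%Sample Rate = %g Hz", recording$fs)), con)
    if (n > 0) {
      m <- cbind(as.character((seq_len(n) - 1) %% 256),
                 format(t(recording$data), trim = TRUE, digits = 15,
                        scientific = FALSE))
      utils::write.table(m, con, sep = ",", row.names = FALSE,
                         col.names = FALSE, quote = FALSE)
    }
  } else {
    m <- t(recording$data)
    colnames(m) <- recording$channel_labels
    utils::write.table(rbind(recording$channel_labels,
                             if (n > 0) format(m, trim = TRUE, digits = 15,
                                               scientific = FALSE)),
                       path, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read an event-annotation table
#'
#' Expects the CSV header `label,is_bruxism,onset_s,offset_s`. Annotations
#' are validated (positive extent, no overlap) and returned sorted by onset.
#'
#' @param path File path.
#' @return Annotation tibble.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path))
    abort(sprintf("File not found: %s", path), class = "earpipe_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "is_bruxism", "onset_s", "offset_s")
  if (!all(need %in% names(df)))
    abort(sprintf("Annotation file must have columns %s.",
                  paste(need, collapse = ", ")),
          class = "earpipe_format_error")
  ann <- as_tibble(df[need])
  ann$is_bruxism <- as.logical(ann$is_bruxism)
  validate_annotations(ann)
}

#' Write an event-annotation table
#' @param annotations Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations[c("label", "is_bruxism", "onset_s", "offset_s")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate and sort an annotation table
#'
#' @param annotations Annotation tibble.
#' @param duration_s Optional recording duration for bounds checking.
#' @return The sorted tibble, or an error for negative/zero-length or
#'   overlapping events.
#' @export
validate_annotations <- function(annotations, duration_s = NULL) {
  ann <- arrange(annotations, .data$onset_s)
  if (nrow(ann) == 0) return(ann)
  if (any(ann$onset_s < 0) || any(ann$offset_s <= ann$onset_s))
    abort("Annotations must satisfy 0 <= onset < offset.",
          class = "earpipe_validation_error")
  if (!is.null(duration_s) && any(ann$offset_s > duration_s + 1e-9))
    abort("Annotation extends beyond the recording.",
          class = "earpipe_validation_error")
  if (nrow(ann) > 1 &&
      any(ann$onset_s[-1] < ann$offset_s[-nrow(ann)] - 1e-9))
    abort("Annotations overlap.", class = "earpipe_validation_error")
  ann
}
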