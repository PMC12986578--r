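#' Write a recording to CSV with a JSON sidecar
#'
#' The signal is stored as a plain CSV (`time_s` column plus one column per
#' channel) and the metadata (`fs_hz`, `scale`, per-channel `subject` /
#' `group` / `is_noise_channel`) in a JSON sidecar named `<path>.json`.
#' Writers are deterministic: fixed column order and 9-significant-digit
#' float formatting.
#'
#' @param recording an [emg_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "emg_recording"))
  n <- n_samples(recording)
  df <- data.frame(time_s = signif((seq_len(n) - 1) / recording$fs, 9))
  for (j in seq_len(n_channels(recording)))
    df[[paste0("ch", j)]] <- signif(recording$samples[, j], 9)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(
    fs_hz = recording$fs,
    scale = 1.0,
    subject = recording$channel_meta$subject,
    group = recording$channel_meta$group,
    is_noise_channel = recording$channel_meta$is_noise_channel
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path CSV path; the `<path>.json` sidecar must exist and contain
#'   `fs_hz`.
#' @return An [emg_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("format error: missing JSON sidecar (fs unknown): ", sidecar)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(side$fs_hz)) stop("format error: sidecar lacks fs_hz")
  df <- utils::read.csv(path, check.names = FALSE)
  ch_cols <- setdiff(names(df), "time_s")
  if (length(ch_cols) < 1L) stop("format error: no channel columns")
  samples <- as.matrix(df[, ch_cols, drop = FALSE])
  if (anyNA(samples)) stop("format error: ragged or non-numeric channels")
  scale <- side$scale %||% 1.0
  n_ch <- ncol(samples)
  meta <- data.frame(
    subject = rep_len(side$subject %||% paste0("ch", seq_len(n_ch)), n_ch),
    group = rep_len(side$group %||% NA_character_, n_ch),
    is_noise_channel = rep_len(side$is_noise_channel %||% FALSE, n_ch),
    stringsAsFactors = FALSE
  )
  emg_recording(samples * scale, as.numeric(side$fs_hz), meta)
}

#' Write / read burst annotations
#'
#' Annotations are half-open `[onset_s, offset_s)` intervals, 0-based in
#' seconds, one row per burst, sorted by subject then onset.
#'
#' @param annotations data.frame with columns subject, group, burst_id,
#'   onset_s, offset_s.
#' @param path CSV path.
#' @return `path` (writer) or the annotations data.frame (reader).
#' @export
write_annotations <- function(annotations, path) {
  cols <- c("subject", "group", "burst_id", "onset_s", "offset_s")
  stopifnot(all(cols %in% names(annotations)))
  ann <- annotations[order(annotations$subject, annotations$onset_s), cols]
  ann$onset_s <- signif(ann$onset_s, 9)
  ann$offset_s <- signif(ann$offset_s, 9)
  utils::write.csv(ann, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (any(ann$offset_s <= ann$onset_s))
    stop("format error: annotation offsets must exceed onsets")
  ann
}

#' Write / read the tidy phase-feature table
#'
#' Fixed column order (subject, group, burst_id, phase, source, metric,
#' value), rows sorted by all key columns; `NA` values are serialized as
#' empty fields and restored as missing on read.
#'
#' @param table data.frame as produced by the feature-extraction steps.
#' @param path CSV path.
#' @return `path` (writer) or the table (reader).
#' @export
write_feature_table <- function(table, path) {
  cols <- c("subject", "group", "burst_id", "phase", "source", "metric", "value")
  stopifnot(nrow(table) > 0, all(cols %in% names(table)))
  tab <- table[do.call(order, table[, cols[1:6]]), cols]
  tab$value <- ifelse(is.na(tab$value), "", formatC(signif(tab$value, 9), format = "g", digits = 9))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  tab$value <- as.numeric(tab$value)
  tab
}
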