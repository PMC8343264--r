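#' Construct a hypnogram
#'
#' A hypnogram is the epoch-level time series of sleep-wake stage labels. It is
#' represented as a data frame with one row per 30-second epoch, columns
#' `timestamp` (POSIXct, UTC, epoch start) and `label` (factor with levels
#' WAKE, N1, N2, N3, REM, UNKNOWN).
#'
#' @param timestamp POSIXct vector of epoch start times (strictly increasing,
#'   30 s apart).
#' @param label character or factor of stage labels.
#' @return A `data.frame` of class `hypnogram`.
#' @export
hypnogram <- function(timestamp, label) {
  if (length(timestamp) != length(label))
    stop("timestamp and label must have equal length")
  label <- as.character(label)
  bad <- setdiff(unique(label), STAGE_LEVELS)
  if (length(bad))
    stop("unknown stage labels: ", paste(bad, collapse = ", "))
  if (length(timestamp) > 1) {
    dt <- as.numeric(diff(timestamp), units = "secs")
    if (any(abs(dt - EPOCH_SEC) > 1e-6))
      stop("epochs must be contiguous at 30-s resolution")
  }
  h <- data.frame(timestamp = as.POSIXct(timestamp, tz = "UTC"),
                  label = factor(label, levels = STAGE_LEVELS))
  class(h) <- c("hypnogram", "data.frame")
  h
}

#' Stage labels known by the package
#' @return Character vector of the six epoch labels.
#' @export
stage_levels <- function() STAGE_LEVELS

#' Map a timestamp to its noon-anchored day key
#'
#' Days run noon-to-noon (UTC) so that a main overnight sleep period is never
#' split across two analysis days. The key is the calendar date on which the
#' 24-h window starts.
#'
#' @param time POSIXct vector.
#' @return `Date` vector.
#' @export
day_key <- function(time) {
  as.Date(as.POSIXct(time, tz = "UTC") - 12 * 3600, tz = "UTC")
}

#' End of a day key's 24-hour window
#' @param key Date vector as returned by [day_key()].
#' @return POSIXct (noon UTC of the following day).
#' @export
day_window_end <- function(key) {
  as.POSIXct(paste(as.Date(key) + 1, "12:00:00"), tz = "UTC")
}

#' Read / write hypnogram CSV
#'
#' CSV format: header `timestamp_iso8601,label`, one row per 30-s epoch,
#' labels in WAKE/N1/N2/N3/REM/UNKNOWN.
#'
#' @param path file path.
#' @return `read_hypnogram` returns a [hypnogram()].
#' @export
read_hypnogram <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("timestamp_iso8601", "label") %in% names(d)))
  ts <- as.POSIXct(d$timestamp_iso8601, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  hypnogram(ts, d$label)
}

#' @rdname read_hypnogram
#' @param h a [hypnogram()].
#' @export
write_hypnogram <- function(h, path) {
  out <- data.frame(
    timestamp_iso8601 = format(h$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    label = as.character(h$label))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write seizure event CSV
#'
#' CSV format: header `onset_iso8601,duration_s`.
#' @param path file path.
#' @return `read_seizures` returns a data.frame with POSIXct `onset` and
#'   numeric `duration_s`.
#' @export
read_seizures <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("onset_iso8601", "duration_s") %in% names(d)))
  data.frame(
    onset = as.POSIXct(d$onset_iso8601, tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S")),
    duration_s = as.numeric(d$duration_s))
}

#' @rdname read_seizures
#' @param seizures data.frame with columns `onset`, `duration_s`.
#' @export
write_seizures <- function(seizures, path) {
  out <- data.frame(
    onset_iso8601 = format(seizures$onset, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    duration_s = seizures$duration_s)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
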