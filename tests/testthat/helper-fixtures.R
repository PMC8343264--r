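# Shared fixtures: hand-built hypnograms and small simulated datasets.

T0 <- as.POSIXct("2020-01-01 12:00:00", tz = "UTC")

# Build a hypnogram from run-length labels, e.g. run_labels(WAKE = 10, N2 = 4).
run_labels <- function(...) {
  v <- c(...)
  rep(names(v), v)
}

toy_hypnogram <- function(labels, start = T0) {
  hypnogram(start + 30 * (seq_along(labels) - 1), labels)
}

# A full noon-to-noon day of labels padded with WAKE (2880 epochs).
toy_day <- function(labels) {
  stopifnot(length(labels) <= 2880)
  c(labels, rep("WAKE", 2880 - length(labels)))
}
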