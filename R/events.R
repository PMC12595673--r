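# Stimulus event tables and epoching of continuous recordings.

#' Read a stimulus event table
#'
#' Tab-separated file with header `onset_s` and `stim_rate_hz`, one row per
#' stimulus train, onsets in seconds from the start of the recording.
#'
#' @param path TSV file path.
#' @return `data.frame` with columns `onset_s`, `stim_rate_hz`, sorted checks
#'   applied (onsets strictly increasing).
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("onset_s", "stim_rate_hz") %in% names(ev))) {
    stop("event table must have columns 'onset_s' and 'stim_rate_hz'")
  }
  validate_events(ev)
  ev
}

#' Write a stimulus event table
#'
#' @param events `data.frame` with `onset_s`, `stim_rate_hz`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  utils::write.table(events[, c("onset_s", "stim_rate_hz")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_events <- function(events) {
  if (nrow(events) > 1 && any(diff(events$onset_s) <= 0)) {
    stop("event onsets must be strictly increasing")
  }
  invisible(events)
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' Extracts one `[window_s[1], window_s[2])` segment per event, time-locked to
#' the train onset; the sample at exactly t = 0 belongs to the post-stimulus
#' side. No filtering or detrending is applied.
#'
#' @param x Numeric vector, continuous signal in uV.
#' @param fs_hz Sampling rate in Hz.
#' @param events Event table (`onset_s`, `stim_rate_hz`).
#' @param window_s Epoch window in seconds relative to onset (default
#'   `c(-1, 1)`).
#' @param meta Metadata list passed to the resulting [epochs_set()].
#' @return An `epochs_set`; `stim_rate_hz` is taken from the events when they
#'   share a single rate, `NA` otherwise.
#' @export
epoch <- function(x, fs_hz, events, window_s = c(-1, 1), meta = list()) {
  validate_events(events)
  stopifnot(length(window_s) == 2, window_s[2] > window_s[1])
  n_samp <- round((window_s[2] - window_s[1]) * fs_hz)
  onset_idx <- round(events$onset_s * fs_hz)      # sample index of t = 0 (0-based)
  start <- onset_idx + round(window_s[1] * fs_hz) # 0-based start of window
  bad <- which(start < 0 | start + n_samp > length(x))
  if (length(bad)) {
    stop(sprintf("epoch window [%g, %g) s overruns the recording for onset(s): %s",
                 window_s[1], window_s[2],
                 paste(format(events$onset_s[bad]), collapse = ", ")))
  }
  dat <- matrix(0, nrow = nrow(events), ncol = n_samp)
  for (i in seq_len(nrow(events))) {
    dat[i, ] <- x[(start[i] + 1):(start[i] + n_samp)]
  }
  rates <- unique(events$stim_rate_hz)
  rate <- if (length(rates) == 1) rates else NA_real_
  epochs_set(dat, fs_hz, window_s[1], rate, meta)
}
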