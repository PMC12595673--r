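# The epochs container: trials x samples of one recording session.

#' Construct an epochs set
#'
#' The universal unit of analysis: a trials x samples matrix of stimulus-locked
#' ECoG segments (microvolts) from one session, with sampling rate, the time of
#' the first sample relative to train onset, the stimulation rate, and session
#' metadata.
#'
#' @param data Numeric matrix, trials in rows, samples in columns (uV). A
#'   0-row matrix is a valid (empty) set.
#' @param fs_hz Sampling rate in Hz.
#' @param t0_s Time of the first sample relative to stimulus-train onset
#'   (seconds; negative when a pre-stimulus baseline is present).
#' @param stim_rate_hz Stimulation train rate in Hz, or `NA` for
#'   stimulation-free data.
#' @param meta Named list of session metadata (`animal_id`, `sex`, `day`,
#'   `condition`, `session_id`); free-form, all optional.
#' @return An object of class `epochs_set`.
#' @export
epochs_set <- function(data, fs_hz, t0_s, stim_rate_hz = NA_real_,
                       meta = list()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.finite(fs_hz) || fs_hz <= 0) stop("fs_hz must be > 0")
  if (!is.finite(t0_s)) stop("t0_s must be finite")
  if (nrow(data) > 0 && !all(is.finite(data))) {
    stop("epoch samples must all be finite")
  }
  structure(
    list(data = data, fs_hz = as.numeric(fs_hz), t0_s = as.numeric(t0_s),
         stim_rate_hz = as.numeric(stim_rate_hz), meta = meta),
    class = "epochs_set"
  )
}

#' @export
print.epochs_set <- function(x, ...) {
  rate <- if (is.na(x$stim_rate_hz)) "none" else paste0(x$stim_rate_hz, " Hz")
  cat(sprintf("<epochs_set> %d trial(s) x %d samples @ %g Hz, t0 = %+0.3f s, stim %s\n",
              nrow(x$data), ncol(x$data), x$fs_hz, x$t0_s, rate))
  if (length(x$meta)) {
    kv <- vapply(names(x$meta), function(k) paste0(k, "=", x$meta[[k]]), "")
    cat("  meta:", paste(kv, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.epochs_set <- function(x) dim(x$data)

#' Sample times of an epochs set
#'
#' @param x An `epochs_set`.
#' @return Numeric vector of sample times in seconds relative to train onset.
#' @export
epoch_times <- function(x) {
  stopifnot(inherits(x, "epochs_set"))
  x$t0_s + (seq_len(ncol(x$data)) - 1) / x$fs_hz
}

# Column indices of samples with t in [w1, w2) relative to train onset.
# Half-open on the right; the sample at exactly t = 0 is post-stimulus.
window_index <- function(x, window_s) {
  stopifnot(length(window_s) == 2, window_s[2] > window_s[1])
  t <- epoch_times(x)
  idx <- which(t >= window_s[1] - 1e-9 & t < window_s[2] - 1e-9)
  if (!length(idx)) {
    stop(sprintf("window [%g, %g) s not covered by epochs (t0 = %g s, %g s long)",
                 window_s[1], window_s[2], x$t0_s, ncol(x$data) / x$fs_hz))
  }
  idx
}

# Average trials sample-wise (for evoked analyses).
average_epochs <- function(x) {
  stopifnot(inherits(x, "epochs_set"))
  if (nrow(x$data) < 1) stop("cannot average an empty epochs set")
  epochs_set(matrix(colMeans(x$data), nrow = 1), x$fs_hz, x$t0_s,
             x$stim_rate_hz, x$meta)
}
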