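# Morlet-wavelet time-frequency analysis of stimulus-locked epochs and the
# ASSR metrics derived from it: phase-locking factor (inter-trial phase
# coherence), induced power ratio, evoked power, and harmonic responses.

#' Morlet wavelet time-frequency transform
#'
#' Convolves every trial with L2-normalized complex Morlet wavelets
#' (`n_cycles` cycles at every frequency, Gaussian SD
#' `sigma_t = n_cycles / (2 pi f)`), retaining complex coefficients so both
#' power and phase are available. Output times are decimated to `dt_out_s`.
#' Time-frequency bins whose wavelet support (half-length `n_cycles / (2 f)`
#' seconds) crosses the epoch edge are flagged in the `edge` matrix and
#' excluded from all window averages downstream.
#'
#' @param x An `epochs_set`.
#' @param freqs_hz Analysis frequencies in Hz (default 1--100 in 1 Hz steps).
#' @param n_cycles Wavelet width in cycles (default 7).
#' @param dt_out_s Output time step in seconds (default 0.005).
#' @return An object of class `assr_tfr`: complex array `coef`
#'   (trial x frequency x time), `freqs_hz`, `times_s`, logical `edge`
#'   (frequency x time), and params.
#' @export
morlet_tfr <- function(x, freqs_hz = 1:100, n_cycles = 7, dt_out_s = 0.005) {
  stopifnot(inherits(x, "epochs_set"))
  nt <- nrow(x$data)
  ns <- ncol(x$data)
  if (nt < 1 || ns < 2) stop("need at least one trial with >= 2 samples")
  fs <- x$fs_hz
  dur <- ns / fs
  if (any(freqs_hz < 1 / dur - 1e-9)) {
    stop(sprintf("analysis frequencies below 1/epoch-duration = %.3f Hz are not resolvable", 1 / dur))
  }
  step <- max(1L, as.integer(round(dt_out_s * fs)))
  out_idx <- seq(1L, ns, by = step)
  times <- x$t0_s + (out_idx - 1) / fs

  # wavelet half-lengths in samples, capped at the epoch length
  half_sup_s <- n_cycles / (2 * freqs_hz)
  h <- pmin(round(half_sup_s * fs), ns)
  nfft <- stats::nextn(ns + 2 * max(h) + 1, c(2, 3, 5))
  X <- stats::mvfft(rbind(t(x$data), matrix(0, nfft - ns, nt)))

  nf <- length(freqs_hz)
  coef <- array(0 + 0i, dim = c(nt, nf, length(out_idx)))
  edge <- matrix(FALSE, nf, length(out_idx))
  for (fi in seq_len(nf)) {
    f <- freqs_hz[fi]
    hf <- h[fi]
    tw <- (-hf:hf) / fs
    sigma_t <- n_cycles / (2 * pi * f)
    wv <- exp(-tw^2 / (2 * sigma_t^2)) * exp(2i * pi * f * tw)
    wv <- wv / sqrt(sum(Mod(wv)^2))
    Wf <- stats::fft(c(wv, rep(0 + 0i, nfft - length(wv))))
    Y <- stats::mvfft(X * Wf, inverse = TRUE) / nfft
    coef[, fi, ] <- t(Y[out_idx + hf, , drop = FALSE])
    edge[fi, ] <- (out_idx - 1) < hf | (ns - out_idx) < hf
  }
  structure(
    list(coef = coef, freqs_hz = freqs_hz, times_s = times, edge = edge,
         params = list(n_cycles = n_cycles, dt_out_s = step / fs, fs_hz = fs),
         meta = x$meta, stim_rate_hz = x$stim_rate_hz),
    class = "assr_tfr"
  )
}

#' @export
print.assr_tfr <- function(x, ...) {
  d <- dim(x$coef)
  cat(sprintf("<assr_tfr> %d trial(s) x %d freqs (%g-%g Hz) x %d times (%+0.2f..%+0.2f s), %g cycles\n",
              d[1], d[2], min(x$freqs_hz), max(x$freqs_hz), d[3],
              min(x$times_s), max(x$times_s), x$params$n_cycles))
  invisible(x)
}

#' @export
plot.assr_tfr <- function(x, what = c("power", "plf"), ...) {
  what <- match.arg(what)
  z <- if (what == "power") {
    apply(Mod(x$coef)^2, c(2, 3), mean)
  } else {
    u <- x$coef / ifelse(Mod(x$coef) > 0, Mod(x$coef), 1)
    Mod(apply(u, c(2, 3), mean))
  }
  graphics::image(x$times_s, x$freqs_hz, t(z), xlab = "Time (s)",
                  ylab = "Frequency (Hz)", main = what,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

# Indices of TFR band/window bins; errors if empty, drops edge-flagged bins.
# Frequency band endpoints are inclusive on the analysis grid.
.tfr_bins <- function(tfr, band_hz, window_s) {
  fi <- which(tfr$freqs_hz >= band_hz[1] - 1e-9 & tfr$freqs_hz <= band_hz[2] + 1e-9)
  ti <- which(tfr$times_s >= window_s[1] - 1e-9 & tfr$times_s < window_s[2] - 1e-9)
  if (!length(fi) || !length(ti)) {
    stop(sprintf("band [%g, %g] Hz x window [%g, %g) s does not intersect the TFR support",
                 band_hz[1], band_hz[2], window_s[1], window_s[2]))
  }
  keep <- !tfr$edge[fi, ti, drop = FALSE]
  if (!any(keep)) {
    stop("all bins in the requested band x window are edge-contaminated")
  }
  list(fi = fi, ti = ti, keep = keep)
}

#' Phase-locking factor (inter-trial phase coherence)
#'
#' At every unflagged time-frequency bin of the band x window region, the
#' magnitude of the across-trial mean unit phase vector is computed; the
#' returned value is the mean over bins. 1 = perfect phase consistency;
#' with N uniformly random trial phases the expectation is
#' `sqrt(pi / (4 N))`. Zero-magnitude coefficients contribute a zero unit
#' vector.
#'
#' @param tfr An `assr_tfr` with at least 2 trials.
#' @param band_hz `c(low, high)` in Hz, endpoints inclusive on the grid.
#' @param window_s Analysis window (default `c(0.2, 0.9)` s after onset).
#' @return PLF value in `[0, 1]`.
#' @export
plf <- function(tfr, band_hz, window_s = c(0.2, 0.9)) {
  stopifnot(inherits(tfr, "assr_tfr"))
  if (dim(tfr$coef)[1] < 2) stop("PLF needs at least 2 trials")
  b <- .tfr_bins(tfr, band_hz, window_s)
  cc <- tfr$coef[, b$fi, b$ti, drop = FALSE]
  nt <- dim(cc)[1]
  m <- Mod(cc)
  u <- matrix(cc / ifelse(m > 0, m, 1), nrow = nt)  # trials x (band*window) bins
  r <- Mod(colMeans(u))
  mean(r[as.vector(b$keep)])
}

#' Induced power ratio (stimulation vs baseline)
#'
#' Per trial, the mean wavelet power over band x stimulation window divided
#' by the mean power over band x baseline window; the returned value averages
#' the per-trial ratios (`"mean_of_ratios"`, default) or takes the ratio of
#' trial-mean powers (`"ratio_of_means"`, for sensitivity analyses). The
#' measure is insensitive to across-trial phase alignment.
#'
#' @param tfr An `assr_tfr`.
#' @param band_hz Analysis band in Hz.
#' @param stim_window_s Stimulation window (default `c(0.2, 0.9)` s).
#' @param base_window_s Baseline window (default `c(-0.5, -0.1)` s, i.e.
#'   0.1--0.5 s before train onset).
#' @param aggregate Aggregation rule, see above.
#' @return Nonnegative unitless ratio.
#' @export
induced_power_ratio <- function(tfr, band_hz, stim_window_s = c(0.2, 0.9),
                                base_window_s = c(-0.5, -0.1),
                                aggregate = c("mean_of_ratios", "ratio_of_means")) {
  stopifnot(inherits(tfr, "assr_tfr"))
  aggregate <- match.arg(aggregate)
  bs <- .tfr_bins(tfr, band_hz, stim_window_s)
  bb <- .tfr_bins(tfr, band_hz, base_window_s)
  nt <- dim(tfr$coef)[1]
  ps <- matrix(Mod(tfr$coef[, bs$fi, bs$ti, drop = FALSE])^2, nrow = nt)
  pb <- matrix(Mod(tfr$coef[, bb$fi, bb$ti, drop = FALSE])^2, nrow = nt)
  stim_p <- rowMeans(ps[, as.vector(bs$keep), drop = FALSE])
  base_p <- rowMeans(pb[, as.vector(bb$keep), drop = FALSE])
  zero <- which(base_p <= 0)
  if (length(zero)) {
    stop("zero baseline power in trial(s): ", paste(zero, collapse = ", "))
  }
  if (aggregate == "mean_of_ratios") mean(stim_p / base_p) else mean(stim_p) / mean(base_p)
}

#' Evoked power
#'
#' Trials are averaged sample-wise in the time domain first, so only the
#' phase-locked component survives; the average is then wavelet-transformed
#' and the mean power over band x stimulation window is returned (uV^2 under
#' the L2 wavelet normalization). No baseline normalization is applied.
#'
#' @param x An `epochs_set` with at least 2 trials.
#' @param band_hz Analysis band in Hz.
#' @param stim_window_s Stimulation window (default `c(0.2, 0.9)` s).
#' @param freqs_hz,n_cycles Passed to [morlet_tfr()].
#' @return Nonnegative power (uV^2).
#' @export
evoked_power <- function(x, band_hz, stim_window_s = c(0.2, 0.9),
                         freqs_hz = 1:100, n_cycles = 7) {
  stopifnot(inherits(x, "epochs_set"))
  if (nrow(x$data) < 2) stop("evoked power needs at least 2 trials")
  avg <- average_epochs(x)
  tfr <- morlet_tfr(avg, freqs_hz = freqs_hz, n_cycles = n_cycles)
  b <- .tfr_bins(tfr, band_hz, stim_window_s)
  p <- matrix(Mod(tfr$coef[1, b$fi, b$ti, drop = FALSE])^2, nrow = length(b$fi))
  mean(p[b$keep])
}

#' Harmonic response at twice the stimulation rate
#'
#' Same computation as [plf()] or [evoked_power()], but on the band
#' `[2f - 2, 2f + 2]` Hz around the first harmonic of the stimulation rate
#' (e.g. the 80 Hz response during 40 Hz trains).
#'
#' @param x An `assr_tfr` (for `kind = "plf"`) or an `epochs_set`
#'   (for `kind = "evoked"`; also accepted for `"plf"`, in which case the TFR
#'   is computed over the harmonic band).
#' @param stim_rate_hz Stimulation rate in Hz.
#' @param kind `"plf"` or `"evoked"`.
#' @param stim_window_s Stimulation window.
#' @param n_cycles Wavelet cycles when a transform must be computed.
#' @param max_freq_hz Maximum analysis frequency available (defaults to the
#'   TFR grid maximum, or 100 Hz for epochs input).
#' @return Harmonic PLF or evoked power.
#' @export
harmonic_response <- function(x, stim_rate_hz, kind = c("plf", "evoked"),
                              stim_window_s = c(0.2, 0.9), n_cycles = 7,
                              max_freq_hz = NULL) {
  kind <- match.arg(kind)
  f2 <- 2 * stim_rate_hz
  if (inherits(x, "assr_tfr")) {
    max_f <- max_freq_hz %||% max(x$freqs_hz)
  } else {
    max_f <- max_freq_hz %||% 100
  }
  if (f2 > max_f) {
    stop(sprintf("harmonic frequency %g Hz exceeds the maximum analysis frequency %g Hz",
                 f2, max_f))
  }
  band <- c(f2 - 2, f2 + 2)
  if (kind == "plf") {
    tfr <- if (inherits(x, "assr_tfr")) x else
      morlet_tfr(x, freqs_hz = seq(band[1], band[2]), n_cycles = n_cycles)
    plf(tfr, band, stim_window_s)
  } else {
    if (!inherits(x, "epochs_set")) {
      stop("evoked harmonic response needs an epochs_set (trial average precedes the transform)")
    }
    evoked_power(x, band, stim_window_s, freqs_hz = seq(band[1], band[2]),
                 n_cycles = n_cycles)
  }
}

#' All ASSR metrics for one session
#'
#' Convenience wrapper computing PLF, induced power ratio, evoked power and
#' the harmonic PLF for an epochs set at its stimulation rate.
#'
#' @param x An `epochs_set` with a stimulation rate.
#' @param freqs_hz Wavelet frequency grid; defaults to the union of the
#'   fundamental and harmonic analysis bands.
#' @param n_cycles Wavelet cycles.
#' @param stim_window_s,base_window_s Analysis windows.
#' @return One-row `data.frame` with `plf`, `induced_ratio`, `evoked_power`,
#'   `harmonic_plf`.
#' @export
assr_metrics <- function(x, freqs_hz = NULL, n_cycles = 7,
                         stim_window_s = c(0.2, 0.9),
                         base_window_s = c(-0.5, -0.1)) {
  stopifnot(inherits(x, "epochs_set"))
  rate <- x$stim_rate_hz
  if (is.na(rate)) stop("epochs set has no stimulation rate")
  band <- assr_band(rate)
  hband <- c(2 * rate - 2, 2 * rate + 2)
  if (is.null(freqs_hz)) {
    freqs_hz <- sort(unique(c(seq(band[1], band[2]), seq(hband[1], hband[2]))))
  }
  tfr <- morlet_tfr(x, freqs_hz = freqs_hz, n_cycles = n_cycles)
  harm <- if (2 * rate <= max(freqs_hz)) {
    harmonic_response(tfr, rate, "plf", stim_window_s)
  } else NA_real_
  # evoked power via linearity: the transform of the trial average equals the
  # trial average of the transform, so the TFR is reused
  b <- .tfr_bins(tfr, band, stim_window_s)
  cm <- matrix(colMeans(matrix(tfr$coef[, b$fi, b$ti, drop = FALSE],
                               nrow = nrow(x$data))), nrow = length(b$fi))
  ev <- mean(Mod(cm[b$keep])^2)
  data.frame(
    plf = plf(tfr, band, stim_window_s),
    induced_ratio = induced_power_ratio(tfr, band, stim_window_s, base_window_s),
    evoked_power = ev,
    harmonic_plf = harm
  )
}
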