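# Multitaper spectral estimation: discrete prolate spheroidal (Slepian)
# tapers, trial-averaged one-sided power spectral density, and band
# summaries.

.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequence (DPSS) tapers
#'
#' Computes the `n_tapers` most concentrated orthonormal Slepian tapers for a
#' window of `n_samples` at sampling rate `fs_hz` and half-bandwidth
#' `half_bandwidth_hz`, via the classical symmetric tridiagonal eigenproblem
#' whose eigenvectors are the DPSS. The spectral concentration of each taper
#' within +/- W is computed by FFT quadrature and returned as the
#' `"concentration"` attribute; a warning is raised if any falls below 0.90.
#'
#' @param n_samples Window length in samples.
#' @param half_bandwidth_hz Half-bandwidth W in Hz. The time-bandwidth
#'   product is `NW = half_bandwidth_hz * n_samples / fs_hz`.
#' @param fs_hz Sampling rate in Hz.
#' @param n_tapers Number of tapers; must not exceed `floor(2 NW) - 1`.
#' @return `n_tapers` x `n_samples` matrix with orthonormal rows, attribute
#'   `"concentration"`.
#' @export
dpss_tapers <- function(n_samples, half_bandwidth_hz, fs_hz, n_tapers) {
  n <- as.integer(n_samples)
  W <- half_bandwidth_hz / fs_hz
  NW <- n * W
  if (NW < 1) {
    stop(sprintf("time-bandwidth product NW = %.3f < 1; increase the window or bandwidth", NW))
  }
  kmax <- floor(2 * NW) - 1
  if (n_tapers > kmax) {
    stop(sprintf("n_tapers = %d infeasible for NW = %.2f; maximum is %d",
                 n_tapers, NW, kmax))
  }
  if (n_tapers < 1) stop("n_tapers must be >= 1")
  key <- sprintf("%d|%.10g|%d", n, W, n_tapers)
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])

  # Tridiagonal commuting matrix (Slepian): eigenvectors are the DPSS.
  t_idx <- 0:(n - 1)
  diag_v <- ((n - 1 - 2 * t_idx) / 2)^2 * cos(2 * pi * W)
  off_v <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- diag_v
  A[cbind(1:(n - 1), 2:n)] <- off_v
  A[cbind(2:n, 1:(n - 1))] <- off_v
  ev <- eigen(A, symmetric = TRUE)
  tapers <- t(ev$vectors[, seq_len(n_tapers), drop = FALSE])
  # Normalize and fix sign convention: positive mean for symmetric tapers,
  # positive leading lobe otherwise.
  for (k in seq_len(n_tapers)) {
    v <- tapers[k, ]
    v <- v / sqrt(sum(v^2))
    s <- sum(v)
    if (abs(s) > 1e-8) {
      if (s < 0) v <- -v
    } else if (v[which.max(abs(v[1:(n %/% 2)]))] < 0) {
      v <- -v
    }
    tapers[k, ] <- v
  }
  # Spectral concentration in [-W, W]: exact quadratic form v' K v with the
  # sinc concentration kernel K_ij = sin(2 pi W (i-j)) / (pi (i-j)).
  dd <- outer(seq_len(n), seq_len(n), "-")
  K <- sin(2 * pi * W * dd) / (pi * dd)
  K[dd == 0] <- 2 * W
  conc <- vapply(seq_len(n_tapers), function(k) {
    v <- tapers[k, ]
    drop(v %*% (K %*% v))
  }, 0)
  rm(K, dd)
  if (any(conc < 0.90)) {
    warning(sprintf("taper concentration below 0.90: %s",
                    paste(format(conc, digits = 4), collapse = ", ")))
  }
  attr(tapers, "concentration") <- conc
  .taper_cache[[key]] <- tapers
  tapers
}

#' Multitaper power spectral density of an epochs set
#'
#' Estimates the one-sided PSD (uV^2/Hz) of spontaneous activity from a fixed
#' window of every trial: each demeaned segment is multiplied by each Slepian
#' taper, the eigenspectra are combined with concentration weights summing to
#' one, and the per-trial spectra are averaged. The default window
#' `c(-0.9, -0.2)` s is the stimulation-free part of the inter-train interval
#' (0.2--0.9 s before train onset). Calibration: the integral of the PSD over
#' `[0, fs/2]` matches the mean variance of the demeaned tapered segments.
#'
#' @param x An `epochs_set` with at least one trial.
#' @param window_s Analysis window (seconds relative to train onset),
#'   half-open.
#' @param half_bandwidth_hz Taper half-bandwidth W in Hz (default 2.9, NW
#'   close to 2 on the default 0.7 s window).
#' @param n_tapers Number of tapers (default 3 = 2NW - 1).
#' @return An object of class `assr_spectrum` with fields `freqs_hz`, `psd`,
#'   `n_epochs_averaged`, `params`.
#' @export
psd_multitaper <- function(x, window_s = c(-0.9, -0.2),
                           half_bandwidth_hz = 2.9, n_tapers = 3) {
  stopifnot(inherits(x, "epochs_set"))
  if (nrow(x$data) < 1) stop("need at least one trial")
  idx <- window_index(x, window_s)
  seg <- x$data[, idx, drop = FALSE]     # trials x n
  n <- ncol(seg)
  fs <- x$fs_hz
  tapers <- dpss_tapers(n, half_bandwidth_hz, fs, n_tapers)
  lam <- attr(tapers, "concentration")
  w <- lam / sum(lam)
  seg <- seg - rowMeans(seg)             # demean each segment
  nfreq <- n %/% 2 + 1
  acc <- numeric(nfreq)
  segT <- t(seg)                          # n x trials
  for (k in seq_len(n_tapers)) {
    Y <- stats::mvfft(segT * tapers[k, ])
    P <- Mod(Y[seq_len(nfreq), , drop = FALSE])^2
    acc <- acc + w[k] * rowMeans(P)
  }
  # one-sided density: double all bins except DC (and Nyquist for even n)
  scale <- rep(2 / fs, nfreq)
  scale[1] <- 1 / fs
  if (n %% 2 == 0) scale[nfreq] <- 1 / fs
  psd <- acc * scale
  structure(
    list(freqs_hz = (seq_len(nfreq) - 1) * fs / n,
         psd = psd,
         n_epochs_averaged = nrow(x$data),
         params = list(window_s = window_s,
                       half_bandwidth_hz = half_bandwidth_hz,
                       n_tapers = n_tapers, fs_hz = fs)),
    class = "assr_spectrum"
  )
}

#' @export
print.assr_spectrum <- function(x, ...) {
  cat(sprintf("<assr_spectrum> %d bins, 0-%.1f Hz, %d epoch(s) averaged, W = %g Hz, %d tapers\n",
              length(x$freqs_hz), max(x$freqs_hz), x$n_epochs_averaged,
              x$params$half_bandwidth_hz, x$params$n_tapers))
  invisible(x)
}

#' @export
plot.assr_spectrum <- function(x, log = "y", xlim = c(1, 100), ...) {
  keep <- x$freqs_hz >= xlim[1] & x$freqs_hz <= xlim[2] & x$psd > 0
  graphics::plot(x$freqs_hz[keep], x$psd[keep], type = "l", log = log,
                 xlab = "Frequency (Hz)", ylab = expression(PSD ~ (mu * V^2 / Hz)),
                 ...)
  invisible(x)
}

#' Band-averaged power from a spectrum
#'
#' Mean PSD (uV^2/Hz) over the frequency bins of each band, after removing
#' bins inside any exclusion interval. Band and exclusion edges are half-open
#' `[low, high)`. The mean (not the integral) is reported so units remain a
#' density.
#'
#' @param spectrum An `assr_spectrum`.
#' @param bands Named list of `c(low, high)` pairs; default [default_bands()].
#' @param exclusions List of `c(low, high)` intervals removed from every band;
#'   default the 45--55 Hz AC interval.
#' @return One-row `data.frame` with one column per band.
#' @export
band_power <- function(spectrum, bands = default_bands(),
                       exclusions = ac_exclusion()) {
  stopifnot(inherits(spectrum, "assr_spectrum"))
  f <- spectrum$freqs_hz
  fmax <- max(f)
  excluded <- rep(FALSE, length(f))
  for (ex in exclusions) {
    excluded <- excluded | (f >= ex[1] & f < ex[2])
  }
  vals <- lapply(names(bands), function(bn) {
    b <- bands[[bn]]
    if (b[2] > fmax + 1e-9) {
      stop(sprintf("band %s [%g, %g) exceeds spectrum support (max %g Hz)",
                   bn, b[1], b[2], fmax))
    }
    inb <- f >= b[1] & f < b[2]
    fully_excluded <- any(vapply(exclusions, function(ex) {
      b[1] >= ex[1] && b[2] <= ex[2]
    }, TRUE))
    if (fully_excluded) {
      stop(sprintf("band %s [%g, %g) lies entirely inside an exclusion interval",
                   bn, b[1], b[2]))
    }
    keep <- inb & !excluded
    if (!any(keep)) return(0)
    mean(spectrum$psd[keep])
  })
  out <- as.data.frame(stats::setNames(vals, names(bands)))
  out
}
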