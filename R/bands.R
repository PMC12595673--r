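# Canonical frequency-band definitions for spontaneous ECoG power and the
# per-rate ASSR analysis bands.

#' Default spontaneous frequency bands
#'
#' Standard rodent ECoG bands: delta 2--4, theta 4--8, alpha 8--12,
#' beta 12--30, low gamma 30--45 and high gamma 55--90 Hz. Band edges are
#' half-open `[low, high)`. The 45--55 Hz mains (AC) interval is excluded
#' separately via [ac_exclusion()]; the `high_gamma = "wide"` variant
#' (45--90 Hz) relies on that exclusion to remove line noise.
#'
#' @param high_gamma Either `"split"` (default, 55--90 Hz) or `"wide"`
#'   (45--90 Hz, to be combined with the AC exclusion).
#' @return Named list of `c(low, high)` pairs in Hz.
#' @export
default_bands <- function(high_gamma = c("split", "wide")) {
  high_gamma <- match.arg(high_gamma)
  hg <- if (high_gamma == "split") c(55, 90) else c(45, 90)
  list(
    delta      = c(2, 4),
    theta      = c(4, 8),
    alpha      = c(8, 12),
    beta       = c(12, 30),
    low_gamma  = c(30, 45),
    high_gamma = hg
  )
}

#' Mains-interference exclusion interval
#'
#' The 45--55 Hz interval around the 50 Hz mains frequency, excluded from all
#' band summaries (the acquisition notch leaves residual line power).
#'
#' @return List with one `c(low, high)` pair in Hz.
#' @export
ac_exclusion <- function() list(ac = c(45, 55))

#' ASSR analysis band for a stimulation rate
#'
#' The +/- 2 Hz band around the stimulation rate within which wavelet
#' coefficients are averaged: 8--12 Hz for 10 Hz trains, 18--22 for 20 Hz,
#' 38--42 for 40 Hz and 78--82 for 80 Hz. Endpoints are inclusive on the
#' integer wavelet frequency grid.
#'
#' @param stim_rate_hz Stimulation rate in Hz.
#' @param halfwidth_hz Half-width of the band (default 2 Hz).
#' @return `c(low, high)` in Hz.
#' @export
assr_band <- function(stim_rate_hz, halfwidth_hz = 2) {
  stopifnot(is.finite(stim_rate_hz), stim_rate_hz > 0)
  c(stim_rate_hz - halfwidth_hz, stim_rate_hz + halfwidth_hz)
}
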