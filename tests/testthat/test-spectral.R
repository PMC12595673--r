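# Multitaper spectral estimation and band summaries.

test_that("DPSS tapers are orthonormal, feasible, and concentration-checked", {
  tp <- dpss_tapers(512, 4 * 2000 / 512, 2000, 3)   # NW = 4
  G <- tp %*% t(tp)
  expect_lt(max(abs(G - diag(3))), 1e-8)
  expect_true(all(attr(tp, "concentration") >= 0.90))

  # 2NW - 1 rule with the feasible maximum in the message
  expect_error(dpss_tapers(1000, 2 * 2000 / 1000, 2000, 5), "maximum is 3")
  expect_error(dpss_tapers(100, 0.5 * 2000 / 100, 2000, 1), "NW")

  # default analysis window: 3 tapers, all well concentrated
  tp3 <- dpss_tapers(1400, 2.9, 2000, 3)
  expect_equal(nrow(tp3), 3)
  expect_true(all(attr(tp3, "concentration") >= 0.90))
})

test_that("DPSS tapers match the scipy Slepian oracle", {
  if (!expect_python_available()) return(invisible())
  tp <- dpss_tapers(1400, 2.9, 2000, 3)
  f <- tempfile(fileext = ".csv")
  utils::write.table(t(tp), f, sep = ",", row.names = FALSE, col.names = FALSE)
  out <- run_python(sprintf("
import numpy as np
from scipy.signal.windows import dpss
ours = np.loadtxt('%s', delimiter=',').T
ref, lam = dpss(1400, 2.9*1400/2000.0, 3, return_ratios=True)
err = 0.0
for k in range(3):
    v = ours[k] if np.dot(ours[k], ref[k]) > 0 else -ours[k]
    err = max(err, np.abs(v - ref[k]).max())
print(err)
print(' '.join('%%.10f' %% x for x in lam))
", f))
  unlink(f)
  expect_lt(as.numeric(out[1]), 1e-6)
  lam_ref <- as.numeric(strsplit(out[2], " ")[[1]])
  expect_equal(attr(tp, "concentration"), lam_ref, tolerance = 1e-5)
})

test_that("white-noise PSD is flat at sigma^2/(fs/2) and integrates to the variance", {
  set.seed(11)
  fs <- 2000
  e <- epochs_set(matrix(rnorm(100 * 4000), 100, 4000), fs, -1)
  sp <- psd_multitaper(e)
  sel <- sp$freqs_hz >= 10 & sp$freqs_hz <= 900
  expect_lt(abs(mean(sp$psd[sel]) / 1e-3 - 1), 0.10)

  # calibration: integral of the PSD matches the mean segment variance
  idx <- assrtools:::window_index(e, c(-0.9, -0.2))
  seg <- e$data[, idx]
  seg <- seg - rowMeans(seg)
  mean_var <- mean(rowSums(seg^2) / ncol(seg))
  integral <- sum(sp$psd) * fs / length(idx)
  expect_lt(abs(integral / mean_var - 1), 0.05)

  # zero input -> identically zero PSD
  z <- psd_multitaper(epochs_set(matrix(0, 3, 4000), fs, -1))
  expect_true(all(z$psd == 0))
  expect_error(psd_multitaper(e, window_s = c(-3, -2)), "window")
})

test_that("a pure 40 Hz tone concentrates its spectral mass within the taper bandwidth", {
  fs <- 2000
  t <- seq(-1, 1 - 1 / fs, by = 1 / fs)
  e <- epochs_set(matrix(rep(sin(2 * pi * 40 * t), 5), 5, byrow = TRUE), fs, -1)
  sp <- psd_multitaper(e)
  inband <- abs(sp$freqs_hz - 40) <= 3.5
  expect_gte(sum(sp$psd[inband]) / sum(sp$psd), 0.95)
})

test_that("PSD obeys amplitude scaling and trial-permutation invariance", {
  set.seed(12)
  e <- epochs_set(matrix(rnorm(8 * 4000), 8, 4000), 2000, -1)
  sp1 <- psd_multitaper(e)
  e3 <- epochs_set(3 * e$data, 2000, -1)
  sp3 <- psd_multitaper(e3)
  expect_equal(sp3$psd, 9 * sp1$psd, tolerance = 1e-12)
  ep <- epochs_set(e$data[sample(8), ], 2000, -1)
  expect_equal(psd_multitaper(ep)$psd, sp1$psd, tolerance = 1e-12)
  b1 <- band_power(sp1); b3 <- band_power(sp3)
  expect_equal(unlist(b3), 9 * unlist(b1), tolerance = 1e-12)
})

test_that("band power averages half-open bands with AC exclusion", {
  mk_spec <- function(freqs, psd) {
    structure(list(freqs_hz = freqs, psd = psd, n_epochs_averaged = 1,
                   params = list()), class = "assr_spectrum")
  }
  f <- 0:100
  # flat density: every band equals the constant
  bp <- band_power(mk_spec(f, rep(2.5, 101)))
  expect_true(all(abs(unlist(bp) - 2.5) < 1e-12))

  # power only at 50 Hz: the wide high-gamma variant is zeroed by the AC cut
  p50 <- ifelse(f == 50, 7, 0)
  bp50 <- band_power(mk_spec(f, p50), default_bands("wide"))
  expect_equal(bp50$high_gamma, 0)

  # hand mean over included bins: psd(f) = f, delta = mean(2, 3) = 2.5
  bpd <- band_power(mk_spec(f, f))
  expect_equal(bpd$delta, 2.5)
  expect_equal(bpd$theta, mean(4:7))

  # band beyond support, band inside an exclusion
  expect_error(band_power(mk_spec(0:50, rep(1, 51))), "support")
  expect_error(band_power(mk_spec(f, f), bands = list(ac_mid = c(46, 54))),
               "exclusion")
})

test_that("band values agree with the MNE multitaper reference within 5%", {
  if (!expect_python_available()) return(invisible())
  set.seed(13)
  fs <- 2000
  t <- seq(-1, 1 - 1 / fs, by = 1 / fs)
  dat <- matrix(rnorm(20 * 4000), 20, 4000) +
    matrix(rep(0.8 * sin(2 * pi * 20 * t), 20), 20, byrow = TRUE)
  e <- epochs_set(dat, fs, -1)
  sp <- psd_multitaper(e)
  ours <- unlist(band_power(sp))

  idx <- assrtools:::window_index(e, c(-0.9, -0.2))
  seg <- e$data[, idx]
  seg <- seg - rowMeans(seg)
  f <- tempfile(fileext = ".csv")
  utils::write.table(seg, f, sep = ",", row.names = FALSE, col.names = FALSE)
  out <- run_python(sprintf("
import numpy as np
from mne.time_frequency import psd_array_multitaper
x = np.loadtxt('%s', delimiter=',')
psd, freqs = psd_array_multitaper(x, 2000.0, bandwidth=5.8, adaptive=False,
                                  low_bias=True, normalization='full',
                                  verbose=False)
for v in psd.mean(axis=0):
    print(repr(float(v)))
", f))
  unlink(f)
  mne_psd <- as.numeric(out)
  expect_length(mne_psd, length(sp$psd))
  # same band-bin selection applied to both estimates (bin-edge rounding of
  # the two FFT frequency grids differs at exact band boundaries)
  sp_ref <- sp
  sp_ref$psd <- mne_psd
  ref <- unlist(band_power(sp_ref))
  for (b in names(ref)) {
    expect_lt(abs(ours[[b]] / ref[[b]] - 1), 0.05, label = paste("band", b))
  }
})
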