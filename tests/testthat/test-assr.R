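# Morlet TFR and the ASSR metrics: PLF, induced power ratio, evoked power,
# harmonics.

test_that("a pure tone is an eigenfunction of the wavelet transform", {
  fs <- 2000
  t <- seq(-1, 1 - 1 / fs, by = 1 / fs)
  for (A in c(1, 2)) {
    e <- epochs_set(matrix(rep(A * sin(2 * pi * 40 * t), 2), 2, byrow = TRUE),
                    fs, -1, 40)
    tfr <- morlet_tfr(e, freqs_hz = 38:42)
    mid <- which(tfr$times_s > -0.3 & tfr$times_s < 0.3)
    m40 <- Mod(tfr$coef[1, 3, mid])
    expect_lt(diff(range(m40)) / mean(m40), 0.02)
    assign(paste0("p", A), mean(m40)^2)
  }
  expect_equal(p2 / p1, 4, tolerance = 1e-3)   # power scales with A^2

  z <- morlet_tfr(epochs_set(matrix(0, 2, 4000), fs, -1, 40), freqs_hz = 38:42)
  expect_true(all(Mod(z$coef) == 0))
  expect_error(morlet_tfr(epochs_set(matrix(0, 1, 1000), fs, -0.25, 40),
                          freqs_hz = 1), "resolvable")
})

test_that("antiphase trials yield opposite wavelet phases", {
  fs <- 2000
  t <- seq(-1, 1 - 1 / fs, by = 1 / fs)
  dat <- rbind(sin(2 * pi * 40 * t), sin(2 * pi * 40 * t + pi))
  tfr <- morlet_tfr(epochs_set(dat, fs, -1, 40), freqs_hz = 40)
  mid <- which(tfr$times_s > -0.3 & tfr$times_s < 0.3)
  dphi <- Arg(tfr$coef[1, 1, mid] / tfr$coef[2, 1, mid])
  expect_true(all(abs(abs(dphi) - pi) < 0.05))
})

test_that("PLF: perfect locking, antipodal cancellation, uniform floor", {
  e <- make_tone_epochs(rep(0.3, 4))
  tfr <- morlet_tfr(e, freqs_hz = 38:42)
  expect_equal(plf(tfr, c(38, 42)), 1, tolerance = 1e-9)

  t2 <- make_phase_tfr(c(0.7, 0.7 + pi))
  expect_lt(plf(t2, c(38, 42), c(0, 1)), 1e-10)

  # Rayleigh resultant floor for N = 100 uniform phases, 200 replicates
  set.seed(21)
  floors <- vapply(1:200, function(i) {
    plf(make_phase_tfr(runif(100, -pi, pi)), c(38, 42), c(0, 1))
  }, 0)
  expect_lt(abs(mean(floors) - sqrt(pi / 400)), 0.01)

  expect_error(plf(tfr, c(200, 210)), "intersect")
  expect_error(plf(make_phase_tfr(1), c(38, 42), c(0, 1)), "2 trials")
})

test_that("metric invariances: scaling and trial permutation", {
  set.seed(22)
  ph <- rvonmises(12, 0, 2)
  e <- make_tone_epochs(ph, amp = 2, noise_density = 1e-3, seed = 5)
  tfr <- morlet_tfr(e, freqs_hz = 38:42)
  ec <- epochs_set(3.7 * e$data, e$fs_hz, e$t0_s, 40)
  tfrc <- morlet_tfr(ec, freqs_hz = 38:42)
  band <- c(38, 42)
  expect_equal(plf(tfrc, band), plf(tfr, band), tolerance = 1e-12)
  expect_equal(induced_power_ratio(tfrc, band), induced_power_ratio(tfr, band),
               tolerance = 1e-9)
  expect_equal(evoked_power(ec, band, freqs_hz = 38:42),
               3.7^2 * evoked_power(e, band, freqs_hz = 38:42),
               tolerance = 1e-9)

  perm <- sample(12)
  ep <- epochs_set(e$data[perm, ], e$fs_hz, e$t0_s, 40)
  tfrp <- morlet_tfr(ep, freqs_hz = 38:42)
  expect_equal(plf(tfrp, band), plf(tfr, band), tolerance = 1e-12)
  expect_equal(induced_power_ratio(tfrp, band), induced_power_ratio(tfr, band),
               tolerance = 1e-12)
  expect_equal(evoked_power(ep, band, freqs_hz = 38:42),
               evoked_power(e, band, freqs_hz = 38:42), tolerance = 1e-12)
})

test_that("induced power ratio: stationarity, aggregation bias, monotonicity", {
  set.seed(23)
  fs <- 2000
  noise_epochs <- function(n) {
    epochs_set(t(vapply(seq_len(n), function(i) {
      simulate_background(2, fs, 0, aperiodic_density = 1e-3)
    }, numeric(2 * fs))), fs, -1, 40)
  }
  tfr <- morlet_tfr(noise_epochs(80), freqs_hz = 38:42)
  # ratio of trial-mean powers is unbiased under stationarity
  expect_lt(abs(induced_power_ratio(tfr, c(38, 42),
                                    aggregate = "ratio_of_means") - 1), 0.10)
  # the default per-trial aggregation carries a small positive bias from the
  # reciprocal of the noisy baseline mean
  mor <- induced_power_ratio(tfr, c(38, 42))
  expect_gt(mor, 0.95)
  expect_lt(mor, 1.40)

  # monotone in entrained amplitude
  rho <- 1e-3
  ratios <- vapply(c(0.5, 1, 2, 4) * sqrt(rho * fs / 2), function(A) {
    ph <- runif(30, -pi, pi)
    e <- make_tone_epochs(ph, amp = A, noise_density = rho)
    induced_power_ratio(morlet_tfr(e, freqs_hz = 38:42), c(38, 42))
  }, 0)
  expect_true(all(diff(ratios) > 0))

  # zero baseline power names the trial
  ez <- make_tone_epochs(c(0, 0, 0), amp = 0)
  tz <- morlet_tfr(ez, freqs_hz = 38:42)
  expect_error(induced_power_ratio(tz, c(38, 42)), "trial")
})

test_that("evoked power: identity on identical trials, zero case", {
  e <- make_tone_epochs(rep(1.1, 5), amp = 1.5)
  ev <- evoked_power(e, c(38, 42), freqs_hz = 38:42)
  tfr1 <- morlet_tfr(epochs_set(e$data[1, , drop = FALSE], e$fs_hz, e$t0_s, 40),
                     freqs_hz = 38:42)
  b <- assrtools:::.tfr_bins(tfr1, c(38, 42), c(0.2, 0.9))
  p1 <- matrix(Mod(tfr1$coef[1, b$fi, b$ti, drop = FALSE])^2,
               nrow = length(b$fi))
  expect_equal(ev, mean(p1[b$keep]), tolerance = 1e-12)

  expect_equal(evoked_power(make_tone_epochs(c(0, 0), amp = 0), c(38, 42),
                            freqs_hz = 38:42), 0)
  expect_error(evoked_power(epochs_set(matrix(0, 1, 4000), 2000, -1, 40),
                            c(38, 42)), "2 trials")
})

test_that("incoherent averaging attenuates evoked power by ~1/N", {
  set.seed(24)
  N <- 50
  ev_lock <- evoked_power(make_tone_epochs(rep(0, N), amp = 2), c(38, 42),
                          freqs_hz = 38:42)
  ev0 <- vapply(1:25, function(i) {
    evoked_power(make_tone_epochs(runif(N, -pi, pi), amp = 2), c(38, 42),
                 freqs_hz = 38:42)
  }, 0)
  expect_gt(ev_lock / mean(ev0), N / 2)
  expect_lt(ev_lock / mean(ev0), 2 * N)
})

test_that("harmonic responses reflect the 2f component", {
  set.seed(25)
  fs <- 2000
  mk_sess <- function(frac, kappa, n = 80) {
    ph <- rvonmises(n, 0, kappa)
    t <- seq(-1, 1 - 1 / fs, by = 1 / fs)
    dat <- t(vapply(ph, function(p) {
      bg <- simulate_background(2, fs, 0, aperiodic_density = 1e-3)
      s <- ifelse(t >= 0 & t < 1,
                  2 * sin(2 * pi * 40 * t + p) +
                    frac * 2 * sin(2 * pi * 80 * t + 2 * p), 0)
      bg + s
    }, numeric(2 * fs)))
    epochs_set(dat, fs, -1, 40)
  }
  floor_plf <- sqrt(pi / (4 * 80))
  h0 <- harmonic_response(mk_sess(0, 8), 40, "plf")
  expect_lt(h0, 2.5 * floor_plf)
  h5 <- harmonic_response(mk_sess(0.5, 8), 40, "plf")
  expect_gt(h5, 3 * floor_plf)
  expect_gt(h5, h0)

  tfr <- morlet_tfr(make_tone_epochs(c(0, 1)), freqs_hz = 1:100)
  expect_error(harmonic_response(tfr, 80, "plf"), "exceeds")
})

test_that("edge-contaminated bins are flagged and excluded", {
  fs <- 2000
  e <- epochs_set(matrix(rnorm(2 * 4000), 2, 4000), fs, -1, 10)
  tfr <- morlet_tfr(e, freqs_hz = 10)
  # half support at 10 Hz is 0.35 s: bins within 0.35 s of either edge flagged
  expect_true(all(tfr$edge[1, tfr$times_s < -0.66]))
  expect_false(any(tfr$edge[1, tfr$times_s > -0.6 & tfr$times_s < 0.6]))
  # at 2 Hz the wavelet exceeds the epoch: every bin is flagged
  tfr2 <- morlet_tfr(e, freqs_hz = 2)
  expect_true(all(tfr2$edge))
  expect_error(plf(tfr2, c(2, 2), c(0.2, 0.9)), "edge-contaminated")
})
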