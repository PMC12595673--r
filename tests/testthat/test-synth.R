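# Synthetic cohort generator: spectral shaping, von Mises phases,
# hierarchy, determinism.

test_that("spectral shaping reproduces the target density and variance", {
  fs <- 2000
  dens <- 1e-3   # sigma^2 / (fs/2) for unit variance
  # periodogram oracle averaged over 200 draws
  set.seed(41)
  n <- fs
  acc <- numeric(n %/% 2 + 1)
  vars <- numeric(200)
  for (i in 1:200) {
    x <- simulate_background(1, fs, exponent = 0, aperiodic_density = dens)
    vars[i] <- var(x)
    P <- Mod(stats::fft(x))^2 / (n * fs) * 2    # one-sided periodogram
    acc <- acc + P[seq_len(n %/% 2 + 1)] / 200
  }
  f <- (0:(n %/% 2)) * fs / n
  sel <- f >= 1 & f <= 900
  expect_lt(abs(mean(acc[sel]) / dens - 1), 0.10)
  # variance bookkeeping: sample variance matches the density integral
  expect_lt(max(abs(vars - 1)), 0.15)

  # zero density -> silence; identical rng_state -> identical draw
  expect_equal(simulate_background(1, fs, 0, NULL, 1, 0), rep(0, fs))
  expect_identical(simulate_background(0.5, fs, 1, NULL, 9, aperiodic_density = 2),
                   simulate_background(0.5, fs, 1, NULL, 9, aperiodic_density = 2))
  expect_error(simulate_background(1, fs, 1, aperiodic_density = -1), "aperiodic")
  expect_error(
    simulate_background(1, fs, 0,
                        data.frame(center_hz = 10, bandwidth_hz = 1,
                                   density_uv2 = -2)),
    "finite")
})

test_that("per-trial phases follow the von Mises model", {
  # degenerate concentration: phases collapse to a point mass
  ph <- vapply(1:100, function(i) {
    simulate_assr_trial(40, 1, 1e6, rng_state = i)$trial_phase
  }, 0)
  R <- Mod(mean(exp(1i * ph)))
  circ_sd <- sqrt(-2 * log(R))
  expect_lt(circ_sd, 0.01)

  # kappa = 0: uniform phases (Rayleigh test non-significant at alpha 0.001)
  set.seed(7)
  u <- rvonmises(1000, 0, 0)
  expect_true(all(u > -pi & u <= pi))
  Rn <- Mod(mean(exp(1i * u)))
  p_rayleigh <- exp(-1000 * Rn^2)
  expect_gt(p_rayleigh, 0.001)

  # zero amplitude: epoch identical to background-only draw from same state
  tr <- simulate_assr_trial(40, 0, 2, rng_state = 11,
                            background = list(aperiodic_density = 1e-3,
                                              exponent = 0))
  bg <- simulate_background(2, 2000, 0, NULL, 11, aperiodic_density = 1e-3)
  expect_identical(tr$epoch, bg)

  # window must cover the train
  expect_error(simulate_assr_trial(40, 1, 1, epoch_window_s = c(-1, 0.5)),
               "cover")
  expect_error(simulate_assr_trial(40, 1, -1), "kappa")
})

test_that("expected_plf equals the Bessel ratio (numerical oracle)", {
  # independent oracle: direct quadrature of the von Mises resultant
  oracle <- function(k) {
    num <- integrate(function(th) cos(th) * exp(k * cos(th)), -pi, pi)$value
    den <- integrate(function(th) exp(k * cos(th)), -pi, pi)$value
    num / den
  }
  for (k in c(0.5, 1, 2, 4, 8)) {
    expect_equal(expected_plf(k), oracle(k), tolerance = 1e-8)
  }
  expect_identical(expected_plf(0), 0)
  expect_gte(expected_plf(1e6), 0.999)
  expect_equal(expected_plf(2), 0.6978, tolerance = 1e-4)
  expect_error(expected_plf(-1), "kappa")
})

test_that("cohort generation: session counts, determinism, degenerate variance", {
  spec <- cohort_spec(n_males = 2, n_females = 2, n_days = 1,
                      stim_rates_hz = 40, n_trials = 4,
                      conditions = "baseline", seed = 5)
  ch <- simulate_cohort(spec)
  expect_length(ch$sessions, 4)
  expect_s3_class(ch$sessions[[1]], "epochs_set")
  expect_equal(dim(ch$sessions[[1]]$data), c(4, 4000))

  # bit-identical on re-simulation
  ch2 <- simulate_cohort(spec)
  expect_identical(ch$sessions[[3]]$data, ch2$sessions[[3]]$data)
  expect_identical(ch$ground_truth, ch2$ground_truth)

  # no within-animal variance: session parameters identical across days
  spec0 <- cohort_spec(n_males = 2, n_females = 1, n_days = 3,
                       stim_rates_hz = 40, n_trials = 2,
                       conditions = "baseline",
                       sigma_day = 0, sigma_resid = 0, seed = 2)
  gt <- simulate_cohort(spec0)$ground_truth$sessions
  for (an in c("M01", "M02", "F01")) {
    kaps <- vapply(gt[grep(an, names(gt))], function(g) g$kappa, 0)
    expect_equal(max(kaps) - min(kaps), 0)
    expect_equal(unname(expected_plf(kaps[1])), unname(expected_plf(kaps[3])),
                 tolerance = 1e-3)
  }

  expect_error(cohort_spec(stim_rates_hz = 30), "subset")
  expect_error(cohort_spec(conditions = character(0)), "conditions")
  expect_error(cohort_spec(n_males = 0), "counts")
  expect_error(cohort_spec(sigma_animal = -0.1), "sigma")
})

test_that("ketamine multipliers scale ground-truth densities exactly", {
  spec <- cohort_spec(n_males = 1, n_females = 1, n_days = 1,
                      stim_rates_hz = 40, drug_rates_hz = 40, n_trials = 2,
                      conditions = c("SAL", "KET"), seed = 3)
  gt <- simulate_cohort(spec)$ground_truth$sessions
  for (an in c("M01", "F01")) {
    sal <- gt[[grep(paste0(an, ".*SAL"), names(gt))]]
    ket <- gt[[grep(paste0(an, ".*KET"), names(gt))]]
    ratio <- unlist(ket$band_density_uv2) / unlist(sal$band_density_uv2)
    # session random effects differ, but the systematic part is the multiplier
    expected <- spec$ket_band_multiplier *
      exp(ket$resid_effect + ket$day_effect - sal$resid_effect - sal$day_effect)
    expect_equal(unname(ratio), unname(expected[names(ket$band_density_uv2)]),
                 tolerance = 1e-10)
    expect_lt(ket$kappa / exp(ket$resid_effect + ket$day_effect),
              sal$kappa / exp(sal$resid_effect + sal$day_effect))
  }
})
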