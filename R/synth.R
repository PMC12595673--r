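# Synthetic ECoG cohort generator. Produces stimulus-locked epochs whose
# spontaneous spectra, entrainment strength, trial-phase concentration, and
# animal/day/session variance structure are all known, so every downstream
# estimator can be validated by parameter recovery.
#
# Generative model, per session:
#   background: spectrally shaped Gaussian-like noise with one-sided density
#     S(f) = c / f^chi  +  sum_b  d_b exp(-(f - f_b)^2 / (2 w_b^2))
#     realized by assigning sqrt(S(f) fs N / 2) amplitudes with iid uniform
#     phases and inverse transforming (so each epoch's variance equals the
#     integral of its target density exactly);
#   entrainment: inside [0, train_dur) s, a sinusoid at the train rate with a
#     von Mises(0, kappa) per-trial phase plus an optional 2f harmonic at
#     `harmonic_amp_frac` of the amplitude, under 10 ms raised-cosine ramps;
#   hierarchy: animal, day and session random effects on the log scale act as
#     multipliers exp(sigma_a z_a + sigma_d z_d + sigma_r z_s) on band
#     densities, entrainment amplitude and kappa, making the intended ICC of
#     any log-scale session metric sigma_a^2 / (sigma_a^2+sigma_d^2+sigma_r^2);
#   ketamine: per-band density multipliers (< 1 below 30 Hz, > 1 in gamma) and
#     reductions of 40 Hz kappa and amplitude, as phenomenological labels.

#' Simulate spectrally shaped background activity
#'
#' Zero-mean signal whose expected one-sided spectral density is
#' `aperiodic_density / f^exponent` (clamped below 1 Hz) plus Gaussian bumps
#' at requested bands, generated by spectral shaping of random-phase noise:
#' the amplitude envelope is the square root of the target density, so the
#' sample variance equals the integral of the density over the spectrum.
#'
#' @param duration_s Signal duration in seconds.
#' @param fs_hz Sampling rate in Hz.
#' @param exponent Aperiodic exponent chi of the 1/f^chi background
#'   (`>= 0`).
#' @param band_components `data.frame` (or NULL) with columns `center_hz`,
#'   `bandwidth_hz` (Gaussian SD in Hz) and `density_uv2` (peak density,
#'   uV^2/Hz).
#' @param rng_state Integer seed for this draw, or `NULL` to consume the
#'   current RNG stream.
#' @param aperiodic_density Aperiodic density at 1 Hz (uV^2/Hz); with
#'   `exponent = 0` this is the flat density, so a unit-variance white
#'   background at `fs_hz = 2000` corresponds to `1 / 1000 = 1e-3`... i.e.
#'   `sigma^2 / (fs/2)`.
#' @return Numeric vector of `duration_s * fs_hz` samples (uV).
#' @export
simulate_background <- function(duration_s, fs_hz, exponent = 1,
                                band_components = NULL, rng_state = NULL,
                                aperiodic_density = 0) {
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (exponent < 0) stop("exponent must be >= 0")
  if (!is.finite(aperiodic_density) || aperiodic_density < 0) {
    stop("aperiodic_density must be finite and >= 0")
  }
  n <- round(duration_s * fs_hz)
  S <- .target_density(n, fs_hz, exponent, aperiodic_density, band_components)
  with_seed(rng_state, {
    phases <- stats::runif(length(S), 0, 2 * pi)
    .shaped_noise(S, n, fs_hz, matrix(phases, ncol = 1))[, 1]
  })
}

# One-sided target density at the positive FFT bins 1..floor((n-1)/2).
.target_density <- function(n, fs_hz, exponent, aperiodic_density,
                            band_components) {
  h <- floor((n - 1) / 2)
  f <- (1:h) * fs_hz / n
  S <- aperiodic_density / pmax(f, 1)^exponent
  if (!is.null(band_components) && nrow(band_components) > 0) {
    dens <- band_components$density_uv2
    if (any(!is.finite(dens)) || any(dens < 0)) {
      stop("band component densities must be finite and >= 0")
    }
    for (i in seq_len(nrow(band_components))) {
      S <- S + dens[i] *
        exp(-(f - band_components$center_hz[i])^2 /
              (2 * band_components$bandwidth_hz[i]^2))
    }
  }
  S
}

# Inverse-transform shaped noise: one column per trial, given per-bin phases.
.shaped_noise <- function(S, n, fs_hz, phases) {
  h <- nrow(phases)
  stopifnot(length(S) == h)
  amp <- sqrt(S * fs_hz * n / 2)
  ntr <- ncol(phases)
  X <- matrix(0 + 0i, n, ntr)
  X[2:(h + 1), ] <- amp * exp(1i * phases)
  X[n:(n - h + 1), ] <- Conj(X[2:(h + 1), ])
  Re(stats::mvfft(X, inverse = TRUE)) / n
}

#' Simulate one stimulus-locked ASSR trial
#'
#' Background activity (via [simulate_background()]) plus, inside
#' `[0, train_dur_s)`, an entrained sinusoid `amp sin(2 pi f t + phi)` with a
#' von Mises(0, kappa) trial phase and an optional first harmonic
#' `harmonic_amp_frac * amp * sin(2 pi 2f t + 2 phi)`, under 10 ms
#' raised-cosine on/off ramps.
#'
#' @param stim_rate_hz Train rate in Hz.
#' @param amp_uv Entrained amplitude (uV, `>= 0`).
#' @param kappa von Mises phase concentration (`>= 0`; 0 = uniform phases).
#' @param harmonic_amp_frac Harmonic amplitude as a fraction of `amp_uv`.
#' @param epoch_window_s Epoch window relative to train onset; must cover
#'   `[0, train_dur_s]`.
#' @param fs_hz Sampling rate.
#' @param train_dur_s Train duration (default 1 s).
#' @param rng_state Seed or `NULL`.
#' @param background Named list of extra arguments for
#'   [simulate_background()] (`exponent`, `aperiodic_density`,
#'   `band_components`).
#' @return List with `epoch` (uV vector) and `trial_phase` (radians).
#' @export
simulate_assr_trial <- function(stim_rate_hz, amp_uv, kappa,
                                harmonic_amp_frac = 0,
                                epoch_window_s = c(-1, 1), fs_hz = 2000,
                                train_dur_s = 1, rng_state = NULL,
                                background = list()) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (amp_uv < 0) stop("amp_uv must be >= 0")
  if (epoch_window_s[1] > 0 || epoch_window_s[2] < train_dur_s) {
    stop("epoch window must cover the full stimulus train [0, train_dur_s]")
  }
  dur <- epoch_window_s[2] - epoch_window_s[1]
  with_seed(rng_state, {
    bg <- do.call(simulate_background,
                  c(list(duration_s = dur, fs_hz = fs_hz, rng_state = NULL),
                    background))
    phi <- rvonmises(1, 0, kappa)
    n <- length(bg)
    t <- epoch_window_s[1] + (0:(n - 1)) / fs_hz
    in_train <- which(t >= 0 & t < train_dur_s)
    if (amp_uv > 0 && length(in_train)) {
      tt <- t[in_train]
      env <- ramp_envelope(length(in_train), fs_hz)
      stim <- amp_uv * sin(2 * pi * stim_rate_hz * tt + phi) +
        harmonic_amp_frac * amp_uv * sin(2 * pi * 2 * stim_rate_hz * tt + 2 * phi)
      bg[in_train] <- bg[in_train] + env * stim
    }
    list(epoch = bg, trial_phase = phi)
  })
}

#' Specification of a synthetic cohort
#'
#' Full generative description of a synthetic experiment. Defaults follow the
#' emulated study design: 35 male and 33 female animals, five consecutive
#' baseline days, trains at 10/20/40/80 Hz of 1 s with 1 s inter-stimulus
#' intervals, 100 trials per session at 2 kHz sampling, saline and ketamine
#' sessions (40 Hz paradigm) after the baseline period. Band density targets
#' are set near the observed saline-condition band powers; ketamine effects
#' are phenomenological multipliers (< 1 below 30 Hz, > 1 in gamma, reduced
#' 40 Hz amplitude and phase concentration); the 40 Hz entrainment parameters
#' are higher in males, all other parameters sex-equal.
#'
#' @param n_males,n_females Animals per sex (`>= 1`).
#' @param n_days Baseline recording days (default 5).
#' @param stim_rates_hz Subset of `c(10, 20, 40, 80)`.
#' @param n_trials Trials per session (default 100).
#' @param fs_hz Sampling rate (default 2000; must exceed twice the maximum
#'   analysis frequency).
#' @param train_dur_s,isi_s Train duration and inter-stimulus interval (s).
#' @param epoch_window_s Epoch window relative to onset.
#' @param aperiodic_exponent Exponent chi of the 1/f^chi background.
#' @param aperiodic_density Aperiodic density at 1 Hz (uV^2/Hz).
#' @param band_power_uv2 Named per-band target peak densities (uV^2/Hz).
#' @param ket_band_multiplier Named per-band ketamine density multipliers.
#' @param entrain_amp_uv List with elements `M` and `F`: named per-rate
#'   entrained amplitudes (uV).
#' @param kappa List with elements `M` and `F`: named per-rate von Mises
#'   concentrations.
#' @param ket_amp_multiplier,ket_kappa_multiplier Ketamine multipliers on the
#'   drug-paradigm entrainment amplitude and kappa.
#' @param harmonic_amp_frac Harmonic (2f) amplitude fraction.
#' @param sigma_animal,sigma_day,sigma_resid SDs of the animal, day and
#'   session random effects on the log scale.
#' @param mains_density_uv2 Residual (post-notch) 50 Hz line-noise peak
#'   density (uV^2/Hz); 0 disables.
#' @param conditions Subset of `c("baseline", "SAL", "KET")`.
#' @param drug_rates_hz Stimulation rates used in the drug sessions
#'   (default 40).
#' @param seed Integer master seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_males = 35, n_females = 33, n_days = 5,
                        stim_rates_hz = c(10, 20, 40, 80), n_trials = 100,
                        fs_hz = 2000, train_dur_s = 1, isi_s = 1,
                        epoch_window_s = c(-1, 1),
                        aperiodic_exponent = 1, aperiodic_density = 1,
                        band_power_uv2 = c(delta = 54, theta = 54, alpha = 17,
                                           beta = 2.8, low_gamma = 0.19,
                                           high_gamma = 0.075),
                        ket_band_multiplier = c(delta = 0.73, theta = 0.70,
                                                alpha = 0.62, beta = 0.72,
                                                low_gamma = 1.57,
                                                high_gamma = 1.87),
                        entrain_amp_uv = list(
                          M = c(`10` = 1.0, `20` = 1.5, `40` = 2.0, `80` = 1.2),
                          F = c(`10` = 1.0, `20` = 1.5, `40` = 1.6, `80` = 1.2)),
                        kappa = list(
                          M = c(`10` = 0.65, `20` = 1.2, `40` = 1.6, `80` = 0.7),
                          F = c(`10` = 0.65, `20` = 1.2, `40` = 1.2, `80` = 0.7)),
                        ket_amp_multiplier = 0.75,
                        ket_kappa_multiplier = 0.8,
                        harmonic_amp_frac = 0.3,
                        sigma_animal = 0.50, sigma_day = 0.08,
                        sigma_resid = 0.15,
                        mains_density_uv2 = 5,
                        conditions = c("baseline", "SAL", "KET"),
                        drug_rates_hz = 40,
                        seed = 1) {
  spec <- structure(as.list(environment()), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' @param spec A `cohort_spec`.
#' @return `spec`, invisibly; errors describe the first violated constraint.
#' @export
validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_males < 1 || n_females < 1 || n_days < 1 || n_trials < 1) {
      stop("all counts (animals, days, trials) must be >= 1")
    }
    if (!all(stim_rates_hz %in% c(10, 20, 40, 80)) || !length(stim_rates_hz)) {
      stop("stim_rates_hz must be a non-empty subset of {10, 20, 40, 80}")
    }
    if (!all(drug_rates_hz %in% c(10, 20, 40, 80))) {
      stop("drug_rates_hz must be a subset of {10, 20, 40, 80}")
    }
    if (fs_hz < 400) stop("fs_hz must exceed twice the maximum analysis frequency (>= 400)")
    if (!length(conditions) || !all(conditions %in% c("baseline", "SAL", "KET"))) {
      stop("conditions must be a non-empty subset of {baseline, SAL, KET}")
    }
    if (any(unlist(kappa) < 0)) stop("kappa values must be >= 0")
    if (any(unlist(entrain_amp_uv) < 0)) stop("entrainment amplitudes must be >= 0")
    if (sigma_animal < 0 || sigma_day < 0 || sigma_resid < 0) {
      stop("sigma_* must be >= 0")
    }
    if (any(band_power_uv2 < 0) || any(!is.finite(band_power_uv2))) {
      stop("band density targets must be finite and >= 0")
    }
  })
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %dM + %dF animals, %d day(s), rates {%s} Hz, %d trials @ %g Hz, conditions {%s}, seed %d\n",
              x$n_males, x$n_females, x$n_days,
              paste(x$stim_rates_hz, collapse = ","), x$n_trials, x$fs_hz,
              paste(x$conditions, collapse = ","), x$seed))
  invisible(x)
}

#' Simulate a full synthetic cohort
#'
#' Generates one [epochs_set()] per animal x day x stimulation-rate x
#' condition, together with the full ground truth (realized random effects,
#' per-session kappa, amplitude and band densities, and per-trial phases).
#' Baseline sessions span days `1..n_days` at all `stim_rates_hz`; saline and
#' ketamine sessions (when requested) are recorded after the baseline period
#' (day indices `n_days + 1` and `n_days + 2`) at `drug_rates_hz`, with the
#' administration order counterbalanced across animals so the shared
#' day effect cancels out of group-mean drug deltas. The whole
#' dataset is deterministic given the spec's seed; each session has its own
#' RNG stream keyed by (seed, animal, day, rate, condition).
#'
#' @param spec A `cohort_spec`.
#' @return Object of class `assr_cohort`: named list `sessions` of
#'   `epochs_set`s, `ground_truth`, and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  animals <- data.frame(
    animal = c(sprintf("M%02d", seq_len(spec$n_males)),
               sprintf("F%02d", seq_len(spec$n_females))),
    sex = c(rep("M", spec$n_males), rep("F", spec$n_females)),
    stringsAsFactors = FALSE
  )
  n_an <- nrow(animals)
  drug_conds <- intersect(c("SAL", "KET"), spec$conditions)
  day_of_cond <- c(SAL = spec$n_days + 1, KET = spec$n_days + 2)
  all_days <- c(if ("baseline" %in% spec$conditions) seq_len(spec$n_days),
                unname(day_of_cond[drug_conds]))

  # hierarchy: one stream for all random effects
  eff <- with_seed(derive_seed(spec$seed, 999983), {
    list(animal = stats::rnorm(n_an, 0, spec$sigma_animal),
         day = stats::rnorm(max(all_days), 0, spec$sigma_day))
  })
  names(eff$animal) <- animals$animal

  # session plan per animal; drug order is counterbalanced across animals
  # (odd-indexed animals receive SAL first, even-indexed KET first) so the
  # shared day effect cancels out of group-mean drug deltas, as in a
  # counterbalanced administration design
  make_plan <- function(ai) {
    plan <- list()
    if ("baseline" %in% spec$conditions) {
      for (d in seq_len(spec$n_days)) for (r in spec$stim_rates_hz) {
        plan[[length(plan) + 1]] <- list(day = d, rate = r, cond = "baseline")
      }
    }
    for (cond in drug_conds) {
      d <- if (length(drug_conds) == 2 && ai %% 2 == 0) {
        unname(day_of_cond[setdiff(drug_conds, cond)])
      } else {
        unname(day_of_cond[cond])
      }
      for (r in spec$drug_rates_hz) {
        plan[[length(plan) + 1]] <- list(day = d, rate = r, cond = cond)
      }
    }
    if (!length(plan)) stop("empty session plan: no conditions or rates requested")
    plan
  }

  band_defs <- default_bands()
  sessions <- list()
  gt_sessions <- list()
  for (ai in seq_len(n_an)) {
    an <- animals$animal[ai]; sex <- animals$sex[ai]
    for (pl in make_plan(ai)) {
      rate_idx <- match(pl$rate, c(10, 20, 40, 80))
      sseed <- derive_seed(spec$seed, ai, pl$day, rate_idx, .cond_code(pl$cond))
      resid <- with_seed(derive_seed(sseed, 7), stats::rnorm(1, 0, spec$sigma_resid))
      e <- eff$animal[ai] + eff$day[pl$day] + resid
      mult <- exp(e)
      is_ket <- pl$cond == "KET"
      bn <- names(band_defs)
      dens <- spec$band_power_uv2[bn] * mult *
        (if (is_ket) spec$ket_band_multiplier[bn] else 1)
      amp <- spec$entrain_amp_uv[[sex]][[as.character(pl$rate)]] * mult *
        (if (is_ket) spec$ket_amp_multiplier else 1)
      kap <- spec$kappa[[sex]][[as.character(pl$rate)]] * mult *
        (if (is_ket) spec$ket_kappa_multiplier else 1)

      # bump SD = band width / 6 keeps each band's density under the control
      # of its own multiplier (wider bumps bleed across band edges, which
      # couples neighbouring bands' drug effects)
      bumps <- data.frame(
        center_hz = vapply(band_defs, mean, 0),
        bandwidth_hz = vapply(band_defs, function(b) diff(b) / 6, 0),
        density_uv2 = unname(dens[names(band_defs)])
      )
      if (spec$mains_density_uv2 > 0) {
        bumps <- rbind(bumps, data.frame(center_hz = 50, bandwidth_hz = 0.5,
                                         density_uv2 = spec$mains_density_uv2))
      }
      sess <- .simulate_session(spec, bumps, amp, kap, pl$rate,
                                aperiodic_density = spec$aperiodic_density * mult,
                                rng_state = sseed)
      sid <- sprintf("%s_d%d_%s_%02dHz", an, pl$day, pl$cond, pl$rate)
      meta <- list(animal_id = an, sex = sex, day = pl$day,
                   condition = pl$cond, session_id = sid)
      sessions[[sid]] <- epochs_set(sess$data, spec$fs_hz,
                                    spec$epoch_window_s[1], pl$rate, meta)
      gt_sessions[[sid]] <- list(
        animal_id = an, sex = sex, day = pl$day, condition = pl$cond,
        stim_rate_hz = pl$rate,
        animal_effect = unname(eff$animal[ai]), day_effect = eff$day[pl$day],
        resid_effect = resid,
        kappa = unname(kap), amp_uv = unname(amp),
        band_density_uv2 = as.list(dens),
        trial_phases = sess$phases
      )
    }
  }
  structure(
    list(sessions = sessions,
         ground_truth = list(seed = spec$seed,
                             sigma = c(animal = spec$sigma_animal,
                                       day = spec$sigma_day,
                                       resid = spec$sigma_resid),
                             animal_effects = as.list(eff$animal),
                             day_effects = eff$day,
                             sessions = gt_sessions),
         spec = spec),
    class = "assr_cohort"
  )
}

# Vectorized one-session simulator: all trials at once.
.simulate_session <- function(spec, bumps, amp, kap, rate, aperiodic_density,
                              rng_state) {
  w <- spec$epoch_window_s
  n <- round((w[2] - w[1]) * spec$fs_hz)
  ntr <- spec$n_trials
  S <- .target_density(n, spec$fs_hz, spec$aperiodic_exponent,
                       aperiodic_density, bumps)
  with_seed(rng_state, {
    phases_bg <- matrix(stats::runif(length(S) * ntr, 0, 2 * pi), ncol = ntr)
    x <- .shaped_noise(S, n, spec$fs_hz, phases_bg)   # samples x trials
    phi <- rvonmises(ntr, 0, kap)
    t <- w[1] + (0:(n - 1)) / spec$fs_hz
    in_train <- which(t >= 0 & t < spec$train_dur_s)
    if (amp > 0 && length(in_train)) {
      tt <- t[in_train]
      env <- ramp_envelope(length(in_train), spec$fs_hz)
      s1 <- sin(2 * pi * rate * tt); c1 <- cos(2 * pi * rate * tt)
      s2 <- sin(4 * pi * rate * tt); c2 <- cos(4 * pi * rate * tt)
      stim <- amp * (outer(s1, cos(phi)) + outer(c1, sin(phi))) +
        spec$harmonic_amp_frac * amp *
          (outer(s2, cos(2 * phi)) + outer(c2, sin(2 * phi)))
      x[in_train, ] <- x[in_train, ] + env * stim
    }
    list(data = t(x), phases = phi)
  })
}

#' @export
print.assr_cohort <- function(x, ...) {
  cat(sprintf("<assr_cohort> %d session(s) from %s; seed %d\n",
              length(x$sessions), format(x$spec), x$spec$seed))
  invisible(x)
}

#' @export
format.cohort_spec <- function(x, ...) {
  sprintf("%dM+%dF x %d day(s) x {%s} Hz x {%s}", x$n_males, x$n_females,
          x$n_days, paste(x$stim_rates_hz, collapse = ","),
          paste(x$conditions, collapse = ","))
}
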