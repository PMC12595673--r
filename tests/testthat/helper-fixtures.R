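# Shared fixture builders. Everything is generated in code at test time.

# Epochs of pure sinusoids with given per-trial phases, optional shaped
# background noise.
make_tone_epochs <- function(phases, amp = 1, freq = 40, fs = 2000,
                             window = c(-1, 1), noise_density = 0,
                             stim_only = TRUE, seed = NULL) {
  n <- round((window[2] - window[1]) * fs)
  t <- window[1] + (0:(n - 1)) / fs
  dat <- assrtools:::with_seed(seed, {
    t(vapply(phases, function(p) {
      x <- if (noise_density > 0) {
        simulate_background(window[2] - window[1], fs, exponent = 0,
                            aperiodic_density = noise_density)
      } else numeric(n)
      s <- amp * sin(2 * pi * freq * t + p)
      if (stim_only) s[t < 0 | t >= 1] <- 0
      x + s
    }, numeric(n)))
  })
  epochs_set(dat, fs, window[1], freq)
}

# Minimal single-bin TFR with one coefficient per trial (unit phasors), for
# estimator-level PLF properties.
make_phase_tfr <- function(phases, freq = 40, time = 0.5) {
  coef <- array(exp(1i * phases), dim = c(length(phases), 1, 1))
  structure(
    list(coef = coef, freqs_hz = freq, times_s = time,
         edge = matrix(FALSE, 1, 1),
         params = list(n_cycles = 7, dt_out_s = 0.005, fs_hz = 2000),
         meta = list(), stim_rate_hz = freq),
    class = "assr_tfr"
  )
}

# Independent ICC mean-square route through stats::aov (the implementation
# computes sums of squares by hand).
oracle_icc_ms <- function(m) {
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                  sess = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(y ~ subj + sess, data = d))[[1]]
  list(msr = tab["subj", "Mean Sq"], msc = tab["sess", "Mean Sq"],
       mse = tab["Residuals", "Mean Sq"])
}

# Run a python snippet and return its stdout lines.
run_python <- function(code) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  on.exit(unlink(f))
  system2("python", f, stdout = TRUE)
}

expect_python_available <- function() {
  ok <- nzchar(Sys.which("python"))
  expect_true(ok, label = "python interpreter available")
  ok
}
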