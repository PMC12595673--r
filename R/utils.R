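# Internal helpers: deterministic RNG plumbing and small numerics.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to `seed`, runs `code`, and restores the caller's RNG state,
#' so seeded simulations never perturb the global stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Mix an integer seed with a sequence of non-negative integer keys into a new
# seed < 2^31. Multiplicative hashing in double precision: 69069 * 2^31 < 2^53,
# so the arithmetic is exact.
derive_seed <- function(seed, ...) {
  keys <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in keys) {
    s <- (s * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

# Stable integer codes for session keys.
.cond_code <- function(condition) {
  match(condition, c("baseline", "SAL", "KET"))
}

#' Draw from a von Mises distribution
#'
#' Best–Fisher rejection sampler. `kappa = 0` reduces to the uniform
#' distribution on (-pi, pi]. Used for per-trial ASSR phases.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration, `kappa >= 0`.
#' @return Numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot(n >= 0, is.finite(mu))
  if (!is.finite(kappa) || kappa < 0) stop("kappa must be finite and >= 0")
  if (n == 0) return(numeric(0))
  if (kappa == 0) {
    th <- stats::runif(n, -pi, pi)
    return(wrap_angle(th + mu))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(max(-1, min(1, f)))
      i <- i + 1L
    }
  }
  wrap_angle(out + mu)
}

# Wrap angles into (-pi, pi].
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Expected phase-locking factor under a von Mises phase model
#'
#' Mean resultant length of the von Mises distribution,
#' \eqn{A_1(\kappa) = I_1(\kappa)/I_0(\kappa)}: the large-trial limit of the
#' phase-locking factor when per-trial phases have concentration `kappa`.
#' Uses exponentially scaled Bessel functions so large `kappa` is stable.
#'
#' @param kappa Concentration parameter(s), `>= 0`.
#' @return Value(s) in `[0, 1)`.
#' @examples
#' expected_plf(c(0, 2, 8))
#' @export
expected_plf <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa < 0)) {
    stop("kappa must be finite and >= 0")
  }
  out <- numeric(length(kappa))
  small <- kappa > 0 & kappa <= 1e4
  large <- kappa > 1e4
  out[small] <- besselI(kappa[small], 1, expon.scaled = TRUE) /
    besselI(kappa[small], 0, expon.scaled = TRUE)
  # asymptotic expansion beyond the range of R's Bessel functions
  out[large] <- 1 - 1 / (2 * kappa[large]) - 1 / (8 * kappa[large]^2)
  out
}

# Next power of two >= n.
next_pow2 <- function(n) 2^ceiling(log2(max(2, n)))

# Raised-cosine on/off ramp envelope for a stimulus segment of n samples.
ramp_envelope <- function(n, fs, ramp_s = 0.010) {
  env <- rep(1, n)
  nr <- min(n %/% 2, round(ramp_s * fs))
  if (nr > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    env[seq_len(nr)] <- up
    env[n - nr + seq_len(nr)] <- rev(up)
  }
  env
}
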