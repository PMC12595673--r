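# Normality-routed group comparisons and within-animal drug-effect deltas.
#
# The decision tree mirrors standard pharmaco-EEG practice: Shapiro-Wilk
# normality at alpha_norm decides between the parametric test (paired or
# unpaired Student t) and its rank-based counterpart (Wilcoxon matched-pairs
# or Mann-Whitney U). Paired routing tests normality of the differences. All
# tests are two-sided; p-values are reported raw (no multiplicity
# correction by default).

#' Normality-routed two-sample comparison
#'
#' @param a,b Numeric samples (`n >= 3` each; paired comparisons require
#'   equal, subject-aligned lengths).
#' @param paired Paired design?
#' @param alpha_norm Shapiro-Wilk alpha for the routing decision
#'   (default 0.05).
#' @param force `"auto"` (route by normality), `"parametric"` or
#'   `"nonparametric"` to override the routing.
#' @param labels Group labels used in the reported effect direction.
#' @return Object of class `assr_comparison`: `test_name`, `statistic`,
#'   `p_value`, `n`, `effect_direction`, `normality_p`, routing metadata.
#' @details Exact rank-test p-values are used when feasible: Mann-Whitney for
#'   combined n <= 20 without ties, Wilcoxon signed-rank for n <= 25 nonzero
#'   differences without ties (zero differences dropped); otherwise the
#'   normal approximation with tie correction and continuity correction.
#'   Unpaired t is the classical equal-variance Student test.
#' @export
route_test <- function(a, b, paired = FALSE, alpha_norm = 0.05,
                       force = c("auto", "parametric", "nonparametric"),
                       labels = c("a", "b")) {
  force <- match.arg(force)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3) stop("need at least 3 observations per sample")
  if (paired && length(a) != length(b)) stop("paired samples must have equal length")

  norm_p <- c(NA_real_, NA_real_)
  if (paired) {
    d <- a - b
    if (all(d == 0)) stop("degenerate paired comparison: all differences are zero")
    if (stats::sd(d) <= 1e-10 * max(abs(d))) {
      stop("degenerate paired comparison: zero-variance differences")
    }
    if (force == "auto") norm_p <- c(stats::shapiro.test(d)$p.value, NA_real_)
    use_param <- switch(force,
                        auto = norm_p[1] >= alpha_norm,
                        parametric = TRUE, nonparametric = FALSE)
    if (use_param) {
      ht <- stats::t.test(a, b, paired = TRUE)
      test_name <- "paired t"
    } else {
      nz <- d[d != 0]
      exact <- length(nz) <= 25 && !anyDuplicated(abs(nz))
      ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                                exact = exact, correct = TRUE))
      test_name <- "Wilcoxon matched-pairs"
    }
    dirn <- mean(d)
  } else {
    sd_a <- stats::sd(a); sd_b <- stats::sd(b)
    if (force == "auto") {
      if (sd_a == 0 || sd_b == 0) stop("degenerate sample: zero variance")
      norm_p <- c(stats::shapiro.test(a)$p.value, stats::shapiro.test(b)$p.value)
    }
    use_param <- switch(force,
                        auto = all(norm_p >= alpha_norm),
                        parametric = TRUE, nonparametric = FALSE)
    if (use_param) {
      ht <- stats::t.test(a, b, var.equal = TRUE)
      test_name <- "unpaired t"
    } else {
      exact <- (length(a) + length(b)) <= 20 && !anyDuplicated(c(a, b))
      ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                                correct = TRUE))
      test_name <- "Mann-Whitney U"
    }
    dirn <- mean(a) - mean(b)
  }
  direction <- if (dirn > 0) {
    paste(labels[1], ">", labels[2])
  } else if (dirn < 0) {
    paste(labels[1], "<", labels[2])
  } else "equal"
  structure(
    list(test_name = test_name,
         statistic = unname(ht$statistic),
         p_value = ht$p.value,
         n = c(length(a), length(b)),
         effect_direction = direction,
         normality_p = norm_p,
         paired = paired, alpha_norm = alpha_norm, force = force,
         labels = labels),
    class = "assr_comparison"
  )
}

#' @export
print.assr_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, P = %.4g (n = %s; %s)\n",
              x$test_name, x$statistic, x$p_value,
              paste(x$n, collapse = "/"), x$effect_direction))
  invisible(x)
}

#' Within-animal drug-effect deltas
#'
#' Per-animal differences `metric[KET] - metric[SAL]` (or any ordered pair of
#' condition labels); negative deltas mean a reduction under the first
#' condition.
#'
#' @param data Long `data.frame` with one value per animal x condition.
#' @param value_col Metric column name.
#' @param conditions Length-2 character vector `(minuend, subtrahend)`;
#'   default `c("KET", "SAL")`.
#' @param subject_col,condition_col Column names.
#' @return `data.frame` with columns `animal`, `delta`, `metric`.
#' @export
delta_effect <- function(data, value_col, conditions = c("KET", "SAL"),
                         subject_col = "animal", condition_col = "condition") {
  stopifnot(length(conditions) == 2,
            all(c(value_col, subject_col, condition_col) %in% names(data)))
  d <- data[data[[condition_col]] %in% conditions, ]
  animals <- unique(d[[subject_col]])
  pick <- function(an, cond) {
    v <- d[[value_col]][d[[subject_col]] == an & d[[condition_col]] == cond]
    if (length(v) == 0) return(NA_real_)
    mean(v)
  }
  v1 <- vapply(animals, pick, 0, cond = conditions[1])
  v2 <- vapply(animals, pick, 0, cond = conditions[2])
  missing <- animals[is.na(v1) | is.na(v2)]
  if (length(missing)) {
    stop("missing condition value(s) for animal(s): ",
         paste(missing, collapse = ", "))
  }
  data.frame(animal = animals, delta = v1 - v2, metric = value_col,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sex comparison of a session-level metric
#'
#' Averages the metric within animal across days (pooled presentation of a
#' multi-day baseline), then runs the unpaired normality-routed comparison of
#' males vs females.
#'
#' @param data Long `data.frame` with columns for animal, sex, day and the
#'   metric; optionally filtered by `rate`.
#' @param value_col Metric column name.
#' @param rate Optional stimulation rate filter (needs a `rate` column).
#' @param alpha_norm Routing alpha.
#' @param sex_col,subject_col Column names.
#' @return An `assr_comparison` with labels `M`/`F`.
#' @export
compare_sexes <- function(data, value_col, rate = NULL, alpha_norm = 0.05,
                          sex_col = "sex", subject_col = "animal") {
  stopifnot(all(c(value_col, sex_col, subject_col) %in% names(data)))
  if (!is.null(rate)) {
    stopifnot("rate" %in% names(data))
    data <- data[!is.na(data$rate) & data$rate == rate, ]
  }
  agg <- stats::aggregate(data[[value_col]],
                          by = list(animal = data[[subject_col]],
                                    sex = data[[sex_col]]),
                          FUN = mean)
  males <- agg$x[agg$sex == "M"]
  females <- agg$x[agg$sex == "F"]
  if (length(males) < 3 || length(females) < 3) {
    stop("need at least 3 animals per sex")
  }
  route_test(males, females, paired = FALSE, alpha_norm = alpha_norm,
             labels = c("M", "F"))
}
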