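# Test-retest reliability: two-way mixed-effects, absolute-agreement,
# single-measurement intraclass correlation ICC(A,1) with F statistic and
# McGraw-Wong 95% confidence interval.

#' ICC(A,1): single-measure absolute-agreement intraclass correlation
#'
#' From the two-way ANOVA decomposition of an n subjects x k sessions matrix
#' (rows = subjects, columns = sessions) with mean squares MSR (rows),
#' MSC (columns) and MSE (residual):
#' \deqn{ICC(A,1) = \frac{MSR - MSE}{MSR + (k-1) MSE + \frac{k}{n}(MSC - MSE)}}
#' The F statistic is `MSR/MSE` with df `(n-1, (n-1)(k-1))`, and the
#' confidence interval follows the McGraw-Wong absolute-agreement
#' construction with Satterthwaite denominator degrees of freedom.
#'
#' @param m Numeric matrix, subjects x sessions, complete (no missing cells),
#'   `n >= 2`, `k >= 2`.
#' @param alpha Confidence level is `1 - alpha` (default 0.05).
#' @return Object of class `icc_a1`: `icc`, `f_value`, `df`, `ci95`,
#'   `category` (see [classify_icc()]), mean squares, `n`, `k`.
#' @references McGraw & Wong (1996) Psychological Methods 1:30-46.
#' @export
icc_a1 <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("ratings matrix must be complete (no missing cells)")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 sessions")
  g <- mean(m)
  if (sum((m - g)^2) == 0) stop("degenerate input: ratings matrix is constant")
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  ssr <- k * sum((rm_ - g)^2)
  ssc <- n * sum((cm_ - g)^2)
  sst <- sum((m - g)^2)
  sse <- max(0, sst - ssr - ssc)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  fv <- if (mse > 0) msr / mse else Inf
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  if (abs(1 - icc) < 1e-12) {
    ci <- c(1, 1)
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    num <- (a * msc + b * mse)^2
    den <- (a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1))
    v <- if (den > 0) num / den else k - 1
    fl <- suppressWarnings(stats::qf(1 - alpha / 2, df1, v))
    fu <- suppressWarnings(stats::qf(1 - alpha / 2, v, df1))
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(lower, upper)
  }
  structure(
    list(icc = icc, f_value = fv, df = c(df1, df2), ci95 = ci,
         category = classify_icc(min(icc, 1)),
         ms = list(msr = msr, msc = msc, mse = mse),
         n = n, k = k, alpha = alpha),
    class = "icc_a1"
  )
}

#' @export
print.icc_a1 <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f [%s], %d%% CI %.3f-%.3f, F(%d, %d) = %.4g (n = %d, k = %d)\n",
              x$icc, x$category, round(100 * (1 - x$alpha)), x$ci95[1], x$ci95[2],
              x$df[1], x$df[2], x$f_value, x$n, x$k))
  invisible(x)
}

#' Categorical interpretation of an ICC value
#'
#' Reliability bands: poor below 0.5, moderate in `[0.5, 0.75)`, good in
#' `[0.75, 0.90)`, excellent at and above 0.90. Interval joins are assigned
#' upward (0.75 is good, 0.90 is excellent); negative estimates are poor.
#'
#' @param value ICC estimate(s), `<= 1`.
#' @return Character vector of categories.
#' @export
classify_icc <- function(value) {
  if (any(!is.finite(value))) stop("ICC value must be finite")
  if (any(value > 1 + 1e-9)) stop("ICC value cannot exceed 1")
  cut_pts <- c(-Inf, 0.5, 0.75, 0.90, Inf)
  labs <- c("poor", "moderate", "good", "excellent")
  as.character(cut(value, cut_pts, labs, right = FALSE))
}

#' Per-group ICC table for a session-level metric
#'
#' Builds one complete subjects x sessions matrix per group from a long table
#' of per-animal, per-day metric values and returns one ICC(A,1) row per
#' group (the layout used for reporting reliability per sex).
#'
#' @param data Long `data.frame`.
#' @param value_col Name of the metric column.
#' @param subject_col,session_col,group_col Column names for animal, day and
#'   grouping factor.
#' @param strict If `TRUE` (default), an incomplete animal x day series is an
#'   error naming the missing cells; if `FALSE`, incomplete subjects are
#'   dropped with a warning.
#' @param log10_transform Apply `log10` to the values first (power metrics
#'   are right-skewed; the default analyses raw values).
#' @param alpha Passed to [icc_a1()].
#' @return `data.frame` with columns `metric`, `group`, `n`, `k`, `F`, `df1`,
#'   `df2`, `ICC`, `CI_low`, `CI_high`, `category`.
#' @export
icc_table <- function(data, value_col, subject_col = "animal",
                      session_col = "day", group_col = "sex",
                      strict = TRUE, log10_transform = FALSE, alpha = 0.05) {
  stopifnot(all(c(value_col, subject_col, session_col, group_col) %in% names(data)))
  out <- list()
  for (grp in unique(data[[group_col]])) {
    d <- data[data[[group_col]] == grp, ]
    subs <- unique(d[[subject_col]])
    sess <- sort(unique(d[[session_col]]))
    m <- matrix(NA_real_, length(subs), length(sess),
                dimnames = list(subs, sess))
    for (i in seq_len(nrow(d))) {
      m[as.character(d[[subject_col]][i]), as.character(d[[session_col]][i])] <-
        d[[value_col]][i]
    }
    if (any(is.na(m))) {
      miss <- which(is.na(m), arr.ind = TRUE)
      desc <- paste(rownames(m)[miss[, 1]], "day", colnames(m)[miss[, 2]],
                    sep = " ", collapse = "; ")
      if (strict) {
        stop("incomplete series for group ", grp, ": ", desc)
      }
      warning("dropping incomplete subject(s) in group ", grp, ": ", desc)
      m <- m[stats::complete.cases(m), , drop = FALSE]
    }
    if (log10_transform) m <- log10(m)
    r <- icc_a1(m, alpha = alpha)
    out[[length(out) + 1]] <- data.frame(
      metric = value_col, group = grp, n = r$n, k = r$k,
      F = r$f_value, df1 = r$df[1], df2 = r$df[2],
      ICC = r$icc, CI_low = r$ci95[1], CI_high = r$ci95[2],
      category = r$category, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
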