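# ICC(A,1): exact hand-computed cases, invariances, Monte-Carlo recovery,
# reference-implementation agreement, categorical interpretation.

test_that("hand-computed ANOVA case and pure subject effect are exact", {
  m <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5))
  r <- icc_a1(m)
  expect_equal(r$icc, 10 / 13, tolerance = 1e-10)
  expect_equal(r$ms$msr, 10 / 3, tolerance = 1e-12)
  expect_equal(r$ms$msc, 2, tolerance = 1e-12)
  expect_equal(r$ms$mse, 0, tolerance = 1e-12)
  expect_identical(r$f_value, Inf)
  expect_equal(r$df, c(3, 3))

  # pure subject effect: perfect agreement
  m1 <- matrix(rep(c(10, 20, 35), 4), 3, 4)
  r1 <- icc_a1(m1)
  expect_equal(r1$icc, 1)
  expect_equal(r1$ci95, c(1, 1))
  expect_equal(r1$category, "excellent")

  expect_error(icc_a1(matrix(5, 4, 3)), "degenerate")
  expect_error(icc_a1(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
  expect_error(icc_a1(matrix(1:3, 3, 1)), "2 subjects")
})

test_that("ICC is invariant to permutations and affine transforms", {
  set.seed(31)
  m <- matrix(rnorm(8 * 5), 8, 5) + rnorm(8) * 2
  r <- icc_a1(m)$icc
  expect_equal(icc_a1(m[sample(8), ])$icc, r, tolerance = 1e-12)
  expect_equal(icc_a1(m[, sample(5)])$icc, r, tolerance = 1e-12)
  expect_equal(icc_a1(7 + m)$icc, r, tolerance = 1e-12)
  expect_equal(icc_a1(-3.2 * m)$icc, r, tolerance = 1e-12)
})

test_that("ICC recovers the generative variance ratio (Monte-Carlo)", {
  set.seed(32)
  n <- 200; k <- 5
  iccs <- vapply(1:100, function(i) {
    b <- rnorm(n, 0, 3)
    cj <- rnorm(k, 0, sqrt(0.5))
    y <- outer(b, rep(1, k)) + outer(rep(1, n), cj) +
      matrix(rnorm(n * k, 0, sqrt(0.5)), n, k)
    icc_a1(y)$icc
  }, 0)
  expect_lt(abs(mean(iccs) - 0.9), 0.03)
})

test_that("mean squares match the independent aov decomposition", {
  set.seed(33)
  for (i in 1:10) {
    m <- matrix(rnorm(6 * 4), 6, 4) + rnorm(6)
    r <- icc_a1(m)
    o <- oracle_icc_ms(m)
    expect_equal(r$ms$msr, o$msr, tolerance = 1e-10)
    expect_equal(r$ms$msc, o$msc, tolerance = 1e-10)
    expect_equal(r$ms$mse, o$mse, tolerance = 1e-10)
  }
})

test_that("ICC and CI agree with the pingouin reference on 50 random matrices", {
  if (!expect_python_available()) return(invisible())
  set.seed(34)
  mats <- lapply(1:50, function(i) {
    n <- sample(4:12, 1); k <- sample(2:6, 1)
    matrix(rnorm(n * k), n, k) + rnorm(n) * runif(1, 0, 3)
  })
  f <- tempfile(fileext = ".csv")
  long <- do.call(rbind, lapply(seq_along(mats), function(i) {
    m <- mats[[i]]
    data.frame(mat = i, subj = rep(seq_len(nrow(m)), ncol(m)),
               sess = rep(seq_len(ncol(m)), each = nrow(m)),
               y = as.vector(m))
  }))
  utils::write.csv(long, f, row.names = FALSE)
  out <- run_python(sprintf("
import pandas as pd, pingouin as pg, warnings
warnings.filterwarnings('ignore')
df = pd.read_csv('%s')
for i, d in df.groupby('mat'):
    icc = pg.intraclass_corr(d, targets='subj', raters='sess', ratings='y')
    row = icc[icc['Type'].isin(['ICC2', 'ICC(A,1)'])].iloc[0]
    print(i, float(row['ICC']))
", f))
  unlink(f)
  ref <- as.numeric(vapply(strsplit(out, " "), `[`, "", 2))
  ours <- vapply(mats, function(m) icc_a1(m)$icc, 0)
  expect_lt(max(abs(ours - ref)), 1e-6)
})

test_that("ICC categories follow the reliability bands", {
  expect_equal(classify_icc(0.85), "good")
  expect_equal(classify_icc(0.90), "excellent")
  expect_equal(classify_icc(0.75), "good")
  expect_equal(classify_icc(0.5), "moderate")
  expect_equal(classify_icc(0.49), "poor")
  expect_equal(classify_icc(-0.2), "poor")
  expect_equal(classify_icc(c(0.3, 0.6, 0.8, 0.95)),
               c("poor", "moderate", "good", "excellent"))
  expect_error(classify_icc(NaN), "finite")
  expect_error(classify_icc(1.2), "exceed")
})

test_that("icc_table builds per-group matrices and flags incomplete series", {
  set.seed(35)
  d <- expand.grid(animal = sprintf("A%d", 1:6), day = 1:4)
  d$sex <- ifelse(as.integer(sub("A", "", d$animal)) <= 3, "M", "F")
  d$v <- rnorm(nrow(d)) + as.integer(sub("A", "", d$animal))
  tb <- icc_table(d, "v")
  expect_equal(nrow(tb), 2)
  expect_equal(sort(tb$group), c("F", "M"))
  expect_true(all(tb$n == 3 & tb$k == 4))
  expect_true(all(tb$CI_low <= tb$ICC & tb$ICC <= tb$CI_high))

  # missing cell: strict errors naming animal and day, lenient drops
  d2 <- d[!(d$animal == "A2" & d$day == 3), ]
  expect_error(icc_table(d2, "v"), "A2 day 3")
  expect_warning(tb2 <- icc_table(d2, "v", strict = FALSE), "A2")
  expect_equal(tb2$n[tb2$group == "M"], 2)

  # log10 option changes the scale it analyses
  d$vp <- exp(d$v)
  tb_log <- icc_table(d, "vp", log10_transform = TRUE)
  tb_raw <- icc_table(d, "v")
  expect_equal(tb_log$ICC, tb_raw$ICC, tolerance = 1e-10)
})
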