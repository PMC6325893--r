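test_that("histogram construction enforces the type invariants", {
  h <- size_histogram(c(10, 20, 30), c(1, 2, 3), strain_id = "wt")
  expect_s3_class(h, "size_histogram")
  expect_error(size_histogram(c(10, 10, 30), c(1, 2, 3)), "increasing")
  expect_error(size_histogram(c(-5, 10), c(1, 1)), "> 0")
  expect_error(size_histogram(c(10, 20), c(1, -1)), "nonnegative")
  expect_error(size_histogram(c(10, 20), c(0, 0)), "positive")
})

test_that("normalize rescales to unit mass, leaves bins alone, and is idempotent", {
  h <- size_histogram(c(1, 2), c(2, 2))
  n1 <- normalize_histogram(h)
  expect_equal(n1$frequencies, c(0.5, 0.5))
  expect_equal(n1$bin_values, h$bin_values)

  h2 <- normalize_histogram(size_histogram(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(h2$frequencies, c(1, 2, 3) / 6)
  expect_equal(sum(h2$frequencies), 1, tolerance = 1e-12)

  # idempotence: normalize of normalized is unchanged within 1e-12
  expect_equal(normalize_histogram(h2)$frequencies, h2$frequencies,
               tolerance = 1e-12)
})

test_that("resampling is multinomial over bins, deterministic per seed", {
  # all mass in one bin -> identical values at that center
  h1 <- size_histogram(c(10, 20, 30), c(0, 1, 0))
  s <- resample_cells(h1, n = 5, seed = 3)
  expect_equal(s$values, rep(20, 5))
  expect_equal(s$n, 5)

  # fixed seed -> identical sample; different seed -> different sample
  h <- toy_hist()
  a <- resample_cells(h, n = 200, seed = 7)
  b <- resample_cells(h, n = 200, seed = 7)
  expect_identical(a$values, b$values)
  expect_false(identical(resample_cells(h, n = 200, seed = 8)$values,
                         a$values))

  expect_error(resample_cells(h, n = 0), "n must be")

  # deterministic mode: counts are round(freq * n) with largest-remainder fix
  d <- resample_cells(h, n = 10, mode = "deterministic")
  expect_equal(as.vector(table(factor(d$values, levels = h$bin_values))),
               c(1, 4, 3, 2))
})

test_that("resampled mean matches the frequency-weighted bin mean (Monte Carlo)", {
  h <- normalize_histogram(toy_hist())
  exact_mean <- sum(h$bin_values * h$frequencies)
  exact_var <- sum(h$frequencies * (h$bin_values - exact_mean)^2)
  n <- 1000
  means <- vapply(1:100, function(s)
    mean(resample_cells(h, n = n, seed = s)$values), numeric(1))
  se <- sqrt(exact_var / (n * 100))
  expect_lt(abs(mean(means) - exact_mean), 3 * se)
})

test_that("long-run bin occupancy converges to the normalized frequencies", {
  h <- normalize_histogram(toy_hist())
  total <- 1e6
  counts <- table(factor(resample_cells(h, n = total, seed = 42)$values,
                         levels = h$bin_values))
  chisq <- sum((as.vector(counts) - total * h$frequencies)^2 /
                 (total * h$frequencies))
  expect_lt(chisq, qchisq(1 - 0.001, df = length(h$bin_values) - 1))
})

test_that("jitter draws within bin intervals and falls back for single bins", {
  h <- toy_hist()
  s <- resample_cells(h, n = 500, seed = 1, jitter = TRUE)
  e <- bin_edges(h)
  expect_true(all(s$values >= e[1] & s$values <= e[length(e)]))
  expect_equal(anyDuplicated(s$values), 0L)

  h1 <- size_histogram(50, 1)
  expect_warning(s1 <- resample_cells(h1, n = 5, seed = 1, jitter = TRUE),
                 "jitter disabled")
  expect_equal(s1$values, rep(50, 5))
})

test_that("weighted median is the smallest bin crossing half the mass", {
  expect_equal(weighted_median(size_histogram(c(10, 20, 30),
                                              c(0.2, 0.3, 0.5))), 30)
  # symmetric histogram -> central bin
  expect_equal(weighted_median(size_histogram(c(10, 20, 30),
                                              c(0.25, 0.5, 0.25))), 20)
  # large-sample oracle: median of a huge jitter-free resample
  h <- toy_hist()
  s <- resample_cells(h, n = 1e5, seed = 9)
  bw <- max(diff(h$bin_values))
  expect_lt(abs(weighted_median(h) - median(s$values)), bw + 1e-12)
})

test_that("frequency tables round-trip through both layouts", {
  hists <- list(
    a = size_histogram(c(10, 20, 30), c(0.2, 0.5, 0.3), strain_id = "a"),
    b = size_histogram(c(10, 20, 30), c(0.1, 0.1, 0.8), strain_id = "b"))

  wide <- file.path(tempdir(), "cohort_wide.tsv")
  write_frequency_table(hists, wide, layout = "wide")
  rd <- read_frequency_table(wide, layout = "wide")
  expect_length(rd, 2)
  expect_length(rd$a$bin_values, 3)
  expect_identical(rd$a$frequencies, hists$a$frequencies)
  expect_identical(rd$b$bin_values, hists$b$bin_values)

  long <- file.path(tempdir(), "cohort_long.csv")
  write_frequency_table(hists, long, layout = "long")
  rd2 <- read_frequency_table(long, layout = "long")
  expect_identical(rd2$b$frequencies, hists$b$frequencies)
  # round-trip the long file again through the writer: identical content
  long2 <- file.path(tempdir(), "cohort_long2.csv")
  write_frequency_table(rd2, long2, layout = "long")
  expect_identical(readLines(long), readLines(long2))
})

test_that("reader errors name the offending row and column", {
  bad <- file.path(tempdir(), "bad.tsv")
  writeLines(c("size_fl\tstrainA", "10\t0.5", "oops\t0.5"), bad)
  expect_error(read_frequency_table(bad, "wide"), "row 2.*size_fl")

  writeLines(c("size_fl\tstrainA", "10\t0.5", "10\t0.5"), bad)
  expect_error(read_frequency_table(bad, "wide"), "duplicate bin")

  writeLines(c("size_fl\tstrainA", "10\t0", "20\t0"), bad)
  expect_error(read_frequency_table(bad, "wide"), "all-zero")
})

test_that("screen tables round-trip losslessly, including at cohort scale", {
  one <- data.frame(strain = "s1", n = 1000L, seed = 5L,
                    fixed_null_ad = pi, median_fl = exp(1),
                    size_class = "normal", deviant_rank = 1L)
  p <- file.path(tempdir(), "screen_one.tsv")
  write_screen_table(one, p)
  expect_length(readLines(p), 2)
  back <- read_screen_table(p)
  expect_identical(back$fixed_null_ad, pi)

  # 5,052-row table with full-precision doubles
  set.seed(77)
  big <- data.frame(strain = sprintf("Y%04d", 1:5052),
                    fixed_null_ad = rexp(5052) * 1e3,
                    median_fl = runif(5052, 20, 200),
                    gamma_shape = rgamma(5052, 4),
                    deviant_rank = sample.int(5052))
  pb <- file.path(tempdir(), "screen_big.tsv")
  write_screen_table(big, pb)
  back <- read_screen_table(pb)
  expect_equal(nrow(back), 5052)
  expect_identical(back$fixed_null_ad, big$fixed_null_ad)
  expect_identical(back$median_fl, big$median_fl)
  expect_identical(back$gamma_shape, big$gamma_shape)

  expect_error(write_screen_table(big[0, ], pb), "nonempty")
})

test_that("per-strain seeds depend only on master seed and strain id", {
  expect_identical(derive_seed(42, "YPR086W"), derive_seed(42, "YPR086W"))
  expect_false(derive_seed(42, "YPR086W") == derive_seed(43, "YPR086W"))
  expect_false(derive_seed(42, "YPR086W") == derive_seed(42, "YPR087W"))
  s <- derive_seed(2^30, "a_very_long_systematic_name_with_suffix.1")
  expect_true(s >= 1 && s <= 2^31 - 2)
})
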