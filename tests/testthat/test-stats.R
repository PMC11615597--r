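# Independent brute-force oracles, written directly from the definitions.
oracle_quantile <- function(x, p) {
  # linear interpolation between order statistics (type 7)
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
oracle_agreement <- function(a, b) {
  d <- a - b
  n <- length(d)
  bias <- sum(d) / n
  s <- sqrt(sum((d - bias)^2) / (n - 1))
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       pearson_r = r)
}

fake_curves <- function(vals) {
  n <- length(vals)
  structure(data.frame(phase = 0:(n - 1),
                       mean_displacement_mm = vals,
                       max_displacement_mm = vals,
                       mean_diameter_mm = vals,
                       mean_diameter_change_mm = vals,
                       mean_diameter_change_pct = vals),
            reference_phase = 0L, class = c("motion_curves", "data.frame"))
}

test_that("group median/IQR matches hand values and an independent quantile oracle", {
  curves <- lapply(c(1, 2, 3, 4, 5), function(v) fake_curves(rep(v, 4)))
  g <- group_median_iqr(curves, metrics = "mean_displacement_mm")
  expect_true(all(g$median == 3))
  expect_true(all(g$q1 == 2) && all(g$q3 == 4))
  expect_true(all(g$iqr == 2))

  same <- lapply(1:6, function(i) fake_curves(c(1, 5, 2)))
  gs <- group_median_iqr(same)
  expect_true(all(gs$iqr == 0))

  set.seed(11)
  rand <- lapply(1:9, function(i) fake_curves(rnorm(5)))
  gr <- group_median_iqr(rand, metrics = "mean_diameter_mm")
  x <- sapply(rand, function(cv) cv$mean_diameter_mm)
  for (ph in 1:5) {
    expect_equal(gr$median[ph], oracle_quantile(x[ph, ], 0.5), tolerance = 1e-12)
    expect_equal(gr$q1[ph], oracle_quantile(x[ph, ], 0.25), tolerance = 1e-12)
    expect_equal(gr$q3[ph], oracle_quantile(x[ph, ], 0.75), tolerance = 1e-12)
  }
  # permutation invariance across subjects
  gp <- group_median_iqr(rand[sample(9)], metrics = "mean_diameter_mm")
  expect_equal(gr, gp, tolerance = 1e-15)
  expect_error(group_median_iqr(list(fake_curves(1:3), fake_curves(1:4))),
               "mixed phase counts")
})

test_that("agreement statistics match the Bland-Altman definitions", {
  a <- c(1, 2, 3, 4, 5)
  ag <- agreement_stats(a, a)
  expect_identical(ag$bias, 0)
  expect_identical(ag$loa_high - ag$loa_low, 0)
  expect_equal(ag$pearson_r, 1, tolerance = 1e-12)
  expect_true(is.na(ag$shapiro_p))

  ag1 <- agreement_stats(a, a + 1)
  expect_identical(ag1$bias, -1)

  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(10); y <- x + rnorm(10, sd = 0.3)
    # random draws may legitimately trip the normality gate
    got <- suppressWarnings(agreement_stats(x, y))
    want <- oracle_agreement(x, y)
    expect_equal(got$bias, want$bias, tolerance = 1e-12)
    expect_equal(got$loa_low, want$loa_low, tolerance = 1e-12)
    expect_equal(got$loa_high, want$loa_high, tolerance = 1e-12)
    expect_equal(got$pearson_r, want$pearson_r, tolerance = 1e-12)
    # antisymmetry of the bias, exactly
    expect_identical(got$bias, -suppressWarnings(agreement_stats(y, x))$bias)
  }
  expect_error(agreement_stats(1:4, 1:5), "equal length")
  expect_error(agreement_stats(1:2, 2:3), "at least 3")
  expect_error(agreement_stats(rep(1, 5), c(1, 2, 3, 4, 5)), "zero variance")
})

test_that("non-normal differences raise the Shapiro-Wilk warning flag", {
  set.seed(2)
  a <- rexp(60)^3
  b <- rep(0, 60)
  b <- b + rnorm(60, sd = 1e-6)
  expect_warning(ag <- agreement_stats(a, b), "normality")
  expect_true(ag$normality_warning)
  expect_lt(ag$shapiro_p, 0.05)
})

test_that("maximum variability is the largest across-scan range over phases", {
  c1 <- fake_curves(c(1, 2, 3))
  c3 <- fake_curves(c(1, 2, 6))
  v0 <- max_variability(list(c1, c1, c1))
  expect_identical(v0$max_variability, 0)
  v <- max_variability(list(c1, c1, c3), metric = "mean_displacement_mm")
  expect_identical(v$max_variability, 3)
  expect_identical(v$per_phase_range, c(0, 0, 3))
  # constructed offsets {0, +0.5, -0.5} -> range 1.0 at every phase
  base <- c(2, 4, 3, 1)
  vo <- max_variability(list(base, base + 0.5, base - 0.5))
  expect_identical(vo$max_variability, 1.0)
  # invariance to scan order
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  scans <- list(c1, c3, fake_curves(c(0, 2, 4)))
  vals <- sapply(perms, function(p) max_variability(scans[p])$max_variability)
  expect_true(all(vals == vals[1]))
  expect_error(max_variability(list(c1, c1)), "exactly 3")
  expect_error(max_variability(list(1:3, 1:3, 1:4)), "mixed phase counts")
})

test_that("area-derived diameter inverts the circle area exactly", {
  expect_equal(diameter_from_area(pi)$da_mm, 2, tolerance = 1e-15)
  expect_identical(diameter_from_area(0)$da_mm, 0)
  expect_equal(diameter_from_area(526.85)$da_mm, 25.9, tolerance = 0.001)
  d <- seq(0.5, 40, by = 0.5)
  back <- diameter_from_area(pi * (d / 2)^2)$da_mm
  expect_equal(back, d, tolerance = 1e-12)
  expect_true(all(diff(diameter_from_area(seq(0, 100, 5))$da_mm) > 0))
  expect_error(diameter_from_area(-1), ">= 0")
})

test_that("statistics export as CSV and JSON", {
  g <- group_median_iqr(lapply(1:4, function(i) fake_curves(c(1, 2, 3))))
  fc <- tempfile(fileext = ".csv"); fj <- tempfile(fileext = ".json")
  write_stats(g, fc)
  expect_equal(nrow(read.csv(fc)), nrow(g))
  write_stats(agreement_stats(c(1, 2, 3.5), c(1.1, 2.2, 3.3)), fj)
  parsed <- jsonlite::fromJSON(fj)
  expect_true(all(c("bias", "loa_low", "loa_high", "pearson_r") %in% names(parsed)))
  unlink(c(fc, fj))
})
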