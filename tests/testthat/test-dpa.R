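test_that("ROR matches direct odds-ratio arithmetic and its Wald CI", {
  r <- ror_stats(10, 90, 100, 9900)
  expect_equal(r$ror, 11.0)
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 9900)
  expect_equal(r$ror_lo, exp(log(11) - 1.96 * se))
  expect_equal(r$ror_hi, exp(log(11) + 1.96 * se))
  # independence: a*d == b*c
  expect_equal(ror_stats(10, 90, 100, 900)$ror, 1.0)
})

test_that("PRR matches the proportion ratio and is antisymmetric", {
  p <- prr_stats(10, 90, 100, 9900)
  expect_equal(p$prr, 10.0)
  expect_equal(prr_stats(10, 90, 100, 900)$prr, 1.0)
  t <- random_tables(50, seed = 101)
  expect_equal(prr_stats(t$a, t$b, t$c, t$d)$prr,
               1 / prr_stats(t$c, t$d, t$a, t$b)$prr)
})

test_that("chi-square matches the cell-sum form, with and without Yates", {
  expect_equal(round(chi2_stat(10, 90, 100, 9900, yates = FALSE), 2), 74.45)
  brute <- function(a, b, c, d, yates) {
    o <- as.numeric(c(a, b, c, d))
    a <- o[1]; b <- o[2]; c <- o[3]; d <- o[4]
    N <- sum(o)
    e <- c((a + b) * (a + c), (a + b) * (b + d),
           (c + d) * (a + c), (c + d) * (b + d)) / N
    dev <- abs(o - e)
    if (yates) dev <- pmax(0, dev - 0.5)
    sum(dev^2 / e)
  }
  t <- random_tables(200, seed = 7)
  for (y in c(TRUE, FALSE)) {
    ours <- chi2_stat(t$a, t$b, t$c, t$d, yates = y)
    ref <- mapply(brute, t$a, t$b, t$c, t$d, MoreArgs = list(yates = y))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
  # independence and transposition
  expect_equal(chi2_stat(10, 90, 100, 900, yates = FALSE), 0)
  expect_equal(chi2_stat(t$a, t$b, t$c, t$d),
               chi2_stat(t$a, t$c, t$b, t$d))
})

test_that("zero cells give undefined markers unless Haldane-corrected", {
  expect_true(is.na(ror_stats(0, 10, 5, 100)$ror))
  expect_true(is.na(prr_stats(3, 0, 5, 100)$prr))
  h <- ror_stats(0, 10, 5, 100, zero_cell = "haldane")
  expect_equal(h$ror, (0.5 * 100.5) / (10.5 * 5.5))
  expect_true(is.na(chi2_stat(0, 0, 5, 100))) # degenerate margin
})

test_that("BCPNN information component behaves like a shrunk log2 ratio", {
  # a = 0 with large margins: negative IC
  expect_lt(bcpnn_ic(0, 500, 500, 100000)$ic, 0)
  # observed equals expected at large N: IC near 0
  expect_lt(abs(bcpnn_ic(100, 9900, 9900, 980100)$ic), 0.05)
  # interval ordering on random tables, including zero cells
  t <- random_tables(200, seed = 31)
  t$a[1:10] <- 0
  ic <- bcpnn_ic(t$a, t$b, t$c, t$d)
  expect_true(all(ic$ic025 < ic$ic))
  expect_true(all(is.finite(ic$ic)))
})

test_that("BCPNN closed form is locked against an independent evaluation", {
  # direct transcription of the documented expectation/variance expressions,
  # written out scalar-by-scalar
  ref_ic <- function(a, b, c, d) {
    N <- a + b + c + d; n1 <- a + b; m1 <- a + c
    gam <- 1 * (N + 2) * (N + 2) / ((n1 + 1) * (m1 + 1))
    ic <- log2((a + 1) * (N + 2) * (N + 2) / ((N + gam) * (n1 + 1) *
                                                (m1 + 1)))
    v <- ((N - a + gam - 1) / ((a + 1) * (1 + N + gam)) +
            (N - n1 + 2 - 1) / ((n1 + 1) * (1 + N + 2)) +
            (N - m1 + 2 - 1) / ((m1 + 1) * (1 + N + 2))) / log(2)^2
    c(ic, ic - 2 * sqrt(v))
  }
  t <- random_tables(100, seed = 17)
  got <- bcpnn_ic(t$a, t$b, t$c, t$d)
  ref <- t(mapply(ref_ic, t$a, t$b, t$c, t$d))
  expect_equal(got$ic, ref[, 1], tolerance = 1e-12)
  expect_equal(got$ic025, ref[, 2], tolerance = 1e-12)
})

test_that("classification applies the four-criteria rule with strict EBGM05", {
  crit <- signal_criteria()
  # printed SOC-level statistics: blood/lymphatic positive, psychiatric not
  rows <- data.frame(
    a = c(4325, 877),
    ror = c(6.58, 0.34), prr = c(5.99, 0.35),
    ebgm05 = c(5.81, 0.34), ic025 = c(2.53, -1.59))
  got <- classify_signals(rows, crit)
  expect_equal(got$signal, c("positive", "negative"))
  # exactly at the thresholds: negative, EBGM05 must strictly exceed 2
  at <- data.frame(a = 10, ror = 3, prr = 2, ebgm05 = 2, ic025 = 0.5)
  expect_equal(classify_signals(at, crit)$signal, "negative")
  above <- data.frame(a = 10, ror = 3, prr = 2, ebgm05 = 2.0001, ic025 = 0.5)
  expect_equal(classify_signals(above, crit)$signal, "positive")
  # ic025 criterion is strict too and individually overridable
  ic0 <- data.frame(a = 10, ror = 5, prr = 5, ebgm05 = 3, ic025 = 0)
  expect_equal(classify_signals(ic0, crit)$signal, "negative")
  expect_equal(classify_signals(
    ic0, signal_criteria(ic025_min = NA))$signal, "positive")
})

test_that("undefined statistics classify negative with a reason code", {
  rows <- data.frame(a = c(5, 0), ror = c(NA, NA), prr = c(4, NA),
                     ebgm05 = c(3, NA), ic025 = c(1, -2))
  got <- classify_signals(rows)
  expect_equal(got$signal, c("negative", "negative"))
  expect_equal(got$reason, c("not evaluable", "not evaluable"))
})

test_that("negative criteria thresholds are rejected", {
  expect_error(signal_criteria(ror_min = -1), "ror_min")
})
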