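# frozen micro-example: a=10, b=20, c=30, d=120
micro <- list(a = 10, b = 20, c = 30, d = 120)

test_that("worked micro-example reproduces the hand-computed statistics", {
  r <- ror_stats(micro$a, micro$b, micro$c, micro$d)
  expect_equal(r$ror, 2.0)
  expect_equal(r$ror_lo, 0.848, tolerance = 1e-3)
  expect_equal(r$ror_hi, 4.717, tolerance = 1e-3)

  p <- prr_stats(micro$a, micro$b, micro$c, micro$d)
  expect_equal(p$prr, 5 / 3)
  expect_equal(p$prr_lo, 0.916, tolerance = 1e-3)
  expect_equal(p$prr_hi, 3.033, tolerance = 1e-3)

  expect_equal(chisq_stat(micro$a, micro$b, micro$c, micro$d), 18 / 7,
               tolerance = 1e-10)
  expect_equal(chisq_stat(micro$a, micro$b, micro$c, micro$d, yates = TRUE),
               1.8578, tolerance = 1e-4)

  oe <- bcpnn_stats(micro$a, micro$b, micro$c, micro$d,
                    variant = "oe_simple", continuity = FALSE)
  expect_equal(oe$ic, log2(1.5))
})

test_that("symmetric tables are null under every statistic", {
  expect_equal(ror_stats(5, 5, 5, 5)$ror, 1)
  expect_equal(prr_stats(5, 5, 5, 5)$prr, 1)
  expect_equal(chisq_stat(5, 5, 5, 5), 0)
  # independence (ad == bc) zeroes the chi-square even off-symmetry
  expect_equal(chisq_stat(10, 20, 30, 60), 0)
  # balanced 2x2 gives Bate E(IC) = 0 exactly
  expect_equal(bcpnn_stats(25, 25, 25, 25, variant = "bate")$ic, 0,
               tolerance = 1e-12)
})

test_that("scaling all cells preserves the ROR but narrows its interval", {
  s1 <- ror_stats(5, 10, 15, 60)
  s2 <- ror_stats(50, 100, 150, 600)
  expect_equal(s1$ror, s2$ror)
  expect_lt(s2$ror_hi - s2$ror_lo, s1$ror_hi - s1$ror_lo)
})

test_that("zero cells give NA markers or a flagged Haldane correction", {
  off <- ror_stats(0, 10, 5, 100, zero_correction = FALSE)
  expect_true(is.na(off$ror))
  on <- ror_stats(0, 10, 5, 100, zero_correction = TRUE)
  expect_true(on$corrected)
  expect_equal(on$ror, (0.5 * 100.5) / (10.5 * 5.5))
  expect_true(is.na(prr_stats(3, 7, 0, 100, zero_correction = FALSE)$prr))
  expect_true(is.na(chisq_stat(0, 0, 5, 5)))   # zero margin
})

test_that("chi-square and ROR are transpose-symmetric; PRR is not", {
  a <- 7; b <- 21; c <- 13; d <- 99
  # transpose swaps b and c
  expect_equal(chisq_stat(a, b, c, d), chisq_stat(a, c, b, d))
  expect_equal(ror_stats(a, b, c, d)$ror, ror_stats(a, c, b, d)$ror)
  expect_false(isTRUE(all.equal(prr_stats(a, b, c, d)$prr,
                                prr_stats(a, c, b, d)$prr)))
})

test_that("ROR and PRR always sit on the same side of 1, ROR further out", {
  set.seed(31)
  for (i in 1:200) {
    k <- as.list(sample(1:400, 4, replace = TRUE))
    names(k) <- c("a", "b", "c", "d")
    ror <- ror_stats(k$a, k$b, k$c, k$d)$ror
    prr <- prr_stats(k$a, k$b, k$c, k$d)$prr
    if (ror >= 1) expect_true(ror >= prr && prr >= 1 - 1e-12)
    else expect_true(ror <= prr && prr <= 1 + 1e-12)
  }
})

test_that("Bate IC converges to the observed/expected IC in large samples", {
  # N = 1e6 at fixed proportions
  a <- 2000; b <- 48000; c <- 38000; d <- 912000
  bate <- bcpnn_stats(a, b, c, d, variant = "bate")
  oe <- bcpnn_stats(a, b, c, d, variant = "oe_simple", continuity = FALSE)
  expect_equal(bate$ic, oe$ic, tolerance = 0.01)
})

test_that("interval bounds bracket their point estimates", {
  set.seed(32)
  k <- data.frame(a = sample(1:300, 50, TRUE), b = sample(1:300, 50, TRUE),
                  c = sample(1:300, 50, TRUE), d = sample(1:300, 50, TRUE))
  r <- ror_stats(k$a, k$b, k$c, k$d)
  p <- prr_stats(k$a, k$b, k$c, k$d)
  ic <- bcpnn_stats(k$a, k$b, k$c, k$d)
  expect_true(all(r$ror_lo <= r$ror & r$ror <= r$ror_hi))
  expect_true(all(p$prr_lo <= p$prr & p$prr <= p$prr_hi))
  expect_true(all(ic$ic025 <= ic$ic))
  expect_true(all(chisq_stat(k$a, k$b, k$c, k$d) >= 0))
})

test_that("vectorized statistics agree with per-table evaluation", {
  set.seed(33)
  k <- data.frame(a = sample(1:99, 20, TRUE), b = sample(1:99, 20, TRUE),
                  c = sample(1:99, 20, TRUE), d = sample(1:99, 20, TRUE))
  vec <- signal_stats(k$a, k$b, k$c, k$d)
  for (i in c(1, 7, 20)) {
    one <- signal_stats(contingency_table(k$a[i], k$b[i], k$c[i], k$d[i]))
    expect_equal(as.list(vec[i]), as.list(one))
  }
})
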