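test_that("nyquist limit follows the sampling rate", {
  expect_equal(round(nyquist(0.735), 3), 0.680)
  expect_equal(nyquist(0.5), 1.0)
  expect_equal(nyquist(2.0), 0.25)
  expect_error(nyquist(0), "positive")
  expect_error(nyquist(-1), "positive")
})

test_that("a 6-minute acquisition at TR 0.735 s has 490 volumes", {
  expect_identical(n_timepoints_for_duration(6 * 60, 0.735), 490L)
})

test_that("band validation enforces ordering and the Nyquist limit", {
  expect_error(band_spec(0.08, 0.01), "invalid band")
  expect_error(band_spec(-0.1, 0.08), "invalid band")
  ts <- bold_ts(matrix(rnorm(2 * 64), 2), tr = 1)
  expect_error(bandpass(ts, band_spec(0.1, 0.9)), "Nyquist")
})

test_that("linear detrending removes exactly the affine component", {
  n <- 100
  const <- bold_ts(matrix(7, 1, n), tr = 1)
  expect_lt(max(abs(detrend_linear(const)$values)), 1e-10)

  ramp <- bold_ts(matrix(2 + 0.3 * seq_len(n), 1), tr = 1)
  expect_lt(max(abs(detrend_linear(ramp)$values)), 1e-10)

  set.seed(1)
  y <- sin(2 * pi * 5 * seq_len(n) / n) + 0.05 * seq_len(n) + 3
  got <- detrend_linear(bold_ts(y, tr = 1))$values[1, ]
  expect_lt(max(abs(got - (y - linear_fit_oracle(y)))), 1e-8)
})

test_that("detrending is idempotent", {
  set.seed(2)
  ts <- bold_ts(matrix(rnorm(5 * 90), 5), tr = 0.735)
  once <- detrend_linear(ts)
  twice <- detrend_linear(once)
  expect_lt(max(abs(once$values - twice$values)), 1e-10)
})

test_that("ideal bandpass keeps in-band bins and annihilates the rest", {
  n <- 128; tr <- 1
  band <- band_spec(0.05, 0.2)
  in_bin <- bin_sinusoid(n, tr, k = 10)        # 10/128 = 0.078 Hz, in band
  out_bin <- bin_sinusoid(n, tr, k = 40)       # 0.3125 Hz, out of band
  ts <- bold_ts(rbind(in_bin, out_bin), tr)
  got <- bandpass(ts, band)$values
  expect_lt(max(abs(got[1, ] - in_bin)), 1e-8)
  expect_lt(max(abs(got[2, ])), 1e-8)
})

test_that("bandpass preserves the Parseval fraction of white noise", {
  n <- 200; tr <- 1
  band <- band_spec(0.1, 0.3)
  n_bins <- length(seq_len(n %/% 2)[seq_len(n %/% 2) / n > 0.1 &
                                      seq_len(n %/% 2) / n <= 0.3])
  set.seed(3)
  x <- matrix(rnorm(1000 * n), 1000)
  out <- bandpass(bold_ts(x, tr), band)$values
  ratio <- sum(out^2) / sum(x^2)
  frac <- 2 * n_bins / n        # each retained bin has a conjugate partner
  expect_lt(abs(ratio - frac), 4 * sqrt(2 * frac^2 / 1000))
})

test_that("periodogram equals direct DFT summation on a fixed 16-point vector", {
  x <- c(1.5, -0.2, 0.8, 2.1, -1.3, 0.4, 0.0, -0.7,
         1.1, 0.3, -2.2, 0.9, 0.5, -0.1, 1.7, -0.6)
  ps <- periodogram(bold_ts(x, tr = 2))
  expect_equal(length(ps$frequencies), 8L)
  expect_lt(max(abs(ps$power[1, ] - dft_power_oracle(x))), 1e-10)
  expect_equal(ps$frequencies, (1:8) / (16 * 2))
})

test_that("periodogram concentrates a bin sinusoid and vanishes on silence", {
  n <- 64
  ps <- periodogram(bold_ts(bin_sinusoid(n, 1, k = 7), tr = 1))
  expect_equal(which.max(ps$power[1, ]), 7L)
  expect_lt(sum(ps$power[1, -7]) / ps$power[1, 7], 1e-20)

  ps0 <- periodogram(bold_ts(matrix(0, 1, n), tr = 1))
  expect_true(all(ps0$power == 0))
})

test_that("Parseval holds for odd and even series lengths", {
  for (n in c(490, 489)) {
    set.seed(n)
    x <- matrix(rnorm(3 * n), 3)
    ps <- periodogram(bold_ts(x, tr = 0.735))
    h <- n %/% 2
    w <- rep(2, h)
    if (n %% 2 == 0) w[h] <- 1   # even n: the Nyquist bin is self-conjugate
    lhs <- as.vector(ps$power %*% w)
    rhs <- rowSums((x - rowMeans(x))^2)
    expect_lt(max(abs(lhs - rhs) / rhs), 1e-6)
  }
})

test_that("ALFF is the mean in-band amplitude and scales linearly", {
  n <- 100; tr <- 1
  band <- band_spec(0.1, 0.3)
  ps <- periodogram(bold_ts(bin_sinusoid(n, tr, k = 15, amplitude = 2), tr))
  idx <- which(ps$frequencies > 0.1 & ps$frequencies <= 0.3)
  p_peak <- ps$power[1, 15]
  expect_equal(alff(ps, band)$values, sqrt(p_peak) / length(idx))

  set.seed(4)
  x <- rnorm(n)
  a1 <- alff(periodogram(bold_ts(x, tr)), band)$values
  a3 <- alff(periodogram(bold_ts(3 * x, tr)), band)$values
  expect_equal(a3, 3 * a1, tolerance = 1e-12)
})

test_that("ALFF of white noise matches brute-force bin enumeration and theory", {
  n <- 490; tr <- 0.735
  band <- band_broad()
  set.seed(5)
  x <- matrix(rnorm(1000 * n), 1000)
  ps <- periodogram(bold_ts(x, tr))
  got <- alff(ps, band)$values
  # brute force: enumerate the band bins, sqrt, mean
  freqs <- seq_len(n %/% 2) / (n * tr)
  idx <- which(freqs > 0 & freqs <= 0.1164)
  brute <- apply(ps$power, 1, function(p) mean(sqrt(p[idx])))
  expect_lt(max(abs(got - brute)), 1e-12)
  # each two-sided bin power is Gamma-distributed; E sqrt(power) for a
  # unit-variance white series is sqrt(pi/4) in this scaling
  expect_lt(abs(mean(got) - sqrt(pi) / 2), 0.01)
})

test_that("the mean/sum identity links the two ALFF denominators", {
  set.seed(6)
  ps <- periodogram(bold_ts(matrix(rnorm(3 * 490), 3), tr = 0.735))
  band <- band_narrow()
  idx_n <- length(which(ps$frequencies > 0.01 & ps$frequencies <= 0.08))
  a_band <- alff(ps, band, bins = "band")$values
  a_all <- alff(ps, band, bins = "all")$values
  expect_equal(a_all, a_band * idx_n / length(ps$frequencies), tolerance = 1e-12)
})

test_that("fALFF is the in-band fraction of total amplitude", {
  n <- 490; tr <- 0.735
  full <- band_full(tr)
  set.seed(7)
  ps <- periodogram(bold_ts(matrix(rnorm(5 * n), 5), tr))
  expect_equal(falff(ps, full)$values, rep(1, 5), tolerance = 1e-12)

  in_sin <- bin_sinusoid(n, tr, k = 20)     # 20/360.15 = 0.0555 Hz
  out_sin <- bin_sinusoid(n, tr, k = 100)   # 0.2777 Hz
  ps2 <- periodogram(bold_ts(rbind(in_sin, out_sin), tr))
  f <- falff(ps2, band_narrow())$values
  expect_equal(unname(f[1]), 1, tolerance = 1e-10)
  expect_equal(unname(f[2]), 0, tolerance = 1e-10)
})

test_that("fALFF of white noise approximates the band bin fraction", {
  n <- 490; tr <- 0.735
  set.seed(8)
  ps <- periodogram(bold_ts(matrix(rnorm(1000 * n), 1000), tr))
  freqs <- ps$frequencies
  for (band in list(band_broad(), band_narrow())) {
    frac <- sum(freqs > band$f_low & freqs <= band$f_high) / length(freqs)
    f <- falff(ps, band)$values
    expect_lt(abs(mean(f) - frac), 4 * stats::sd(f) / sqrt(1000) + 0.002)
  }
})

test_that("fALFF is scale invariant and additive over a band partition", {
  n <- 490; tr <- 0.735
  set.seed(9)
  x <- matrix(rnorm(10 * n), 10)
  f1 <- compute_falff(bold_ts(x, tr), band_narrow())$values
  f2 <- compute_falff(bold_ts(1e4 * x, tr), band_narrow())$values
  expect_lt(max(abs(f1 - f2)), 1e-10)

  ps <- periodogram(bold_ts(x, tr))
  ny <- nyquist(tr)
  cuts <- c(0, 0.01, 0.08, 0.1164, 0.3, ny)
  total <- rowSums(sapply(seq_len(length(cuts) - 1), function(i) {
    falff(ps, band_spec(cuts[i], cuts[i + 1]))$values
  }))
  expect_lt(max(abs(total - 1)), 1e-10)
})

test_that("an all-zero voxel propagates as missing, never as zero", {
  n <- 64
  x <- rbind(rnorm(n), rep(0, n))
  ps <- periodogram(bold_ts(x, tr = 1))
  f <- falff(ps, band_spec(0.1, 0.3))$values
  expect_false(is.na(f[1]))
  expect_true(is.na(f[2]))
})

test_that("a band with no bins raises an empty-band error", {
  ps <- periodogram(bold_ts(matrix(rnorm(32), 1), tr = 1))
  expect_error(alff(ps, band_spec(0.001, 0.002)), "no frequency bins")
  expect_error(falff(ps, band_spec(0.001, 0.002)), "no frequency bins")
})

test_that("broadband-but-flat voxels have higher ALFF yet lower fALFF", {
  # constructed spectra: the CSF-like voxel has uniformly higher power at
  # every frequency but a flatter profile than the brainstem-like voxel
  freqs <- (1:245) / (490 * 0.735)
  brainstem <- ifelse(freqs > 0.01 & freqs <= 0.08, 2.0, 0.05)
  csf <- rep(2.5, 245)   # 2.5 > 2.0 everywhere, perfectly flat
  ps <- structure(
    list(frequencies = freqs, power = rbind(csf, brainstem),
         tr = 0.735, n_timepoints = 490L),
    class = "power_spectrum"
  )
  band <- band_narrow()
  a <- alff(ps, band)$values
  f <- falff(ps, band)$values
  expect_gt(a[1], a[2])   # ALFF: CSF above brainstem
  expect_lt(f[1], f[2])   # fALFF: fractional correction suppresses CSF
})
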