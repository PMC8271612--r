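test_that("window_signal is a verbatim slice with round(duration*fps) samples", {
  tr <- sine_trace(0.3, fps = 8.6, duration = 30)
  w <- window_signal(tr, start = 0, duration = 15)
  expect_length(w$samples, 129L)  # round(15 * 8.6)
  expect_identical(w$samples, tr$values[1:129])
  w2 <- window_signal(tr, start = 10, duration = 15)
  expect_identical(w2$start_index, 86L)
  expect_identical(w2$samples, tr$values[87:215])
  expect_error(window_signal(tr, start = 20, duration = 15), "exceeds")
  expect_error(window_signal(tr, start = 0, duration = 0.5), ">= 8")
})

test_that("detrend_linear removes affine components exactly and is idempotent", {
  fps <- 8.6
  t <- (0:128) / fps
  w <- window_signal(signal_trace(3 * t + 7, fps = fps), 0, 15)
  d <- detrend_linear(w)
  expect_lt(max(abs(d$samples)), 1e-9 * max(abs(w$samples)))

  # sinusoid plus strong drift: residual decorrelates from time
  x <- sin(2 * pi * 0.3 * t) + 5 * t
  d2 <- detrend_linear(window_signal(signal_trace(x, fps = fps), 0, 15))
  fit <- lm(d2$samples ~ t)  # independent least-squares check
  expect_lt(abs(coef(fit)[2]), 1e-9)
  expect_lt(abs(coef(fit)[1]), 1e-9)

  # idempotence on an already detrended signal
  d3 <- detrend_linear(d2)
  expect_equal(d3$samples, d2$samples, tolerance = 1e-9)

  expect_error(detrend_linear(c(1)), "at least 2")
})

test_that("periodogram matches a direct O(N^2) DFT oracle at n_fft = N", {
  set.seed(3)
  fps <- 8.6
  x <- rnorm(129)
  w <- detrend_linear(window_signal(signal_trace(x, fps = fps), 0, 15))
  spec <- periodogram(w, n_fft = 129)
  oracle <- dft_psd_oracle(w$samples, fs = fps)
  expect_equal(spec$freqs, oracle$freqs, tolerance = 1e-12)
  expect_equal(spec$values, oracle$values, tolerance = 1e-9)

  # and with zero-padding against the oracle on the padded grid
  spec_p <- periodogram(w, n_fft = 256)
  oracle_p <- dft_psd_oracle(c(w$samples, rep(0, 256 - 129)), fs = fps,
                             native_n = 129)
  expect_equal(spec_p$values, oracle_p$values, tolerance = 1e-9)

  expect_error(periodogram(w, n_fft = 100), "n_fft")
})

test_that("periodogram locates a sinusoid's frequency within one grid step", {
  spec <- chain_spectrum(sine_trace(0.333), n_fft = 2048)
  pk <- spec$freqs[which.max(spec$values)]
  expect_lt(abs(pk - 0.333), 8.6 / 2048)
})

test_that("all-zero window has an identically zero spectrum", {
  w <- window_signal(signal_trace(rep(0, 129), fps = 8.6), 0, 15)
  expect_true(all(periodogram(w, n_fft = 512)$values == 0))
})

test_that("zero-padding conserves integrated power and the native-bin peak", {
  set.seed(9)
  fps <- 8.6
  x <- sin(2 * pi * 0.4 * (0:128) / fps) + rnorm(129, sd = 0.1)
  w <- detrend_linear(window_signal(signal_trace(x, fps = fps), 0, 15))
  # two-sided integrated power: df * (full-circle sum) == mean(x^2)
  int_power <- function(spec) {
    one <- spec$values
    n <- spec$n_fft
    # reconstruct two-sided sum from the one-sided grid
    interior <- if (n %% 2 == 0) one[2:(length(one) - 1)] else one[-1]
    (spec$fps / n) * (sum(one) + sum(interior))
  }
  p_native <- int_power(periodogram(w, n_fft = 129))
  p_padded <- int_power(periodogram(w, n_fft = 4096))
  expect_equal(p_native, mean(w$samples^2), tolerance = 1e-6)
  expect_equal(p_padded, p_native, tolerance = 1e-6)

  # peak moves by at most one native bin under padding
  pk_native <- with(periodogram(w, n_fft = 129),
                    freqs[which.max(values)])
  pk_padded <- with(periodogram(w, n_fft = 4096),
                    freqs[which.max(values)])
  expect_lt(abs(pk_native - pk_padded), fps / 129)
})

test_that("band edges partition the spectrum and reject too-low sampling", {
  b <- band_edges(8.6)
  expect_identical(c(b$bf_lo, b$bf_hi, b$hf_hi), c(0.1, 2.0, 4.3))
  expect_error(band_edges(3.5), "fps too low")
  # a bin at exactly 2.0 Hz belongs to BF, not HF
  spec <- power_spectrum(freqs = seq(0, 4, by = 0.1),
                         values = rep(1, 41), n_fft = 80, native_n = 80,
                         fps = 8)
  m <- thermalrr:::band_masks(spec, band_edges(8))
  expect_true(m$bf[spec$freqs == 2.0])
  expect_false(m$hf[spec$freqs == 2.0])
  expect_true(m$hf[spec$freqs == 2.1])
})

test_that("spectrum CSV export round-trips frequencies and densities", {
  spec <- chain_spectrum(sine_trace(0.25), n_fft = 512)
  path <- tempfile(fileext = ".csv")
  write_spectrum_csv(spec, path)
  df <- read.csv(path)
  expect_identical(names(df), c("freq_hz", "psd"))
  expect_equal(df$psd, spec$values)
})
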