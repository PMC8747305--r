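test_that("butterworth preserves DC and matches the analytic response", {
  x <- rep(3.7, 400)
  y <- butterworth(x, 50, filter_spec("lowpass", 2, 5))
  expect_equal(y, x, tolerance = 1e-9)

  # zero-phase second order: power gain |H|^2 with |H| = 1/sqrt(1+(f/fc)^4)
  fs <- 200; tt <- seq(0, 10, by = 1 / fs)
  mid <- 400:1600
  for (f in c(1, 2, 40)) {
    x <- sin(2 * pi * f * tt)
    y <- butterworth(x, fs, filter_spec("lowpass", 2, 5))
    gain <- rms(y[mid]) / rms(x[mid])
    analytic <- 1 / (1 + (f / 5)^4)
    expect_equal(gain, analytic, tolerance = 0.01)
  }
  # 1 Hz through 5 Hz low-pass: attenuation < 1%; 40 Hz (8x cutoff): < 2%
  x1 <- sin(2 * pi * 1 * tt)
  expect_gt(rms(butterworth(x1, fs, filter_spec("lowpass", 2, 5))[mid]) /
              rms(x1[mid]), 0.99)
  x40 <- sin(2 * pi * 40 * tt)
  expect_lt(rms(butterworth(x40, fs, filter_spec("lowpass", 2, 5))[mid]) /
              rms(x40[mid]), 0.02)
})

test_that("filters reject invalid specifications", {
  expect_error(butterworth(rnorm(100), 50,
                           filter_spec("lowpass", 2, 30)), "Nyquist")
  expect_error(butterworth(rnorm(5), 50, filter_spec("lowpass", 2, 5)),
               "short")
  expect_error(filter_spec("bandpass", 2, 10), "two cutoff")
})

test_that("filtering is linear", {
  set.seed(1)
  fs <- 50
  x <- rnorm(300); y <- rnorm(300)
  for (spec in list(filter_spec("lowpass", 2, 5),
                    filter_spec("highpass", 2, 3),
                    filter_spec("bandpass", 2, c(2, 10)))) {
    lhs_ <- butterworth(2.5 * x - 1.3 * y, fs, spec)
    rhs_ <- 2.5 * butterworth(x, fs, spec) - 1.3 * butterworth(y, fs, spec)
    expect_equal(lhs_, rhs_, tolerance = 1e-9)
  }
})

test_that("emg envelope follows the rectified-mean of a carrier", {
  fs <- 2000
  tt <- seq(0, 3, by = 1 / fs)
  a <- 0.8
  env <- emg_envelope(a * sin(2 * pi * 100 * tt), fs)
  mid <- round(length(env) * 0.3):round(length(env) * 0.7)
  expect_equal(mean(env[mid]), 2 * a / pi, tolerance = 0.05 * 2 * a / pi)
  expect_true(all(env >= 0))
  # envelope varies no faster than its 2.5 Hz band limit allows
  expect_lt(max(abs(diff(env[mid]))),
            2 * pi * 2.5 / fs * max(env) * 1.5)
})

test_that("emg envelope suppresses content outside the pass band", {
  fs <- 2000
  tt <- seq(0, 3, by = 1 / fs)
  env0 <- emg_envelope(numeric(length(tt)), fs)
  expect_equal(env0, numeric(length(tt)))
  a <- 1
  env5 <- emg_envelope(a * sin(2 * pi * 5 * tt), fs)
  mid <- round(length(env5) * 0.3):round(length(env5) * 0.7)
  expect_lt(mean(env5[mid]), 0.05 * 2 * a / pi)
  expect_error(emg_envelope(rnorm(500), fs), "1 s")
})

test_that("MVC normalization is a plain scaling", {
  env <- abs(rnorm(100))
  expect_equal(normalize_mvc(rep(2.5, 10), 2.5), rep(1, 10))
  expect_equal(normalize_mvc(env, 4), normalize_mvc(env, 2) / 2)
  expect_error(normalize_mvc(env, 0), "positive")
  # self-normalization: peak of an envelope divided by its own peak is 1
  expect_equal(max(normalize_mvc(env, max(env))), 1)
})

test_that("resampling to 50 Hz decimates without delay or aliasing", {
  x <- rep(2, 400)
  y <- resample_to_50hz(x, 200)
  expect_length(y, 100L)
  expect_equal(y, rep(2, 100), tolerance = 1e-9)
  expect_error(resample_to_50hz(x, 130), "multiple")

  fs <- 2000
  tt <- seq(0, 4, by = 1 / fs)
  x2 <- sin(2 * pi * 2 * tt)
  y2 <- resample_to_50hz(x2, fs)
  ref <- sin(2 * pi * 2 * seq(0, by = 1 / 50, length.out = length(y2)))
  cc <- stats::ccf(y2, ref, lag.max = 5, plot = FALSE)
  expect_lte(abs(cc$lag[which.max(cc$acf)]), 1)

  set.seed(2)
  noise <- rnorm(8000)
  yn <- resample_to_50hz(noise, 2000)
  # only the 0-20 Hz band of a 0-1000 Hz flat spectrum should survive
  expect_lt(stats::var(yn) / stats::var(noise), 0.05)
  x30 <- sin(2 * pi * 30 * tt)
  expect_lt(rms(resample_to_50hz(x30, fs)), 0.05 * rms(x30))
})

test_that("cross-correlation recovers constructed delays", {
  set.seed(3)
  # a lift cycle: flex down, hold, extend back up
  prof <- c(minimum_jerk(0, 1.2, 2.5, 50), rep(1.2, 25),
            minimum_jerk(1.2, 0, 2.5, 50))
  sig <- c(rep(0, 30), prof, rep(0, 30))
  delayed <- c(rep(0, 7), sig)[seq_along(sig)]
  expect_identical(estimate_delay_xcorr(sig, delayed), 7L)
  expect_identical(estimate_delay_xcorr(sig, sig), 0L)
  noisy <- delayed + rnorm(length(sig), 0, rms(sig - mean(sig)) /
                             sqrt(10))
  expect_lte(abs(estimate_delay_xcorr(sig, noisy) - 7L), 1L)
  expect_error(estimate_delay_xcorr(rep(1, 200), rep(1, 200)),
               "degenerate")
})
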