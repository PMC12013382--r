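# EMG conditioning, windowing, and the Hudgins + AR feature set.

rms <- function(x) sqrt(mean(x^2))

test_that("conditioning passes 150 Hz, rejects 60 Hz and DC", {
  fs <- 1000
  t <- seq_len(2 * fs) / fs
  one <- function(f) emg_recording(matrix(sin(2 * pi * f * t), ncol = 1), fs)
  post <- 501:2000   # past the causal transient
  for (mode in c("offline", "causal")) {
    y60 <- condition_signal(one(60), mode)$samples[post, 1]
    expect_lt(20 * log10(rms(y60) / rms(sin(2 * pi * 60 * t))), -20)
    y150 <- condition_signal(one(150), mode)$samples[post, 1]
    expect_lt(abs(20 * log10(rms(y150) / rms(sin(2 * pi * 150 * t)))), 1)
  }
  dc <- condition_signal(emg_recording(matrix(1, 2000, 1), fs), "offline")
  expect_lt(rms(dc$samples[post, 1]), 1e-6)
})

test_that("conditioning rejects too-low sampling rates with explanation", {
  r <- emg_recording(matrix(rnorm(600), ncol = 1), fs = 600)
  expect_error(condition_signal(r), "fs >= 700")
})

test_that("windowing: 200/25 ms gives 175 ms overlap and 393 windows per 10 s", {
  r <- emg_recording(matrix(rnorm(10000 * 2), ncol = 2), 1000)
  w <- segment_windows(r, 200, 25)
  expect_identical(attr(w, "overlap_ms"), 175)
  expect_length(w, 393)
  expect_equal(dim(w[[1]]$samples), c(200L, 2L))
  expect_equal(w[[2]]$start_ms - w[[1]]$start_ms, 25)
  # boundary: exactly one window
  r1 <- emg_recording(matrix(rnorm(200), ncol = 1), 1000)
  expect_length(segment_windows(r1, 200, 25), 1)
  # too short: empty with warning
  r0 <- emg_recording(matrix(rnorm(150), ncol = 1), 1000)
  expect_warning(w0 <- segment_windows(r0, 200, 25), "shorter than one window")
  expect_length(w0, 0)
})

test_that("window count matches the closed form over many geometries", {
  for (n in c(200, 201, 449, 1000, 2375, 10000)) {
    for (spec in list(c(200, 25), c(100, 50), c(150, 10))) {
      if (n < spec[1]) next
      r <- emg_recording(matrix(0 * seq_len(n) + 1e-3, ncol = 1), 1000)
      got <- length(segment_windows(r, spec[1], spec[2]))
      expect_equal(got, floor((n - spec[1]) / spec[2]) + 1,
                   info = sprintf("n=%d w=%d s=%d", n, spec[1], spec[2]))
    }
  }
})

test_that("mav matches hand values and rejects empty input", {
  expect_equal(mav(c(1, -1, 1, -1)), 1.0)
  expect_equal(mav(numeric(4)), 0.0)
  expect_equal(mav(c(3, -4)), 3.5)
  expect_error(mav(numeric(0)), "empty")
})

test_that("zero crossings honour the amplitude gate", {
  expect_equal(zero_crossings(c(1, -1, 1, -1), 0), 3)
  expect_equal(zero_crossings(c(2, 1, 3, 0.5), 0), 0)   # strictly positive
  expect_equal(zero_crossings(c(1, -0.001, 1), 0.01), 0) # gated out
  expect_equal(zero_crossings(c(1, -0.001, 1), 0), 2)
})

test_that("slope sign changes count interior reversals", {
  expect_equal(slope_sign_changes(c(0, 1, 0, 1, 0), 0), 3)
  expect_equal(slope_sign_changes(1:10, 0), 0)           # monotone ramp
  expect_equal(slope_sign_changes(rep(2, 10), 0), 0)     # constant
  expect_warning(out <- slope_sign_changes(c(1, 2), 0), "shorter than 3")
  expect_equal(out, 0L)
})

test_that("waveform length sums absolute increments", {
  expect_equal(waveform_length(c(0, 1, 0, 1)), 3.0)
  expect_equal(waveform_length(rep(5, 10)), 0.0)
  expect_equal(waveform_length(c(0, 5)), 5.0)
  expect_warning(out <- waveform_length(3), "shorter than 2")
  expect_equal(out, 0)
})

test_that("Burg AR recovers a known AR(1) and vanishes on white noise", {
  set.seed(42)
  x <- as.numeric(stats::arima.sim(list(ar = 0.5), 10000))
  a <- ar_coefficients(x, 6)
  expect_lt(abs(a[1] - 0.5), 0.05)
  w <- rnorm(10000)
  expect_true(all(abs(ar_coefficients(w, 6)) < 0.05))
  expect_warning(z <- ar_coefficients(numeric(200), 6), "constant")
  expect_identical(z, numeric(6))
})

test_that("feature vectors are 10 per channel, deterministic, ordered", {
  set.seed(1)
  w <- matrix(rnorm(200 * 12), 200, 12,
              dimnames = list(NULL, default_channel_names()))
  fv <- extract_features(w)
  expect_length(fv, 120)
  expect_identical(names(fv)[1:4],
                   c("ant_delt_mav", "ant_delt_zc", "ant_delt_ssc",
                     "ant_delt_wl"))
  expect_length(attr(fv, "mav"), 12)
  expect_identical(fv, extract_features(w))   # determinism
  # all-zero window: degenerate but defined
  z <- suppressWarnings(extract_features(matrix(0, 200, 12)))
  expect_true(all(z == 0))
})

test_that("positive scaling scales MAV/WL and leaves ZC/SSC fixed (zero gate)", {
  set.seed(7)
  w <- matrix(rnorm(200 * 3), 200, 3)
  f1 <- extract_features(w)
  f3 <- extract_features(3.5 * w)
  sel <- function(fv, what) fv[grepl(paste0("_", what, "$"), names(fv))]
  expect_equal(sel(f3, "mav"), 3.5 * sel(f1, "mav"))
  expect_equal(sel(f3, "wl"), 3.5 * sel(f1, "wl"))
  expect_equal(sel(f3, "zc"), sel(f1, "zc"))
  expect_equal(sel(f3, "ssc"), sel(f1, "ssc"))
})
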