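test_that("EMG conditioning recovers rectified-sine envelopes", {
  fs <- 2000
  t <- seq(0, 4, by = 1 / fs)
  A <- 0.8
  env <- process_emg(A * sin(2 * pi * 50 * t), fs)
  mid <- env[round(length(env) * 0.4):round(length(env) * 0.6)]
  # steady-state mean of a rectified sine is 2A/pi
  expect_lt(abs(mean(mid) - 2 * A / pi) / (2 * A / pi), 0.03)
  expect_true(all(env >= 0))
  expect_equal(process_emg(rep(0, 1000), fs), rep(0, 1000))
  expect_error(process_emg(sin(t), 30), "sampling rate")
})

test_that("EMG envelope is invariant to a DC offset in the raw signal", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)
  raw <- 0.5 * sin(2 * pi * 60 * t) * (1 + sin(2 * pi * 1 * t))
  a <- process_emg(raw, fs)
  b <- process_emg(raw + 2.5, fs)
  mid <- seq(round(length(t) * 0.2), round(length(t) * 0.8))
  expect_lt(max(abs(a[mid] - b[mid])), 0.02 * max(a))
})

test_that("MVC normalization caps trial maxima at one", {
  env <- c(0.1, 0.4, 0.5)
  expect_equal(max(normalize_emg(env, 1)), 0.5)
  over <- c(0.2, 1.3)
  expect_equal(max(normalize_emg(over, 1)), 1.0)
  expect_equal(normalize_emg(rep(0, 5), 2), rep(0, 5))
  expect_error(normalize_emg(env, 0), "mvc")
})

test_that("GRF filter passes low and rejects high frequencies", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  gain <- function(f) {
    y <- filter_grf(sin(2 * pi * f * t), fs)
    max(abs(y[mid]))
  }
  expect_gt(gain(1), 0.99)
  expect_lt(gain(50), 10^(-20 / 20))   # > 20 dB attenuation
  expect_equal(filter_grf(rep(5, 500), fs), rep(5, 500), tolerance = 1e-3)
  expect_equal(filter_grf(rep(0, 500), fs), rep(0, 500))
  expect_error(filter_grf(t, 10), "sampling rate")
})

test_that("stride detection matches threshold crossings and debounces", {
  fs <- 100
  contact <- function(starts, len, n, level = 800) {
    g <- numeric(n)
    for (s in starts) g[s:(s + len - 1)] <- level
    g
  }
  n <- 500
  ipsi <- contact(c(50, 150, 250, 350), 60, n)
  contra <- contact(c(100, 200, 300, 400), 60, n)
  ev <- detect_strides(ipsi, contra, fs, threshold = 20)
  expect_equal(ev$ipsi_heel_strikes, c(50L, 150L, 250L, 350L))
  expect_equal(ev$ipsi_toe_offs, c(109L, 209L, 309L, 409L))
  expect_equal(ev$contra_heel_strikes, c(100L, 200L, 300L, 400L))
  # sub-threshold noise creates no events
  noisy <- ipsi + 5 * sin(seq_len(n))
  ev2 <- detect_strides(noisy, contra, fs, threshold = 20)
  expect_equal(ev2$ipsi_heel_strikes, ev$ipsi_heel_strikes)
  # a 1-sample dropout inside stance does not split the contact
  dropped <- ipsi
  dropped[70] <- 0
  ev3 <- detect_strides(dropped, contra, fs, threshold = 20)
  expect_equal(ev3$ipsi_heel_strikes, ev$ipsi_heel_strikes)
  expect_equal(ev3$ipsi_toe_offs, ev$ipsi_toe_offs)
  expect_error(detect_strides(contact(50, 60, n), contra, fs), "heel strikes")
})

test_that("phase partition follows the gait events", {
  # symmetric gait, 65% stance: double supports 15%, single support and
  # swing 35% each
  ev <- structure(list(ipsi_heel_strikes = c(1L, 201L),
                       ipsi_toe_offs = c(131L, 331L),
                       contra_heel_strikes = c(101L, 301L),
                       contra_toe_offs = c(31L, 231L)),
                  class = "stride_events")
  ph <- partition_phases(ev, 1)
  expect_equal(ph$phase, c("ds1", "ss", "ds2", "swing"))
  expect_equal(ph$start, c(0, 0.15, 0.5, 0.65))
  expect_equal(ph$end, c(0.15, 0.5, 0.65, 1))
  # contiguous partition of [0, 1)
  expect_equal(ph$end[-4], ph$start[-1])
  expect_equal(sum(ph$end - ph$start), 1)
  # missing contralateral events are rejected
  ev_bad <- ev; ev_bad$contra_toe_offs <- integer(0)
  expect_error(partition_phases(ev_bad, 1), "contralateral")
})

test_that("default synthetic gait puts phase boundaries near 15/50/65%", {
  tr <- fix_trial()
  ev <- detect_strides(tr$grf_ipsi, tr$grf_contra, tr$fs, threshold = 20)
  ph <- partition_phases(ev, 2)
  expect_lt(abs(ph$end[1] - 0.12), 0.04)
  expect_lt(abs(ph$end[2] - 0.50), 0.02)
  expect_lt(abs(ph$end[3] - 0.62), 0.04)
})

test_that("time normalization preserves constants, ramps and means", {
  expect_equal(time_normalize(rep(3, 100), c(10, 60), 11), rep(3, 11))
  ramp <- seq(0, 99)
  prof <- time_normalize(ramp, c(1, 100), 101)
  expect_equal(prof[1], 0)
  expect_equal(prof[101], 99)
  expect_equal(diff(prof), rep(diff(prof)[1], 100))
  # stride-mean preservation against a dense oracle
  x <- sin(seq(0, 2 * pi, length.out = 1000))^2 + 0.5
  prof2 <- time_normalize(x, c(1, 1000), 1001)
  expect_lt(abs(mean(prof2[-1001]) - mean(x[-1000])) / mean(x), 0.005)
  expect_error(time_normalize(x, c(50, 50), 101), "empty")
})

test_that("outlier removal applies the median +/- 3 IQR rule", {
  # median 12, IQR 2 -> bounds [6, 18], so 100 is removed
  r <- remove_outliers(c(10, 11, 12, 13, 100))
  expect_equal(r$values, c(10, 11, 12, 13))
  expect_equal(r$keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(remove_outliers(rep(7, 5))$keep))
  expect_true(all(remove_outliers(c(1, 2, 3, 4, 5))$keep))
  expect_error(remove_outliers(c(1, 2)), "at least 3")
})

test_that("net metabolic rate is the Brockway sum minus standing", {
  expect_equal(net_metabolic_rate(0, 0, 1.4, 80), -1.4)
  one <- net_metabolic_rate(10, 8, 0, 80)
  expect_equal(net_metabolic_rate(20, 16, 0, 80), 2 * one)
  # independent hand computation with the default coefficients
  expect_equal(net_metabolic_rate(15, 12.75, 1.4, 79.9),
               (16.58 * 15 + 4.51 * 12.75) / 79.9 - 1.4)
  expect_error(net_metabolic_rate(-1, 0, 1, 80), "nonnegative")
})
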