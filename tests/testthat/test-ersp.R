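test_that("scale/frequency mapping matches the wavelet's centre frequency", {
  wp <- wavelet_params(fs = 512)
  expect_equal(scale_for_frequency(8, wp), 64)
  expect_equal(scale_for_frequency(16, wp), 32)
  expect_equal(scale_for_frequency(512, wp), 1)
  expect_error(scale_for_frequency(0, wp), "freq")
  expect_error(scale_for_frequency(600, wp), "freq")
  expect_error(scale_grid(300, wp), "fs/2")
})

test_that("a tone is localized at its own scale and null input gives null
           power", {
  fs <- 512
  time <- seq(0, 4 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * time)
  P <- cwt_power(matrix(x, 1), freqs = 4:32, params = wavelet_params(fs = fs))
  prof <- apply(P[1, , 300:1700], 1, mean)
  expect_equal((4:32)[which.max(prof)], 10)
  # on-scale power is approximately constant along time (interior)
  tr <- P[1, 7, 300:1700]
  expect_lt(diff(range(tr)) / mean(tr), 0.01)

  P0 <- cwt_power(matrix(0, 1, 2048), freqs = 8:13,
                  params = wavelet_params(fs = fs))
  expect_equal(max(P0), 0)
})

test_that("power follows the amplitude-squared law across a step", {
  fs <- 512
  time <- seq(0, 4 - 1 / fs, by = 1 / fs)
  amp <- ifelse(time < 2, 1, 2)
  x <- amp * sin(2 * pi * 10 * time)
  P <- cwt_power(matrix(x, 1), freqs = 10, params = wavelet_params(fs = fs))
  early <- mean(P[1, 1, time > 0.5 & time < 1.5])
  late <- mean(P[1, 1, time > 2.5 & time < 3.5])
  expect_equal(late / early, 4, tolerance = 0.02)
})

test_that("ERSP is zero-mean over the baseline window and invariant to
           global rescaling", {
  ep <- tone_epochs(8, function(time) rep(1, length(time)), seed = 3)
  er <- compute_ersp(ep, freqs = seq(8, 13), group_by_target = FALSE)
  bmean <- apply(er$values[, , er$time < 0, drop = FALSE], c(1, 2), mean)
  expect_equal(max(abs(bmean)), 0, tolerance = 1e-9)

  ep2 <- ep
  ep2$data <- ep2$data * 37.5
  er2 <- compute_ersp(ep2, freqs = seq(8, 13), group_by_target = FALSE)
  expect_equal(er2$values, er$values, tolerance = 1e-9)
})

test_that("zero baseline power is a named error", {
  ep <- make_epochs(2, 1, fs = 512, make = function(i, time)
    matrix(0, 1, length(time)))
  expect_error(suppressWarnings(
    compute_ersp(ep, freqs = 10, group_by_target = FALSE)),
    "zero baseline power at frequency 10")
})

test_that("a stationary tone gives ~0% ERSP and a gain-0.5 ramp gives
           ~ -75% in the late window", {
  amp_null <- function(time) rep(1, length(time))
  amp_erd <- function(time)
    ifelse(time < 0.5, 1, ifelse(time < 1, 1 - (time - 0.5), 0.5))
  er0 <- compute_ersp(tone_epochs(20, amp_null, seed = 8),
                      freqs = 4:32, group_by_target = FALSE)
  w0 <- window_average(band_average(er0, c(8, 13)), c(1, 2))
  expect_lt(abs(w0), 3)

  er1 <- compute_ersp(tone_epochs(20, amp_erd, seed = 8),
                      freqs = 4:32, group_by_target = FALSE)
  w1 <- window_average(band_average(er1, c(8, 13)), c(1, 2))
  expect_equal(unname(w1), -75, tolerance = 5)
})

test_that("band and window reductions are plain means with half-open
           boundaries", {
  er <- structure(list(
    values = array(rep(c(-10, -30, -20, -20), each = 1),
                   dim = c(1, 4, 3)),
    per_target = list(), freqs = c(8, 12, 13, 30), time = c(0, 1, 2),
    fs = 1, labels = "roi", baseline_window = c(-1, 0)),
    class = "ersp_map")
  er$values[1, , ] <- c(-10, -30, -20, -20)  # constant over time per freq
  # alpha [8,13) picks 8 and 12 only
  ba <- band_average(er, c(8, 13))
  expect_equal(unname(ba$values[1, 1]), -20)
  # beta [13,30] closed picks 13 and 30
  bb <- band_average(er, c(13, 30), include_upper = TRUE)
  expect_equal(unname(bb$values[1, 1]), -20)
  expect_error(band_average(er, c(100, 120)), "intersect")

  ramp <- structure(list(values = matrix(seq(0, -30, length.out = 10), 1),
                         band = c(8, 13),
                         time = seq(1, 1.9, by = 0.1), labels = "roi"),
                    class = "band_ersp")
  expect_equal(unname(window_average(ramp, c(1, 2))), -15)
  con <- ramp; con$values[] <- -15
  expect_equal(unname(window_average(con, c(1, 2))), -15)
  expect_error(window_average(ramp, c(5, 6)), "empty")
})

test_that("per-target grouping yields one map per target plus their
           average", {
  ep <- tone_epochs(12, function(time) rep(1, length(time)), seed = 2)
  ep$targets <- rep(1:3, each = 4)
  er <- compute_ersp(ep, freqs = c(9, 10, 11))
  expect_named(er$per_target, c("target1", "target2", "target3"))
  expect_equal(er$values,
               (er$per_target[[1]] + er$per_target[[2]] +
                  er$per_target[[3]]) / 3)
})

test_that("coi_mask excludes the scale-dependent edge region", {
  m <- coi_mask(c(8, 32), 2048, wavelet_params(fs = 512))
  expect_false(any(m[1, 1:100]))
  expect_true(all(m[2, 60:1980]))
  expect_gt(sum(m[2, ]), sum(m[1, ]))   # higher frequency -> narrower cone
})
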