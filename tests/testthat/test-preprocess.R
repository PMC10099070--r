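test_that("linear_detrend removes exactly the least-squares line", {
  t <- seq_len(500)
  rec <- continuous_recording(rbind(3 * t + 7, rep(0, 500)), fs = 100)
  out <- linear_detrend(rec)
  expect_equal(max(abs(out$data)), 0, tolerance = 1e-9)

  # ramp + sinusoid: result equals the sinusoid minus its own fitted line
  s <- sin(2 * pi * 5 * t / 100)
  rec2 <- continuous_recording(rbind(2 * t - 1 + s), fs = 100)
  fit <- lm(s ~ t)
  expect_equal(drop(linear_detrend(rec2)$data), unname(residuals(fit)),
               tolerance = 1e-9)
})

test_that("bandpass_notch suppresses 50 Hz, keeps 10 Hz, confines noise
           to the passband", {
  fs <- 512
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))
  mid <- seq(fs, length(t) - fs)      # avoid filter edge transients

  r50 <- bandpass_notch(continuous_recording(rbind(sin(2 * pi * 50 * t)), fs))
  expect_lt(rms(r50$data[1, mid]), 0.1 * rms(sin(2 * pi * 50 * t)))

  r10 <- bandpass_notch(continuous_recording(rbind(sin(2 * pi * 10 * t)), fs))
  expect_equal(rms(r10$data[1, mid]), rms(sin(2 * pi * 10 * t)),
               tolerance = 0.05)

  set.seed(2)
  rn <- bandpass_notch(continuous_recording(rbind(rnorm(length(t))), fs))
  x <- rn$data[1, ]
  pg <- Mod(fft(x))^2
  f <- (seq_along(pg) - 1) * fs / length(pg)
  f <- pmin(f, fs - f)                     # fold to one-sided frequencies
  expect_gt(sum(pg[f >= 1 & f <= 60]) / sum(pg), 0.90)
  # including the Butterworth transition bands the mass is near-total
  expect_gt(sum(pg[f >= 0.5 & f <= 70]) / sum(pg), 0.95)

  expect_error(bandpass_notch(r10, low = 60, high = 1), "low < high")
})

test_that("epoch_recording cuts one trial per in-bounds cue and labels it", {
  fs <- 100
  n <- 5000
  dat <- rbind(seq_len(n), rep(1, n))
  ev <- data.frame(sample = c(30, 500, 1000, 4950),   # first & last OOB
                   code = c(1, 2, 3, 4))
  rec <- continuous_recording(dat, fs, events = ev)
  expect_warning(ep <- epoch_recording(rec, -1, 3), "2 epoch")
  expect_equal(dim(ep$data)[1], 2L)
  expect_equal(ep$targets, c(2L, 3L))
  expect_equal(ep$time[1], -1)
  expect_equal(dim(ep$data)[3], 400L)
  # slicing preserves values: channel 1 is the sample index
  expect_equal(ep$data[1, 1, ], seq(500 - 100, length.out = 400))
  expect_equal(ep$data[1, 2, ], rep(1, 400))
})

test_that("baseline_correct subtracts the rest-window mean and is
           idempotent", {
  ep <- make_epochs(2, 1, fs = 10, make = function(i, time)
    matrix(ifelse(time < 0, 2, 5), 1))
  out <- baseline_correct(ep)
  expect_equal(unique(out$data[1, 1, out$time < 0]), 0)
  expect_equal(unique(out$data[1, 1, out$time >= 0]), 3)

  ep7 <- make_epochs(1, 2, fs = 10, make = function(i, time)
    matrix(7, 2, length(time)))
  expect_equal(max(abs(baseline_correct(ep7)$data)), 0)

  out2 <- baseline_correct(out)
  expect_equal(out2$data, out$data)
  expect_error(baseline_correct(ep, c(5, 6)), "empty")
})

test_that("common average reference zeroes the channel mean everywhere", {
  c1 <- sin(seq(0, 10, length.out = 40))
  ep <- make_epochs(1, 2, fs = 10, make = function(i, time)
    rbind(c1, -c1))
  expect_equal(common_average_reference(ep)$data, ep$data)

  ep2 <- make_epochs(1, 2, fs = 10, make = function(i, time) rbind(c1, c1))
  expect_equal(max(abs(common_average_reference(ep2)$data)), 0)

  ep3 <- make_epochs(3, 3, fs = 10, make = function(i, time)
    matrix(c(1, 2, 3), 3, length(time)))
  out3 <- common_average_reference(ep3)
  expect_equal(out3$data[2, , 5], c(-1, 0, 1))
  expect_equal(max(abs(apply(out3$data, c(1, 3), sum))), 0,
               tolerance = 1e-12)

  ep1 <- make_epochs(1, 1, fs = 10, make = function(i, time)
    matrix(1, 1, length(time)))
  expect_error(common_average_reference(ep1), "2 channels")
})

test_that("roi_aggregate flips anti-aligned vertices before averaging", {
  s <- sin(seq(0, 20, length.out = 100))
  n <- c(0, 0, 1)
  # antiparallel orientations carrying sign-flipped copies of one source
  expect_equal(roi_aggregate(rbind(s, -s), rbind(n, -n)), s)
  # single vertex: identity up to a global sign
  expect_equal(abs(roi_aggregate(rbind(s), rbind(n))), abs(s))
  # co-oriented vertices: plain average
  s2 <- cos(seq(0, 20, length.out = 100)); s3 <- s + s2
  expect_equal(roi_aggregate(rbind(s, s2, s3),
                             rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0))),
               (s + s2 + s3) / 3)
  expect_error(roi_aggregate(rbind(s), rbind(c(0, 0, 0))), "zero orientation")
})

test_that("roi_aggregate magnitude is invariant to a global flip", {
  set.seed(5)
  for (rep in 1:5) {
    o <- matrix(rnorm(15), 5, 3)
    o <- o / sqrt(rowSums(o^2))
    sig <- matrix(rnorm(5 * 50), 5, 50)
    a <- roi_aggregate(sig, o)
    b <- roi_aggregate(-sig, -o)
    expect_equal(abs(a), abs(b), tolerance = 1e-12)
  }
})

test_that("decimation subsamples the axis and rescales fs", {
  ep <- make_epochs(2, 2, fs = 512, make = function(i, time)
    rbind(time, 2 * time))
  dec <- decimate_epochs(ep, 4)
  expect_equal(dec$fs, 128)
  expect_equal(dim(dec$data)[3], 512)
  expect_equal(dec$data[1, 1, ], ep$data[1, 1, seq(1, 2048, by = 4)])
  expect_equal(dec$time[1], -1)
})
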