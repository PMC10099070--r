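test_that("remove_evoked subtracts the across-trial mean per target group", {
  # identical trials = pure evoked -> zeros
  ep <- make_epochs(4, 2, fs = 64, make = function(i, time)
    rbind(sin(2 * pi * time), cos(2 * pi * time)))
  expect_equal(max(abs(remove_evoked(ep, FALSE)$data)), 0)

  # template + noise: the residual is uncorrelated with the template
  set.seed(11)
  tmpl <- sin(2 * pi * 3 * seq(-1, 3 - 1 / 64, by = 1 / 64))
  ep2 <- make_epochs(40, 1, fs = 64, make = function(i, time)
    matrix(tmpl + rnorm(length(time)), 1))
  out <- remove_evoked(ep2, FALSE)
  cors <- apply(out$data[, 1, ], 1, cor, y = tmpl)
  expect_lt(max(abs(cors)), 0.2)
  expect_equal(max(abs(apply(out$data, c(2, 3), mean))), 0,
               tolerance = 1e-12)

  ep3 <- ep
  ep3$targets <- c(1L, 1L, 1L, 2L)
  expect_error(remove_evoked(ep3), "2 trials")
})

test_that("extract_windows cuts half-open demeaned 1 s segments", {
  ep <- make_epochs(3, 2, fs = 512, targets = c(1L, 2L, 1L),
                    make = function(i, time) rbind(time + i, time - i))
  sb <- extract_windows(ep, c(-1, 0))
  sp <- extract_windows(ep, c(1, 2))
  expect_equal(dim(sb$data)[3], 512)
  expect_equal(dim(sb$data)[1], dim(sp$data)[1])
  expect_equal(max(abs(apply(sb$data, c(1, 2), mean))), 0,
               tolerance = 1e-12)
  expect_error(extract_windows(ep, c(2.5, 3.5)), "outside epoch")
})

test_that("the bivariate fit recovers known coefficients and white noise", {
  m <- build_var_model(2, 2,
                       edges = list(c(1, 2, 1, 0.4), c(2, 1, 2, -0.3)),
                       self_decay = c(0.4, 0.2))
  x <- simulate_var(m, 512, n_trials = 120, seed = 21)
  fit <- fit_bivariate_var(x[, 1, ], x[, 2, ], order = 2)
  expect_equal(fit$coeffs, m$coeffs, tolerance = 0.05)
  expect_equal(fit$resid_cov, diag(2), tolerance = 0.05)

  set.seed(3)
  w1 <- matrix(rnorm(40 * 512), 40); w2 <- matrix(rnorm(40 * 512), 40)
  fw <- fit_bivariate_var(w1, w2, order = 5)
  expect_lt(max(abs(fw$coeffs)), 0.05)
  expect_equal(fw$resid_cov, diag(2), tolerance = 0.05)

  expect_error(fit_bivariate_var(w1[, 1:100], w2[, 1:100], order = 200),
               "exceed the order")
})

test_that("gc_spectrum is zero for uncoupled fits and matches the analytic
           oracle on true coefficients", {
  fit0 <- structure(list(order = 1L,
                         coeffs = array(c(0.5, 0, 0, 0.5), c(1, 2, 2)),
                         resid_cov = diag(2), n_effective = 1000L),
                    class = "bivariate_var_fit")
  sp0 <- gc_spectrum(fit0, seq(1, 45, 0.5), 512)
  expect_true(all(sp0$x_to_y == 0) && all(sp0$y_to_x == 0))

  m <- ref_var2()
  fit <- structure(list(order = 1L, coeffs = m$coeffs,
                        resid_cov = m$noise_cov, n_effective = 1000L),
                   class = "bivariate_var_fit")
  freqs <- seq(1, 45, 0.5)
  sp <- gc_spectrum(fit, freqs, 512)
  ga <- analytic_spectral_gc(m, freqs)
  expect_lt(max(abs(sp$x_to_y - ga[1, 2, ])), 1e-10)
  expect_lt(max(abs(sp$y_to_x - ga[2, 1, ])), 1e-10)
  expect_true(sp$stable)
})

test_that("band-averaged GC estimates converge to the analytic value with
           data length", {
  m <- ref_var2()
  freqs <- seq(8, 12.5, 0.5)
  truth <- mean(analytic_spectral_gc(m, freqs)[1, 2, ])
  err <- vapply(c(10, 60, 300), function(secs) {
    errs <- vapply(1:7, function(r) {
      x <- simulate_var(m, 512, n_trials = secs, seed = 700 * r + secs)
      fit <- fit_bivariate_var(x[, 1, ], x[, 2, ], order = 30)
      abs(mean(suppressWarnings(
        gc_spectrum(fit, freqs, 512))$x_to_y) - truth)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("build_gc_matrices fills all ordered pairs with nonnegative
           values and a planted edge dominates the contrast", {
  truth <- small_truth(erd_gain = 1)
  truth$var_postcue <- build_var_model(
    4, 2, edges = list(c(3, 2, 1, 0.3)), self_decay = c(0.5, -0.1),
    noise_cov = diag(0.09, 4))
  ds <- generate_reaching_dataset(n_subjects = 1, trials_per_target = 8,
                                  truth = truth, seed = 17)
  ep <- remove_evoked(ds$subjects[[1]])
  mats <- build_gc_matrices(ep, order = 10)
  expect_named(mats, c("alpha", "beta"))
  expect_named(mats$alpha, c("baseline", "post_cue_late"))
  for (b in names(mats)) for (w in names(mats[[b]])) {
    v <- mats[[b]][[w]]$values
    expect_true(all(diag(v) == 0))
    expect_true(all(v >= 0))
    expect_equal(sum(v > 0), 12)      # all ordered off-diagonal pairs
  }
  d <- mats$alpha$post_cue_late$values - mats$alpha$baseline$values
  expect_equal(which.max(d), which(outer(1:4, 1:4, function(i, j)
    i == 3 & j == 2)))
})

test_that("normalization yields unit off-diagonal sum, is idempotent and
           scale-invariant", {
  v <- matrix(c(0, 3, 1, 0), 2)
  n1 <- normalize_gc(v)
  expect_equal(n1[2, 1], 0.75)
  expect_equal(n1[1, 2], 0.25)
  expect_equal(normalize_gc(n1), n1)
  expect_equal(normalize_gc(17 * v), n1)
  expect_error(normalize_gc(matrix(0, 3, 3)), "cannot normalize")

  set.seed(1)
  r <- matrix(abs(rnorm(16)), 4); diag(r) <- 0
  rn <- normalize_gc(r)
  expect_equal(sum(rn) - sum(diag(rn)), 1, tolerance = 1e-12)
})
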