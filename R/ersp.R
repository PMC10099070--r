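#' Complex Morlet wavelet parameters
#'
#' The mother wavelet is `cmorB-C`:
#' \deqn{\psi(t) = (\pi B)^{-1/2} e^{-t^2/B} e^{i 2 \pi C t}}
#' with bandwidth `B` and normalized centre frequency `C` (cycles per
#' sampling period). At sampling rate `fs` the mother wavelet's effective
#' centre frequency is `C * fs` (512 Hz for the defaults), and a daughter at
#' scale `a` analyses `C * fs / a` Hz.
#'
#' @param bandwidth Bandwidth parameter B (default 1.5).
#' @param center_freq_norm Normalized centre frequency C (default 1.0).
#' @param fs Sampling rate in Hz.
#' @return A `wavelet_params` object.
#' @export
wavelet_params <- function(bandwidth = 1.5, center_freq_norm = 1.0, fs = 512) {
  stopifnot(bandwidth > 0, center_freq_norm > 0, fs > 0)
  structure(list(bandwidth = bandwidth, center_freq_norm = center_freq_norm,
                 fs = fs), class = "wavelet_params")
}

#' Wavelet scale analysing a given frequency
#'
#' `scale = fs * C / freq`: e.g. 8 Hz at 512 Hz with C = 1 maps to scale 64,
#' and the mother-wavelet frequency `C * fs` maps to scale 1.
#'
#' @param freq Frequency in Hz (0 < freq <= fs * C).
#' @param params A [wavelet_params()].
#' @return The scale (dimensionless, in samples per wavelet period).
#' @export
scale_for_frequency <- function(freq, params = wavelet_params()) {
  lim <- params$fs * params$center_freq_norm
  if (any(freq <= 0) || any(freq > lim))
    stop("freq must lie in (0, fs * C] = (0, ", lim, "]")
  params$fs * params$center_freq_norm / freq
}

#' Scale grid for a set of analysis frequencies
#'
#' @param freqs Analysis frequencies in Hz, all within `(0, fs/2]`.
#' @param params A [wavelet_params()].
#' @return List with `freqs` and the matching `scales`.
#' @export
scale_grid <- function(freqs, params = wavelet_params()) {
  if (any(freqs <= 0) || any(freqs > params$fs / 2))
    stop("analysis frequencies must lie in (0, fs/2]")
  list(freqs = freqs, scales = scale_for_frequency(freqs, params))
}

# Extend the columns of X by `pad` samples on both sides via autoregressive
# (Burg) extrapolation. A stationary AR forecast continues every narrowband
# component phase-coherently (backward prediction reuses the forward
# coefficients, valid for a stationary process), so a wavelet centred near
# an epoch edge sees an uninterrupted oscillation instead of a truncation.
.ar_extend <- function(X, pad, order = 30) {
  ns <- nrow(X); nc <- ncol(X)
  ord <- max(2L, min(order, ns - 2L, floor(ns / 3)))
  Phi <- matrix(0, ord, nc)
  for (j in seq_len(nc)) {
    xj <- X[, j]
    if (stats::var(xj) < .Machine$double.xmin) next
    a <- tryCatch(stats::ar.burg(xj, aic = FALSE, order.max = ord,
                                 demean = TRUE),
                  error = function(e) NULL)
    if (!is.null(a) && length(a$ar)) Phi[seq_along(a$ar), j] <- a$ar
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  forecast <- function(tail_chron) {
    # tail_chron: ord x nc, chronological (last row = most recent sample)
    ext <- rbind(tail_chron, matrix(0, pad, nc))
    for (t in seq_len(pad)) {
      lagrows <- ext[(ord + t - 1):t, , drop = FALSE]   # lags 1..ord
      ext[ord + t, ] <- colSums(Phi * lagrows)
    }
    ext[(ord + 1):(ord + pad), , drop = FALSE]
  }
  fwd <- forecast(Xc[(ns - ord + 1):ns, , drop = FALSE])
  bwd <- forecast(Xc[ord:1, , drop = FALSE])            # time-reversed
  rbind(sweep(bwd[pad:1, , drop = FALSE], 2, mu, "+"), X,
        sweep(fwd, 2, mu, "+"))
}

# CWT power of signals in the columns of X (ns x ncols), via FFT
# convolution with L2-normalized daughters. With `edge_correction` the
# signals are first extended by AR extrapolation (see .ar_extend) so the
# finite epoch does not bias power estimates near its edges: a truncation
# discontinuity would both attenuate on-peak power and smear tone energy
# into neighbouring frequencies there. Without it, plain zero padding is
# used. Returns list(power = ncols x nfreq x ns array, pad = samples of
# extension used).
.cwt_power_core <- function(X, scales, bandwidth, center, edge_correction,
                            t_cut = 5) {
  ns <- nrow(X); ncols <- ncol(X); B <- bandwidth
  halfmax <- ceiling(t_cut * max(scales))
  pad <- if (edge_correction) halfmax else 0L
  Xp <- if (pad > 0) .ar_extend(X, pad) else X
  np <- ns + 2 * pad
  nfft <- stats::nextn(np + 2 * halfmax + 1, 2)
  FX <- stats::mvfft(rbind(Xp, matrix(0, nfft - np, ncols)))
  keep <- (pad + 1):(pad + ns)
  P <- array(0, dim = c(ncols, length(scales), ns))
  for (si in seq_along(scales)) {
    a <- scales[si]
    half <- ceiling(t_cut * a)
    u <- (-half:half) / a
    psi <- (pi * B)^(-0.5) * exp(-u^2 / B) * exp(2i * pi * center * u) / sqrt(a)
    arr <- complex(length.out = nfft)
    arr[1:(half + 1)] <- psi[(half + 1):(2 * half + 1)]   # n = 0..half
    arr[(nfft - half + 1):nfft] <- psi[1:half]            # n = -half..-1
    K <- Conj(stats::fft(arr))
    W <- stats::mvfft(FX * K, inverse = TRUE)[keep, , drop = FALSE] / nfft
    P[, si, ] <- t(Mod(W)^2)
  }
  list(power = P, pad = pad)
}

#' Per-trial time-frequency power via complex Morlet CWT
#'
#' Squared modulus of the continuous wavelet transform at the scales
#' matching `freqs`. By default each signal is first extended beyond the
#' epoch by autoregressive (Burg) extrapolation, which continues narrowband
#' components phase-coherently so power estimates near the epoch edges are
#' not biased by truncation (with `edge_correction = FALSE` plain zero
#' padding is used instead). Cone-of-influence masking is additionally
#' available via [coi_mask()] but is not applied by default.
#'
#' A warning flags scales whose wavelet support exceeds the epoch length
#' (strong edge effects); computation proceeds.
#'
#' @param x An [epoch_set()] or a numeric matrix `signals x samples`.
#' @param freqs Analysis frequencies in Hz (default 4-32 Hz in 1 Hz steps).
#' @param params A [wavelet_params()]; its `fs` must match the data.
#' @param edge_correction Extend signals by AR extrapolation before the
#'   transform (recommended whenever an analysis window abuts an epoch
#'   edge, as the baseline window does).
#' @return For a matrix input, an array `signals x freq x time`. For an
#'   `epoch_set`, a `trial_power` object: list with `power`
#'   (`trials x channels x freq x time`), `freqs`, `time`, `fs`, `targets`,
#'   `labels`.
#' @export
cwt_power <- function(x, freqs = 4:32, params = NULL,
                      edge_correction = TRUE) {
  if (inherits(x, "epoch_set")) {
    if (is.null(params)) params <- wavelet_params(fs = x$fs)
    if (abs(params$fs - x$fs) > 1e-9) stop("params$fs must match data fs")
    d <- dim(x$data)
    Xm <- t(matrix(x$data, d[1] * d[2], d[3]))      # samples x (trial*chan)
    res <- .cwt_check_and_run(Xm, freqs, params, edge_correction)
    P <- array(res$power, dim = c(d[1], d[2], length(freqs), d[3]))
    return(structure(list(power = P, freqs = freqs, time = x$time,
                          fs = x$fs, targets = x$targets, labels = x$labels,
                          pad = res$pad),
                     class = "trial_power"))
  }
  x <- rbind(x)
  if (is.null(params)) params <- wavelet_params()
  .cwt_check_and_run(t(x), freqs, params, edge_correction)$power
}

.cwt_check_and_run <- function(Xm, freqs, params, edge_correction) {
  g <- scale_grid(freqs, params)
  ns <- nrow(Xm)
  sup <- 2 * ceiling(5 * max(g$scales))
  if (sup > ns)
    warning(sprintf(
      "widest wavelet support (%d samples) exceeds the epoch (%d samples); edge effects dominate the lowest frequencies", sup, ns))
  res <- .cwt_power_core(Xm, g$scales, params$bandwidth,
                         params$center_freq_norm, edge_correction)
  list(power = res$power, pad = res$pad)
}

#' Cone-of-influence mask for a CWT power map
#'
#' `TRUE` where the sample is farther than `n_sigma` wavelet time standard
#' deviations (`sigma_t = scale * sqrt(B/2)` samples) from both epoch edges.
#'
#' @param freqs Analysis frequencies in Hz.
#' @param n_samples Epoch length in samples.
#' @param params A [wavelet_params()].
#' @param n_sigma Width of the excluded edge region in wavelet sigmas.
#' @return Logical matrix `freq x time`.
#' @export
coi_mask <- function(freqs, n_samples, params = wavelet_params(),
                     n_sigma = 2) {
  scales <- scale_for_frequency(freqs, params)
  sig <- scales * sqrt(params$bandwidth / 2) * n_sigma
  t(vapply(sig, function(s) {
    i <- seq_len(n_samples)
    i > s & i <= n_samples - s
  }, logical(n_samples)))
}

#' Event-related spectral perturbation (percent change from baseline)
#'
#' Power is first averaged across trials (separately per reaching target
#' when `group_by_target`); then, per frequency, the average baseline power
#' `B(f)` over the rest window is computed and
#' \deqn{ERSP(t, f) = 100 \cdot (P(t, f) - B(f)) / B(f).}
#' Per-target maps are always retained; the cross-target average (the final
#' map used once targets have been shown not to differ) is taken of the
#' per-target normalized maps.
#'
#' @param x An [epoch_set()] (power computed internally, trial-chunked to
#'   bound memory) or a `trial_power` object from [cwt_power()].
#' @param freqs Analysis frequencies in Hz (used when `x` is an
#'   `epoch_set`).
#' @param baseline_window Baseline window in seconds, half-open.
#' @param group_by_target Average trials separately per target first.
#' @param average_targets Also compute the cross-target average map.
#' @param params,edge_correction Passed to [cwt_power()].
#' @param chunk_trials Trials per CWT batch (memory/speed trade-off).
#' @return An `ersp_map`: list with `values` (ROI x freq x time cross-target
#'   average, percent), `per_target` (named list of such arrays), `freqs`,
#'   `time`, `fs`, `labels`, `baseline_window`.
#' @export
compute_ersp <- function(x, freqs = 4:32, baseline_window = c(-1, 0),
                         group_by_target = TRUE, average_targets = TRUE,
                         params = NULL, edge_correction = TRUE,
                         chunk_trials = 32) {
  if (inherits(x, "trial_power")) {
    pow <- x$power; time <- x$time; fs <- x$fs
    freqs <- x$freqs; targets <- x$targets; labels <- x$labels
    groups <- if (group_by_target) sort(unique(targets)) else 1L
    mean_pow <- lapply(groups, function(g) {
      sel <- if (group_by_target) which(targets == g) else seq_len(dim(pow)[1])
      if (length(sel) < 1) stop("no trials for target ", g)
      apply(pow[sel, , , , drop = FALSE], c(2, 3, 4), mean)
    })
  } else {
    stopifnot(inherits(x, "epoch_set"))
    if (is.null(params)) params <- wavelet_params(fs = x$fs)
    time <- x$time; fs <- x$fs; targets <- x$targets; labels <- x$labels
    d <- dim(x$data)
    groups <- if (group_by_target) sort(unique(targets)) else 1L
    mean_pow <- lapply(groups, function(g) {
      sel <- if (group_by_target) which(targets == g) else seq_len(d[1])
      if (length(sel) < 1) stop("no trials for target ", g)
      acc <- array(0, dim = c(d[2], length(freqs), d[3]))
      for (chunk in split(sel, ceiling(seq_along(sel) / chunk_trials))) {
        Xm <- t(matrix(x$data[chunk, , , drop = FALSE],
                       length(chunk) * d[2], d[3]))
        P <- .cwt_check_and_run(Xm, freqs, params, edge_correction)$power
        P <- array(P, dim = c(length(chunk), d[2], length(freqs), d[3]))
        acc <- acc + apply(P, c(2, 3, 4), sum)
      }
      acc / length(sel)
    })
  }
  bidx <- .win_idx(time, baseline_window, "baseline window")
  per_target <- lapply(mean_pow, function(P) {
    B <- apply(P[, , bidx, drop = FALSE], c(1, 2), mean)
    if (any(B <= .Machine$double.eps)) {
      bad <- which(B <= .Machine$double.eps, arr.ind = TRUE)[1, ]
      stop(sprintf("zero baseline power at frequency %g Hz (channel %s)",
                   freqs[bad[2]], labels[bad[1]]))
    }
    100 * (P - as.vector(B)) / as.vector(B)   # recycle over time
  })
  names(per_target) <- paste0("target", groups)
  values <- if (average_targets || length(per_target) == 1L)
    Reduce(`+`, per_target) / length(per_target) else NULL
  structure(list(values = values, per_target = per_target, freqs = freqs,
                 time = time, fs = fs, labels = labels,
                 baseline_window = baseline_window),
            class = "ersp_map")
}

#' @export
print.ersp_map <- function(x, ...) {
  cat(sprintf("<ersp_map> %d ROIs x %d freqs (%g-%g Hz) x %d samples; %d target group(s)\n",
              length(x$labels), length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$time), length(x$per_target)))
  invisible(x)
}

#' Average an ERSP map over a frequency band
#'
#' Unweighted mean over the grid frequencies inside the band. The band is
#' half-open `[low, high)` by default so that the 13 Hz boundary shared by
#' alpha (8-13 Hz) and beta (13-30 Hz) is never double-counted; pass
#' `include_upper = TRUE` for the closed upper edge of the beta band.
#'
#' @param ersp An `ersp_map`.
#' @param band `c(low, high)` in Hz.
#' @param include_upper Include frequencies equal to the upper edge.
#' @param per_target Reduce the per-target maps instead of the average map.
#' @return A `band_ersp`: list with `values` (ROI x time matrix, percent; or
#'   a per-target list), `band`, `time`, `labels`.
#' @export
band_average <- function(ersp, band, include_upper = FALSE,
                         per_target = FALSE) {
  sel <- ersp$freqs >= band[1] &
    (ersp$freqs < band[2] | (include_upper & ersp$freqs <= band[2]))
  if (!any(sel))
    stop(sprintf("band [%g, %g%s Hz does not intersect the frequency grid",
                 band[1], band[2], if (include_upper) "]" else ")"))
  red <- function(v) apply(v[, sel, , drop = FALSE], c(1, 3), mean)
  values <- if (per_target) lapply(ersp$per_target, red) else red(ersp$values)
  structure(list(values = values, band = band, time = ersp$time,
                 labels = ersp$labels), class = "band_ersp")
}

#' Average a band ERSP trace over a time window
#'
#' @param band_ersp A `band_ersp` from [band_average()].
#' @param window Time window `c(start, end)` in seconds, half-open; default
#'   the late post-cue (movement preparation) window 1-2 s.
#' @return Named numeric vector: one percent value per ROI.
#' @export
window_average <- function(band_ersp, window = c(1, 2)) {
  idx <- .win_idx(band_ersp$time, window)
  v <- band_ersp$values
  if (is.list(v)) stop("window_average expects a single band trace matrix")
  stats::setNames(rowMeans(v[, idx, drop = FALSE]), band_ersp$labels)
}
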