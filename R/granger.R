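#' Remove the across-trial evoked component
#'
#' Subtracts, per channel (and per reaching target when grouped, since
#' different targets can evoke different responses), the across-trial mean
#' waveform from every trial. Residual phase-locked activity would otherwise
#' leak non-stationarity into the autoregressive connectivity fit.
#'
#' @param epochs An `epoch_set` with >= 2 trials per group.
#' @param group_by_target Subtract a separate evoked estimate per target.
#' @return The evoked-removed `epoch_set`.
#' @export
remove_evoked <- function(epochs, group_by_target = TRUE) {
  groups <- if (group_by_target) unique(epochs$targets) else 1L
  for (g in groups) {
    sel <- if (group_by_target) which(epochs$targets == g)
           else seq_len(dim(epochs$data)[1])
    if (length(sel) < 2)
      stop("evoked removal needs >= 2 trials per group (target ", g, ")")
    m <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
    epochs$data[sel, , ] <- sweep(epochs$data[sel, , , drop = FALSE],
                                  c(2, 3), m)
  }
  epochs
}

#' Extract per-trial analysis windows
#'
#' Cuts the half-open window out of every trial and removes the per-segment
#' mean (per trial and channel), producing the segments the concatenated
#' VAR fit consumes. Lags never span a segment boundary downstream.
#'
#' @param epochs An `epoch_set`.
#' @param window `c(start, end)` seconds, within the epoch.
#' @return A `window_segments` object: list with `data`
#'   (`trials x channels x samples`, demeaned), `fs`, `window`, `labels`,
#'   `targets`.
#' @export
extract_windows <- function(epochs, window) {
  if (window[1] < epochs$time[1] - 1e-9 ||
      window[2] > epochs$time[length(epochs$time)] + 1 / epochs$fs + 1e-9)
    stop(sprintf("window [%g, %g) outside epoch [%g, %g]",
                 window[1], window[2], epochs$time[1],
                 epochs$time[length(epochs$time)]))
  idx <- .win_idx(epochs$time, window)
  seg <- epochs$data[, , idx, drop = FALSE]
  m <- apply(seg, c(1, 2), mean)
  seg <- seg - as.vector(m)
  structure(list(data = seg, fs = epochs$fs, window = window,
                 labels = epochs$labels, targets = epochs$targets),
            class = "window_segments")
}

# Stacked lag design for segments `seg` (trials x nodes x len): returns
# crossproducts of the within-segment lagged design (no lag crosses a trial
# boundary). Column block for node r holds its lags 1..p.
.lag_crossprods <- function(seg, p) {
  d <- dim(seg); n_tr <- d[1]; n <- d[2]; len <- d[3]
  if (len <= p) stop("segment length (", len, ") must exceed the order (", p, ")")
  rows <- len - p
  L <- matrix(0, n_tr * rows, n * p)
  Y <- matrix(0, n_tr * rows, n)
  for (r in seq_len(n)) {
    Y[, r] <- as.vector(seg[, r, (p + 1):len])
    for (k in seq_len(p))
      L[, (r - 1) * p + k] <- as.vector(seg[, r, (p + 1 - k):(len - k)])
  }
  list(G = crossprod(L), C = crossprod(L, Y), YY = crossprod(Y),
       n_rows = n_tr * rows)
}

# Solve the bivariate normal equations. Column order of XtX/XtY: x lags
# 1..p then y lags 1..p; YtY over (x, y).
.fit_from_crossprods <- function(XtX, XtY, YtY, n_rows, order,
                                 cond_limit = 1e10) {
  rc <- rcond(XtX)
  if (!is.finite(rc) || 1 / rc > cond_limit)
    stop(sprintf(
      "ill-conditioned VAR normal matrix (condition ~ %.2e); use more data or a lower order",
      1 / rc))
  B <- solve(XtX, XtY)
  Sig <- (YtY - t(B) %*% XtY - t(XtY) %*% B + t(B) %*% XtX %*% B) / n_rows
  Sig <- (Sig + t(Sig)) / 2
  p <- order
  coeffs <- array(0, dim = c(p, 2, 2))
  coeffs[, 1, 1] <- B[1:p, 1];           coeffs[, 1, 2] <- B[p + 1:p, 1]
  coeffs[, 2, 1] <- B[1:p, 2];           coeffs[, 2, 2] <- B[p + 1:p, 2]
  structure(list(order = p, coeffs = coeffs, resid_cov = Sig,
                 n_effective = n_rows),
            class = "bivariate_var_fit")
}

#' Fit a bivariate VAR by within-segment least squares
#'
#' Ordinary least squares with no intercept (segments are demeaned) on
#' design rows accumulated within each segment only, so no lag spans a trial
#' boundary — the estimation equivalent of concatenating trials. Residual
#' covariance is the pooled maximum-likelihood estimate.
#'
#' @param x_segments,y_segments Matrices `trials x samples` (or vectors for
#'   a single segment), trial-aligned.
#' @param order Model order p (default 30).
#' @return A `bivariate_var_fit`: list with `order`, `coeffs`
#'   (`p x 2 x 2`, standard orientation, node 1 = x), `resid_cov`,
#'   `n_effective`.
#' @export
fit_bivariate_var <- function(x_segments, y_segments, order = 30) {
  x_segments <- rbind(x_segments); y_segments <- rbind(y_segments)
  if (!all(dim(x_segments) == dim(y_segments)))
    stop("x and y segments must be trial-aligned with equal lengths")
  p <- order
  if (ncol(x_segments) <= p)
    stop("segment length (", ncol(x_segments), ") must exceed the order (", p, ")")
  seg <- aperm(array(c(x_segments, y_segments),
                     dim = c(nrow(x_segments), ncol(x_segments), 2)),
               c(1, 3, 2))
  cp <- .lag_crossprods(seg, p)
  if (cp$n_rows < 4 * p)
    stop("too few regression rows (", cp$n_rows, ") for 4p = ", 4 * p,
         " unknowns")
  .fit_from_crossprods(cp$G, cp$C, cp$YY, cp$n_rows, p)
}

# Geweke spectral GC of a fitted/true bivariate system, vectorized over
# frequencies. Returns both directions.
.gc_spectrum_core <- function(coeffs, Sig, freqs, fs, floor_frac = 1e-12) {
  p <- dim(coeffs)[1]
  Ph <- exp(outer(seq_len(p), -2i * pi * freqs / fs))      # p x nf
  Af <- function(i, j) drop(crossprod(Ph, coeffs[, i, j]))
  A11 <- Af(1, 1); A12 <- Af(1, 2); A21 <- Af(2, 1); A22 <- Af(2, 2)
  det <- (1 - A11) * (1 - A22) - A12 * A21
  H11 <- (1 - A22) / det; H12 <- A12 / det
  H21 <- A21 / det;       H22 <- (1 - A11) / det
  s11 <- Sig[1, 1]; s22 <- Sig[2, 2]; s12 <- Sig[1, 2]
  S11 <- Re(s11 * Mod(H11)^2 + s22 * Mod(H12)^2 +
              2 * s12 * Re(H11 * Conj(H12)))
  S22 <- Re(s22 * Mod(H22)^2 + s11 * Mod(H21)^2 +
              2 * s12 * Re(H22 * Conj(H21)))
  gam_yx <- s22 - s12^2 / s11    # partial innovation variance of y given x
  gam_xy <- s11 - s12^2 / s22
  den_yx <- S11 - gam_yx * Mod(H12)^2
  den_xy <- S22 - gam_xy * Mod(H21)^2
  floored <- which(den_yx <= floor_frac * S11 | den_xy <= floor_frac * S22)
  den_yx <- pmax(den_yx, floor_frac * S11)
  den_xy <- pmax(den_xy, floor_frac * S22)
  y_to_x <- log(S11 / den_yx)
  x_to_y <- log(S22 / den_xy)
  clamped <- sum(y_to_x < 0) + sum(x_to_y < 0)
  list(x_to_y = pmax(x_to_y, 0), y_to_x = pmax(y_to_x, 0),
       clamped = clamped, floored_freqs = freqs[floored])
}

#' Spectral Granger causality of a fitted bivariate VAR
#'
#' Geweke's causal-power decomposition: with transfer function
#' \eqn{H(f) = (I - \sum_k A_k e^{-i2\pi f k/f_s})^{-1}} and spectral matrix
#' \eqn{S = H \Sigma H^*}, the causality from y to x is
#' \eqn{\ln[S_{xx} / (S_{xx} - (\Sigma_{yy} - \Sigma_{xy}^2/\Sigma_{xx})
#' |H_{xy}|^2)]}, and symmetrically for x to y. Negative values arising from
#' floating-point roundoff are clamped to zero (count reported); a
#' non-positive denominator is floored at `1e-12 * S_xx` with the offending
#' frequencies flagged. An unstable fit (companion spectral radius >= 1)
#' warns and proceeds with `stable = FALSE`.
#'
#' @param fit A `bivariate_var_fit`.
#' @param freqs Frequency grid in Hz.
#' @param fs Sampling rate in Hz.
#' @return A `gc_spectrum` object: list with `freqs`, `x_to_y`, `y_to_x`
#'   (nonnegative GC per frequency), `clamped`, `floored_freqs`, `stable`,
#'   `radius`.
#' @export
gc_spectrum <- function(fit, freqs, fs) {
  stopifnot(inherits(fit, "bivariate_var_fit"))
  radius <- var_spectral_radius(list(order = fit$order, n_nodes = 2L,
                                     coeffs = fit$coeffs))
  stable <- radius < 1
  if (!stable)
    warning(sprintf("fitted VAR is unstable (companion radius %.4f); spectrum may be unreliable", radius))
  res <- .gc_spectrum_core(fit$coeffs, fit$resid_cov, freqs, fs)
  structure(c(list(freqs = freqs), res,
              list(stable = stable, radius = radius)),
            class = "gc_spectrum")
}

# Grid-point membership of a band under the pipeline's half-open rule
# (upper edge closed only when `include_upper`).
.band_members <- function(freqs, band, include_upper) {
  freqs >= band[1] & (freqs < band[2] | (include_upper & freqs <= band[2]))
}

#' Band-averaged directed connectivity matrices
#'
#' For every ordered ROI pair (240 pairs at 16 ROIs) and each condition
#' window, fits a bivariate VAR on the concatenated per-trial windows,
#' evaluates the Geweke GC spectrum, and averages it over each band,
#' producing one `NROI x NROI` matrix per band and condition (rows = source
#' ROI, columns = target ROI, diagonal 0), unnormalized. The upper band
#' edge is included for the last band (beta, 13-30 Hz closed) and excluded
#' otherwise (alpha, 8-13 Hz half-open).
#'
#' Expects evoked-removed epochs (see [remove_evoked()]).
#'
#' @param epochs An `epoch_set`.
#' @param bands Named list of `c(low, high)` bands.
#' @param windows Named list of condition windows `c(start, end)` s.
#' @param order VAR order p (default 30).
#' @param freqs GC spectrum grid in Hz (default 1-45 Hz in 0.5 Hz steps).
#' @return Nested list `result[[band]][[condition]]`, each a `gc_matrix`:
#'   list with `values`, `band`, `condition`, `normalized = FALSE`,
#'   `roi_labels`, `order`, plus `clamped` (total clamp events).
#' @export
build_gc_matrices <- function(epochs,
                              bands = list(alpha = c(8, 13),
                                           beta = c(13, 30)),
                              windows = list(baseline = c(-1, 0),
                                             post_cue_late = c(1, 2)),
                              order = 30, freqs = seq(1, 45, by = 0.5)) {
  n <- dim(epochs$data)[2]
  labels <- epochs$labels
  p <- order
  upper_closed <- seq_along(bands) == length(bands)
  members <- lapply(seq_along(bands), function(b)
    which(.band_members(freqs, bands[[b]], upper_closed[b])))
  names(members) <- names(bands)
  for (b in names(bands)) if (length(members[[b]]) == 0)
    stop("band ", b, " does not intersect the GC frequency grid")

  out <- lapply(names(bands), function(b)
    stats::setNames(vector("list", length(windows)), names(windows)))
  names(out) <- names(bands)

  for (w in names(windows)) {
    seg <- extract_windows(epochs, windows[[w]])
    cp <- .lag_crossprods(seg$data, p)
    mats <- lapply(bands, function(b) matrix(0, n, n,
                                             dimnames = list(labels, labels)))
    clamp_total <- 0L
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      idx <- c((i - 1) * p + seq_len(p), (j - 1) * p + seq_len(p))
      fit <- tryCatch(
        .fit_from_crossprods(cp$G[idx, idx], cp$C[idx, c(i, j)],
                             cp$YY[c(i, j), c(i, j)], cp$n_rows, p),
        error = function(e) stop("pair (", labels[i], ", ", labels[j],
                                 "), window ", w, ": ", conditionMessage(e)))
      sp <- .gc_spectrum_core(fit$coeffs, fit$resid_cov, freqs,
                              epochs$fs)
      clamp_total <- clamp_total + sp$clamped
      for (b in names(bands)) {
        m <- members[[b]]
        mats[[b]][i, j] <- mean(sp$x_to_y[m])   # i -> j
        mats[[b]][j, i] <- mean(sp$y_to_x[m])   # j -> i
      }
    }
    for (b in names(bands))
      out[[b]][[w]] <- structure(
        list(values = mats[[b]], band = b, condition = w,
             normalized = FALSE, roi_labels = labels, order = p,
             clamped = clamp_total),
        class = "gc_matrix")
  }
  out
}

#' @export
print.gc_matrix <- function(x, ...) {
  cat(sprintf("<gc_matrix> %s / %s, %d ROIs, %s (off-diagonal sum %.6g)\n",
              x$band, x$condition, nrow(x$values),
              if (x$normalized) "normalized" else "raw",
              sum(x$values) - sum(diag(x$values))))
  invisible(x)
}

#' Normalize a connectivity matrix to unit off-diagonal sum
#'
#' Divides every entry by the off-diagonal total, so each connection value
#' expresses its share of the overall connectivity
#' (\eqn{\tilde A = A / \sum_{i \ne j} A_{ij}}). Idempotent and invariant
#' to positive rescaling of the input.
#'
#' @param matrix A `gc_matrix` (or plain square matrix with zero diagonal).
#' @return The normalized object (off-diagonal sum exactly 1).
#' @export
normalize_gc <- function(matrix) {
  v <- if (inherits(matrix, "gc_matrix")) matrix$values else matrix
  s <- sum(v) - sum(diag(v))
  if (s <= 0) stop("cannot normalize: off-diagonal sum is ", s)
  v <- v / s
  diag(v) <- 0
  if (inherits(matrix, "gc_matrix")) {
    matrix$values <- v
    matrix$normalized <- TRUE
    matrix
  } else v
}

#' Write a GC matrix as a delimited table with ROI headers
#' @param m A `gc_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gc_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(m$values), path, row.names = TRUE)
  invisible(path)
}
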