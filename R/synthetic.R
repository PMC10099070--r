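#' Amplitude-envelope specification for a programmed oscillation
#'
#' Describes one band-limited oscillation on one ROI: its baseline
#' amplitude and the multiplicative amplitude factor reached after the cue.
#' `postcue_gain < 1` programs event-related desynchronization (ERD),
#' `> 1` programs synchronization (ERS); power changes as the square of the
#' amplitude factor, so gain g yields a band ERSP of `100 * (g^2 - 1)` %.
#'
#' @param roi ROI label the oscillation lives on.
#' @param band_center_hz Oscillation frequency in Hz.
#' @param baseline_amp Amplitude during the baseline window (> 0).
#' @param postcue_gain Amplitude factor in the late post-cue window (>= 0).
#' @param ramp Transition shape: `ramp_linear(on, off)` (default, linear
#'   between `on` and `off` seconds post-cue) or `ramp_step(at)`.
#' @return An `envelope_spec` object.
#' @export
envelope_spec <- function(roi, band_center_hz, baseline_amp = 1,
                          postcue_gain = 1, ramp = ramp_linear(0.5, 1)) {
  stopifnot(baseline_amp > 0, postcue_gain >= 0, band_center_hz > 0)
  structure(list(roi = roi, band_center_hz = band_center_hz,
                 baseline_amp = baseline_amp, postcue_gain = postcue_gain,
                 ramp = ramp),
            class = "envelope_spec")
}

#' @rdname envelope_spec
#' @param on,off Ramp onset/offset times in seconds post-cue.
#' @export
ramp_linear <- function(on = 0.5, off = 1) {
  stopifnot(off >= on)
  list(type = "linear", on = on, off = off)
}

#' @rdname envelope_spec
#' @param at Step time in seconds post-cue.
#' @export
ramp_step <- function(at = 0.5) list(type = "step", at = at)

# Transition weight w(t) in [0, 1]: 0 before the ramp, 1 after it.
.ramp_weight <- function(ramp, time) {
  if (ramp$type == "step") return(as.numeric(time >= ramp$at))
  if (ramp$off == ramp$on) return(as.numeric(time >= ramp$on))
  pmin(1, pmax(0, (time - ramp$on) / (ramp$off - ramp$on)))
}

#' Amplitude profile of an envelope over a time axis
#' @param env An `envelope_spec`.
#' @param time Time axis in seconds (cue at 0).
#' @return Amplitude at each time point.
#' @export
envelope_amplitude <- function(env, time) {
  w <- .ramp_weight(env$ramp, time)
  env$baseline_amp * (1 + (env$postcue_gain - 1) * w)
}

#' Cue-evoked transient template
#'
#' A damped 5 Hz oscillation lasting 0.5 s, emulating the visual evoked
#' response to the target LED: it extinguishes about 500 ms after stimulus
#' onset. Added identically to every trial on designated (visual) ROIs, so
#' it forms the across-trial evoked component that [remove_evoked()]
#' subtracts before connectivity estimation.
#'
#' @param fs Sampling rate in Hz.
#' @param duration Duration in seconds.
#' @param freq Oscillation frequency in Hz.
#' @param amplitude Peak scale factor.
#' @param decay Exponential decay rate (1/s).
#' @return Numeric vector of `duration * fs` samples.
#' @export
evoked_template <- function(fs = 512, duration = 0.5, freq = 5,
                            amplitude = 1, decay = 6) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  amplitude * sin(2 * pi * freq * t) * exp(-decay * t)
}

# 1/f-amplitude-shaped Gaussian noise, unit variance, one column per signal.
.pink_noise <- function(n_samples, n_signals) {
  W <- matrix(stats::rnorm(n_samples * n_signals), n_samples, n_signals)
  F <- stats::mvfft(W)
  k <- seq_len(n_samples) - 1
  k <- pmin(k, n_samples - k)          # fold to two-sided frequency index
  shape <- 1 / sqrt(pmax(k, 1))        # amplitude ~ f^(-1/2)  => power ~ 1/f
  X <- Re(stats::mvfft(F * shape, inverse = TRUE)) / n_samples
  sc <- sqrt(colMeans(X^2))
  sweep(X, 2, pmax(sc, .Machine$double.eps), "/")
}

#' Default study-condition ground truth for the reaching generator
#'
#' Encodes the emulated experiment: 16 ROIs (8 per hemisphere: CU, LO, PCU,
#' SP, PoC, PrC, PaC, SF), alpha (10 Hz) and beta (20 Hz) oscillations on
#' every ROI with ERD gains concentrated on visual/visuomotor ROIs in alpha
#' and on (left-lateralized) sensorimotor ROIs in beta, a cue-evoked
#' transient on the visual ROIs, and a weakly coupled stable VAR(2)
#' background whose post-cue coefficients add couplings into right
#' sensorimotor cortex.
#'
#' @param fs Sampling rate in Hz.
#' @return List with `roi_labels`, `envelopes`, `var_baseline`,
#'   `var_postcue`, `evoked`, `evoked_rois`.
#' @export
default_reaching_truth <- function(fs = 512) {
  base <- c("CU", "LO", "PCU", "SP", "PoC", "PrC", "PaC", "SF")
  labels <- c(paste0("L.", base), paste0("R.", base))
  idx <- function(l) match(l, labels)
  visual <- c("L.CU", "R.CU", "L.LO", "R.LO")
  visuomotor <- c("L.PCU", "R.PCU", "L.SP", "R.SP")
  sensorimotor <- c("PoC", "PrC", "PaC")

  envs <- list()
  for (l in labels) {
    a_gain <- if (l %in% c(visual, visuomotor)) 0.9 else 1
    b_gain <- if (sub("^[LR]\\.", "", l) %in% sensorimotor) {
      if (startsWith(l, "L.")) 0.85 else 0.92
    } else if (l %in% visual) 0.95 else if (l %in% visuomotor) 0.9 else 1
    envs <- c(envs,
              list(envelope_spec(l, 10, baseline_amp = 2.0, postcue_gain = a_gain),
                   envelope_spec(l, 20, baseline_amp = 1.5, postcue_gain = b_gain)))
  }

  e <- function(from, to, w) c(idx(from), idx(to), 1, w)
  base_edges <- list(
    e("L.LO", "L.SP", 0.15), e("R.LO", "R.SP", 0.15),
    e("L.SP", "L.PrC", 0.15), e("R.SP", "R.PrC", 0.15),
    e("L.PCU", "L.SF", 0.15), e("R.PCU", "R.SF", 0.15))
  post_edges <- c(base_edges, list(
    e("L.PrC", "R.PrC", 0.2), e("R.PCU", "R.PrC", 0.2)))

  mk <- function(edges) build_var_model(
    16, 2, edges = edges, self_decay = c(0.5, -0.1),
    noise_cov = diag(0.09, 16), fs = fs)
  list(roi_labels = labels, envelopes = envs,
       var_baseline = mk(base_edges), var_postcue = mk(post_edges),
       evoked = evoked_template(fs, amplitude = 1.5),
       evoked_rois = visual)
}

#' Generate a multi-subject synthetic reaching dataset
#'
#' Each trial is a 4 s epoch (\eqn{-1} to 3 s around the cue, fs = 512 Hz by
#' default): a VAR background whose coefficients cross-fade from the
#' baseline model to the post-cue model at `switch_time`, plus
#' amplitude-modulated sinusoids (random per-trial phase) shaped by the
#' envelope specs, plus a cue-locked evoked transient on designated ROIs,
#' plus 1/f background noise. Trial structure emulates 5 reaching targets
#' with `trials_per_target` trials each; the generator applies identical
#' spectral dynamics for every target.
#'
#' @param n_subjects Number of simulated subjects.
#' @param trials_per_target Trials per target (5 targets), default 60, i.e.
#'   300 trials per subject.
#' @param truth Ground-truth description as from [default_reaching_truth()];
#'   fields: `roi_labels`, `envelopes`, `var_baseline`, `var_postcue`,
#'   `evoked`, `evoked_rois`.
#' @param noise_sd Standard deviation of the additive 1/f noise.
#' @param tmin,tmax Epoch limits in seconds (cue at 0).
#' @param switch_time Time (s post-cue) at which VAR coefficients switch.
#' @param crossfade Cross-fade duration of the coefficient switch (s).
#' @param n_targets Number of reaching targets.
#' @param seed Master seed; per-subject streams are derived from it.
#' @return A `synthetic_dataset`: list with `subjects` (list of
#'   [epoch_set()]) and `truth` (inputs above plus the seed).
#' @export
generate_reaching_dataset <- function(n_subjects = 20, trials_per_target = 60,
                                      truth = default_reaching_truth(),
                                      noise_sd = 0.2, tmin = -1, tmax = 3,
                                      switch_time = 0.5, crossfade = 0.05,
                                      n_targets = 5, seed = 1) {
  vb <- truth$var_baseline; vp <- truth$var_postcue
  if (vb$n_nodes != vp$n_nodes)
    stop("baseline and post-cue VAR models must share n_nodes")
  n_roi <- vb$n_nodes
  if (length(truth$roi_labels) != n_roi)
    stop("roi_labels length must equal the VAR node count")
  fs <- vb$fs
  ns <- round((tmax - tmin) * fs)
  time <- tmin + (seq_len(ns) - 1) / fs
  n_trials <- n_targets * trials_per_target

  p <- max(vb$order, vp$order)
  pad <- function(m) {
    co <- array(0, dim = c(p, n_roi, n_roi))
    co[seq_len(m$order), , ] <- m$coeffs
    co
  }
  cb <- pad(vb); cp <- pad(vp)
  w <- .ramp_weight(list(type = "linear", on = switch_time,
                         off = switch_time + crossfade), time)
  coeff_fun <- function(t) {
    wt <- w[min(t, ns)]
    if (wt <= 0) cb else if (wt >= 1) cp else (1 - wt) * cb + wt * cp
  }

  env_amp <- lapply(truth$envelopes, envelope_amplitude, time = time)
  env_roi <- vapply(truth$envelopes,
                    function(e) match(e$roi, truth$roi_labels), integer(1))
  if (anyNA(env_roi)) stop("envelope roi not found among roi_labels")
  ev_idx <- match(truth$evoked_rois, truth$roi_labels)
  cue_sample <- which.min(abs(time))           # time 0
  ev_len <- length(truth$evoked)

  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    subjects[[s]] <- with_seed(derive_seed(seed, 101L, s), {
      X <- .simulate_var_core(cb, vb$noise_cov, ns, n_trials,
                              burn_in = 10 * p, coeff_fun = coeff_fun)
      for (ei in seq_along(truth$envelopes)) {
        e <- truth$envelopes[[ei]]
        phase <- stats::runif(n_trials, 0, 2 * pi)
        osc <- sin(outer(phase, 2 * pi * e$band_center_hz * time, "+"))
        X[, env_roi[ei], ] <- X[, env_roi[ei], ] +
          sweep(osc, 2, env_amp[[ei]], "*")
      }
      if (length(ev_idx) && ev_len > 0) {
        ev_cols <- cue_sample:(cue_sample + ev_len - 1)
        for (r in ev_idx)
          X[, r, ev_cols] <- sweep(matrix(X[, r, ev_cols], n_trials), 2,
                                   truth$evoked, "+")
      }
      if (noise_sd > 0) {
        pn <- .pink_noise(ns, n_trials * n_roi)
        X <- X + aperm(array(pn, dim = c(ns, n_trials, n_roi)),
                       c(2, 3, 1)) * noise_sd
      }
      targets <- sample(rep(seq_len(n_targets), trials_per_target))
      epoch_set(X, fs = fs, tmin = tmin, labels = truth$roi_labels,
                targets = targets)
    })
  }
  structure(list(subjects = subjects,
                 truth = c(truth, list(seed = seed, noise_sd = noise_sd,
                                       switch_time = switch_time,
                                       crossfade = crossfade))),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d subjects, seed %s\n",
              length(x$subjects), x$truth$seed))
  print(x$subjects[[1]])
  invisible(x)
}

#' Serialize a synthetic dataset to a directory
#'
#' Writes one CSV + JSON sidecar per subject (see [write_epoch_set()]) and a
#' `truth.json` manifest (envelope specs, VAR coefficients, evoked template,
#' seed).
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reaching_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_along(dataset$subjects))
    write_epoch_set(dataset$subjects[[s]],
                    file.path(dir, sprintf("subject%02d", s)))
  tr <- dataset$truth
  manifest <- list(
    n_subjects = length(dataset$subjects),
    roi_labels = tr$roi_labels, seed = tr$seed, noise_sd = tr$noise_sd,
    switch_time = tr$switch_time, crossfade = tr$crossfade,
    evoked = tr$evoked, evoked_rois = tr$evoked_rois,
    envelopes = lapply(tr$envelopes, unclass),
    var_baseline = list(order = tr$var_baseline$order,
                        coeffs = tr$var_baseline$coeffs,
                        noise_cov = tr$var_baseline$noise_cov,
                        fs = tr$var_baseline$fs),
    var_postcue = list(order = tr$var_postcue$order,
                       coeffs = tr$var_postcue$coeffs,
                       noise_cov = tr$var_postcue$noise_cov,
                       fs = tr$var_postcue$fs))
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_reaching_dataset()]
#' @param dir Directory written by [write_reaching_dataset()].
#' @return A `synthetic_dataset` (truth block restricted to the manifest).
#' @export
read_reaching_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "truth.json"),
                                  simplifyVector = TRUE)
  subjects <- lapply(seq_len(manifest$n_subjects), function(s)
    read_epoch_set(file.path(dir, sprintf("subject%02d", s))))
  structure(list(subjects = subjects, truth = manifest),
            class = "synthetic_dataset")
}
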