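# Shared fixture builders; everything is generated in code.

# The two-node reference system: node 1 drives node 2 with weight 0.9 at
# lag 1, self-decay 0.5, identity innovations.
ref_var2 <- function(fs = 512) {
  build_var_model(2, 1, edges = list(c(1, 2, 1, 0.9)), self_decay = 0.5,
                  fs = fs)
}

# Minimal epoch set around a cue at 0 s with given per-trial signals.
# `make` is function(trial_index, time) -> channels x samples matrix.
make_epochs <- function(n_trials, n_chan, fs = 512, tmin = -1, tmax = 3,
                        targets = NULL, make) {
  ns <- round((tmax - tmin) * fs)
  time <- tmin + (seq_len(ns) - 1) / fs
  arr <- array(0, dim = c(n_trials, n_chan, ns))
  for (i in seq_len(n_trials)) arr[i, , ] <- make(i, time)
  epoch_set(arr, fs = fs, tmin = tmin, targets = targets)
}

# Random-phase tone trials on one channel: amplitude profile `amp(time)`
# plus white noise.
tone_epochs <- function(n_trials, amp_fun, freq = 10, noise_sd = 0.05,
                        fs = 512, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    make_epochs(n_trials, 1, fs = fs, make = function(i, time) {
      ph <- stats::runif(1, 0, 2 * pi)
      matrix(amp_fun(time) * sin(2 * pi * freq * time + ph) +
               stats::rnorm(length(time), 0, noise_sd), 1)
    })
  })
}

# Tiny 4-ROI ground truth with a programmed alpha ERD on one ROI; the other
# ROIs are spectrally flat (gain 1) controls.
small_truth <- function(erd_gain = 0.5, fs = 512) {
  labels <- c("L.A", "R.A", "L.B", "R.B")
  envs <- list(envelope_spec("L.A", 10, 2.0, erd_gain),
               envelope_spec("R.A", 10, 2.0, 1.0),
               envelope_spec("L.B", 10, 2.0, 1.0),
               envelope_spec("R.B", 20, 1.5, 1.0))
  vm <- build_var_model(4, 2, self_decay = c(0.5, -0.1),
                        noise_cov = diag(0.09, 4), fs = fs)
  list(roi_labels = labels, envelopes = envs, var_baseline = vm,
       var_postcue = vm, evoked = evoked_template(fs, amplitude = 1.5),
       evoked_rois = "L.B")
}
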