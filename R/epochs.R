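#' Epoched multi-trial data container
#'
#' The pipeline's universal container: a `trials x channels x samples` array
#' with a time axis relative to the cue (0 s = cue onset), sampling rate,
#' channel/ROI labels and per-trial reaching-target labels. The time axis is
#' half-open: samples cover `[tmin, tmax)` so every trial has exactly
#' `(tmax - tmin) * fs` samples.
#'
#' @param data Numeric array `trials x channels x samples`.
#' @param fs Sampling rate in Hz.
#' @param tmin Start of the epoch in seconds relative to the cue (default -1).
#' @param labels Channel/ROI labels (default `ch1..chN`). Hemisphere-prefixed
#'   labels like `"L.PrC"` / `"R.PrC"` are used for lateralization tests.
#' @param targets Integer per-trial target id (default all 1).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, tmin = -1, labels = NULL, targets = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L, fs > 0)
  d <- dim(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(d[2]))
  if (is.null(targets)) targets <- rep(1L, d[1])
  if (length(labels) != d[2]) stop("labels length must match channel dimension")
  if (length(targets) != d[1]) stop("targets length must match trial dimension")
  time <- tmin + (seq_len(d[3]) - 1) / fs
  structure(
    list(data = data, time = time, fs = fs, labels = labels,
         targets = as.integer(targets)),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  time [%g, %g] s; targets: %s\n", min(x$time), max(x$time),
              paste(sort(unique(x$targets)), collapse = ",")))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Write an epoch set as delimited text plus a JSON sidecar
#'
#' One CSV holds the signal values, one row per (trial, channel), columns =
#' samples; the sidecar records fs, epoch start, labels and targets. Intended
#' for small exchange files, not bulk storage.
#'
#' @param x An `epoch_set`.
#' @param path Output path prefix; writes `<path>.csv` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_epoch_set <- function(x, path) {
  stopifnot(inherits(x, "epoch_set"))
  d <- dim(x$data)
  flat <- matrix(aperm(x$data, c(3, 2, 1)), nrow = d[1] * d[2], byrow = TRUE)
  utils::write.table(flat, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(fs = x$fs, tmin = x$time[1], n_trials = d[1],
               n_channels = d[2], n_samples = d[3],
               labels = x$labels, targets = x$targets)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an epoch set written by [write_epoch_set()]
#' @param path Path prefix used at write time.
#' @return An `epoch_set`.
#' @export
read_epoch_set <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ","))
  arr <- aperm(array(t(flat), dim = c(meta$n_samples, meta$n_channels,
                                      meta$n_trials)), c(3, 2, 1))
  epoch_set(arr, fs = meta$fs, tmin = meta$tmin, labels = meta$labels,
            targets = meta$targets)
}
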