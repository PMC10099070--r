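#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so calling code's random stream is
#' untouched. With `seed = NULL` the expression runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a sub-seed from a master seed
#'
#' Deterministic stream splitting: every stochastic stage of the pipeline
#' draws its own seed from the master seed plus integer indices (subject,
#' stage, ...), so runs are reproducible and stages are decoupled.
#' Result is always in `[1, 2^31 - 2]`.
#'
#' @param seed Master integer seed.
#' @param ... Integer indices identifying the stream.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1 (Mersenne prime; Lehmer modulus)
  s <- as.double(seed) %% m
  for (k in c(...)) {
    s <- (s * 48271 + as.double(k) + 1) %% m
  }
  as.integer(s + 1)
}

# Sample indices of a half-open time window [w1, w2) on a time axis.
.win_idx <- function(time, window, what = "window") {
  if (length(window) != 2L || window[2] <= window[1])
    stop(sprintf("invalid %s: [%s, %s)", what, window[1], window[2]))
  idx <- which(time >= window[1] - 1e-9 & time < window[2] - 1e-9)
  if (length(idx) == 0L)
    stop(sprintf("empty %s [%s, %s) on time axis [%s, %s]",
                 what, window[1], window[2], min(time), max(time)))
  idx
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && x >= 1 && x == round(x)
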