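#' Construct a stable vector-autoregressive (VAR) model
#'
#' Builds the ground-truth generative system
#' \deqn{x[n] = \sum_{k=1}^{p} A_k x[n-k] + e[n], \quad e \sim N(0, \Sigma)}
#' from a self-decay diagonal plus an explicit list of directed edges.
#' Lag-slice matrices use the standard orientation: `coeffs[k, i, j]` is the
#' influence of node `j`'s value `k` samples ago on node `i` now, so an edge
#' `from -> to` with weight `w` at lag `k` sets `coeffs[k, to, from] = w`.
#'
#' Construction fails if the companion-matrix spectral radius is >= 1
#' (non-stationary process) or if `noise_cov` is not symmetric positive
#' definite.
#'
#' @param n_nodes Number of nodes (ROIs).
#' @param order Model order p (number of lags).
#' @param edges Directed couplings: a list of `c(from, to, lag, weight)`
#'   vectors or a 4-column matrix/data.frame with those columns (1-based
#'   node indices).
#' @param self_decay Numeric vector of per-lag diagonal coefficients
#'   (recycled to length `order`), e.g. `0.5` puts 0.5 on every node's lag-1
#'   self term and 0 beyond.
#' @param noise_cov Innovation covariance (default identity).
#' @param fs Sampling rate in Hz carried for spectral evaluation.
#' @return An object of class `var_model` with fields `n_nodes`, `order`,
#'   `coeffs` (`order x n_nodes x n_nodes`), `noise_cov`, `fs` and the
#'   companion `spectral_radius`.
#' @examples
#' m <- build_var_model(2, 1, edges = list(c(1, 2, 1, 0.9)), self_decay = 0.5)
#' m$spectral_radius
#' @export
build_var_model <- function(n_nodes, order, edges = NULL,
                            self_decay = 0, noise_cov = NULL, fs = 512) {
  stopifnot(.is_count(n_nodes), .is_count(order), fs > 0)
  if (is.null(noise_cov)) noise_cov <- diag(n_nodes)
  noise_cov <- as.matrix(noise_cov)
  if (!isTRUE(all.equal(noise_cov, t(noise_cov), tolerance = 1e-10)))
    stop("noise_cov must be symmetric")
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("noise_cov must be positive definite (min eigenvalue ",
         format(min(ev)), ")")

  sd_lags <- rep_len(c(self_decay, rep(0, order)), order)
  coeffs <- array(0, dim = c(order, n_nodes, n_nodes))
  for (k in seq_len(order)) coeffs[k, , ] <- diag(sd_lags[k], n_nodes)

  if (!is.null(edges)) {
    em <- if (is.list(edges) && !is.data.frame(edges))
      do.call(rbind, edges) else as.matrix(edges)
    if (ncol(em) != 4L) stop("edges need 4 columns: from, to, lag, weight")
    for (r in seq_len(nrow(em))) {
      from <- em[r, 1]; to <- em[r, 2]; lag <- em[r, 3]; w <- em[r, 4]
      if (lag < 1 || lag > order) stop("edge lag out of 1..order: ", lag)
      if (min(from, to) < 1 || max(from, to) > n_nodes)
        stop("edge node index out of range")
      coeffs[lag, to, from] <- w
    }
  }

  model <- structure(
    list(n_nodes = n_nodes, order = order, coeffs = coeffs,
         noise_cov = noise_cov, fs = fs),
    class = "var_model")
  rad <- var_spectral_radius(model)
  if (rad >= 1)
    stop(sprintf(
      "unstable VAR model: companion spectral radius %.4f >= 1", rad))
  model$spectral_radius <- rad
  model
}

#' Companion-matrix spectral radius of a VAR model
#' @param model A `var_model` (or a bare `order x n x n` coefficient array
#'   packed in a list with fields `coeffs`, `order`, `n_nodes`).
#' @return The largest eigenvalue modulus of the companion matrix.
#' @export
var_spectral_radius <- function(model) {
  p <- model$order; n <- model$n_nodes
  comp <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) comp[1:n, ((k - 1) * n + 1):(k * n)] <- model$coeffs[k, , ]
  if (p > 1) comp[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("<var_model> %d nodes, order %d, fs %g Hz, spectral radius %.4f\n",
              x$n_nodes, x$order, x$fs,
              if (is.null(x$spectral_radius)) var_spectral_radius(x)
              else x$spectral_radius))
  invisible(x)
}

#' Simulate independent trials from a VAR model
#'
#' Each trial is an independent realization seeded from the current (or
#' given) RNG state; a burn-in prefix is simulated and discarded so trials
#' start in the stationary regime.
#'
#' @param model A stable `var_model`.
#' @param n_samples Samples to keep per trial.
#' @param n_trials Number of independent trials.
#' @param burn_in Discarded prefix length; must be >= 10 * order.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return Array `n_trials x n_nodes x n_samples`.
#' @export
simulate_var <- function(model, n_samples, n_trials = 1,
                         burn_in = 10 * model$order, seed = NULL) {
  stopifnot(inherits(model, "var_model"))
  rad <- if (is.null(model$spectral_radius)) var_spectral_radius(model)
         else model$spectral_radius
  if (rad >= 1) stop("refusing to simulate an unstable model (radius ",
                     format(rad), ")")
  if (burn_in < 10 * model$order)
    stop("burn_in must be >= 10 * order (= ", 10 * model$order, ")")
  with_seed(seed, .simulate_var_core(model$coeffs, model$noise_cov,
                                     n_samples, n_trials, burn_in))
}

# Core recursion, vectorized across trials. `coeffs` may be a function(t)
# returning the order x n x n array at output sample t (time-varying case,
# t counted from the start of the kept segment, burn-in uses t = 1).
.simulate_var_core <- function(coeffs, noise_cov, n_samples, n_trials,
                               burn_in, coeff_fun = NULL) {
  n <- ncol(noise_cov)
  p <- dim(coeffs)[1]
  tot <- burn_in + n_samples
  U <- chol(noise_cov)
  X <- array(stats::rnorm(n_trials * n * tot), dim = c(n_trials, n, tot))
  for (t in seq_len(tot)) X[, , t] <- matrix(X[, , t], n_trials, n) %*% U
  tA <- lapply(seq_len(p), function(k) t(coeffs[k, , ]))
  for (t in (p + 1):tot) {
    acc <- matrix(X[, , t], n_trials, n)
    if (is.null(coeff_fun)) {
      for (k in seq_len(p))
        acc <- acc + matrix(X[, , t - k], n_trials, n) %*% tA[[k]]
    } else {
      Ct <- coeff_fun(max(1L, t - burn_in))
      for (k in seq_len(p))
        acc <- acc + matrix(X[, , t - k], n_trials, n) %*% t(Ct[k, , ])
    }
    X[, , t] <- acc
  }
  X[, , (burn_in + 1):tot, drop = FALSE]
}

#' Analytic spectral Granger causality of a known VAR model
#'
#' Evaluates, from the true coefficients, the Geweke frequency-domain
#' causality for every ordered node pair: with transfer function
#' \deqn{H(f) = (I - \sum_k A_k e^{-i 2 \pi f k / f_s})^{-1}}
#' and spectral matrix \eqn{S(f) = H \Sigma H^*}, the causality from node j
#' to node i at frequency f is
#' \deqn{GC_{j \to i}(f) = \ln \frac{S_{ii}(f)}
#'   {S_{ii}(f) - (\Sigma_{jj} - \Sigma_{ij}^2/\Sigma_{ii}) |H_{ij}(f)|^2}.}
#' This is the oracle the estimator ([gc_spectrum()]) is validated against.
#'
#' @param model A stable `var_model`.
#' @param freqs Frequency grid in Hz (all <= fs/2).
#' @return Array `n x n x length(freqs)`; entry `[j, i, f]` is
#'   \eqn{GC_{j \to i}} at `freqs[f]`. Diagonal is 0.
#' @export
analytic_spectral_gc <- function(model, freqs) {
  stopifnot(inherits(model, "var_model"))
  if (any(freqs < 0) || any(freqs > model$fs / 2))
    stop("frequencies must lie in [0, fs/2] = [0, ", model$fs / 2, "]")
  n <- model$n_nodes; p <- model$order; Sig <- model$noise_cov
  out <- array(0, dim = c(n, n, length(freqs)))
  I_n <- diag(n)
  for (fi in seq_along(freqs)) {
    z <- exp(-2i * pi * freqs[fi] * seq_len(p) / model$fs)
    Af <- matrix(0 + 0i, n, n)
    for (k in seq_len(p)) Af <- Af + model$coeffs[k, , ] * z[k]
    H <- solve(I_n - Af)
    S <- H %*% Sig %*% Conj(t(H))
    for (i in seq_len(n)) {
      Sii <- Re(S[i, i])
      for (j in seq_len(n)) {
        if (i == j) next
        gam <- Sig[j, j] - Sig[i, j]^2 / Sig[i, i]
        val <- log(Sii / (Sii - gam * Mod(H[i, j])^2))
        out[j, i, fi] <- max(val, 0)
      }
    }
  }
  out
}
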