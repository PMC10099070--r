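#' In-degree and out-degree of a directed connectivity matrix
#'
#' With rows = source and columns = target, the in-degree of ROI i is the
#' column sum (total connectivity inflow) and the out-degree of ROI j is the
#' row sum (total outflow). For a normalized matrix both sum to 1 across
#' ROIs.
#'
#' @param matrix A `gc_matrix` or plain square matrix with zero diagonal.
#' @return Named numeric vector of per-ROI degrees.
#' @export
in_degree <- function(matrix) {
  v <- if (inherits(matrix, "gc_matrix")) matrix$values else matrix
  if (any(abs(diag(v)) > 1e-12)) stop("matrix diagonal must be zero")
  colSums(v)
}

#' @rdname in_degree
#' @export
out_degree <- function(matrix) {
  v <- if (inherits(matrix, "gc_matrix")) matrix$values else matrix
  if (any(abs(diag(v)) > 1e-12)) stop("matrix diagonal must be zero")
  rowSums(v)
}

# Exact two-sided signed-rank p-value by sign-assignment enumeration.
# Midrank ties are handled by doubling ranks to integers and convolving the
# subset-sum distribution (equivalent to enumerating all 2^n assignments).
.signed_rank_exact_p <- function(ranks, W) {
  w2 <- round(2 * ranks)
  dist <- 1
  for (w in w2) {
    padded <- c(dist, rep(0, w))
    dist <- (padded + c(rep(0, w), dist)) / 2
  }
  sums <- seq_along(dist) - 1
  mu <- sum(w2) / 2
  sum(dist[abs(sums - mu) >= abs(round(2 * W) - mu) - 1e-9])
}

#' Wilcoxon signed-rank test (paired or against zero)
#'
#' Zero differences are dropped; `W` is the sum of the midranks of the
#' positive differences. For up to `exact_limit` non-zero differences the
#' two-sided p-value is computed by exact enumeration of all sign
#' assignments (valid under midrank ties); beyond that, a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a Per-subject values.
#' @param b Per-subject values to pair against, or a constant (default 0).
#' @param exact_limit Largest n for the exact null distribution.
#' @return List with `statistic` (W), `p.value`, `n` (non-zero pairs),
#'   `method` ("exact" or "approx"). All-zero differences give `p = 1` with
#'   a warning.
#' @export
wilcoxon_signed_rank <- function(a, b = 0, exact_limit = 15) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; p = 1")
    return(list(statistic = 0, p.value = 1, n = 0L, method = "degenerate"))
  }
  if (n < 5) stop("need >= 5 non-zero paired differences (got ", n, ")")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- .signed_rank_exact_p(r, W)
    return(list(statistic = W, p.value = min(1, p), n = n, method = "exact"))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- W - mu
  z <- (z - sign(z) * 0.5) / sqrt(sig2)
  list(statistic = W, p.value = min(1, 2 * stats::pnorm(-abs(z))), n = n,
       method = "approx")
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Standard step-up procedure; a hypothesis is rejected when its adjusted
#' p-value is at most `alpha`.
#'
#' @param pvals Raw p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return List with `adjusted` p-values and logical `rejected` flags (both
#'   empty for empty input).
#' @export
bh_fdr <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0)
    return(list(adjusted = numeric(0), rejected = logical(0)))
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, rejected = adj <= alpha)
}

# Sign-flip null statistics for columns of D (subjects x m): returns
# n_perm x m matrix of permuted mean differences (shared flips across
# columns, preserving cross-column dependence).
.signflip_means <- function(D, n_perm) {
  n <- nrow(D)
  S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  (S %*% D) / n
}

#' Paired sign-flip permutation test
#'
#' Statistic: mean paired difference. The null is built by independent
#' random sign flips of the per-subject differences (exchangeability of the
#' pair order); two-sided p-value with the add-one rule
#' `(1 + #{|perm| >= |obs|}) / (n_perm + 1)`.
#'
#' @param a,b Equal-length per-subject values (n >= 6).
#' @param n_perm Number of permutations (default 5000).
#' @param seed Optional seed (RNG state restored).
#' @return List with `statistic` (observed mean difference), `p.value`,
#'   `n_perm`.
#' @export
paired_permutation_test <- function(a, b, n_perm = 5000, seed = NULL) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 6) stop("need >= 6 subjects (got ", n, ")")
  d <- a - b
  obs <- mean(d)
  if (all(d == 0)) return(list(statistic = 0, p.value = 1, n_perm = n_perm))
  p <- with_seed(seed, {
    perm <- drop(.signflip_means(matrix(d, ncol = 1), n_perm))
    (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
  })
  list(statistic = obs, p.value = p, n_perm = n_perm)
}

# Battery version: one permutation scheme shared across the m columns of
# a - b (subjects x m). Returns raw p-values per column.
.paired_permutation_batch <- function(A, B, n_perm, seed = NULL) {
  D <- A - B
  obs <- colMeans(D)
  with_seed(seed, {
    perm <- .signflip_means(D, n_perm)
    vapply(seq_along(obs), function(k) {
      if (all(D[, k] == 0)) return(1)
      (1 + sum(abs(perm[, k]) >= abs(obs[k]) - 1e-12)) / (n_perm + 1)
    }, numeric(1))
  })
}

# Sign-consistent supra-threshold clusters of a t trace: returns
# data.frame(start, end, mass).
.t_clusters <- function(tstat, threshold) {
  code <- (tstat > threshold) - (tstat < -threshold)
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != 0
  if (!any(keep)) return(data.frame(start = integer(), end = integer(),
                                    mass = numeric()))
  data.frame(start = starts[keep], end = ends[keep],
             mass = vapply(which(keep), function(i)
               sum(tstat[starts[i]:ends[i]]), numeric(1)))
}

#' One-dimensional cluster-based permutation test (paired)
#'
#' Point-wise paired t statistics are thresholded (default: two-sided 0.05
#' critical t); contiguous sign-consistent supra-threshold samples form
#' clusters scored by their summed t. The null distribution of the maximum
#' absolute cluster mass is built by per-subject sign flips, controlling
#' the family-wise error across time points. An empty cluster list is a
#' valid, non-significant outcome.
#'
#' @param a,b Matrices `subjects x time`, aligned; n >= 6.
#' @param n_perm Number of sign-flip permutations.
#' @param cluster_threshold t threshold; default `qt(0.975, n - 1)`.
#' @param seed Optional seed (RNG state restored).
#' @return Data frame with one row per cluster: `start`, `end` (sample
#'   indices), `mass` (summed t) and `p`; attribute `threshold`.
#' @export
cluster_permutation_test_1d <- function(a, b, n_perm = 1000,
                                        cluster_threshold = NULL,
                                        seed = NULL) {
  a <- rbind(a); b <- rbind(b)
  if (!all(dim(a) == dim(b))) stop("a and b must share dimensions")
  n <- nrow(a)
  if (n < 6) stop("need >= 6 subjects (got ", n, ")")
  D <- a - b
  if (is.null(cluster_threshold))
    cluster_threshold <- stats::qt(0.975, n - 1)
  tfun <- function(m, ssq) {
    v <- (ssq - n * m^2) / (n - 1)
    m / sqrt(pmax(v, .Machine$double.eps) / n)
  }
  ssq <- colSums(D^2)
  t_obs <- tfun(colMeans(D), ssq)
  cl <- .t_clusters(t_obs, cluster_threshold)
  if (nrow(cl) == 0) {
    attr(cl, "threshold") <- cluster_threshold
    cl$p <- numeric(0)
    return(cl)
  }
  maxmass <- with_seed(seed, {
    M <- .signflip_means(D, n_perm)
    vapply(seq_len(n_perm), function(i) {
      ci <- .t_clusters(tfun(M[i, ], ssq), cluster_threshold)
      if (nrow(ci) == 0) 0 else max(abs(ci$mass))
    }, numeric(1))
  })
  cl$p <- vapply(cl$mass, function(m)
    (1 + sum(maxmass >= abs(m) - 1e-12)) / (n_perm + 1), numeric(1))
  attr(cl, "threshold") <- cluster_threshold
  cl
}
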