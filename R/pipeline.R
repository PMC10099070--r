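#' Pipeline run configuration
#'
#' Collects every tunable of the two analysis arms (ERSP; connectivity) and
#' the simulation arm, with defaults encoding the study conditions: bands
#' alpha = \[8, 13) Hz / beta = \[13, 30\] Hz, windows baseline = \[-1, 0) s
#' and post-cue-late = \[1, 2) s, cmor1.5-1.0 wavelet, VAR order 30, 5000
#' permutations, FDR level 0.05. The seed is mandatory: every stochastic
#' stage derives its own stream from it (see [derive_seed()]).
#'
#' @param n_subjects,trials_per_target Simulation-arm cohort size.
#' @param truth Ground truth for the generator ([default_reaching_truth()]).
#' @param dataset Optional pre-built `synthetic_dataset` (or a directory
#'   written by [write_reaching_dataset()]); overrides the simulation arm.
#' @param bands Named list of band edges in Hz (last band's upper edge is
#'   closed, earlier bands are half-open).
#' @param windows Named list of condition windows (first = baseline,
#'   second = the contrasted preparation window).
#' @param baseline_window ERSP normalization window in seconds.
#' @param ersp_freqs ERSP analysis grid in Hz.
#' @param ersp_decimate Integer decimation factor applied before the CWT
#'   (the data are 1-60 Hz band-limited, so factors up to 4 keep the
#'   analysis grid below Nyquist).
#' @param wavelet A [wavelet_params()] built at the (decimated) rate; `NULL`
#'   derives it from the data.
#' @param gc_freqs GC spectrum grid in Hz.
#' @param var_order Bivariate VAR order p.
#' @param n_perm Permutations for the GC condition contrast.
#' @param n_perm_cluster Permutations per target-pair cluster test.
#' @param alpha FDR / significance level.
#' @param gc_correction `"raw"` (default) or `"bh"`: which p-values decide
#'   the rejected flags of the 240-pair GC battery (both are reported).
#' @param target_cluster_check Run the per-target-pair cluster permutation
#'   check on the band ERSP traces.
#' @param seed Master seed (mandatory for any stochastic stage).
#' @param outdir Optional output directory for result tables.
#' @return A `run_config` list.
#' @export
run_config <- function(n_subjects = 20, trials_per_target = 60,
                       truth = default_reaching_truth(), dataset = NULL,
                       bands = list(alpha = c(8, 13), beta = c(13, 30)),
                       windows = list(baseline = c(-1, 0),
                                      post_cue_late = c(1, 2)),
                       baseline_window = c(-1, 0),
                       ersp_freqs = 4:32, ersp_decimate = 1,
                       wavelet = NULL,
                       gc_freqs = seq(1, 45, by = 0.5), var_order = 30,
                       n_perm = 5000, n_perm_cluster = 500, alpha = 0.05,
                       gc_correction = c("raw", "bh"),
                       target_cluster_check = TRUE,
                       seed = 1, outdir = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  gc_correction <- match.arg(gc_correction)
  cfg <- list(n_subjects = n_subjects, trials_per_target = trials_per_target,
              truth = truth, dataset = dataset, bands = bands,
              windows = windows, baseline_window = baseline_window,
              ersp_freqs = ersp_freqs, ersp_decimate = ersp_decimate,
              wavelet = wavelet, gc_freqs = gc_freqs,
              var_order = var_order, n_perm = n_perm,
              n_perm_cluster = n_perm_cluster, alpha = alpha,
              gc_correction = gc_correction,
              target_cluster_check = target_cluster_check,
              seed = as.integer(seed), outdir = outdir)
  class(cfg) <- "run_config"
  cfg
}

# Group statistical layer, shared by run_full_analysis and the CLI `stats`
# subcommand so that running the stages separately reproduces the pipeline's
# tables exactly. `gc_norm` is the per-subject nested band/condition list of
# normalized gc_matrix objects; `deg` the nested band/condition/in-out
# degree matrices (subjects x ROI).
.group_stats <- function(ersp_window, gc_norm, deg, labels, window_names,
                         bands, n_perm, alpha_lvl, gc_correction, seed) {
  nb <- names(bands)
  ns <- length(gc_norm)
  n_roi <- length(labels)
  wstat_battery <- function(mat, against = NULL) {
    res <- lapply(seq_len(ncol(mat)), function(r) {
      if (is.null(against)) wilcoxon_signed_rank(mat[, r])
      else wilcoxon_signed_rank(mat[, r], against[, r])
    })
    p <- vapply(res, `[[`, numeric(1), "p.value")
    fdr <- bh_fdr(p, alpha_lvl)
    data.frame(statistic = vapply(res, `[[`, numeric(1), "statistic"),
               p_raw = p, p_adjusted = fdr$adjusted,
               rejected = fdr$rejected)
  }

  ersp_stats <- lapply(nb, function(b)
    cbind(roi = labels, band = b, wstat_battery(ersp_window[[b]])))
  names(ersp_stats) <- nb

  hp <- .homologous_pairs(labels)
  lateralization <- lapply(nb, function(b) {
    if (is.null(hp)) return(NULL)
    cbind(pair = sub("^L\\.", "", labels[hp[, 1]]), band = b,
          wstat_battery(ersp_window[[b]][, hp[, 1], drop = FALSE],
                        ersp_window[[b]][, hp[, 2], drop = FALSE]))
  })
  names(lateralization) <- nb

  od <- which(diag(n_roi) == 0)            # off-diagonal linear indices
  pair_names <- outer(labels, labels,
                      function(a, b) paste0(a, "->", b))
  gc_stats <- lapply(nb, function(b) {
    A <- t(vapply(seq_len(ns), function(s)
      gc_norm[[s]][[b]][[window_names[2]]]$values[od],
      numeric(length(od))))
    B <- t(vapply(seq_len(ns), function(s)
      gc_norm[[s]][[b]][[window_names[1]]]$values[od],
      numeric(length(od))))
    p <- .paired_permutation_batch(A, B, n_perm,
                                   seed = derive_seed(seed, 3L,
                                                      match(b, nb)))
    fdr <- bh_fdr(p, alpha_lvl)
    rejected <- if (gc_correction == "bh") fdr$rejected
                else p < alpha_lvl
    data.frame(pair = pair_names[od], band = b,
               mean_diff = colMeans(A - B), p_raw = p,
               p_adjusted = fdr$adjusted, rejected = rejected)
  })
  names(gc_stats) <- nb

  degree_stats <- list()
  for (b in nb) for (k in c("in", "out")) {
    tab <- cbind(roi = labels, band = b, centrality = k,
                 wstat_battery(deg[[b]][[window_names[2]]][[k]],
                               deg[[b]][[window_names[1]]][[k]]))
    degree_stats[[paste(b, k, sep = "_")]] <- tab
  }
  list(ersp_stats = ersp_stats, lateralization = lateralization,
       gc_stats = gc_stats, degree_stats = degree_stats)
}

# Homologous left/right ROI pairs from "L."/"R." prefixed labels.
.homologous_pairs <- function(labels) {
  stems <- sub("^[LR]\\.", "", labels)
  left <- which(startsWith(labels, "L."))
  pairs <- lapply(left, function(l) {
    r <- which(startsWith(labels, "R.") & stems == stems[l])
    if (length(r) == 1) c(l, r) else NULL
  })
  do.call(rbind, pairs)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) the cohort, then per subject: ERSP arm (Morlet CWT,
#' per-target normalization, band and late-window reductions) and
#' connectivity arm (evoked removal, pairwise spectral GC in both condition
#' windows, normalization, degree centralities); then the group statistical
#' layer: (1) late-window band ERSP vs 0 per ROI, Wilcoxon + BH; (2)
#' left-right homologous-pair Wilcoxon + BH; (3) paired sign-flip
#' permutation tests on every ordered ROI pair's normalized GC contrast;
#' (4) in/out-degree contrasts, Wilcoxon + BH; plus the per-target-pair
#' cluster permutation check on band ERSP traces.
#'
#' Deterministic: config + seed fully determine every output.
#'
#' @param config A [run_config()].
#' @return A `result_bundle` list: `ersp_window` (per band, subjects x ROI
#'   matrices), `ersp_stats`, `lateralization`, `gc` (per subject nested
#'   band/condition normalized matrices), `gc_stats`, `degrees`,
#'   `degree_stats`, `target_cluster`, `manifest`.
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dataset <- config$dataset
  if (is.character(dataset)) dataset <- read_reaching_dataset(dataset)
  if (is.null(dataset))
    dataset <- generate_reaching_dataset(
      n_subjects = config$n_subjects,
      trials_per_target = config$trials_per_target,
      truth = config$truth, seed = derive_seed(config$seed, 1L))
  subjects <- dataset$subjects
  ns <- length(subjects)
  labels <- subjects[[1]]$labels
  n_roi <- length(labels)
  bands <- config$bands
  nb <- names(bands)
  upper_closed <- stats::setNames(seq_along(bands) == length(bands), nb)
  base_w <- config$windows[[1]]
  post_w <- config$windows[[2]]

  ersp_window <- lapply(bands, function(b) matrix(
    NA_real_, ns, n_roi, dimnames = list(NULL, labels)))
  band_traces <- lapply(bands, function(b) vector("list", ns))
  gc_norm <- vector("list", ns)
  deg <- list()   # deg[[band]][[cond]][[in|out]]: ns x n_roi
  for (b in nb) for (w in names(config$windows))
    for (k in c("in", "out"))
      deg[[b]][[w]][[k]] <- matrix(NA_real_, ns, n_roi,
                                   dimnames = list(NULL, labels))

  for (s in seq_len(ns)) {
    ep <- subjects[[s]]
    # --- ERSP arm -------------------------------------------------------
    epd <- decimate_epochs(ep, config$ersp_decimate)
    wp <- if (is.null(config$wavelet)) wavelet_params(fs = epd$fs)
          else config$wavelet
    ersp <- compute_ersp(epd, freqs = config$ersp_freqs,
                         baseline_window = config$baseline_window,
                         params = wp)
    for (b in nb) {
      ba <- band_average(ersp, bands[[b]], include_upper = upper_closed[b])
      ersp_window[[b]][s, ] <- window_average(ba, post_w)
      if (config$target_cluster_check)
        band_traces[[b]][[s]] <- band_average(ersp, bands[[b]],
                                              include_upper = upper_closed[b],
                                              per_target = TRUE)$values
    }
    # --- connectivity arm ----------------------------------------------
    epc <- remove_evoked(ep)
    mats <- build_gc_matrices(epc, bands = bands, windows = config$windows,
                              order = config$var_order,
                              freqs = config$gc_freqs)
    gc_norm[[s]] <- lapply(mats, function(bw) lapply(bw, normalize_gc))
    for (b in nb) for (w in names(config$windows)) {
      m <- gc_norm[[s]][[b]][[w]]
      deg[[b]][[w]][["in"]][s, ] <- in_degree(m)
      deg[[b]][[w]][["out"]][s, ] <- out_degree(m)
    }
  }

  # --- group statistics ------------------------------------------------
  st <- .group_stats(ersp_window, gc_norm, deg, labels,
                     window_names = names(config$windows), bands = bands,
                     n_perm = config$n_perm, alpha_lvl = config$alpha,
                     gc_correction = config$gc_correction,
                     seed = config$seed)
  ersp_stats <- st$ersp_stats
  lateralization <- st$lateralization
  gc_stats <- st$gc_stats
  degree_stats <- st$degree_stats
  alpha_lvl <- config$alpha

  target_cluster <- NULL
  if (config$target_cluster_check) {
    target_cluster <- list()
    for (b in nb) {
      tgts <- names(band_traces[[b]][[1]])
      rows <- list()
      if (length(tgts) >= 2) {
        combs <- utils::combn(tgts, 2)
        nt <- ncol(band_traces[[b]][[1]][[1]])
        for (ci in seq_len(ncol(combs))) for (r in seq_len(n_roi)) {
          A <- t(vapply(band_traces[[b]], function(tt)
            tt[[combs[1, ci]]][r, ], numeric(nt)))
          B <- t(vapply(band_traces[[b]], function(tt)
            tt[[combs[2, ci]]][r, ], numeric(nt)))
          cl <- cluster_permutation_test_1d(
            A, B, n_perm = config$n_perm_cluster,
            seed = derive_seed(config$seed, 4L, match(b, nb), ci, r))
          rows[[length(rows) + 1]] <- data.frame(
            band = b, roi = labels[r],
            pair = paste(combs[, ci], collapse = "-"),
            min_cluster_p = if (nrow(cl) == 0) 1 else min(cl$p),
            n_clusters = nrow(cl))
        }
      }
      tab <- do.call(rbind, rows)
      if (!is.null(tab)) {
        fdr <- bh_fdr(tab$min_cluster_p, alpha_lvl)
        tab$p_adjusted <- fdr$adjusted
        tab$rejected <- fdr$rejected
      }
      target_cluster[[b]] <- tab
    }
  }

  bundle <- list(
    ersp_window = ersp_window, ersp_stats = ersp_stats,
    lateralization = lateralization, gc = gc_norm, gc_stats = gc_stats,
    degrees = deg, degree_stats = degree_stats,
    target_cluster = target_cluster,
    manifest = list(
      seed = config$seed, n_subjects = ns, roi_labels = labels,
      bands = bands, windows = config$windows,
      var_order = config$var_order, n_perm = config$n_perm,
      alpha = alpha_lvl, gc_correction = config$gc_correction,
      ersp_freqs = config$ersp_freqs, ersp_decimate = config$ersp_decimate,
      package_version = as.character(utils::packageVersion("reachnet"))))
  class(bundle) <- "result_bundle"
  if (!is.null(config$outdir)) write_result_bundle(bundle, config$outdir)
  bundle
}

#' Write the result bundle as delimited tables plus a JSON manifest
#'
#' @param bundle A `result_bundle` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) utils::write.csv(x, file.path(dir, name),
                                           row.names = FALSE)
  for (b in names(bundle$ersp_window))
    wr(as.data.frame(bundle$ersp_window[[b]]),
       sprintf("ersp_window_%s.csv", b))
  wr(do.call(rbind, bundle$ersp_stats), "ersp_stats.csv")
  if (!all(vapply(bundle$lateralization, is.null, logical(1))))
    wr(do.call(rbind, bundle$lateralization), "lateralization_stats.csv")
  wr(do.call(rbind, bundle$gc_stats), "gc_stats.csv")
  wr(do.call(rbind, bundle$degree_stats), "degree_stats.csv")
  if (!is.null(bundle$target_cluster) &&
      !all(vapply(bundle$target_cluster, is.null, logical(1))))
    wr(do.call(rbind, bundle$target_cluster), "target_cluster_check.csv")
  for (s in seq_along(bundle$gc))
    for (b in names(bundle$gc[[s]]))
      for (w in names(bundle$gc[[s]][[b]]))
        write_gc_matrix(bundle$gc[[s]][[b]][[w]],
                        file.path(dir, sprintf("gc_%02d_%s_%s.csv", s, b, w)))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
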