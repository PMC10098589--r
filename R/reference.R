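#' Machine-learning selection of the reference scan
#'
#' Clusters the magnitude FIDs of a set with k-means (k = 2).  Transients
#' carrying nuisance peaks (residual water, lipids) have higher intensity in
#' the initial points of their cluster's mean signal, so the cluster whose
#' mean signal has the LOWER average over its first 10 points is taken as
#' the nuisance-free cluster; within it the transient with the highest
#' estimated SNR is returned as the reference.
#'
#' Clustering uses the magnitude of the initial `feature_points` samples
#' of each FID: nuisance peaks express themselves in the early, coherent
#' part of the FID, while the late FID is noise whose amplitude varies with
#' SNR — including it makes k-means cluster by noise level instead of by
#' contamination.
#'
#' @param s an [mrs_set()] with at least 2 transients.
#' @param k number of clusters (default 2: contaminated vs clean).
#' @param seed integer seed for the k-means initialization (k-means++-style
#'   multi-restart via `nstart`), or `NULL`.
#' @param feature_points number of initial magnitude samples used as
#'   clustering features.
#' @return list with `index` (the selected reference) and `diagnostics`
#'   (cluster sizes, the two first-10-point averages, the clean-cluster id
#'   and per-transient cluster assignment).
#' @export
select_reference <- function(s, k = 2L, seed = NULL, feature_points = 100L) {
  n <- length(s)
  if (n < 2) stop("select_reference needs at least 2 transients")
  if (!is.null(seed)) set.seed(seed)
  npf <- min(feature_points, s$axis$n_points)
  X <- t(Mod(s$samples[seq_len(npf), , drop = FALSE]))  # n_signals x npf

  km <- tryCatch(stats::kmeans(X, centers = k, nstart = 10, iter.max = 50),
                 error = function(e) NULL)
  snr_all <- vapply(seq_len(n), function(j) estimate_snr(set_transient(s, j)),
                    numeric(1))
  if (is.null(km) || any(tabulate(km$cluster, k) == 0)) {
    warning("k-means clustering degenerate; falling back to global max-SNR")
    return(list(index = which.max(snr_all),
                diagnostics = list(fallback = TRUE, snr = snr_all)))
  }

  n_head <- min(10L, npf)
  head_avg <- vapply(seq_len(k), function(cl) {
    mean(km$centers[cl, seq_len(n_head)])
  }, numeric(1))
  clean_cl <- which.min(head_avg)
  members <- which(km$cluster == clean_cl)
  # Residual-water transients that leak into the clean cluster would still
  # win the |S(0)|-based SNR pick (water inflates the first points), and a
  # water-dominated reference derails spectral registration.  Water sits
  # at the carrier (~0 Hz), so it is the only component that survives a
  # coherent average of the early FID; screen candidates whose coherent
  # mean stands far above the cluster's clean quartile.
  if (length(members) > 3) {
    nc <- min(128L, s$axis$n_points)
    dc <- Mod(colMeans(s$samples[seq_len(nc), members, drop = FALSE]))
    keep <- members[dc <= 5 * stats::quantile(dc, 0.25)]
    if (length(keep) >= 2) members <- keep
  }
  index <- members[which.max(snr_all[members])]

  list(index = index,
       diagnostics = list(
         cluster_sizes = as.integer(km$size),
         head_averages = head_avg,
         clean_cluster = clean_cl,
         assignment = km$cluster,
         snr = snr_all,
         fallback = FALSE))
}
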