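#' Classical multidimensional scaling of a distance matrix
#'
#' Torgerson MDS via [stats::cmdscale()]. When the input is exactly
#' Euclidean-embeddable in `dims` dimensions the embedded pairwise distances
#' reproduce the input. Columns are zero-padded when fewer positive
#' eigenvalues than `dims` exist.
#'
#' @param d a [distance_matrix()] (or any symmetric matrix).
#' @param dims embedding dimension, >= 1.
#' @return numeric matrix (items x dims) with the input labels as rownames.
#' @export
mds_embed <- function(d, dims = 2) {
  stopifnot(dims >= 1)
  n <- nrow(d)
  k <- min(dims, n - 1)
  coords <- stats::cmdscale(stats::as.dist(d), k = k)
  if (ncol(coords) < dims) {
    coords <- cbind(coords,
                    matrix(0, n, dims - ncol(coords)))
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  coords
}

## pooled within-cluster dispersion: sum over clusters of
## (sum of squared pairwise distances within the cluster) / (2 * size)
pooled_wk <- function(dmat, clusters) {
  wk <- 0
  for (cl in unique(clusters)) {
    idx <- which(clusters == cl)
    if (length(idx) < 2) next
    sub <- dmat[idx, idx, drop = FALSE]
    wk <- wk + sum(sub^2) / (2 * length(idx))
  }
  wk
}

ward_cut <- function(dmat, k) {
  stats::cutree(stats::hclust(stats::as.dist(dmat), method = "ward.D2"), k)
}

#' Gap-statistic selection of the number of clusters
#'
#' For each K in `k_min:k_max`, individuals are clustered by Ward linkage on
#' the distance matrix and the pooled within-cluster sum of squared distances
#' `Wk` is recorded. A null curve comes from `n_ref` resamples drawn
#' uniformly in the bounding box of the classical MDS embedding of the data.
#' `gap(K) = mean(log Wk_ref) - log(Wk_obs)`; the selected K is the smallest
#' K with `gap(K) >= gap(K+1) - se(K+1)` (Tibshirani's one-standard-error
#' rule, ties resolved toward smaller K).
#'
#' @param d a [distance_matrix()] over individuals.
#' @param k_min,k_max scanned interval of K (defaults 1 and 6).
#' @param n_ref number of uniform reference resamples (default 100).
#' @param seed integer seed; results are deterministic given it.
#' @return list of class `cluster_selection` with `best_k`,
#'   `observed_log_wk`, `reference_log_wk`, `gap`, `se`, `k_range`, and the
#'   cluster assignment `clusters` at `best_k`.
#' @export
select_k_gap <- function(d, k_min = 1, k_max = 6, n_ref = 100, seed = 1) {
  stopifnot(k_min >= 1, k_max >= k_min, n_ref >= 1)
  dmat <- unclass(as.matrix(d))
  if (anyNA(dmat)) stop("distance matrix contains NA cells")
  n <- nrow(dmat)
  if (k_max > n) {
    warning("k_max truncated to the number of individuals (", n, ")")
    k_max <- n
    k_min <- min(k_min, k_max)
  }
  ks <- k_min:k_max
  set.seed(seed)

  log_wk_obs <- vapply(ks, function(k) log(pooled_wk(dmat, ward_cut(dmat, k))),
                       numeric(1))

  emb <- mds_embed(d, dims = max(2, min(n - 1, 5)))
  lo <- apply(emb, 2, min)
  hi <- apply(emb, 2, max)
  ref <- matrix(NA_real_, n_ref, length(ks))
  for (b in seq_len(n_ref)) {
    pts <- sapply(seq_along(lo), function(j) stats::runif(n, lo[j], hi[j]))
    rd <- as.matrix(stats::dist(pts))
    ref[b, ] <- vapply(ks, function(k) log(pooled_wk(rd, ward_cut(rd, k))),
                       numeric(1))
  }
  ref_mean <- colMeans(ref)
  se <- apply(ref, 2, stats::sd) * sqrt(1 + 1 / n_ref)
  gap <- ref_mean - log_wk_obs

  best_k <- ks[length(ks)]
  if (length(ks) > 1) {
    for (i in seq_len(length(ks) - 1)) {
      if (is.finite(gap[i]) && gap[i] >= gap[i + 1] - se[i + 1]) {
        best_k <- ks[i]
        break
      }
    }
  }
  structure(list(best_k = best_k,
                 k_range = ks,
                 observed_log_wk = stats::setNames(log_wk_obs, ks),
                 reference_log_wk = stats::setNames(ref_mean, ks),
                 gap = stats::setNames(gap, ks),
                 se = stats::setNames(se, ks),
                 clusters = ward_cut(dmat, best_k)),
            class = "cluster_selection")
}

#' @exportS3Method base::print
print.cluster_selection <- function(x, ...) {
  cat(sprintf("cluster_selection: best K = %d (scanned %d..%d)\n",
              x$best_k, min(x$k_range), max(x$k_range)))
  invisible(x)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou–Nei neighbour joining via [ape::nj()]. On additive matrices the
#' tree path lengths reproduce the input distances exactly.
#'
#' @param d a [distance_matrix()] with >= 3 labels.
#' @return Newick string (with a `phylo` attribute carrying the tree object).
#' @export
nj_tree <- function(d) {
  dmat <- as.matrix(d)
  if (nrow(dmat) < 3) stop("need at least three labels")
  if (any(abs(dmat - t(dmat)) > 1e-8, na.rm = TRUE))
    stop("distance matrix must be symmetric")
  tr <- ape::nj(stats::as.dist(dmat))
  nwk <- ape::write.tree(tr)
  attr(nwk, "phylo") <- tr
  nwk
}
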