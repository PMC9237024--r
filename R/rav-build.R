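#' Number of clusters for a pooled set of components
#'
#' The cluster count is `round(n_pcs / d)` with half-up rounding,
#' bounded below by 1. The divisor `d` is the calibration knob of the
#' model: smaller `d` gives more, tighter clusters.
#'
#' @param n_pcs Total number of pooled principal components.
#' @param d Positive divisor (default 2.25, the calibrated value).
#' @return Integer cluster count.
#' @examples
#' compute_cluster_count(20 * 536, 2.25)  # 4764
#' @export
compute_cluster_count <- function(n_pcs, d = 2.25) {
  if (!is.numeric(d) || length(d) != 1L || d <= 0) stop("'d' must be > 0")
  if (!is.numeric(n_pcs) || n_pcs < 1) stop("'n_pcs' must be >= 1")
  max(1L, as.integer(floor(n_pcs / d + 0.5)))
}

#' Pool per-study loading vectors into one matrix
#'
#' @param pc_results List of `pc_result` objects on a shared gene set.
#' @param controls Optional list of `pc_result`s from negative-control
#'   datasets; only their first `control_pcs` components are pooled and
#'   flagged.
#' @param control_pcs Number of leading components taken from each
#'   control (default 1).
#' @return An object of class `pooled_loadings`: list with `loadings`
#'   (genes x P matrix) and `provenance` (data.frame `column`,
#'   `study_id`, `pc`, `var_explained`, `control`).
#' @export
pool_loadings <- function(pc_results, controls = NULL, control_pcs = 1L) {
  stopifnot(length(pc_results) >= 1L)
  take <- function(res, npc, flag) {
    npc <- min(npc, ncol(res$loadings))
    list(load = res$loadings[, seq_len(npc), drop = FALSE],
         prov = data.frame(study_id = res$study_id, pc = seq_len(npc),
                           var_explained = res$var_explained[seq_len(npc)],
                           control = flag, stringsAsFactors = FALSE))
  }
  parts <- lapply(pc_results, take, npc = Inf, flag = FALSE)
  if (length(controls))
    parts <- c(parts, lapply(controls, take, npc = control_pcs, flag = TRUE))
  genes <- rownames(parts[[1L]]$load)
  for (p in parts)
    if (!identical(rownames(p$load), genes))
      stop("all pooled loading matrices must share the same gene rows")
  loadings <- do.call(cbind, lapply(parts, `[[`, "load"))
  prov <- do.call(rbind, lapply(parts, `[[`, "prov"))
  prov <- cbind(column = seq_len(nrow(prov)), prov)
  colnames(loadings) <- sprintf("%s.PC%d", prov$study_id, prov$pc)
  rownames(prov) <- NULL
  structure(list(loadings = loadings, provenance = prov),
            class = "pooled_loadings")
}

#' @export
print.pooled_loadings <- function(x, ...) {
  cat(sprintf("<pooled_loadings> %d genes x %d components from %d studies (%d control columns)\n",
              nrow(x$loadings), ncol(x$loadings),
              length(unique(x$provenance$study_id)), sum(x$provenance$control)))
  invisible(x)
}

#' Spearman distance between loading vectors
#'
#' `d(i, j) = 1 - rho_s(i, j)` where `rho_s` is Spearman's rank
#' correlation; distances lie in `[0, 2]` with 0 on the diagonal.
#'
#' @param x A `pooled_loadings` object or a numeric matrix whose
#'   columns are compared.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
spearman_distance <- function(x) {
  m <- if (inherits(x, "pooled_loadings")) x$loadings else x
  if (!is.matrix(m) || ncol(m) < 2L)
    stop("at least 2 columns are required")
  const <- apply(m, 2L, function(v) diff(range(v)) == 0)
  if (any(const))
    stop("constant column(s) ", paste(which(const), collapse = ", "),
         ": rank correlation is undefined")
  d <- 1 - stats::cor(m, method = "spearman")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Ward agglomeration on a distance matrix
#'
#' Hierarchical clustering with the classic Ward coefficients of the
#' Lance-Williams recurrence applied to the *unsquared* input distances
#' (`stats::hclust` method `"ward.D"`), cut to exactly `K` groups.
#' Using this update on a non-Euclidean correlation-based distance is a
#' heuristic, adopted deliberately for its behavior on pooled loading
#' vectors.
#'
#' @param dist A symmetric distance matrix or `dist` object.
#' @param K Number of clusters, between 1 and the number of columns.
#' @return List of class `rav_clustering` with `labels` (integer vector
#'   in `1..K`, labelled in order of first appearance), `K` and `tree`
#'   (the `hclust` object).
#' @export
ward_cluster <- function(dist, K) {
  d <- stats::as.dist(dist)
  n <- attr(d, "Size")
  if (K < 1 || K > n) stop("'K' must be between 1 and ", n)
  tree <- stats::hclust(d, method = "ward.D")
  raw <- stats::cutree(tree, k = K)
  labels <- match(raw, unique(raw))      # contiguous, first-appearance order
  structure(list(labels = labels, K = as.integer(K), tree = tree),
            class = "rav_clustering")
}

#' Sign-align cluster members and average them
#'
#' PCA loadings are sign-ambiguous; members are aligned to the first
#' member of the cluster (a member is flipped when its Pearson
#' correlation with the reference is negative) before the element-wise
#' mean. The average is stored as-is, not re-normalized: downstream
#' comparisons are correlation-based and therefore scale-invariant.
#'
#' @param members Genes x m matrix of member loadings (m >= 1).
#' @return The averaged loading vector.
#' @export
align_and_average <- function(members) {
  if (is.null(dim(members))) members <- cbind(members)
  m <- ncol(members)
  if (m == 0L) stop("a cluster needs at least one member")
  if (m == 1L) return(members[, 1L])
  ref <- members[, 1L]
  for (j in 2:m) {
    r <- suppressWarnings(stats::cor(ref, members[, j]))
    if (is.na(r)) r <- sum(ref * members[, j])
    if (r < 0) members[, j] <- -members[, j]
  }
  rowMeans(members)
}

#' Average silhouette width per cluster
#'
#' Standard silhouette `s(i) = (b - a) / max(a, b)` computed from the
#' supplied distance matrix, averaged within each cluster; singleton
#' clusters get width 0 by convention.
#'
#' @param dist Symmetric distance matrix or `dist` object.
#' @param labels Integer cluster labels (or an `rav_clustering`).
#' @return Numeric vector of per-cluster average widths, named by
#'   cluster label.
#' @export
cluster_avg_silhouette <- function(dist, labels) {
  if (inherits(labels, "rav_clustering")) labels <- labels$labels
  K <- length(unique(labels))
  if (K < 2L) stop("silhouette widths require at least 2 clusters")
  sil <- cluster::silhouette(labels, stats::as.dist(dist))
  widths <- sil[, "sil_width"]
  out <- tapply(widths, labels, mean)
  out[as.character(sort(unique(labels)))]
}

#' Calibrate the cluster-count divisor with negative controls
#'
#' For each divisor in `d_grid` the pooled components are cut into
#' `compute_cluster_count(P, d)` clusters and we record whether every
#' negative-control column lands in a singleton cluster. The chosen `d`
#' is the largest (i.e. the fewest clusters) achieving full separation
#' of all controls.
#'
#' @param pooled A `pooled_loadings` with control columns flagged.
#' @param d_grid Candidate divisors (default the standard sweep
#'   `7, 6, 5, 4, 3, 2.75, 2.5, 2.25, 2`).
#' @return List with `chosen_d` (`NA` if no divisor separates) and
#'   `report` (data.frame `d`, `K`, `n_controls_singleton`,
#'   `separated`).
#' @export
calibrate_d <- function(pooled, d_grid = c(7, 6, 5, 4, 3, 2.75, 2.5, 2.25, 2)) {
  stopifnot(inherits(pooled, "pooled_loadings"))
  ctrl <- which(pooled$provenance$control)
  if (!length(ctrl)) stop("no control columns are flagged in 'pooled'")
  P <- ncol(pooled$loadings)
  d_grid <- sort(d_grid, decreasing = TRUE)
  dm <- spearman_distance(pooled)
  rows <- lapply(d_grid, function(d) {
    K <- compute_cluster_count(P, d)
    cl <- ward_cluster(dm, K)
    sizes <- table(cl$labels)
    singleton <- sizes[as.character(cl$labels[ctrl])] == 1L
    data.frame(d = d, K = K, n_controls_singleton = sum(singleton),
               separated = all(singleton))
  })
  report <- do.call(rbind, rows)
  ok <- report$d[report$separated]
  list(chosen_d = if (length(ok)) max(ok) else NA_real_, report = report)
}

#' Summary statistics of a cluster-size distribution
#'
#' Given the total number of pooled components, the cluster count and
#' the counts of singleton and two-element clusters, derives the
#' multi-element cluster count, the mean size of multi-element clusters
#' and the percentage of multi-element clusters of size two.
#'
#' @param n_pcs Total pooled components.
#' @param n_clusters Total clusters.
#' @param n_singleton Clusters of size 1.
#' @param n_two Clusters of size 2.
#' @return List with `n_multi`, `mean_multi_size`, `pct_two`.
#' @export
cluster_size_stats <- function(n_pcs, n_clusters, n_singleton, n_two) {
  stopifnot(n_clusters >= n_singleton, n_pcs >= n_clusters)
  n_multi <- as.integer(n_clusters - n_singleton)
  list(n_multi = n_multi,
       mean_multi_size = (n_pcs - n_singleton) / n_multi,
       pct_two = 100 * n_two / n_multi)
}
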