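#' Fit a replicable-axes-of-variation model
#'
#' The central fitting function of the package. Each study is reduced
#' to its most variable genes, the studies are restricted to their
#' common genes and row-normalized over the pooled sample set, each
#' study is decomposed by PCA, the top `k` loading vectors per study
#' are pooled and clustered (Ward agglomeration on Spearman distance,
#' `round(P / d)` clusters), and every cluster is sign-aligned and
#' averaged into one Replicable Axis of Variation (RAV).
#'
#' @param studies List of [expr_study()] objects on the log scale
#'   (at least 2).
#' @param meta Optional study metadata data.frame (columns `studyId`,
#'   `sampleCount`, `title`, `meshTerms`), used for provenance lookups
#'   and MeSH annotation.
#' @param k Principal components pooled per study (default 20).
#' @param d Cluster-count divisor (default 2.25).
#' @param var_quantile Fraction of most-variable genes kept per study
#'   before intersecting (default 0.90).
#' @return An object of class `rav_model` with components:
#'   \describe{
#'     \item{index}{genes x K matrix of averaged loadings (the RAV
#'       index).}
#'     \item{membership}{per pooled component: study, PC number,
#'       variance explained and assigned cluster.}
#'     \item{cluster_info}{per RAV: size, number of distinct studies,
#'       average silhouette width, mean variance explained.}
#'     \item{norm_stats}{pooled per-gene mean/sd, reusable for
#'       normalizing further data.}
#'     \item{gsea, mesh}{annotation stores, filled by
#'       [annotate_gsea()] / [annotate_mesh()].}
#'     \item{params}{build parameters.}
#'   }
#' @seealso [validate()], [sample_scores()], [annotate_gsea()],
#'   [annotate_mesh()], [save_model()].
#' @export
rav_model <- function(studies, meta = NULL, k = 20, d = 2.25,
                      var_quantile = 0.90) {
  if (length(studies) < 2L) stop("at least 2 studies are required")
  gene_lists <- lapply(studies, top_variable_genes, q = var_quantile)
  genes <- common_genes(gene_lists)
  if (!length(genes)) stop("no genes are shared by all studies")
  norm <- pooled_row_normalize(studies, genes)
  pcs <- lapply(norm$studies, dataset_pca, k = k)
  pooled <- pool_loadings(pcs)
  P <- ncol(pooled$loadings)
  K <- compute_cluster_count(P, d)
  dm <- spearman_distance(pooled)
  cl <- ward_cluster(dm, K)
  .assemble_model(pooled, cl, dm, norm$stats, meta,
                  params = list(k = as.integer(k), d = d,
                                var_quantile = var_quantile,
                                n_pcs = as.integer(P), K = as.integer(K)))
}

# Shared assembly used by rav_model() and by calibration experiments.
.assemble_model <- function(pooled, cl, dm, norm_stats, meta, params) {
  K <- cl$K
  labels <- cl$labels
  index <- vapply(seq_len(K), function(g) {
    align_and_average(pooled$loadings[, labels == g, drop = FALSE])
  }, numeric(nrow(pooled$loadings)))
  dimnames(index) <- list(rownames(pooled$loadings), paste0("RAV", seq_len(K)))
  membership <- cbind(pooled$provenance, cluster = labels)
  sw <- if (K >= 2L) cluster_avg_silhouette(dm, labels) else
    stats::setNames(0, "1")
  sizes <- as.integer(table(factor(labels, levels = seq_len(K))))
  cluster_info <- data.frame(
    rav = paste0("RAV", seq_len(K)),
    size = sizes,
    n_studies = as.integer(tapply(membership$study_id, factor(labels, seq_len(K)),
                                  function(s) length(unique(s)))),
    avg_sw = as.numeric(sw[as.character(seq_len(K))]),
    mean_var_explained = as.numeric(tapply(membership$var_explained,
                                           factor(labels, seq_len(K)), mean)),
    stringsAsFactors = FALSE)
  structure(list(index = index, membership = membership,
                 cluster_info = cluster_info, norm_stats = norm_stats,
                 studies = meta, gsea = NULL, gsea_collection = NULL,
                 mesh = NULL, mesh_universe = NULL, params = params),
            class = "rav_model")
}

#' @export
print.rav_model <- function(x, ...) {
  ci <- x$cluster_info
  cat(sprintf("<rav_model> %d RAVs over %d genes\n",
              ncol(x$index), nrow(x$index)))
  cat(sprintf("  trained on %d studies, %d pooled PCs (k = %s, d = %s)\n",
              length(unique(x$membership$study_id)), x$params$n_pcs,
              format(x$params$k), format(x$params$d)))
  cat(sprintf("  cluster sizes: %d singleton, %d multi-element (max %d)\n",
              sum(ci$size == 1L), sum(ci$size > 1L), max(ci$size)))
  cat(sprintf("  annotations: GSEA %s, MeSH %s\n",
              if (is.null(x$gsea)) "absent" else "present",
              if (is.null(x$mesh)) "absent" else "present"))
  invisible(x)
}

#' @export
summary.rav_model <- function(object, ...) {
  ci <- object$cluster_info
  out <- list(
    n_rav = nrow(ci),
    n_genes = nrow(object$index),
    n_studies = length(unique(object$membership$study_id)),
    n_pcs = object$params$n_pcs,
    params = object$params,
    size_table = table(ci$size),
    n_singleton = sum(ci$size == 1L),
    n_multi = sum(ci$size > 1L),
    mean_multi_size = if (any(ci$size > 1L)) mean(ci$size[ci$size > 1L]) else NA_real_,
    avg_sw = stats::quantile(ci$avg_sw, c(0, .25, .5, .75, 1)))
  class(out) <- "summary.rav_model"
  out
}

#' @export
print.summary.rav_model <- function(x, ...) {
  cat(sprintf("RAV model: %d RAVs, %d genes, %d studies (%d pooled PCs)\n",
              x$n_rav, x$n_genes, x$n_studies, x$n_pcs))
  cat(sprintf("  singleton clusters: %d; multi-element: %d (mean size %.3f)\n",
              x$n_singleton, x$n_multi, x$mean_multi_size))
  cat("  cluster-size distribution:\n")
  print(x$size_table)
  cat("  average silhouette width quantiles:\n")
  print(round(x$avg_sw, 3))
  invisible(x)
}

#' @describeIn rav_model the RAV index matrix (genes x RAVs).
#' @param object,... Method arguments.
#' @export
coef.rav_model <- function(object, ...) object$index

#' Predict method: interpret a new dataset against a RAV model
#'
#' `type = "validation"` returns per-RAV validation scores (see
#' [validate()]); `type = "scores"` returns per-sample scores for the
#' requested RAVs (see [sample_scores()]).
#'
#' @param object A `rav_model`.
#' @param newdata An [expr_study()].
#' @param type `"validation"` or `"scores"`.
#' @param ... Passed to [validate()] or [sample_scores()].
#' @export
predict.rav_model <- function(object, newdata,
                              type = c("validation", "scores"), ...) {
  type <- match.arg(type)
  if (type == "validation") validate(newdata, object, ...)
  else sample_scores(newdata, object, ...)
}

#' Plot a RAV model overview
#'
#' Scatter of cluster size against average silhouette width, the two
#' quantities used to judge how replicable and tight each RAV is.
#'
#' @param x A `rav_model`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rav_model <- function(x, ...) {
  ci <- x$cluster_info
  graphics::plot(jitter(ci$size, amount = 0.15), ci$avg_sw,
                 xlab = "cluster size (member PCs)",
                 ylab = "average silhouette width",
                 main = "RAV cluster quality", pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.6), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
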