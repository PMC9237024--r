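#' Validate a new dataset against a RAV model
#'
#' The new dataset (counts are routed through [cpm_filter()] first) is
#' restricted to the genes shared with the model, gene rows are
#' centered, the dataset is decomposed by PCA, and Pearson correlations
#' between each of the top `n_pc` loading vectors and every RAV
#' (restricted to the common genes) are computed. The per-RAV
#' validation score is the signed maximum correlation over the PCs
#' (RAV orientation is arbitrary after sign alignment; set
#' `absolute = TRUE` to rank by |r| instead, reporting the signed value
#' attaining it).
#'
#' @param new An [expr_study()] (log scale, or counts).
#' @param model A [rav_model()].
#' @param n_pc Number of top PCs of the new dataset to correlate
#'   (default 8; truncated with a warning when fewer are available).
#' @param min_overlap Minimum gene overlap with the model (default
#'   1000); a warning is raised below 50% of the model's genes.
#' @param absolute Rank by absolute correlation (default `FALSE`).
#' @return Object of class `rav_validation`: list with `cor` (PCs x
#'   RAVs Pearson matrix), `scores` (data.frame `rav`, `score`, `pc`,
#'   `avg_sw`, `cluster_size`) and `dataset`.
#' @export
validate <- function(new, model, n_pc = 8, min_overlap = 1000,
                     absolute = FALSE) {
  stopifnot(inherits(new, "expr_study"), inherits(model, "rav_model"))
  if (new$scale == "counts") new <- cpm_filter(new)
  genes <- intersect(rownames(model$index), genes_of(new))
  if (length(genes) < min_overlap)
    stop(sprintf("gene overlap with the model is %d, below the floor of %d",
                 length(genes), min_overlap))
  if (length(genes) < 0.5 * nrow(model$index))
    warning("gene overlap is below 50% of the model's genes")
  avail <- min(ncol(new$values) - 1L, length(genes))
  if (n_pc > avail) {
    warning(sprintf("only %d PCs available; truncating n_pc from %d", avail, n_pc))
    n_pc <- avail
  }
  sub <- expr_study(new$values[genes, , drop = FALSE], new$study_id, "log")
  pcs <- suppressWarnings(dataset_pca(sub, k = n_pc))
  cc <- stats::cor(pcs$loadings, model$index[genes, , drop = FALSE])
  pick <- apply(cc, 2L, function(v)
    if (absolute) which.max(abs(v)) else which.max(v))
  score <- cc[cbind(pick, seq_len(ncol(cc)))]
  scores <- data.frame(rav = colnames(model$index), score = score,
                       pc = as.integer(pick),
                       avg_sw = model$cluster_info$avg_sw,
                       cluster_size = model$cluster_info$size,
                       stringsAsFactors = FALSE)
  structure(list(cor = cc, scores = scores, dataset = new$study_id),
            class = "rav_validation")
}

#' @export
print.rav_validation <- function(x, n = 5, ...) {
  cat(sprintf("<rav_validation> dataset '%s': %d PCs x %d RAVs\n",
              x$dataset, nrow(x$cor), ncol(x$cor)))
  top <- x$scores[order(-x$scores$score), ][seq_len(min(n, nrow(x$scores))), ]
  rownames(top) <- NULL
  cat("top validated RAVs:\n")
  print(transform(top, score = round(score, 3), avg_sw = round(avg_sw, 3)))
  invisible(x)
}

#' Tabulate validation results across datasets
#'
#' Keeps the RAVs whose score exceeds `cutoff` in at least one dataset
#' (or, when `top_n` is given, the union of each dataset's `top_n`
#' highest-scoring RAVs) and tabulates scores per dataset.
#'
#' @param results List of `rav_validation` objects.
#' @param cutoff Display threshold (default 0.7).
#' @param top_n Alternative selection: union of per-dataset top `n`.
#' @return Data.frame, RAVs in rows, one score column per dataset
#'   (empty when nothing passes).
#' @export
heatmap_table <- function(results, cutoff = 0.7, top_n = NULL) {
  stopifnot(length(results) >= 1L)
  nm <- vapply(results, function(r) r$dataset, "")
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  sc <- do.call(cbind, lapply(results, function(r) r$scores$score))
  dimnames(sc) <- list(results[[1L]]$scores$rav, nm)
  keep <- if (is.null(top_n)) {
    apply(sc, 1L, max) > cutoff
  } else {
    rownames(sc) %in% unique(unlist(lapply(seq_along(results), function(j)
      rownames(sc)[order(-sc[, j])][seq_len(min(top_n, nrow(sc)))])))
  }
  as.data.frame(sc[keep, , drop = FALSE])
}

#' Per-sample scores for selected RAVs
#'
#' Gene rows of the new dataset are z-scored over its samples
#' (zero-variance rows dropped), restricted to the genes shared with
#' the model, and each sample's z-vector is projected onto the RAV
#' loading: `score(sample, RAV) = z . w / (n_genes * |w|)`, where `|w|`
#' is the norm of the RAV restricted to the common genes. The
#' normalization stabilizes the scale across RAVs; any strictly
#' monotone variant preserves rank-based downstream results.
#'
#' @param new An [expr_study()] (counts are CPM-filtered first).
#' @param model A [rav_model()].
#' @param rav_ids RAV names (e.g. `"RAV3"`) or indices; defaults to
#'   all RAVs.
#' @param min_overlap Minimum gene overlap (default 1000).
#' @return Samples x RAVs numeric matrix.
#' @export
sample_scores <- function(new, model, rav_ids = NULL, min_overlap = 1000) {
  stopifnot(inherits(new, "expr_study"), inherits(model, "rav_model"))
  if (new$scale == "counts") new <- cpm_filter(new)
  if (is.null(rav_ids)) rav_ids <- colnames(model$index)
  if (is.numeric(rav_ids)) rav_ids <- paste0("RAV", rav_ids)
  missing_ids <- setdiff(rav_ids, colnames(model$index))
  if (length(missing_ids))
    stop("unknown RAV id(s): ", paste(missing_ids, collapse = ", "))
  genes <- intersect(rownames(model$index), genes_of(new))
  if (length(genes) < min_overlap)
    stop(sprintf("gene overlap with the model is %d, below the floor of %d",
                 length(genes), min_overlap))
  x <- new$values[genes, , drop = FALSE]
  sds <- row_sds(x)
  ok <- sds > 0
  x <- (x[ok, , drop = FALSE] - rowMeans(x[ok, , drop = FALSE])) / sds[ok]
  w <- model$index[genes[ok], rav_ids, drop = FALSE]
  norms <- sqrt(colSums(w^2))
  if (any(norms == 0)) stop("RAV with zero norm on the common genes")
  out <- t(x) %*% w / (nrow(x) * rep(norms, each = ncol(x)))
  dimnames(out) <- list(colnames(new$values), rav_ids)
  out
}

#' Associate a continuous sample variable with RAV scores
#'
#' R-squared is the squared Pearson correlation between the variable
#' and each RAV's score column, with missing values dropped pairwise.
#'
#' @param scores Samples x RAVs matrix from [sample_scores()].
#' @param variable Numeric vector, one value per sample (may contain
#'   `NA`).
#' @return List with `r2` (named vector) and `best` (name of the
#'   argmax RAV).
#' @export
meta_association_r2 <- function(scores, variable) {
  if (length(variable) != nrow(scores))
    stop("'variable' must have one value per sample")
  ok <- !is.na(variable)
  if (sum(ok) < 3L) stop("fewer than 3 non-missing values")
  if (stats::sd(variable[ok]) == 0) stop("'variable' is constant")
  r2 <- apply(scores, 2L, function(s) {
    use <- ok & !is.na(s)
    if (sum(use) < 3L) return(NA_real_)
    stats::cor(variable[use], s[use])^2
  })
  list(r2 = r2, best = names(r2)[which.max(r2)])
}

#' Interpretation flags per RAV
#'
#' Flags RAVs whose interpretation needs caution:
#' `SINGLE_ELEMENT` (cluster of one PC — not a replicated signal),
#' `ANNOTATION_OUT_OF_RANGE` (no enriched gene set, or more than
#' `round(0.05 * collection size)` — "too many"), and `SINGLE_STUDY`
#' (a multi-element cluster built from one study only).
#'
#' @param model An annotated [rav_model()].
#' @param n_sets Size of the gene set collection used for annotation;
#'   defaults to the size recorded at annotation time.
#' @return Data.frame `rav`, `flags` (comma-separated; empty when
#'   clean), `flagged` (logical).
#' @export
flag_ravs <- function(model, n_sets = NULL) {
  stopifnot(inherits(model, "rav_model"))
  if (is.null(n_sets)) {
    if (is.null(model$gsea_collection))
      stop("'n_sets' is required for a model without stored GSEA annotation")
    n_sets <- model$gsea_collection$n_sets
  }
  too_many <- round(0.05 * n_sets)
  ci <- model$cluster_info
  n_enriched <- if (is.null(model$gsea)) rep(0L, nrow(ci)) else
    as.integer(table(factor(model$gsea$rav, levels = ci$rav)))
  flags <- lapply(seq_len(nrow(ci)), function(i) {
    f <- character()
    if (ci$size[i] == 1L) f <- c(f, "SINGLE_ELEMENT")
    if (n_enriched[i] == 0L || n_enriched[i] > too_many)
      f <- c(f, "ANNOTATION_OUT_OF_RANGE")
    if (ci$size[i] > 1L && ci$n_studies[i] == 1L) f <- c(f, "SINGLE_STUDY")
    f
  })
  data.frame(rav = ci$rav,
             flags = vapply(flags, paste, "", collapse = ","),
             flagged = lengths(flags) > 0L, stringsAsFactors = FALSE)
}

# Emits the user-facing caution when flagged RAVs appear in an output.
warn_if_flagged <- function(model, rav_ids) {
  fl <- tryCatch(flag_ravs(model), error = function(e) NULL)
  if (is.null(fl)) return(invisible())
  bad <- fl[fl$flagged & fl$rav %in% rav_ids, , drop = FALSE]
  if (nrow(bad))
    message("note: interpret with caution - flagged RAV(s): ",
            paste(sprintf("%s [%s]", bad$rav, bad$flags), collapse = "; "))
  invisible()
}

#' Studies contributing to one RAV
#'
#' @param model A [rav_model()].
#' @param rav_id RAV name (e.g. `"RAV3"`) or index.
#' @return Data.frame of member PCs with study id, PC number, variance
#'   explained and (when metadata is attached) study title.
#' @export
find_studies_in_cluster <- function(model, rav_id) {
  r <- resolve_rav(model, rav_id)
  mem <- model$membership[model$membership$cluster == r,
                          c("study_id", "pc", "var_explained"), drop = FALSE]
  if (!is.null(model$studies)) {
    ix <- match(mem$study_id, model$studies$studyId)
    mem$title <- model$studies$title[ix]
    mem$sampleCount <- model$studies$sampleCount[ix]
  }
  rownames(mem) <- NULL
  warn_if_flagged(model, paste0("RAV", r))
  mem
}

#' Top enriched pathways of one RAV
#'
#' @param model An annotated [rav_model()].
#' @param rav_id RAV name or index.
#' @param n Number of rows returned, ordered by decreasing |NES|
#'   (default 10; all rows when fewer are stored).
#' @return Data.frame of enrichment rows.
#' @export
subset_enriched_pathways <- function(model, rav_id, n = 10) {
  if (is.null(model$gsea)) stop("the model carries no GSEA annotation")
  r <- resolve_rav(model, rav_id)
  rows <- model$gsea[model$gsea$rav == paste0("RAV", r), , drop = FALSE]
  rows <- rows[order(-abs(rows$NES)), , drop = FALSE]
  rows <- utils::head(rows, n)
  rownames(rows) <- NULL
  rows
}

#' Scored MeSH terms of one RAV
#'
#' @param model A MeSH-annotated [rav_model()].
#' @param rav_id RAV name or index.
#' @return Data.frame `term`, `count`, `score`, descending by score.
#' @export
mesh_table <- function(model, rav_id) {
  if (is.null(model$mesh)) stop("the model carries no MeSH annotation")
  r <- resolve_rav(model, rav_id)
  rows <- model$mesh[model$mesh$rav == paste0("RAV", r),
                     c("term", "count", "score"), drop = FALSE]
  rows <- rows[order(-rows$score, rows$term), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

resolve_rav <- function(model, rav_id) {
  if (is.numeric(rav_id)) rav_id <- paste0("RAV", rav_id)
  r <- match(rav_id, colnames(model$index))
  if (is.na(r)) stop("unknown RAV id: ", rav_id)
  r
}
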