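#' Decide which studies enter model training
#'
#' Studies are excluded when they have more than 1000 samples (large
#' studies are disproportionately single-cell collections), fewer than
#' 50 samples, or carry the MeSH term "Single-Cell Analysis". Records
#' without a usable sample count are rejected with a diagnostic reason.
#'
#' @param study_meta Data.frame with columns `studyId`, `sampleCount`
#'   and `meshTerms` (list column or pipe-separated strings), as
#'   returned by [read_study_metadata()].
#' @param min_samples,max_samples Inclusive sample-count bounds
#'   (defaults 50 and 1000).
#' @param exclude_terms MeSH terms that disqualify a study.
#' @return Data.frame with columns `studyId`, `include` (logical; `NA`
#'   for rejected records) and `reason`.
#' @export
study_filter <- function(study_meta, min_samples = 50, max_samples = 1000,
                         exclude_terms = "Single-Cell Analysis") {
  if (!"sampleCount" %in% names(study_meta))
    stop("study metadata must contain a 'sampleCount' column")
  terms <- study_meta$meshTerms
  if (is.character(terms))
    terms <- lapply(strsplit(terms, "|", fixed = TRUE), function(v) v[nzchar(v)])
  if (is.null(terms))
    terms <- rep(list(character()), nrow(study_meta))
  n <- suppressWarnings(as.numeric(study_meta$sampleCount))
  include <- rep(NA, nrow(study_meta))
  reason <- character(nrow(study_meta))
  for (i in seq_len(nrow(study_meta))) {
    if (is.na(n[i])) {
      reason[i] <- "missing or non-numeric sampleCount"
      next
    }
    if (n[i] > max_samples) {
      include[i] <- FALSE; reason[i] <- sprintf("more than %d samples", max_samples)
    } else if (n[i] < min_samples) {
      include[i] <- FALSE; reason[i] <- sprintf("fewer than %d samples", min_samples)
    } else if (length(intersect(terms[[i]], exclude_terms))) {
      include[i] <- FALSE; reason[i] <- "excluded MeSH term"
    } else {
      include[i] <- TRUE; reason[i] <- ""
    }
  }
  data.frame(studyId = as.character(study_meta$studyId), include = include,
             reason = reason, stringsAsFactors = FALSE)
}

#' Select the most variable genes of a study
#'
#' Keeps the top `q` fraction of genes ranked by within-study standard
#' deviation. The cut is inclusive: genes tied with the boundary value
#' are retained, so exactly `ceiling(q * G)` genes return when all
#' standard deviations are distinct and possibly more under ties.
#'
#' @param m An [expr_study()] on the log scale with at least 2 samples.
#' @param q Fraction of genes to keep (default 0.90).
#' @return Character vector of retained gene identifiers, in the input
#'   row order.
#' @export
top_variable_genes <- function(m, q = 0.90) {
  stopifnot(inherits(m, "expr_study"))
  if (m$scale != "log")
    stop("top_variable_genes() expects log-scale values")
  if (ncol(m$values) < 2L)
    stop("at least 2 samples are required to compute per-gene sd")
  if (q <= 0 || q > 1) stop("'q' must be in (0, 1]")
  sds <- row_sds(m$values)
  n_keep <- ceiling(q * length(sds))
  thr <- sort(sds, decreasing = TRUE)[n_keep]
  rownames(m$values)[sds >= thr]
}

row_sds <- function(x) {
  mu <- rowMeans(x)
  sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
}

#' Intersect gene lists across studies
#'
#' @param gene_lists List of character vectors (one per study).
#' @return The common genes, sorted in C-locale lexicographic order.
#'   An empty intersection is allowed but raises a warning.
#' @export
common_genes <- function(gene_lists) {
  if (!length(gene_lists)) stop("at least one gene list is required")
  common <- Reduce(intersect, gene_lists)
  if (!length(common)) warning("the gene lists have an empty intersection")
  sort(unique(common), method = "radix")
}

#' Row-normalize studies over the pooled sample set
#'
#' Per-gene mean and standard deviation are computed over the
#' concatenation of all samples from all studies (never per study, so
#' between-study scale differences are preserved as signal), and every
#' gene row is transformed to `(x - mean) / sd`. Genes with zero pooled
#' sd are dropped with a warning and listed in the returned report.
#'
#' @param studies List of [expr_study()] objects on the log scale.
#' @param genes Genes to retain (must be present in every study);
#'   defaults to the studies' [common_genes()].
#' @return List with elements `studies` (normalized copies), `stats`
#'   (data.frame `gene`, `mean`, `sd` — reusable e.g. for
#'   negative-control normalization) and `dropped` (zero-sd genes).
#' @export
pooled_row_normalize <- function(studies, genes = NULL) {
  stopifnot(length(studies) >= 1L, all(vapply(studies, inherits, TRUE, "expr_study")))
  if (any(vapply(studies, function(s) s$scale, "") != "log"))
    stop("pooled_row_normalize() expects log-scale studies")
  if (is.null(genes))
    genes <- common_genes(lapply(studies, genes_of))
  for (s in studies)
    if (!all(genes %in% genes_of(s)))
      stop("study '", s$study_id, "' does not contain all requested genes")
  pooled <- do.call(cbind, lapply(studies, function(s) s$values[genes, , drop = FALSE]))
  mu <- rowMeans(pooled)
  sd <- row_sds(pooled)
  dropped <- genes[sd == 0]
  if (length(dropped)) {
    warning(length(dropped), " gene(s) with zero pooled sd dropped")
    keep <- sd > 0
    genes <- genes[keep]; mu <- mu[keep]; sd <- sd[keep]
  }
  stats <- data.frame(gene = genes, mean = unname(mu), sd = unname(sd),
                      stringsAsFactors = FALSE)
  out <- lapply(studies, function(s) {
    v <- (s$values[genes, , drop = FALSE] - mu) / sd
    expr_study(v, s$study_id, "log")
  })
  list(studies = out, stats = stats, dropped = dropped)
}

#' Apply stored normalization statistics to a matrix
#'
#' Transforms each gene row to `(x - mean) / sd` using previously
#' computed pooled statistics; genes absent from the statistics are
#' dropped.
#'
#' @param m An [expr_study()].
#' @param stats Data.frame `gene`, `mean`, `sd` as produced by
#'   [pooled_row_normalize()].
#' @return A normalized [expr_study()] restricted to the stats' genes.
#' @export
apply_normalization <- function(m, stats) {
  stopifnot(inherits(m, "expr_study"))
  genes <- intersect(stats$gene, genes_of(m))
  if (!length(genes)) stop("no overlap between the matrix and the statistics")
  idx <- match(genes, stats$gene)
  v <- (m$values[genes, , drop = FALSE] - stats$mean[idx]) / stats$sd[idx]
  expr_study(v, m$study_id, "log")
}

#' Principal components of one study
#'
#' Gene rows are centered within the study (not scaled) and the
#' centered matrix decomposed by SVD. Loadings are unit-norm gene-space
#' vectors ordered by decreasing variance explained, with a fixed sign
#' convention: the largest-magnitude entry of every loading is positive.
#'
#' @param m A (normalized) [expr_study()].
#' @param k Number of components to keep (default 20). If the matrix
#'   rank is lower, the available components return with a warning.
#' @return An object of class `pc_result`: list with `loadings` (genes
#'   x k matrix), `var_explained` (fraction of the study's total
#'   variance per component) and `study_id`.
#' @export
dataset_pca <- function(m, k = 20) {
  stopifnot(inherits(m, "expr_study"))
  if (k < 1) stop("'k' must be at least 1")
  x <- m$values
  if (ncol(x) < 2L) stop("at least 2 samples are required for PCA")
  if (nrow(x) < k) stop("fewer genes than requested components")
  xc <- x - rowMeans(x)
  # xc = U D V': the columns of U are the gene-space loadings.
  sv <- svd(xc, nv = 0)
  ev <- sv$d^2
  rank <- sum(sv$d > sv$d[1L] * 1e-12)
  kk <- min(k, rank)
  if (kk < k)
    warning(sprintf("rank %d < k = %d; returning %d components", rank, k, kk))
  load <- sv$u[, seq_len(kk), drop = FALSE]
  for (j in seq_len(kk)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(rownames(x), paste0("PC", seq_len(kk)))
  structure(list(loadings = load,
                 var_explained = ev[seq_len(kk)] / sum(ev),
                 study_id = m$study_id),
            class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  cat(sprintf("<pc_result> %s: %d loadings over %d genes (PC1 varExp %.3f)\n",
              x$study_id, ncol(x$loadings), nrow(x$loadings),
              x$var_explained[1L]))
  invisible(x)
}

#' Filter and transform a count matrix for validation
#'
#' Removes low-expressed genes by counts-per-million (CPM), then
#' log2-transforms with a pseudocount of 1 and centers each gene row.
#' The CPM cut keeps a gene when its maximum CPM across samples reaches
#' the threshold (`quantifier = "any"`, the default, retains any gene
#' expressed at threshold level somewhere); `quantifier = "all"`
#' requires the threshold in every sample.
#'
#' @param counts An [expr_study()] on the counts scale with positive
#'   library sizes.
#' @param threshold Minimum CPM (default 2).
#' @param quantifier `"any"` (default) or `"all"`.
#' @return A gene-centered log-scale [expr_study()].
#' @export
cpm_filter <- function(counts, threshold = 2, quantifier = c("any", "all")) {
  stopifnot(inherits(counts, "expr_study"))
  quantifier <- match.arg(quantifier)
  if (counts$scale != "counts")
    stop("cpm_filter() expects a counts-scale matrix")
  libsize <- colSums(counts$values)
  if (any(libsize == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(counts$values)[libsize == 0], collapse = ", "))
  cpm <- edgeR::cpm(counts$values)
  keep <- if (quantifier == "any") {
    apply(cpm, 1L, max) >= threshold
  } else {
    apply(cpm, 1L, min) >= threshold
  }
  if (!any(keep)) stop("no gene passes the CPM filter")
  lg <- log2(counts$values[keep, , drop = FALSE] + 1)
  lg <- lg - rowMeans(lg)
  expr_study(lg, counts$study_id, "log")
}
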