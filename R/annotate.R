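#' Read a GMT gene set file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, members...
#'
#' @param path GMT file path.
#' @param source Label attached to the collection (defaults to the file
#'   base name).
#' @return A named list of character gene vectors with attributes
#'   `descriptions` (named character) and `source`.
#' @export
read_gmt <- function(path, source = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], " in '", path,
         "': expected name, description and at least one gene")
  names_ <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names_))
    stop("duplicate gene set name(s): ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  coll <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(coll) <- names_
  attr(coll, "descriptions") <- stats::setNames(vapply(fields, `[[`, "", 2L), names_)
  attr(coll, "source") <- source
  coll
}

#' Write a gene set collection as GMT
#'
#' @param coll Named list of gene vectors (optionally with a
#'   `descriptions` attribute).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path) {
  desc <- attr(coll, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(coll)), names(coll))
  lines <- vapply(names(coll), function(nm)
    paste(c(nm, desc[[nm]], coll[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Filter gene sets by size
#'
#' Removes sets with fewer than `min_size` or more than `max_size`
#' members (bounds inclusive: a set of exactly `min_size` or
#' `max_size` genes is kept).
#'
#' @param coll Gene set collection (named list).
#' @param min_size,max_size Inclusive size bounds (defaults 10 and 500).
#' @return The filtered collection, attributes preserved.
#' @export
filter_gene_sets <- function(coll, min_size = 10, max_size = 500) {
  sz <- lengths(coll)
  keep <- sz >= min_size & sz <= max_size
  out <- coll[keep]
  desc <- attr(coll, "descriptions")
  if (!is.null(desc)) attr(out, "descriptions") <- desc[names(out)]
  attr(out, "source") <- attr(coll, "source")
  out
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score (weight
# exponent 1) for a set occupying positions `hit` of a list ranked by
# decreasing statistic.
gsea_es <- function(stats_sorted, hit) {
  n <- length(stats_sorted)
  m <- sum(hit)
  w <- abs(stats_sorted)
  wh <- sum(w[hit])
  p_hit <- if (wh > 0) cumsum(w * hit) / wh else cumsum(hit) / m
  p_miss <- cumsum(!hit) / (n - m)
  dev <- p_hit - p_miss
  dev[which.max(abs(dev))]
}

#' Pre-ranked gene set enrichment of one loading vector
#'
#' Genes are ranked by decreasing loading value and each set is scored
#' with the weighted Kolmogorov-Smirnov running-sum statistic (weight
#' exponent 1). The null distribution comes from gene-label
#' permutations — equivalently, random placements of the set on the
#' ranked list: exhaustively enumerated when the number of placements
#' is small (`method = "exact"`, chosen automatically below
#' `exact_limit`), otherwise Monte Carlo with `n_perm` draws. The
#' permutation p-value is two-sided; NES divides the observed ES by
#' the mean |null ES| of matching sign. Sets with fewer than 2 genes
#' present in the ranking are skipped (recorded in the `skipped`
#' attribute).
#'
#' @param loading Named numeric vector (gene -> loading value).
#' @param coll Gene set collection.
#' @param n_perm Monte Carlo permutations (default 1000).
#' @param seed Seed for the Monte Carlo null.
#' @param method `"auto"` (default), `"exact"` or `"permutation"`.
#' @param exact_limit Maximum number of set placements enumerated
#'   exhaustively under `"auto"` (default 2e5).
#' @return Data.frame `set`, `size`, `ES`, `NES`, `pvalue`, `qvalue`
#'   (BH over the scored sets), `description`.
#' @export
preranked_gsea <- function(loading, coll, n_perm = 1000, seed = 1,
                           method = c("auto", "exact", "permutation"),
                           exact_limit = 2e5) {
  method <- match.arg(method)
  if (is.null(names(loading))) stop("'loading' must be named by gene")
  ord <- order(loading, names(loading), decreasing = TRUE, method = "radix")
  stats_sorted <- loading[ord]
  genes <- names(stats_sorted)
  n <- length(genes)
  desc <- attr(coll, "descriptions")
  seeds <- spawn_seeds(seed, length(coll))
  rows <- list(); skipped <- character()
  for (i in seq_along(coll)) {
    nm <- names(coll)[i]
    pos <- which(genes %in% coll[[i]])
    m <- length(pos)
    if (m < 2L) { skipped <- c(skipped, nm); next }
    hit <- logical(n); hit[pos] <- TRUE
    es <- gsea_es(stats_sorted, hit)
    use_exact <- method == "exact" ||
      (method == "auto" && choose(n, m) <= exact_limit)
    null_es <- if (use_exact) {
      combos <- utils::combn(n, m)
      apply(combos, 2L, function(ix) {
        h <- logical(n); h[ix] <- TRUE
        gsea_es(stats_sorted, h)
      })
    } else {
      with_seed(seeds[i], vapply(seq_len(n_perm), function(b) {
        h <- logical(n); h[sample.int(n, m)] <- TRUE
        gsea_es(stats_sorted, h)
      }, 0))
    }
    p <- if (use_exact) {
      mean(abs(null_es) >= abs(es) - 1e-12)
    } else {
      (1 + sum(abs(null_es) >= abs(es) - 1e-12)) / (1 + n_perm)
    }
    same_sign <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      set = nm, size = m, ES = es, NES = nes, pvalue = p,
      description = if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "",
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(), size = integer(), ES = numeric(),
               NES = numeric(), pvalue = numeric(), description = character(),
               stringsAsFactors = FALSE)
  out$qvalue <- if (nrow(out)) bh_adjust(out$pvalue) else numeric()
  out <- out[, c("set", "size", "ES", "NES", "pvalue", "qvalue", "description")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (a thin, range-checked
#' wrapper over [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values (monotone in `p`, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select the enriched rows stored per RAV
#'
#' Keeps rows with BH-adjusted p-value (`qvalue`) below `alpha`, and
#' among those retains the rows attaining the minimum q-value (all
#' ties kept).
#'
#' @param rows Data.frame with a `qvalue` column.
#' @param alpha Significance cut (default 0.05).
#' @return The selected rows (possibly none).
#' @export
select_enriched <- function(rows, alpha = 0.05) {
  sig <- rows[!is.na(rows$qvalue) & rows$qvalue < alpha, , drop = FALSE]
  if (!nrow(sig)) return(sig)
  sig[sig$qvalue == min(sig$qvalue), , drop = FALSE]
}

#' Annotate a model's RAVs by gene set enrichment
#'
#' Runs [preranked_gsea()] on every RAV loading and stores, per RAV,
#' either the min-q selection (`keep = "min_q"`, mirroring the model's
#' standard annotation rule), all significant rows, or everything.
#'
#' @param model A [rav_model()].
#' @param coll Gene set collection (already size-filtered as desired;
#'   see [filter_gene_sets()]).
#' @param n_perm,seed,method Passed to [preranked_gsea()].
#' @param alpha Significance cut on BH-adjusted p (default 0.05).
#' @param keep `"min_q"` (default), `"significant"` or `"all"`.
#' @return The model with `gsea` (data.frame with leading `rav`
#'   column) and `gsea_collection` filled.
#' @export
annotate_gsea <- function(model, coll, n_perm = 1000, seed = 1,
                          method = "auto", alpha = 0.05,
                          keep = c("min_q", "significant", "all")) {
  stopifnot(inherits(model, "rav_model"))
  keep <- match.arg(keep)
  seeds <- spawn_seeds(seed, ncol(model$index))
  res <- lapply(seq_len(ncol(model$index)), function(r) {
    rows <- preranked_gsea(model$index[, r], coll, n_perm = n_perm,
                           seed = seeds[r], method = method)
    rows <- switch(keep,
                   min_q = select_enriched(rows, alpha),
                   significant = rows[!is.na(rows$qvalue) & rows$qvalue < alpha, ,
                                      drop = FALSE],
                   all = rows)
    if (nrow(rows)) cbind(rav = colnames(model$index)[r], rows)
    else NULL
  })
  res <- res[!vapply(res, is.null, TRUE)]
  model$gsea <- if (length(res)) do.call(rbind, res) else
    data.frame(rav = character(), set = character(), size = integer(),
               ES = numeric(), NES = numeric(), pvalue = numeric(),
               qvalue = numeric(), description = character(),
               stringsAsFactors = FALSE)
  rownames(model$gsea) <- NULL
  model$gsea_collection <- list(source = attr(coll, "source"),
                                n_sets = length(coll))
  model
}

#' Fraction of gene sets annotating at least one RAV
#'
#' @param model An annotated [rav_model()].
#' @param coll The gene set collection the model was annotated with
#'   (supplies the denominator).
#' @return A fraction in `[0, 1]`.
#' @export
pathway_coverage <- function(model, coll) {
  if (!length(coll)) stop("the collection is empty")
  if (is.null(model$gsea)) stop("the model carries no GSEA annotation")
  length(unique(model$gsea$set)) / length(coll)
}

#' Can the model separate pairs of related pathways?
#'
#' A pair of pathway-name patterns is *separated* when some RAVs'
#' top-`top_n` enriched pathways match side A only, others match side
#' B only, and no RAV's top-`top_n` matches both.
#'
#' @param model An annotated [rav_model()].
#' @param pairs List of length-2 character vectors
#'   (regular-expression patterns for side A and side B).
#' @param top_n Number of top enriched pathways examined per RAV
#'   (1 or 5 in standard use).
#' @return Logical vector, one flag per pair (`NA`, with a warning,
#'   when a pattern matches no annotated pathway).
#' @export
pathway_separation <- function(model, pairs, top_n = 1) {
  if (is.null(model$gsea)) stop("the model carries no GSEA annotation")
  ravs <- unique(model$gsea$rav)
  tops <- lapply(ravs, function(r) subset_enriched_pathways(model, r, top_n)$set)
  vapply(pairs, function(pr) {
    a <- vapply(tops, function(s) any(grepl(pr[1L], s, ignore.case = TRUE)), TRUE)
    b <- vapply(tops, function(s) any(grepl(pr[2L], s, ignore.case = TRUE)), TRUE)
    if (!any(a) || !any(b)) {
      warning("pattern '", pr[if (!any(a)) 1L else 2L],
              "' matches no annotated pathway")
      return(NA)
    }
    any(a & !b) && any(b & !a) && !any(a & b)
  }, TRUE)
}

#' Score the MeSH terms of one cluster
#'
#' Bag-of-words scoring: after removing `drop_list` terms, terms are
#' noise-filtered by occurrence count among the cluster's member PCs
#' (clusters of fewer than 8 PCs drop terms occurring at most
#' `0.5 * size` times; clusters of 8 or more drop terms occurring at
#' most 4 times). Each surviving term is scored as the sum of the
#' variance explained by the member PCs carrying it, divided by the
#' term's frequency in the universe.
#'
#' @param members Data.frame with one row per member PC: columns
#'   `study_id` and `var_explained`.
#' @param study_terms Named list: study id -> character vector of MeSH
#'   terms.
#' @param universe Named numeric vector of term frequencies over all
#'   training PCs (with multiplicity).
#' @param drop_list Terms excluded regardless of score.
#' @return Data.frame `term`, `count`, `score`, sorted by descending
#'   score.
#' @export
mesh_score <- function(members, study_terms, universe,
                       drop_list = character()) {
  miss <- setdiff(members$study_id, names(study_terms))
  if (length(miss))
    stop("no MeSH metadata for member PC(s) of study: ",
         paste(unique(miss), collapse = ", "))
  size <- nrow(members)
  per_pc <- lapply(members$study_id, function(s)
    setdiff(unique(study_terms[[s]]), drop_list))
  terms <- unique(unlist(per_pc))
  if (!length(terms))
    return(data.frame(term = character(), count = integer(),
                      score = numeric(), stringsAsFactors = FALSE))
  count <- vapply(terms, function(tm)
    sum(vapply(per_pc, function(v) tm %in% v, TRUE)), 0L)
  keep <- if (size < 8L) count > 0.5 * size else count > 4L
  terms <- terms[keep]; count <- count[keep]
  if (!length(terms))
    return(data.frame(term = character(), count = integer(),
                      score = numeric(), stringsAsFactors = FALSE))
  if (!all(terms %in% names(universe)))
    stop("term(s) absent from the universe: ",
         paste(setdiff(terms, names(universe)), collapse = ", "))
  score <- vapply(seq_along(terms), function(i) {
    carrier <- vapply(per_pc, function(v) terms[i] %in% v, TRUE)
    sum(members$var_explained[carrier]) / universe[[terms[i]]]
  }, 0)
  out <- data.frame(term = terms, count = count, score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$term), ]
  rownames(out) <- NULL
  out
}

#' Annotate a model's RAVs with MeSH term scores
#'
#' Builds the term universe from the model's own training membership
#' (every pooled PC contributes its study's terms, with multiplicity)
#' and scores each RAV's cluster with [mesh_score()].
#'
#' @param model A [rav_model()].
#' @param meta Study metadata with `studyId` and `meshTerms` (list
#'   column); defaults to the metadata stored in the model.
#' @param drop_list Uninformative terms to exclude (e.g. "Humans").
#' @return The model with `mesh` (data.frame `rav`, `term`, `count`,
#'   `score`) and `mesh_universe` filled.
#' @export
annotate_mesh <- function(model, meta = model$studies,
                          drop_list = character()) {
  stopifnot(inherits(model, "rav_model"))
  if (is.null(meta)) stop("study metadata with MeSH terms is required")
  terms <- meta$meshTerms
  if (is.character(terms))
    terms <- lapply(strsplit(terms, "|", fixed = TRUE), function(v) v[nzchar(v)])
  study_terms <- stats::setNames(lapply(terms, unique), meta$studyId)
  universe_bag <- unlist(study_terms[model$membership$study_id], use.names = FALSE)
  universe <- c(table(universe_bag))
  ravs <- colnames(model$index)
  res <- lapply(seq_along(ravs), function(r) {
    mem <- model$membership[model$membership$cluster == r, , drop = FALSE]
    tab <- mesh_score(mem, study_terms, universe, drop_list)
    if (nrow(tab)) cbind(rav = ravs[r], tab) else NULL
  })
  res <- res[!vapply(res, is.null, TRUE)]
  model$mesh <- if (length(res)) do.call(rbind, res) else
    data.frame(rav = character(), term = character(), count = integer(),
               score = numeric(), stringsAsFactors = FALSE)
  rownames(model$mesh) <- NULL
  model$mesh_universe <- data.frame(term = names(universe),
                                    freq = as.integer(universe),
                                    stringsAsFactors = FALSE)
  model$drop_list <- drop_list
  model
}
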