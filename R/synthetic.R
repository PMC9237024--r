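# Run code under a temporary RNG state so generators are pure
# functions of (inputs, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

spawn_seeds <- function(seed, n) with_seed(seed, sample.int(2^31 - 2, n))

#' Specification of a planted-factor training corpus
#'
#' Describes a multi-study corpus in which sparse gene-space factors
#' are shared across subsets of studies — the replicable structure the
#' RAV model is designed to recover. Defaults describe the standard
#' test-bench corpus: 20 studies of 50 samples over 1000 genes, 5
#' shared factors at a 3:1 signal-to-noise ratio.
#'
#' @param n_studies Number of studies (default 20).
#' @param n_genes Genes per study (default 1000).
#' @param n_samples Samples per study (default 50).
#' @param n_factors Number of planted factors (default 5).
#' @param sharing List (one element per factor) of study indices
#'   carrying that factor; every factor must appear in at least 2
#'   studies. Default: round-robin, so each factor is carried by
#'   `n_studies / n_factors` studies.
#' @param sparsity Fraction of genes with non-zero factor loading
#'   (default 0.1).
#' @param signal_sd Standard deviation of the per-sample factor scores
#'   (default 3).
#' @param noise_sd Baseline standard deviation of the additive Gaussian
#'   noise (default 1).
#' @param gene_sd_spread Spread of per-gene noise scales: each gene's
#'   noise sd is `noise_sd * exp(N(0, gene_sd_spread^2))`, shared
#'   across studies, emulating the stable between-gene variability
#'   differences that make per-study variable-gene selections overlap
#'   (default 0.3).
#' @param n_background Number of weak gene modules shared by *all*
#'   studies (default 20). Real expression data carries pervasive
#'   correlated gene modules, so loading vectors from independent
#'   studies are mutually far more similar than gene-scrambled data;
#'   without this background the corpus would make scrambled negative
#'   controls indistinguishable from real components and the
#'   cluster-count calibration unseparable by construction.
#' @param background_sd Per-element amplitude of the background
#'   modules relative to the baseline noise sd (default 0.5).
#' @param seed Master seed.
#' @return A `planted_corpus_spec` list.
#' @export
planted_corpus_spec <- function(n_studies = 20, n_genes = 1000,
                                n_samples = 50, n_factors = 5,
                                sharing = NULL, sparsity = 0.1,
                                signal_sd = 3, noise_sd = 1,
                                gene_sd_spread = 0.3, n_background = 20,
                                background_sd = 0.5, seed = 1) {
  stopifnot(n_studies >= 1, n_genes >= 1, n_samples >= 2, n_factors >= 1,
            sparsity > 0, sparsity <= 1, signal_sd >= 0, noise_sd >= 0,
            n_background >= 0, background_sd >= 0)
  if (is.null(sharing))
    sharing <- lapply(seq_len(n_factors),
                      function(f) seq(f, n_studies, by = n_factors))
  if (length(sharing) != n_factors)
    stop("'sharing' must have one element per factor")
  for (f in seq_along(sharing)) {
    s <- sharing[[f]]
    if (length(s) < 2L) stop("factor ", f, " is carried by fewer than 2 studies")
    if (any(s < 1 | s > n_studies)) stop("factor ", f, ": study index out of range")
  }
  structure(list(n_studies = n_studies, n_genes = n_genes,
                 n_samples = n_samples, n_factors = n_factors,
                 sharing = sharing, sparsity = sparsity,
                 signal_sd = signal_sd, noise_sd = noise_sd,
                 gene_sd_spread = gene_sd_spread,
                 n_background = n_background, background_sd = background_sd,
                 seed = seed),
            class = "planted_corpus_spec")
}

#' Generate a planted-factor corpus
#'
#' Study `s` is built as `sum_f w_f z_sf' + E`, where `w_f` is a sparse
#' unit-norm gene loading shared across the studies carrying factor
#' `f` and `E` is Gaussian noise with gene-specific scales. The factor
#' scores `z_sf` are i.i.d. normal with sd `signal_sd * sqrt(support)`
#' (`support` = number of non-zero loading genes), so that on its
#' support the factor's per-element amplitude is `signal_sd` times the
#' baseline noise sd — the sense in which the corpus has a
#' `signal_sd : noise_sd` signal-to-noise ratio. Values carry
#' log-scale semantics.
#'
#' @param spec A [planted_corpus_spec()].
#' @return List with `studies` (list of [expr_study()]), `loadings`
#'   (genes x factors matrix of the true `w_f`), `scores` (list per
#'   study: samples x carried-factors matrix of true `z`), and `spec`.
#' @export
make_planted_corpus <- function(spec) {
  stopifnot(inherits(spec, "planted_corpus_spec"))
  G <- spec$n_genes
  genes <- sprintf("g%05d", seq_len(G))
  seeds <- spawn_seeds(spec$seed, spec$n_studies + 1L)
  setup <- with_seed(seeds[1L], {
    sigma <- spec$noise_sd * exp(stats::rnorm(G, 0, spec$gene_sd_spread))
    n_nz <- max(2L, round(spec$sparsity * G))
    W <- matrix(0, G, spec$n_factors,
                dimnames = list(genes, paste0("factor", seq_len(spec$n_factors))))
    for (f in seq_len(spec$n_factors)) {
      nz <- sample.int(G, n_nz)
      v <- stats::rnorm(n_nz)
      W[nz, f] <- v / sqrt(sum(v^2))
    }
    B <- matrix(0, G, spec$n_background)
    if (spec$n_background > 0)
      for (f in seq_len(spec$n_background)) {
        nz <- sample.int(G, n_nz)
        v <- stats::rnorm(n_nz)
        B[nz, f] <- v / sqrt(sum(v^2))
      }
    list(sigma = sigma, W = W, B = B, n_nz = n_nz)
  })
  carried <- lapply(seq_len(spec$n_studies), function(s)
    which(vapply(spec$sharing, function(ix) s %in% ix, TRUE)))
  studies <- vector("list", spec$n_studies)
  scores <- vector("list", spec$n_studies)
  for (s in seq_len(spec$n_studies)) {
    res <- with_seed(seeds[s + 1L], {
      x <- matrix(stats::rnorm(G * spec$n_samples), G) * setup$sigma
      fs <- carried[[s]]
      z_sd <- spec$signal_sd * sqrt(setup$n_nz)
      z <- matrix(stats::rnorm(spec$n_samples * length(fs), 0, z_sd),
                  spec$n_samples, length(fs),
                  dimnames = list(NULL, colnames(setup$W)[fs]))
      if (length(fs))
        x <- x + setup$W[, fs, drop = FALSE] %*% t(z)
      if (spec$n_background > 0) {
        zb_sd <- spec$background_sd * spec$noise_sd * sqrt(setup$n_nz)
        zb <- matrix(stats::rnorm(spec$n_samples * spec$n_background, 0, zb_sd),
                     spec$n_samples)
        x <- x + setup$B %*% t(zb)
      }
      list(x = x, z = z)
    })
    id <- sprintf("study%02d", s)
    dimnames(res$x) <- list(genes, sprintf("%s_s%03d", id, seq_len(spec$n_samples)))
    rownames(res$z) <- colnames(res$x)
    studies[[s]] <- expr_study(res$x, id, "log")
    scores[[s]] <- res$z
  }
  names(studies) <- names(scores) <- vapply(studies, function(s) s$study_id, "")
  list(studies = studies, loadings = setup$W, scores = scores, spec = spec)
}

#' Gene-scrambled negative-control datasets
#'
#' Each control draws `n_samples` random samples from the pool, permutes
#' the gene labels independently of the other controls, adds i.i.d.
#' uniform(-`noise_range`, `noise_range`) values, and row-normalizes
#' with the *pooled* training statistics (never the control's own).
#' These controls keep the marginal value distribution of real data
#' while destroying gene-level covariance, and are used to calibrate
#' the cluster count (see [calibrate_d()]).
#'
#' @param pool Genes x samples matrix (or list of [expr_study()]s,
#'   column-bound) of real log-scale samples.
#' @param n_datasets Number of controls (default 50).
#' @param n_samples Samples per control (default 50).
#' @param stats Pooled normalization statistics
#'   (data.frame `gene`, `mean`, `sd`, from [pooled_row_normalize()]).
#' @param seed Master seed; each control uses a derived sub-seed.
#' @param noise_range Half-width of the additive uniform noise
#'   (default 0.1).
#' @return List of [expr_study()] objects (`control01`, ...).
#' @export
make_negative_controls <- function(pool, n_datasets = 50, n_samples = 50,
                                   stats, seed = 1, noise_range = 0.1) {
  if (is.list(pool) && !is.matrix(pool))
    pool <- do.call(cbind, lapply(pool, function(s) s$values))
  if (ncol(pool) < n_samples)
    stop("the pool has fewer than ", n_samples, " samples")
  genes <- rownames(pool)
  idx <- match(stats$gene, genes)
  if (anyNA(idx)) stop("normalization statistics cover genes absent from the pool")
  seeds <- spawn_seeds(seed, n_datasets)
  lapply(seq_len(n_datasets), function(i) {
    v <- with_seed(seeds[i], {
      cols <- sample.int(ncol(pool), n_samples)
      x <- pool[, cols, drop = FALSE]
      x <- x[sample.int(nrow(x)), , drop = FALSE]  # scramble gene labels
      rownames(x) <- genes
      x + matrix(stats::runif(length(x), -noise_range, noise_range), nrow(x))
    })
    id <- sprintf("control%02d", i)
    v <- (v[stats$gene, , drop = FALSE] - stats$mean) / stats$sd
    colnames(v) <- sprintf("%s_s%03d", id, seq_len(ncol(v)))
    expr_study(v, id, "log")
  })
}

#' Bootstrap positive-control datasets
#'
#' Draws `n` bootstrap resamples of a study's samples (with
#' replacement, same size). Their leading components should cluster
#' together when the study carries a strong factor.
#'
#' @param study An [expr_study()] with at least 2 samples.
#' @param n Number of resamples (default 10).
#' @param seed Master seed.
#' @return List of [expr_study()] objects.
#' @export
make_positive_controls <- function(study, n = 10, seed = 1) {
  stopifnot(inherits(study, "expr_study"))
  ns <- ncol(study$values)
  if (ns < 2L) stop("the study needs at least 2 samples")
  seeds <- spawn_seeds(seed, n)
  lapply(seq_len(n), function(i) {
    cols <- with_seed(seeds[i], sample.int(ns, ns, replace = TRUE))
    v <- study$values[, cols, drop = FALSE]
    id <- sprintf("%s_boot%02d", study$study_id, i)
    colnames(v) <- sprintf("s%03d", seq_len(ns))
    expr_study(v, id, study$scale)
  })
}

#' Write a corpus to a directory of TSV files
#'
#' One `<studyId>.tsv` expression file per study plus a `metadata.tsv`
#' study table; planted corpora additionally get `truth_loadings.tsv`.
#'
#' @param corpus Result of [make_planted_corpus()] or a plain list of
#'   [expr_study()]s.
#' @param dir Output directory (created if needed).
#' @param mesh Optional list of MeSH term vectors, named by study id.
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir, mesh = NULL) {
  studies <- if (!is.null(corpus$studies)) corpus$studies else corpus
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in studies)
    write_expression(s, file.path(dir, paste0(s$study_id, ".tsv")))
  meta <- data.frame(
    studyId = vapply(studies, function(s) s$study_id, ""),
    sampleCount = vapply(studies, function(s) ncol(s$values), 0L),
    title = vapply(studies, function(s) paste("Synthetic study", s$study_id), ""),
    meshTerms = vapply(studies, function(s)
      paste(if (is.null(mesh)) character() else mesh[[s$study_id]],
            collapse = "|"), ""),
    stringsAsFactors = FALSE)
  data.table::fwrite(meta, file.path(dir, "metadata.tsv"), sep = "\t")
  if (!is.null(corpus$loadings)) {
    dt <- data.table::data.table(gene = rownames(corpus$loadings))
    dt <- cbind(dt, data.table::as.data.table(corpus$loadings))
    data.table::fwrite(dt, file.path(dir, "truth_loadings.tsv"), sep = "\t")
  }
  invisible(dir)
}
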