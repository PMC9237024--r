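# Small fixtures built in code at test time.

rand_study <- function(n_genes = 30, n_samples = 8, seed = 1, id = "toy",
                       scale = "log") {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * n_samples), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  if (scale == "counts") v <- matrix(rpois(n_genes * n_samples, 20),
                                     n_genes, dimnames = dimnames(v))
  expr_study(v, id, scale)
}

# A small planted corpus that builds in well under a second.
tiny_corpus <- function(seed = 1, n_studies = 6, n_genes = 200,
                        n_samples = 15, n_factors = 3, ...) {
  make_planted_corpus(planted_corpus_spec(
    n_studies = n_studies, n_genes = n_genes, n_samples = n_samples,
    n_factors = n_factors, seed = seed, ...))
}

# Richer (but still sub-second) corpus for end-to-end tests that rely
# on factor recovery through the full clustering pipeline.
tiny_model <- function(seed = 1, k = 5, ...) {
  corpus <- tiny_corpus(seed = seed, n_studies = 9, n_genes = 300,
                        n_samples = 30, n_background = 10, ...)
  list(corpus = corpus, model = rav_model(corpus$studies, k = k))
}

# Gene set collection anchored on the planted factors (top loading
# genes) plus random filler sets, so enrichment has known structure.
factor_collection <- function(corpus, genes, n_random = 4, set_size = 15,
                              seed = 99) {
  set.seed(seed)
  W <- corpus$loadings[genes, , drop = FALSE]
  coll <- lapply(seq_len(ncol(W)), function(f)
    genes[order(-W[, f])][seq_len(set_size)])
  names(coll) <- paste0("FACTOR", seq_len(ncol(W)), "_SET")
  rand <- lapply(seq_len(n_random), function(i) sample(genes, set_size))
  names(rand) <- paste0("RANDOM_SET", seq_len(n_random))
  out <- c(coll, rand)
  attr(out, "descriptions") <- stats::setNames(rep("synthetic set", length(out)),
                                               names(out))
  attr(out, "source") <- "synthetic"
  out
}

toy_meta <- function(studies, terms) {
  data.frame(studyId = vapply(studies, function(s) s$study_id, ""),
             sampleCount = vapply(studies, function(s) ncol(s$values), 0L),
             title = paste("Study", seq_along(studies)),
             meshTerms = I(terms), stringsAsFactors = FALSE)
}
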