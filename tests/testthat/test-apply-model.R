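test_that("validate recovers a training study and rejects poor overlap", {
  corpus <- make_planted_corpus(planted_corpus_spec(seed = 31))
  # add a study carrying its own exclusive factor: its PC1 matches no
  # other pooled component, so it ends up in a singleton cluster
  set.seed(310)
  G <- 1000
  w_odd <- numeric(G); nz <- sample(G, 100)
  w_odd[nz] <- rnorm(100); w_odd <- w_odd / sqrt(sum(w_odd^2))
  z <- rnorm(50, sd = 3 * sqrt(100))
  v_odd <- outer(w_odd, z) + matrix(rnorm(G * 50), G)
  dimnames(v_odd) <- dimnames(corpus$studies[[1]]$values)
  odd <- expr_study(v_odd, "oddstudy", "log")
  model <- rav_model(c(corpus$studies, list(odd)), k = 20)
  mem <- model$membership
  cl <- mem$cluster[mem$study_id == "oddstudy" & mem$pc == 1]
  expect_equal(model$cluster_info$size[cl], 1L)
  s1 <- apply_normalization(odd, model$norm_stats)
  v <- validate(s1, model, n_pc = 5, min_overlap = 50)
  expect_gte(v$scores$score[cl], 0.99)
  expect_equal(v$scores$pc[cl], 1L)
  # the top-scoring RAV is built from the odd study's own components
  top <- which.max(v$scores$score)
  expect_true(all(mem$study_id[mem$cluster == top] == "oddstudy"))
  expect_equal(v$scores$score[cl], max(v$scores$score), tolerance = 1e-8)
  # score is the column max of the correlation matrix
  expect_equal(v$scores$score, unname(apply(v$cor, 2, max)))
  expect_true(all(abs(v$cor) <= 1 + 1e-12))
  # silhouette widths travel with the scores
  expect_equal(v$scores$avg_sw, model$cluster_info$avg_sw)
  expect_error(validate(s1, model, min_overlap = 1e6), "overlap")
})

test_that("validate is invariant to gene order", {
  fit <- tiny_model(seed = 32)
  s1 <- apply_normalization(fit$corpus$studies[[2]], fit$model$norm_stats)
  v1 <- validate(s1, fit$model, n_pc = 4, min_overlap = 50)
  set.seed(1)
  perm <- sample(nrow(s1$values))
  s2 <- expr_study(s1$values[perm, , drop = FALSE], s1$study_id, "log")
  v2 <- validate(s2, fit$model, n_pc = 4, min_overlap = 50)
  expect_equal(v1$scores$score, v2$scores$score, tolerance = 1e-10)
})

test_that("a RAV orthogonal to the data scores near zero", {
  fit <- tiny_model(seed = 33)
  model <- fit$model
  set.seed(99)
  # replace one RAV with pure random noise over ~300 genes
  model$index[, 1] <- rnorm(nrow(model$index))
  s1 <- apply_normalization(fit$corpus$studies[[1]], model$norm_stats)
  v <- validate(s1, model, n_pc = 5, min_overlap = 50)
  expect_lt(abs(v$scores$score[1]), 0.25)
})

test_that("heatmap_table filters by cutoff or top_n and nests by cutoff", {
  mk <- function(id, scores) structure(list(
    cor = NULL, dataset = id,
    scores = data.frame(rav = paste0("RAV", seq_along(scores)),
                        score = scores, pc = 1L, avg_sw = 0,
                        cluster_size = 2L)), class = "rav_validation")
  r1 <- mk("d1", c(0.5, 0.71, 0.2))
  r2 <- mk("d2", c(0.5, 0.1, 0.70))
  expect_equal(nrow(heatmap_table(list(mk("d0", c(0.5, 0.5, 0.5))))), 0)
  tab <- heatmap_table(list(r1, r2), cutoff = 0.7)
  expect_equal(rownames(tab), "RAV2")   # 0.70 itself is not above the cutoff
  expect_equal(tab$d1, 0.71)
  # brute-force filter oracle on random score sets
  set.seed(41)
  rs <- lapply(1:5, function(i) mk(paste0("r", i), runif(20)))
  sc <- sapply(rs, function(r) r$scores$score)
  for (cut in c(0.3, 0.6, 0.9)) {
    got <- rownames(heatmap_table(rs, cutoff = cut))
    want <- paste0("RAV", which(apply(sc, 1, max) > cut))
    expect_equal(got, want)
  }
  # monotone nesting in the cutoff
  hi <- rownames(heatmap_table(rs, cutoff = 0.8))
  lo <- rownames(heatmap_table(rs, cutoff = 0.4))
  expect_true(all(hi %in% lo))
  # top_n selection is the union over datasets
  t1 <- heatmap_table(rs, top_n = 2)
  want <- unique(unlist(lapply(1:5, function(j)
    paste0("RAV", order(-sc[, j])[1:2]))))
  expect_setequal(rownames(t1), want)
})

test_that("sample_scores recover planted factor activities", {
  fit <- tiny_model(seed = 34)
  model <- fit$model
  corpus <- fit$corpus
  genes <- rownames(model$index)
  cors <- abs(cor(model$index, corpus$loadings[genes, ]))
  for (f in seq_len(ncol(cors))) {
    rav <- colnames(model$index)[which.max(cors[, f])]
    carriers <- corpus$spec$sharing[[f]]
    for (s in carriers[1:2]) {
      study <- corpus$studies[[s]]
      sc <- sample_scores(study, model, rav_ids = rav, min_overlap = 50)
      truth <- corpus$scores[[s]][, paste0("factor", f)]
      expect_gte(abs(cor(sc[, 1], truth)), 0.9)
    }
  }
})

test_that("sample_scores are monotone in broadcast weights and NaN-free", {
  fit <- tiny_model(seed = 35)
  model <- fit$model
  genes <- rownames(model$index)
  w <- model$index[, 3]
  weights <- c(0.5, 1, 2, 5, 9, 0.1, 3, 7)
  v <- outer(w, weights) + matrix(rnorm(length(w) * 8, sd = 1e-3), length(w))
  # add a zero-variance gene row: must be dropped, not propagated as NaN
  v <- rbind(v, extra_flat = rep(5, 8))
  colnames(v) <- paste0("s", 1:8)
  ds <- expr_study(v, "broadcast", "log")
  sc <- sample_scores(ds, model, rav_ids = "RAV3", min_overlap = 50)
  expect_false(anyNA(sc))
  expect_equal(order(sc[, 1]), order(weights))
  expect_error(sample_scores(ds, model, rav_ids = "RAV9999",
                             min_overlap = 50), "unknown RAV")
})

test_that("sample_scores are invariant to positive gene rescaling", {
  fit <- tiny_model(seed = 36)
  study <- fit$corpus$studies[[1]]
  sc1 <- sample_scores(study, fit$model, rav_ids = "RAV1", min_overlap = 50)
  set.seed(2)
  scale_per_gene <- runif(nrow(study$values), 0.5, 3)
  v2 <- study$values * scale_per_gene
  sc2 <- sample_scores(expr_study(v2, "scaled", "log"), fit$model,
                       rav_ids = "RAV1", min_overlap = 50)
  expect_equal(unname(sc1), unname(sc2), tolerance = 1e-10)
})

test_that("meta_association_r2 matches the correlation formula", {
  set.seed(51)
  sc <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("RAV", 1:3)))
  # exact linear covariate of one column -> R^2 = 1 and argmax
  variable <- 3 * sc[, 2] - 1
  out <- meta_association_r2(sc, variable)
  expect_equal(unname(out$r2["RAV2"]), 1.0)
  expect_equal(out$best, "RAV2")
  expect_true(all(out$r2 >= 0 & out$r2 <= 1))
  # direct formula on all columns
  expect_equal(out$r2, apply(sc, 2, function(s) cor(s, variable)^2),
               tolerance = 1e-12)
  # independent noise: small R^2
  noise <- rnorm(10)
  expect_lt(max(meta_association_r2(sc, noise)$r2), 0.6)
  # missing values are dropped pairwise
  variable[4] <- NA
  out_na <- meta_association_r2(sc, variable)
  keep <- !is.na(variable)
  expect_equal(unname(out_na$r2["RAV1"]),
               cor(sc[keep, 1], variable[keep])^2)
  expect_error(meta_association_r2(sc, rep(1, 10)), "constant")
  expect_error(meta_association_r2(sc, rnorm(9)), "one value per sample")
})

test_that("flag_ravs marks single-element, single-study and annotation extremes", {
  ci <- data.frame(rav = paste0("RAV", 1:4), size = c(1L, 2L, 3L, 2L),
                   n_studies = c(1L, 1L, 3L, 2L), avg_sw = 0,
                   mean_var_explained = 0.1)
  gsea <- data.frame(rav = c("RAV3", rep("RAV4", 300)),
                     set = paste0("S", 1:301), qvalue = 0.01)
  model <- structure(list(cluster_info = ci, gsea = gsea,
                          gsea_collection = list(n_sets = 5520)),
                     class = "rav_model")
  fl <- flag_ravs(model)
  expect_match(fl$flags[1], "SINGLE_ELEMENT")
  expect_match(fl$flags[1], "ANNOTATION_OUT_OF_RANGE")  # zero enriched sets
  expect_match(fl$flags[2], "SINGLE_STUDY")
  expect_equal(fl$flags[3], "")                          # clean RAV
  # too-many threshold for a 5520-set collection is round(0.05 * 5520) = 276
  expect_match(fl$flags[4], "ANNOTATION_OUT_OF_RANGE")   # 300 > 276
  model2 <- model; model2$gsea_collection$n_sets <- 10000
  expect_false(grepl("ANNOTATION", flag_ravs(model2)$flags[4]))
})

test_that("lookup utilities return provenance, pathways and MeSH tables", {
  fit <- tiny_model(seed = 37)
  studies <- fit$corpus$studies
  terms <- rep(list(c("Humans", "Neoplasms", "Transcriptome")), length(studies))
  meta <- toy_meta(studies, terms)
  model <- rav_model(studies, meta = meta, k = 5)
  genes <- rownames(coef(model))
  coll <- factor_collection(fit$corpus, genes)
  model <- annotate_gsea(model, coll, n_perm = 150, seed = 4,
                         keep = "significant")
  model <- annotate_mesh(model, drop_list = "Humans")

  st <- find_studies_in_cluster(model, 1)
  expect_equal(nrow(st), model$cluster_info$size[1])
  expect_true(all(c("study_id", "pc", "var_explained", "title") %in% names(st)))
  # a singleton RAV has exactly one study row
  singles <- which(model$cluster_info$size == 1)
  if (length(singles))
    expect_equal(nrow(suppressMessages(
      find_studies_in_cluster(model, singles[1]))), 1)

  annotated <- unique(model$gsea$rav)
  rav <- annotated[1]
  top <- subset_enriched_pathways(model, rav, n = 2)
  expect_lte(nrow(top), 2)
  all_rows <- subset_enriched_pathways(model, rav, n = 1e6)
  expect_equal(nrow(all_rows), sum(model$gsea$rav == rav))
  expect_true(all(diff(abs(all_rows$NES)) <= 1e-12))  # |NES| descending

  mt <- mesh_table(model, 1)
  expect_true(all(diff(mt$score) <= 1e-12))
  expect_false("Humans" %in% mt$term)
  expect_error(mesh_table(model, "RAV99999"), "unknown RAV")
  expect_error(find_studies_in_cluster(model, "RAV99999"), "unknown RAV")
})

test_that("predict and plot methods drive validation and scoring", {
  fit <- tiny_model(seed = 38)
  s1 <- apply_normalization(fit$corpus$studies[[1]], fit$model$norm_stats)
  v <- predict(fit$model, s1, type = "validation", n_pc = 4, min_overlap = 50)
  expect_s3_class(v, "rav_validation")
  sc <- predict(fit$model, fit$corpus$studies[[1]], type = "scores",
                rav_ids = "RAV1", min_overlap = 50)
  expect_equal(dim(sc), c(30L, 1L))
  expect_identical(coef(fit$model), fit$model$index)
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit$model))
  expect_output(print(fit$model), "rav_model")
  expect_output(print(summary(fit$model)), "cluster-size distribution")
})
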