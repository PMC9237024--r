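MODEL_FORMAT_VERSION <- "1.0"

# Format numeric columns at full round-trip precision so the TSV
# serialization is bit-exact.
fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_table_full <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- fmt_full(out[[j]])
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

write_matrix_full <- function(m, path, rowname_col = "gene") {
  df <- data.frame(rn = rownames(m), stringsAsFactors = FALSE)
  names(df) <- rowname_col
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- fmt_full(m[, j])
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

read_matrix_full <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1L))
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- dt[[1L]]
  m
}

#' Save a RAV model to a directory
#'
#' Plain-text layout: matrices and tables as full-precision TSV,
#' parameters and provenance as JSON, plus a `manifest.json` carrying
#' MD5 content hashes of every component. Two saves of the same model
#' produce identical hashes, and [load_model()] reproduces every
#' matrix bit-exactly.
#'
#' @param model A [rav_model()].
#' @param path Target directory (created; must be empty or absent).
#' @return The manifest, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "rav_model"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_matrix_full(model$index, file.path(path, "index.tsv"))
  write_table_full(model$membership, file.path(path, "membership.tsv"))
  write_table_full(model$cluster_info, file.path(path, "cluster_info.tsv"))
  write_table_full(model$norm_stats, file.path(path, "norm_stats.tsv"))
  if (!is.null(model$studies)) {
    st <- model$studies
    if (is.list(st$meshTerms))
      st$meshTerms <- vapply(st$meshTerms, paste, "", collapse = "|")
    write_table_full(st, file.path(path, "studies.tsv"))
  }
  if (!is.null(model$gsea))
    write_table_full(model$gsea, file.path(path, "enrichment.tsv"))
  if (!is.null(model$mesh)) {
    write_table_full(model$mesh, file.path(path, "mesh.tsv"))
    write_table_full(model$mesh_universe, file.path(path, "mesh_universe.tsv"))
  }
  meta <- list(format_version = MODEL_FORMAT_VERSION,
               package_version = as.character(utils::packageVersion("ravkit")),
               params = model$params,
               drop_list = model$drop_list,
               gsea_collection = model$gsea_collection,
               components = list(
                 studies = !is.null(model$studies),
                 gsea = !is.null(model$gsea),
                 mesh = !is.null(model$mesh)))
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  files <- sort(setdiff(list.files(path), "manifest.json"))
  manifest <- list(format_version = MODEL_FORMAT_VERSION,
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(file.path(path, files))), files)))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Load a RAV model from a directory
#'
#' Verifies the manifest hashes and the format version before
#' reassembling the model; a missing or corrupted component aborts the
#' load with a diagnostic naming it.
#'
#' @param path Directory written by [save_model()].
#' @return A [rav_model()].
#' @export
load_model <- function(path) {
  man_path <- file.path(path, "manifest.json")
  if (!file.exists(man_path)) stop("missing component: manifest.json")
  manifest <- jsonlite::read_json(man_path)
  major <- as.integer(strsplit(manifest$format_version, ".", fixed = TRUE)[[1L]][1L])
  if (major > as.integer(strsplit(MODEL_FORMAT_VERSION, ".", fixed = TRUE)[[1L]][1L]))
    stop("model format version ", manifest$format_version,
         " is newer than this package supports (", MODEL_FORMAT_VERSION, ")")
  for (f in names(manifest$files)) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("missing component: ", f)
    h <- unname(tools::md5sum(fp))
    if (!identical(h, manifest$files[[f]]))
      stop("content hash mismatch for component: ", f)
  }
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = TRUE)
  read_tab <- function(f, classes = NULL)
    data.table::fread(file.path(path, f), sep = "\t", header = TRUE,
                      data.table = FALSE, na.strings = "NA",
                      colClasses = classes)
  index <- read_matrix_full(file.path(path, "index.tsv"))
  membership <- read_tab("membership.tsv",
                         classes = list(character = "study_id"))
  membership$column <- as.integer(membership$column)
  membership$pc <- as.integer(membership$pc)
  membership$cluster <- as.integer(membership$cluster)
  membership$control <- as.logical(membership$control)
  cluster_info <- read_tab("cluster_info.tsv", classes = list(character = "rav"))
  cluster_info$size <- as.integer(cluster_info$size)
  cluster_info$n_studies <- as.integer(cluster_info$n_studies)
  norm_stats <- read_tab("norm_stats.tsv", classes = list(character = "gene"))
  studies <- NULL
  if (isTRUE(meta$components$studies)) {
    studies <- read_tab("studies.tsv",
                        classes = list(character = c("studyId", "title",
                                                     "meshTerms")))
    studies$meshTerms <- lapply(strsplit(studies$meshTerms, "|", fixed = TRUE),
                                function(v) v[nzchar(v)])
  }
  gsea <- NULL
  if (isTRUE(meta$components$gsea)) {
    gsea <- read_tab("enrichment.tsv",
                     classes = list(character = c("rav", "set", "description")))
    gsea$size <- as.integer(gsea$size)
    for (nm in c("ES", "NES", "pvalue", "qvalue"))
      gsea[[nm]] <- as.numeric(gsea[[nm]])
  }
  mesh <- mesh_universe <- NULL
  if (isTRUE(meta$components$mesh)) {
    mesh <- read_tab("mesh.tsv", classes = list(character = c("rav", "term")))
    mesh$count <- as.integer(mesh$count)
    mesh$score <- as.numeric(mesh$score)
    mesh_universe <- read_tab("mesh_universe.tsv",
                              classes = list(character = "term"))
    mesh_universe$freq <- as.integer(mesh_universe$freq)
  }
  params <- meta$params
  for (nm in c("k", "n_pcs", "K")) params[[nm]] <- as.integer(params[[nm]])
  structure(list(index = index, membership = membership,
                 cluster_info = cluster_info, norm_stats = norm_stats,
                 studies = studies, gsea = gsea,
                 gsea_collection = meta$gsea_collection,
                 mesh = mesh, mesh_universe = mesh_universe,
                 params = params,
                 drop_list = if (length(meta$drop_list)) meta$drop_list else
                   if (isTRUE(meta$components$mesh)) character() else NULL),
            class = "rav_model")
}
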