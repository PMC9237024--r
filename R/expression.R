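#' Per-study expression matrix
#'
#' Light container for one study's genes-by-samples expression matrix.
#' Values are either raw counts (`scale = "counts"`) or log-scale
#' expression (`scale = "log"`); most of the model-building pipeline
#' requires the log scale, while [cpm_filter()] converts counts.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names.
#' @param study_id Single string identifying the study.
#' @param scale `"counts"` or `"log"`.
#' @return An object of class `expr_study`: a list with elements
#'   `values`, `study_id` and `scale`.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' expr_study(m, "toy")
#' @export
expr_study <- function(values, study_id, scale = c("log", "counts")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene (row) and sample (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in study '", study_id, "'")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in study '", study_id, "'")
  if (!is.character(study_id) || length(study_id) != 1L || is.na(study_id))
    stop("'study_id' must be a single string")
  if (scale == "counts" && any(values < 0))
    stop("count-scale values must be non-negative")
  structure(list(values = values, study_id = study_id, scale = scale),
            class = "expr_study")
}

#' @export
print.expr_study <- function(x, ...) {
  cat(sprintf("<expr_study> %s: %d genes x %d samples (%s scale)\n",
              x$study_id, nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expr_study <- function(x) dim(x$values)

genes_of <- function(x) rownames(x$values)

#' Read an expression matrix from disk
#'
#' Reads either a delimited text file (first column = gene identifiers,
#' header = sample identifiers) or a MatrixMarket triple of files
#' (`<path>`, `<path>.genes`, `<path>.samples`).
#'
#' @param path File path. Files ending in `.mtx` are parsed as
#'   MatrixMarket with gene/sample name sidecars; anything else as
#'   tab/comma separated text.
#' @param study_id Study identifier; defaults to the file base name.
#' @param scale Value scale of the file, `"log"` (default) or `"counts"`.
#' @return An [expr_study()].
#' @export
read_expression <- function(path, study_id = NULL, scale = c("log", "counts")) {
  scale <- match.arg(scale)
  if (is.null(study_id))
    study_id <- sub("\\.[^.]+$", "", basename(path))
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(paste0(path, ".genes"))
    cn <- readLines(paste0(path, ".samples"))
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("MTX dimensions do not match the .genes/.samples sidecar files")
    dimnames(m) <- list(rn, cn)
  } else {
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
    rn <- as.character(dt[[1L]])
    m <- as.matrix(dt[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- rn
  }
  expr_study(m, study_id, scale)
}

#' Write an expression matrix as TSV
#'
#' @param x An [expr_study()].
#' @param path Output file; first column `gene`, remaining columns the
#'   samples.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_study"))
  dt <- data.table::data.table(gene = rownames(x$values))
  dt <- cbind(dt, data.table::as.data.table(x$values))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a study metadata table
#'
#' Expects a TSV with columns `studyId`, `sampleCount`, `title` and
#' `meshTerms` (pipe-separated term list; may be empty).
#'
#' @param path TSV file path.
#' @return A data.frame with one row per study; `meshTerms` is a list
#'   column of character vectors.
#' @export
read_study_metadata <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          data.table = FALSE, colClasses = list(
                            character = c("studyId", "title", "meshTerms")))
  need <- c("studyId", "sampleCount", "title", "meshTerms")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("metadata table is missing column(s): ", paste(miss, collapse = ", "))
  dt$meshTerms <- lapply(strsplit(dt$meshTerms, "|", fixed = TRUE),
                         function(v) v[nzchar(v)])
  dt
}
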