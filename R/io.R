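#' Read and write expression tables
#'
#' Dense TSV: first column `gene_id`, header row of sample ids, tab-separated
#' numbers. Sparse Matrix Market: a `.mtx` triplet file with `features.tsv`
#' and `barcodes.tsv` sidecars in the same directory (the 10x-style layout).
#' Duplicate gene ids are rejected by both readers.
#'
#' @param path File path (`.tsv`, or `.mtx` with sidecars).
#' @param format `"tsv"` or `"mtx"`; guessed from the extension by default.
#' @param platform Platform tag for the returned table.
#' @return An `expr_tbl`.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "mtx"),
                            platform = c("intensity", "count")) {
  format <- match.arg(format)
  platform <- match.arg(platform)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (names(x)[1L] != "gene_id") {
      stop("malformed header: first column must be 'gene_id', got '",
           names(x)[1L], "'", call. = FALSE)
    }
    expression_tbl(x, platform)
  } else {
    dir <- dirname(path)
    feats <- file.path(dir, "features.tsv")
    cells <- file.path(dir, "barcodes.tsv")
    for (f in c(feats, cells)) {
      if (!file.exists(f)) stop("missing sidecar file: ", f, call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readr::read_tsv(feats, col_names = "gene_id",
                                   show_col_types = FALSE)$gene_id
    colnames(m) <- readr::read_tsv(cells, col_names = "cell_id",
                                   show_col_types = FALSE)$cell_id
    expression_tbl(matrix_tbl(m), platform)
  }
}

#' @rdname read_expression
#' @param x An expression table (wide tibble, gene_id first).
#' @export
write_expression <- function(x, path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "tsv") {
    readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  } else {
    m <- expr_matrix(x)
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(rownames(m), file.path(dir, "features.tsv"))
    writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  }
  invisible(path)
}

#' Serialize a reference basis to a directory
#'
#' Writes `basis.tsv` (gene x K z-scores), `dual.tsv` (K x gene dual
#' operator) and `meta.json` (labels, normalization universe size, gram
#' condition number, tool version).
#'
#' @param basis A `reference_basis`.
#' @param dir Output directory (created if needed).
#' @export
write_basis <- function(basis, dir) {
  stopifnot(inherits(basis, "reference_basis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(matrix_tbl(basis$B), file.path(dir, "basis.tsv"),
                   progress = FALSE)
  dual <- dplyr::bind_cols(tibble::tibble(cell_type = basis$type_labels),
                           tibble::as_tibble(basis$P, .name_repair = "minimal"))
  readr::write_tsv(dual, file.path(dir, "dual.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(type_labels = basis$type_labels, n = basis$n,
         n_genes = length(basis$gene_ids),
         gram_condition = basis$gram_condition,
         version = as.character(utils::packageVersion("lapscore"))),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_basis
#' @export
read_basis <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  bt <- readr::read_tsv(file.path(dir, "basis.tsv"), show_col_types = FALSE)
  basis <- build_basis(new_zscore_tbl(bt, n_genes = meta$n),
                       labels = meta$type_labels)
  basis
}

#' Write projection scores and null calibrations
#'
#' Scores go to long-format TSV (`sample_id`, `cell_type`, `score`, and
#' `significant` when present); calibrations to JSON with fields `R`,
#' `seed`, `mean`, `sd`, `multiplier`, `threshold`.
#'
#' @param scores Tibble from [project_onto_basis()] /
#'   [classify_significant()].
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  readr::write_tsv(scores, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @param calibration A `null_calibration`.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "null_calibration"))
  jsonlite::write_json(
    list(R = calibration$R, seed = calibration$seed,
         mean = calibration$mean, sd = calibration$sd,
         multiplier = calibration$multiplier,
         threshold = calibration$threshold),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(R = as.integer(x$R), mean = x$mean, sd = x$sd,
         multiplier = x$multiplier, threshold = x$threshold,
         seed = as.integer(x$seed), scores = NULL),
    class = "null_calibration")
}
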