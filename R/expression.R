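#' Expression tables
#'
#' `lapscore` represents expression data as wide tibbles: a `gene_id`
#' character column followed by one numeric column per sample, with a
#' `platform` attribute tagging the measurement family (`"count"` for
#' RNA-Seq / UMI counts, `"intensity"` for microarray-style readouts).
#' [expression_tbl()] validates a data frame into this shape;
#' [expr_platform()] reads the tag back.
#'
#' @param x A data frame with a `gene_id` column and numeric sample columns.
#' @param platform One of `"count"` or `"intensity"`.
#' @return A tibble of class `expr_tbl` with a `platform` attribute.
#' @examples
#' expression_tbl(
#'   data.frame(gene_id = c("g1", "g2"), s1 = c(3, 0), s2 = c(1, 8)),
#'   platform = "count"
#' )
#' @export
expression_tbl <- function(x, platform = c("intensity", "count")) {
  platform <- match.arg(platform)
  x <- tibble::as_tibble(x)
  if (!"gene_id" %in% names(x)) {
    stop("expression table must have a 'gene_id' column", call. = FALSE)
  }
  x <- dplyr::relocate(x, "gene_id")
  if (ncol(x) < 2L) {
    stop("expression table has no sample columns", call. = FALSE)
  }
  dup <- unique(x$gene_id[duplicated(x$gene_id)])
  if (length(dup) > 0L) {
    stop("duplicate gene ids: ", paste(utils::head(dup, 5L), collapse = ", "),
         call. = FALSE)
  }
  vals <- x[, -1L, drop = FALSE]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
    stop("non-numeric sample column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(vals)
  if (anyNA(m)) stop("expression table contains missing values", call. = FALSE)
  if (platform == "count" && any(m < 0)) {
    stop("count matrix contains negative values", call. = FALSE)
  }
  structure(x, platform = platform, class = c("expr_tbl", class(x)))
}

#' @rdname expression_tbl
#' @export
expr_platform <- function(x) {
  attr(x, "platform") %||% "intensity"
}

# internal: wide tibble (gene_id + samples) -> numeric matrix with rownames
expr_matrix <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "gene_id"), drop = FALSE])
  rownames(m) <- x$gene_id
  m
}

# internal: matrix with rownames -> wide tibble
matrix_tbl <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(gene_id = rownames(m)),
    tibble::as_tibble(m, .name_repair = "minimal")
  )
}

sample_ids <- function(x) setdiff(names(x), "gene_id")
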