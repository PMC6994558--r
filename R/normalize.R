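#' Shared gene universe across data sets
#'
#' Cross-platform comparison is only meaningful on genes measured in every
#' data set, so all downstream steps operate on the intersection of the gene
#' lists. Matching is exact, case-sensitive symbol equality; no ortholog or
#' alias mapping is attempted.
#'
#' @param matrices A list of expression tables (see [expression_tbl()]), or
#'   anything with a `gene_id` column.
#' @return A lexicographically sorted character vector of shared gene ids.
#' @examples
#' a <- expression_tbl(data.frame(gene_id = c("gA", "gB", "gC"), s = 1:3))
#' b <- expression_tbl(data.frame(gene_id = c("gB", "gC", "gD"), s = 1:3))
#' intersect_genes(list(a, b))
#' @export
intersect_genes <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  gene_sets <- purrr::map(matrices, ~ .x$gene_id)
  common <- purrr::reduce(gene_sets, intersect)
  if (length(common) == 0L) {
    # name the first offending pair for the error message
    for (i in seq_along(gene_sets)) {
      for (j in seq_len(i - 1L)) {
        if (length(intersect(gene_sets[[i]], gene_sets[[j]])) == 0L) {
          stop(sprintf("empty gene intersection between data sets %d and %d",
                       j, i), call. = FALSE)
        }
      }
    }
    stop("empty gene intersection across data sets", call. = FALSE)
  }
  sort(common)
}

#' Rank-quantile normalization to standard-normal profiles
#'
#' Converts each sample of an expression table to a rank-derived z-score
#' profile: values are ranked (ascending, average rank for ties), ranks are
#' turned into percentiles by dividing by N + 1 (N = number of genes), the
#' percentiles are mapped through the standard-normal quantile function, and
#' the resulting vector is rescaled so its squared Euclidean norm equals N
#' exactly. Because only ranks enter, the output is invariant to any strictly
#' increasing per-sample transform, which is what makes microarray
#' intensities and RNA-Seq counts comparable.
#'
#' @param matrix An expression table ([expression_tbl()] or any wide tibble
#'   with `gene_id` first).
#' @param genes Optional gene universe: the table is subset (and reordered)
#'   to these ids before ranking, so every sample is normalized on the same
#'   universe.
#' @return A tibble of class `zscore_tbl` (gene_id + one z-score column per
#'   sample) with attribute `n_genes`.
#' @examples
#' x <- expression_tbl(data.frame(gene_id = c("g1", "g2", "g3"),
#'                                s1 = c(5, 2, 9)))
#' rank_normalize(x)   # (0, -1.2247, 1.2247)
#' @export
rank_normalize <- function(matrix, genes = NULL) {
  x <- tibble::as_tibble(matrix)
  if (!is.null(genes)) {
    missing <- setdiff(genes, x$gene_id)
    if (length(missing) > 0L) {
      stop(sprintf("%d gene(s) of the requested universe absent from input",
                   length(missing)), call. = FALSE)
    }
    x <- x[match(genes, x$gene_id), , drop = FALSE]
  }
  m <- expr_matrix(x)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 genes to rank-normalize", call. = FALSE)
  z <- apply(m, 2L, rank_to_z, n = n)
  rownames(z) <- rownames(m)
  new_zscore_tbl(matrix_tbl(z), n_genes = n)
}

rank_to_z <- function(v, n) {
  if (length(unique(v)) < 2L) {
    stop("degenerate sample: all ranks tied", call. = FALSE)
  }
  z <- stats::qnorm(rank(v, ties.method = "average") / (n + 1))
  z * sqrt(n / sum(z^2))
}

new_zscore_tbl <- function(x, n_genes) {
  structure(tibble::as_tibble(x), n_genes = n_genes,
            class = c("zscore_tbl", class(tibble::tibble())))
}

#' @rdname rank_normalize
#' @param x A `zscore_tbl`.
#' @export
n_genes <- function(x) {
  attr(x, "n_genes") %||% (nrow(x))
}

#' High-expression gene filter
#'
#' Restricts the gene universe to genes highly expressed (z strictly greater
#' than `threshold`) in at least one reference column. Retained z-scores are
#' kept unchanged: the reduced profiles are not re-ranked or re-scaled on the
#' smaller universe.
#'
#' @param basis_z A `zscore_tbl` whose columns are reference cell types.
#' @param threshold Strict lower bound on the per-type z-score (default 1).
#' @return Character vector of retained gene ids, in input order.
#' @export
high_expression_filter <- function(basis_z, threshold = 1.0) {
  m <- expr_matrix(basis_z)
  keep <- apply(m, 1L, max) > threshold
  if (!any(keep)) stop("no gene passes expression filter", call. = FALSE)
  rownames(m)[keep]
}

#' Restrict a z-score table to a gene subset without re-normalizing
#'
#' @param z A `zscore_tbl`.
#' @param genes Gene ids to keep (order taken from `genes`).
#' @return A `zscore_tbl` on the reduced universe; `n_genes` still records
#'   the pre-filter universe size under which the z-scores were computed.
#' @export
filter_genes <- function(z, genes) {
  missing <- setdiff(genes, z$gene_id)
  if (length(missing) > 0L) {
    stop(sprintf("%d gene(s) not present in z-score table", length(missing)),
         call. = FALSE)
  }
  new_zscore_tbl(z[match(genes, z$gene_id), , drop = FALSE],
                 n_genes = n_genes(z))
}
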