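#' Per-cell normalization of single-cell counts
#'
#' Counts are scaled per cell to a fixed total and log1p-transformed, the
#' conventional normalization applied before pseudobulk averaging. The
#' averaged cluster profiles then enter [rank_normalize()] like any bulk
#' sample, keeping the downstream chain uniform across data types.
#'
#' @param counts An expression table of UMI counts (platform `"count"`).
#' @param scale_total Target per-cell total (default 1e4).
#' @return A wide tibble of normalized expression (gene_id + cells).
#' @export
normalize_cells <- function(counts, scale_total = 1e4) {
  m <- expr_matrix(counts)
  totals <- colSums(m)
  if (any(totals == 0)) {
    stop("cell(s) with zero total counts: ",
         paste(utils::head(colnames(m)[totals == 0], 5L), collapse = ", "),
         call. = FALSE)
  }
  matrix_tbl(log1p(sweep(m, 2L, totals, "/") * scale_total))
}

#' Average single-cell profiles within clusters
#'
#' Single-cell data are sparse, with heavy dropout (expressed but undetected
#' transcripts), so individual cells make poor reference profiles. Averaging
#' the normalized expression of all cells in a cluster gives a pseudobulk
#' profile robust enough to serve as one reference basis entry.
#'
#' @param cell_matrix Wide tibble of normalized gene x cell expression
#'   (e.g. output of [normalize_cells()]).
#' @param clusters A data frame with columns `cell_id` and `cluster`
#'   assigning every cell to exactly one cluster.
#' @return Wide tibble of gene x cluster mean profiles, clusters in sorted
#'   label order.
#' @export
average_cluster_profiles <- function(cell_matrix, clusters) {
  clusters <- tibble::as_tibble(clusters)
  stopifnot(all(c("cell_id", "cluster") %in% names(clusters)))
  if (anyDuplicated(clusters$cell_id)) {
    stop("a cell is assigned to more than one cluster", call. = FALSE)
  }
  m <- expr_matrix(cell_matrix)
  unknown <- setdiff(clusters$cell_id, colnames(m))
  if (length(unknown) > 0L) {
    stop("unknown cell id(s) in cluster assignment: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  labels <- sort(unique(as.character(clusters$cluster)))
  avg <- vapply(labels, function(lab) {
    cells <- clusters$cell_id[as.character(clusters$cluster) == lab]
    rowMeans(m[, cells, drop = FALSE])
  }, numeric(nrow(m)))
  matrix_tbl(avg)
}

#' Build a reference basis with its dual (projection) operator
#'
#' The reference basis is a gene x K matrix B of z-score profiles, one
#' labeled column per cell type. Because real cell types share most of their
#' transcriptome, the columns of B are strongly correlated, and a naive
#' correlation against each column would confound related types. The dual
#' operator P — the Moore-Penrose pseudoinverse of B — removes those inherent
#' correlations: P maps a query to its least-squares coordinates on the
#' basis, so each reference type has a projection of exactly 1 with itself
#' and 0 with every other type.
#'
#' @param profiles A `zscore_tbl` (or wide tibble) of gene x K reference
#'   profiles.
#' @param labels Optional K cell-type names (default: column names).
#' @param sv_cutoff Relative singular-value cutoff below which the basis is
#'   declared rank-deficient (default 1e-10).
#' @return An object of class `reference_basis` with elements `gene_ids`,
#'   `type_labels`, `B` (gene x K), `P` (K x gene), `gram_condition`
#'   (condition number of B'B) and `n` (the normalization universe size).
#' @examples
#' prof <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
#'                        a = c(1, 0, 1), b = c(0, 1, 1))
#' b <- build_basis(prof)
#' round(b$P %*% b$B, 10)   # 2 x 2 identity
#' @export
build_basis <- function(profiles, labels = NULL, sv_cutoff = 1e-10) {
  B <- expr_matrix(profiles)
  K <- ncol(B)
  if (K < 2L) stop("need at least 2 reference types", call. = FALSE)
  if (K >= nrow(B)) {
    stop("more reference types than genes; basis must be tall", call. = FALSE)
  }
  labels <- labels %||% colnames(B)
  stopifnot(length(labels) == K)
  if (anyDuplicated(labels)) {
    stop("duplicate type labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  colnames(B) <- labels

  sv <- svd(B)
  if (any(sv$d < sv_cutoff * sv$d[1L])) {
    co <- stats::cor(B)
    diag(co) <- 0
    worst <- sort(which(abs(co) == max(abs(co)), arr.ind = TRUE)[1L, ])
    stop(sprintf(
      "rank-deficient basis: most collinear type pair '%s' / '%s' (cosine %.4f)",
      labels[worst[1L]], labels[worst[2L]], co[worst[1L], worst[2L]]),
      call. = FALSE)
  }
  P <- sv$v %*% (t(sv$u) / sv$d)
  dimnames(P) <- list(labels, rownames(B))

  structure(
    list(
      gene_ids = rownames(B),
      type_labels = labels,
      B = B,
      P = P,
      gram_condition = (sv$d[1L] / sv$d[K])^2,
      n = if (inherits(profiles, "zscore_tbl")) n_genes(profiles) else nrow(B)
    ),
    class = "reference_basis"
  )
}

#' @export
print.reference_basis <- function(x, ...) {
  cat(sprintf(
    "<reference_basis> %d types x %d genes (normalization universe N = %d)\n",
    length(x$type_labels), length(x$gene_ids), x$n))
  cat(sprintf("  gram condition number: %.3g\n", x$gram_condition))
  cat("  types: ", paste(utils::head(x$type_labels, 6L), collapse = ", "),
      if (length(x$type_labels) > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname build_basis
#' @param x A `reference_basis`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.reference_basis <- function(x, ...) {
  matrix_tbl(x$B) |>
    tidyr::pivot_longer(-"gene_id", names_to = "cell_type",
                        values_to = "zscore")
}

#' @rdname build_basis
#' @exportS3Method generics::glance
glance.reference_basis <- function(x, ...) {
  tibble::tibble(
    n_types = length(x$type_labels),
    n_genes = length(x$gene_ids),
    n_universe = x$n,
    gram_condition = x$gram_condition,
    max_dual_identity_error = max(abs(x$P %*% x$B - diag(length(x$type_labels))))
  )
}

#' Assemble a reference basis from heterogeneous expression tables
#'
#' Convenience wrapper running the full chain: intersect gene lists across
#' data sets, rank-normalize every sample on the common universe, pool all
#' reference columns, apply the high-expression (z > `filter_z`) filter, and
#' build the dual operator. Cell-type labels colliding across data sets are
#' suffixed with the data-set name.
#'
#' @param matrices Named list of expression tables; columns of each are
#'   reference cell types.
#' @param filter_z High-expression filter threshold (default 1).
#' @return A `reference_basis`.
#' @export
build_reference <- function(matrices, filter_z = 1.0) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  common <- intersect_genes(matrices)
  zs <- purrr::map(matrices, rank_normalize, genes = common)
  labels <- purrr::map(zs, sample_ids)
  all_labels <- unlist(labels, use.names = FALSE)
  if (anyDuplicated(all_labels) && !is.null(names(matrices))) {
    labels <- purrr::imap(labels, function(l, nm) {
      ifelse(l %in% all_labels[duplicated(all_labels)] & nzchar(nm),
             paste(l, nm, sep = "."), l)
    })
  }
  pooled <- purrr::reduce(
    purrr::map2(zs, labels, ~ rlang::set_names(.x, c("gene_id", .y))),
    dplyr::left_join, by = "gene_id")
  pooled <- new_zscore_tbl(pooled, n_genes = length(common))
  keep <- high_expression_filter(pooled, threshold = filter_z)
  build_basis(filter_genes(pooled, keep))
}
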