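#' Preprocess RNA-Seq counts for gene-set scoring
#'
#' The gene-set scoring route works on log-scale, centered, outlier-capped
#' expression. The chain is: (1) per-sample counts-per-million with a prior
#' offset, log2 (`log2(cpm + prior)`, so the transform never takes log of
#' zero and is exactly invariant to library-size scaling); (2) drop genes
#' whose log-scale values summed across samples fall below `min_total`;
#' (3) center each gene at 0 across samples; (4) per sample, cap values
#' outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` to those fences (quartiles by
#' linear interpolation), taming heavy-tailed outliers.
#'
#' @param counts An expression table with platform `"count"`.
#' @param min_total Minimum summed log-scale expression across samples for a
#'   gene to be kept (default 2), applied before centering.
#' @param prior Prior count added to CPM before the log (default 0.5).
#' @return A wide tibble (gene_id + samples) of processed expression.
#' @export
preprocess_counts <- function(counts, min_total = 2, prior = 0.5) {
  if (inherits(counts, "expr_tbl") && expr_platform(counts) != "count") {
    stop("preprocess_counts expects count data", call. = FALSE)
  }
  m <- expr_matrix(counts)
  lib <- colSums(m)
  if (any(lib == 0)) stop("sample(s) with zero total counts", call. = FALSE)
  lg <- log2(sweep(m, 2L, lib, "/") * 1e6 + prior)
  keep <- rowSums(lg) >= min_total
  if (!any(keep)) stop("all genes removed by the total-expression filter",
                       call. = FALSE)
  lg <- lg[keep, , drop = FALSE]
  lg <- lg - rowMeans(lg)
  capped <- apply(lg, 2L, function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    fence <- c(q[1L] - 1.5 * (q[2L] - q[1L]), q[2L] + 1.5 * (q[2L] - q[1L]))
    pmin(pmax(v, fence[1L]), fence[2L])
  })
  rownames(capped) <- rownames(lg)
  matrix_tbl(capped)
}

#' Build per-condition gene signatures
#'
#' A signature is built in two ranking passes over the processed matrix:
#' the `pool` genes with highest variance across all samples capture those
#' carrying biological signal; then, for each condition, the `size` most
#' expressed of those highly variable genes (by mean over that condition's
#' samples) form its signature. Ties are broken lexicographically by gene id
#' for bit-reproducibility.
#'
#' @param processed Wide tibble from [preprocess_counts()].
#' @param condition_labels Character vector, one condition per sample column.
#' @param pool Variance-pool size (default 3000, capped at the gene count).
#' @param size Signature size (default 100; must not exceed `pool`).
#' @return A named list of character vectors (one signature per condition),
#'   each ordered by decreasing condition expression.
#' @export
build_signatures <- function(processed, condition_labels, pool = 3000L,
                             size = 100L) {
  m <- expr_matrix(processed)
  samples <- colnames(m)
  stopifnot(length(condition_labels) == length(samples))
  if (pool > nrow(m)) {
    stop(sprintf("variance pool (%d) exceeds gene count (%d)", pool, nrow(m)),
         call. = FALSE)
  }
  if (size > pool) stop("signature size exceeds variance pool", call. = FALSE)

  v <- apply(m, 1L, stats::var)
  ord <- order(-v, rownames(m), method = "radix")
  pool_genes <- rownames(m)[ord[seq_len(pool)]]

  conds <- unique(condition_labels)
  sigs <- purrr::map(conds, function(cond) {
    cols <- samples[condition_labels == cond]
    mu <- rowMeans(m[pool_genes, cols, drop = FALSE])
    pool_genes[order(-mu, pool_genes, method = "radix")][seq_len(size)]
  })
  rlang::set_names(sigs, conds)
}

#' Single-sample enrichment score (weighted ECDF difference)
#'
#' Genes are ranked by the sample's expression value, descending. Walking
#' down that ranking, two cumulative distribution functions are tracked: the
#' weighted ECDF of signature genes (weight `|value|^tau`) and the unweighted
#' ECDF of the remaining genes. The enrichment score is the sum over rank
#' positions of their difference — large and positive when signature genes
#' concentrate at the top of the ranking, negative when they sink to the
#' bottom. Ties in value are broken lexicographically by gene id so results
#' are reproducible.
#'
#' @param sample_values Named numeric vector (names = gene ids) of one
#'   sample's processed expression.
#' @param signature Character vector of signature gene ids; must be a
#'   non-empty proper subset of the sample's genes.
#' @param tau Weighting exponent on `|value|` for signature genes
#'   (default 1).
#' @return A single enrichment score.
#' @examples
#' v <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
#' enrichment_score(v, "g1")   #  2
#' enrichment_score(v, "g4")   # -2
#' @export
enrichment_score <- function(sample_values, signature, tau = 1) {
  genes <- names(sample_values)
  if (is.null(genes)) stop("sample_values must be named by gene id",
                           call. = FALSE)
  if (length(signature) == 0L || !all(signature %in% genes) ||
      length(signature) >= length(genes)) {
    stop("signature must be a non-empty proper subset of the sample's genes",
         call. = FALSE)
  }
  ord <- order(-sample_values, genes, method = "radix")
  v <- sample_values[ord]
  in_sig <- genes[ord] %in% signature
  w <- abs(v)^tau * in_sig
  if (sum(w) == 0) w <- as.numeric(in_sig)  # all-zero signature: equal mass
  f_sig <- cumsum(w) / sum(w)
  f_rest <- cumsum(!in_sig) / sum(!in_sig)
  sum(f_sig - f_rest)
}

#' Score every (condition signature, sample) pair
#'
#' @param processed Wide tibble from [preprocess_counts()].
#' @param signatures Named list of gene-id vectors (see
#'   [build_signatures()] or [read_gmt()]).
#' @param tau Weighting exponent passed to [enrichment_score()].
#' @return A tibble with columns `condition`, `sample_id`, `es`.
#' @export
score_signatures <- function(processed, signatures, tau = 1) {
  m <- expr_matrix(processed)
  tidyr::expand_grid(condition = names(signatures),
                     sample_id = colnames(m)) |>
    dplyr::mutate(es = purrr::map2_dbl(
      .data$condition, .data$sample_id,
      ~ enrichment_score(m[, .y], signatures[[.x]], tau = tau)))
}

#' Read and write gene sets in GMT format
#'
#' GMT is the tab-separated gene-set exchange format: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Reading is delegated to
#' \pkg{fgsea}.
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    stop("reading GMT requires the 'fgsea' package", call. = FALSE)
  }
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param signatures Named list of gene-id vectors.
#' @param description Description field written for every set (default
#'   `"lapscore"`).
#' @export
write_gmt <- function(signatures, path, description = "lapscore") {
  stopifnot(!is.null(names(signatures)), all(nzchar(names(signatures))))
  lines <- purrr::imap_chr(signatures, function(genes, nm) {
    paste(c(nm, description, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}
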