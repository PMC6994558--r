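#' Project query profiles onto a reference basis
#'
#' Each query sample's z-score profile is expressed in the coordinates of
#' the reference basis: scores = P q, where P is the basis dual operator.
#' A score near 1 on a type indicates a transcriptome matching that
#' reference, 0 no relation, and negative values an anti-correlated pattern.
#' Queries must live on exactly the basis gene universe; use
#' [normalize_query()] to take a raw expression table there.
#'
#' @param basis A `reference_basis` from [build_basis()].
#' @param query A `zscore_tbl` (one or more sample columns) on the basis
#'   gene universe.
#' @return A tibble with columns `sample_id`, `cell_type`, `score`, in
#'   basis type order within each sample.
#' @export
project_onto_basis <- function(basis, query) {
  stopifnot(inherits(basis, "reference_basis"))
  q <- expr_matrix(query)
  missing <- setdiff(basis$gene_ids, rownames(q))
  extra <- setdiff(rownames(q), basis$gene_ids)
  if (length(missing) > 0L || length(extra) > 0L) {
    stop(sprintf(
      "query gene universe does not match basis: %d missing, %d extra gene(s)",
      length(missing), length(extra)), call. = FALSE)
  }
  q <- q[basis$gene_ids, , drop = FALSE]
  s <- basis$P %*% q
  tibble::tibble(
    sample_id = rep(colnames(q), each = nrow(s)),
    cell_type = rep(basis$type_labels, times = ncol(q)),
    score = as.vector(s)
  )
}

#' Normalize a raw query onto the basis gene universe
#'
#' Subsets a raw expression table to the basis genes and rank-normalizes it
#' on that universe. Queries covering less than `min_coverage` of the basis
#' genes are rejected (the projection geometry assumes a shared universe);
#' basis genes absent from a query that still meets the coverage bound are
#' assigned z = 0 (the rank-neutral value) with a warning.
#'
#' @param basis A `reference_basis`.
#' @param query An expression table of raw values.
#' @param min_coverage Minimum fraction of basis genes the query must
#'   measure (default 0.95).
#' @return A `zscore_tbl` on the basis gene universe.
#' @export
normalize_query <- function(basis, query, min_coverage = 0.95) {
  present <- intersect(basis$gene_ids, query$gene_id)
  coverage <- length(present) / length(basis$gene_ids)
  if (coverage < min_coverage) {
    stop(sprintf("query covers only %.1f%% of basis genes (minimum %.0f%%)",
                 100 * coverage, 100 * min_coverage), call. = FALSE)
  }
  z <- rank_normalize(query[query$gene_id %in% present, , drop = FALSE],
                      genes = sort(present))
  absent <- setdiff(basis$gene_ids, present)
  if (length(absent) > 0L) {
    warning(sprintf("%d basis gene(s) missing from query; set to z = 0",
                    length(absent)), call. = FALSE)
    fill <- matrix_tbl(matrix(0, nrow = length(absent),
                              ncol = length(sample_ids(z)),
                              dimnames = list(absent, sample_ids(z))))
    z <- new_zscore_tbl(dplyr::bind_rows(z, fill), n_genes = n_genes(z))
  }
  filter_genes(z, basis$gene_ids)
}

#' Calibrate the null distribution of projection scores
#'
#' Projection scores have no direct p-value, but random expression profiles
#' give an empirical null: R profiles of iid standard-normal entries,
#' rescaled to squared norm N (the same convention as rank-normalized
#' samples), are projected onto the basis. The grand mean over all R x K
#' scores is zero up to Monte-Carlo error; the pooled standard deviation
#' defines a significance threshold at `multiplier` standard deviations.
#'
#' @param basis A `reference_basis`.
#' @param R Number of random profiles (default 10000; minimum 1000).
#' @param seed Integer RNG seed (default 0); recorded in the result.
#' @param multiplier Threshold multiplier (default 5).
#' @param keep_scores Keep the R x K null score matrix (for plotting)?
#' @return An object of class `null_calibration` with fields `R`, `mean`,
#'   `sd`, `multiplier`, `threshold` (= multiplier * sd) and `seed`.
#' @export
calibrate_null <- function(basis, R = 10000L, seed = 0L, multiplier = 5,
                           keep_scores = FALSE) {
  stopifnot(inherits(basis, "reference_basis"))
  if (R < 1000L) stop("need at least 1000 random profiles", call. = FALSE)
  G <- length(basis$gene_ids)
  scores <- withr::with_seed(seed, {
    Q <- matrix(stats::rnorm(G * R), nrow = G)
    Q <- sweep(Q, 2L, sqrt(colSums(Q^2) / G), "/")  # squared norm = G
    basis$P %*% Q
  })
  sd0 <- stats::sd(as.vector(scores))
  structure(
    list(R = as.integer(R), mean = mean(scores), sd = sd0,
         multiplier = multiplier, threshold = multiplier * sd0,
         seed = as.integer(seed),
         scores = if (keep_scores) scores else NULL),
    class = "null_calibration"
  )
}

#' @export
print.null_calibration <- function(x, ...) {
  cat(sprintf(
    "<null_calibration> R = %d random profiles (seed %d)\n  mean %.3g, sd %.4f -> |score| > %.4f (%g sd) called significant\n",
    x$R, x$seed, x$mean, x$sd, x$threshold, x$multiplier))
  invisible(x)
}

#' @rdname calibrate_null
#' @param x A `null_calibration`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.null_calibration <- function(x, ...) {
  tibble::tibble(R = x$R, mean = x$mean, sd = x$sd,
                 multiplier = x$multiplier, threshold = x$threshold,
                 seed = x$seed)
}

#' Flag significant projection scores
#'
#' A score is called significant when its magnitude strictly exceeds the
#' calibrated threshold (`multiplier` standard deviations of the random-
#' profile null). With the default multiplier of 5, scores this large are
#' highly unlikely to arise from random expression patterns.
#'
#' @param scores A tibble with a `score` column (e.g. from
#'   [project_onto_basis()]), or a bare numeric vector.
#' @param calibration A `null_calibration` for the same basis.
#' @return The scores tibble with a logical `significant` column appended
#'   (or a logical vector for numeric input).
#' @export
classify_significant <- function(scores, calibration) {
  stopifnot(inherits(calibration, "null_calibration"))
  if (is.numeric(scores)) {
    return(abs(scores) > calibration$threshold)
  }
  dplyr::mutate(scores, significant = abs(.data$score) > calibration$threshold)
}
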