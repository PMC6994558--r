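#' Simulate a cross-platform reference data set with known ground truth
#'
#' Emulates the raw material of a mixed-platform reference basis: K latent
#' cell-type profiles with pairwise correlation `rho` (an equicorrelated
#' Gaussian factor model: each profile is `sqrt(rho)` of a shared component
#' plus `sqrt(1-rho)` of a private one), read out on two simulated
#' platforms — lognormal intensities for the microarray-like half of the
#' types and negative-binomial counts for the RNA-Seq-like half. Each
#' platform measures a jittered gene list (a fraction of private genes per
#' platform) so that assembling a basis genuinely exercises the
#' gene-intersection step. Gene-level baseline abundance is shared across
#' types, as in real transcriptomes, so readout profiles are substantially
#' more correlated than the latent ones.
#'
#' @param G Number of genes per platform (pre-jitter universe is slightly
#'   larger). Must be at least `10 * K`.
#' @param K Number of cell types (at least 2).
#' @param rho Between-type latent correlation in `[0, 1)`.
#' @param seed Integer RNG seed.
#' @param dispersion Negative-binomial dispersion (1/size) for the count
#'   platform (default 0.2).
#' @param private_frac Fraction of each platform's gene list private to it
#'   (default 0.05).
#' @param signal_sd Scale of the latent signal on the log readout, relative
#'   to the baseline spread of 1 (default 1).
#' @return A list with `matrices` (named list of `expr_tbl`, one per
#'   platform), `latent` (gene x K latent profile matrix) and `truth`
#'   (tibble of type, platform).
#' @export
simulate_reference <- function(G, K, rho = 0.3, seed = 0L, dispersion = 0.2,
                               private_frac = 0.05, signal_sd = 1) {
  stopifnot(K >= 2L, G >= 10L * K, dispersion > 0)
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  withr::with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(ceiling(G * (1 + private_frac))))
    types <- sprintf("type%02d", seq_len(K))
    n_all <- length(genes)

    shared <- stats::rnorm(n_all)
    latent <- sqrt(rho) * matrix(shared, n_all, K) +
      sqrt(1 - rho) * matrix(stats::rnorm(n_all * K), n_all, K)
    dimnames(latent) <- list(genes, types)
    baseline <- stats::rnorm(n_all, mean = 3, sd = 1)
    log_mu <- baseline + signal_sd * latent

    # each platform keeps G genes: the shared core plus its private tail
    n_private <- n_all - G
    pick <- function(private_ids) {
      shared_ids <- genes[seq_len(n_all - 2L * n_private)]
      sort(c(shared_ids, private_ids))
    }
    private1 <- genes[n_all - 2L * n_private + seq_len(n_private)]
    private2 <- genes[n_all - n_private + seq_len(n_private)]

    k1 <- seq_len(ceiling(K / 2))                    # intensity platform
    k2 <- setdiff(seq_len(K), k1)                    # count platform
    g1 <- pick(private1)
    g2 <- pick(private2)

    intensity <- exp(log_mu[g1, k1, drop = FALSE])
    mu <- exp(log(50) - 3 + log_mu[g2, k2, drop = FALSE])
    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
      nrow = nrow(mu), dimnames = dimnames(mu))

    list(
      matrices = list(
        intensity = expression_tbl(matrix_tbl(intensity), "intensity"),
        count = expression_tbl(matrix_tbl(counts), "count")
      ),
      latent = latent,
      truth = tibble::tibble(
        type = types,
        platform = ifelse(seq_len(K) %in% k1, "intensity", "count"))
    )
  })
}

#' Simulate query samples as noisy mixtures of basis types
#'
#' A query is `q = B w + e` in z-space: a weighted combination of the basis
#' columns plus iid Gaussian noise. The z-space form supports exact
#' recovery tests (the dual operator returns `w` exactly at zero noise); the
#' readout form pushes the same profile back through a monotone lognormal
#' readout, so it must be re-normalized like any raw sample — the full
#' end-to-end path.
#'
#' @param basis A `reference_basis`.
#' @param weights Numeric K-vector of mixture weights summing to 1, or a
#'   K x Q matrix (one column per query).
#' @param noise_sd Standard deviation of additive z-space noise (default 0).
#' @param seed Integer RNG seed.
#' @return A list with `zspace` (a `zscore_tbl` of z-space queries),
#'   `readout` (an intensity `expr_tbl` of the same queries after lognormal
#'   readout) and `weights` (the K x Q truth matrix).
#' @export
simulate_query_mixture <- function(basis, weights, noise_sd = 0, seed = 0L) {
  stopifnot(inherits(basis, "reference_basis"))
  W <- if (is.matrix(weights)) weights else matrix(weights, ncol = 1L)
  K <- length(basis$type_labels)
  stopifnot(nrow(W) == K)
  if (any(abs(colSums(W) - 1) > 1e-12)) {
    stop("mixture weights must sum to 1", call. = FALSE)
  }
  rownames(W) <- basis$type_labels
  colnames(W) <- sprintf("query%03d", seq_len(ncol(W)))
  withr::with_seed(seed, {
    q <- basis$B %*% W
    if (noise_sd > 0) {
      q <- q + matrix(stats::rnorm(length(q), sd = noise_sd), nrow = nrow(q))
    }
    list(
      zspace = new_zscore_tbl(matrix_tbl(q), n_genes = basis$n),
      readout = expression_tbl(matrix_tbl(exp(q)), "intensity"),
      weights = W
    )
  })
}

#' Simulate clustered single-cell count data with dropout
#'
#' Each cluster has a latent lognormal expression profile; cells draw
#' negative-binomial counts around that profile with a per-cell library-size
#' factor, and observed counts are additionally zeroed at random with
#' probability `dropout` (undetected but expressed transcripts). Ground-truth
#' cluster labels and latent profiles are returned for recovery tests.
#'
#' @param G Number of genes.
#' @param n_clusters Number of clusters (at least 2).
#' @param cells_per_cluster Cells per cluster (at least 1).
#' @param dispersion Negative-binomial dispersion (default 0.3).
#' @param dropout Per-entry dropout probability in `[0, 1)` (default 0.2).
#' @param seed Integer RNG seed.
#' @return A list with `counts` (an `expr_tbl` of UMI counts), `clusters`
#'   (tibble `cell_id`, `cluster`) and `latent` (gene x cluster log-mean
#'   profiles).
#' @export
simulate_single_cell <- function(G, n_clusters, cells_per_cluster,
                                 dispersion = 0.3, dropout = 0.2, seed = 0L) {
  stopifnot(G >= 10L, n_clusters >= 2L, cells_per_cluster >= 1L,
            dropout >= 0, dropout < 1)
  withr::with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(G))
    labs <- sprintf("cluster%02d", seq_len(n_clusters))
    latent <- matrix(stats::rnorm(G * n_clusters, mean = 1, sd = 1.5),
                     nrow = G, dimnames = list(genes, labs))
    n_cells <- n_clusters * cells_per_cluster
    cluster_of <- rep(labs, each = cells_per_cluster)
    cell_ids <- sprintf("cell%04d", seq_len(n_cells))
    size_factor <- exp(stats::rnorm(n_cells, sd = 0.3))
    counts <- vapply(seq_len(n_cells), function(i) {
      mu <- exp(latent[, cluster_of[i]]) * size_factor[i]
      x <- stats::rnbinom(G, mu = mu, size = 1 / dispersion)
      if (dropout > 0) x * (stats::runif(G) >= dropout) else x
    }, numeric(G))
    dimnames(counts) <- list(genes, cell_ids)
    list(
      counts = expression_tbl(matrix_tbl(counts), "count"),
      clusters = tibble::tibble(cell_id = cell_ids, cluster = cluster_of),
      latent = latent
    )
  })
}
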