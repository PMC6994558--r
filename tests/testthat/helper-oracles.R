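# Independent oracles and small fixture builders used across the suite.
# These deliberately take different code paths from the package: the
# least-squares oracle goes through QR, the ECDF oracle is a literal
# position-by-position walk, and the orthogonal basis is built from qr.Q.

# least-squares coordinates of q on the columns of B, via QR
ls_oracle <- function(B, q) {
  as.vector(qr.coef(qr(B), q))
}

# literal weighted-ECDF-difference walk (loop form, no cumsum)
es_oracle <- function(values, signature, tau = 1) {
  genes <- names(values)
  ord <- order(-values, genes, method = "radix")
  v <- values[ord]
  g <- genes[ord]
  w_total <- sum(abs(v[g %in% signature])^tau)
  n_rest <- sum(!g %in% signature)
  es <- 0
  f_sig <- 0
  f_rest <- 0
  for (i in seq_along(v)) {
    if (g[i] %in% signature) {
      f_sig <- f_sig + if (w_total > 0) abs(v[i])^tau / w_total else
        1 / length(signature)
    } else {
      f_rest <- f_rest + 1 / n_rest
    }
    es <- es + (f_sig - f_rest)
  }
  unname(es)
}

# expression tibble with lognormal values, G genes x S samples
make_expr <- function(G, S, seed = 1, platform = "intensity") {
  withr::with_seed(seed, {
    m <- matrix(exp(rnorm(G * S, mean = 3)), nrow = G,
                dimnames = list(sprintf("g%04d", seq_len(G)),
                                sprintf("s%02d", seq_len(S))))
    if (platform == "count") m <- round(m)
    expression_tbl(
      dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                       tibble::as_tibble(m)),
      platform)
  })
}

# zscore_tbl wrapping a bare matrix (columns already z-profiles)
as_ztbl <- function(m, n = nrow(m)) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%04d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
  lapscore:::new_zscore_tbl(
    dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                     tibble::as_tibble(m)),
    n_genes = n)
}

# basis with exactly orthogonal columns, each of squared norm G
orthogonal_basis <- function(G, K, seed = 1) {
  withr::with_seed(seed, {
    Q <- qr.Q(qr(matrix(rnorm(G * K), G, K))) * sqrt(G)
    colnames(Q) <- sprintf("type%02d", seq_len(K))
    build_basis(as_ztbl(Q))
  })
}
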