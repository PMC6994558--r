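# count preprocessing, signature construction, ECDF enrichment scores

test_that("preprocessing matches an independent step-by-step oracle", {
  counts <- make_expr(40, 5, seed = 41, platform = "count")
  got <- expr_matrix(preprocess_counts(counts, min_total = 2, prior = 0.5))
  # oracle: literal chain written out independently
  m <- expr_matrix(counts)
  lg <- log2(t(t(m) / colSums(m)) * 1e6 + 0.5)
  lg <- lg[rowSums(lg) >= 2, , drop = FALSE]
  lg <- lg - rowMeans(lg)
  for (j in seq_len(ncol(lg))) {
    q1 <- quantile(lg[, j], 0.25, names = FALSE)
    q3 <- quantile(lg[, j], 0.75, names = FALSE)
    lo <- q1 - 1.5 * (q3 - q1)
    hi <- q3 + 1.5 * (q3 - q1)
    lg[, j] <- pmin(pmax(lg[, j], lo), hi)
  }
  expect_equal(got, lg, tolerance = 1e-12)
})

test_that("outlier capping pulls values to the 1.5 IQR fences", {
  # five values (0,1,2,3,100): Q1=1, Q3=3, IQR=2, so 100 caps to 6
  v <- c(0, 1, 2, 3, 100)
  q <- quantile(v, c(0.25, 0.75), names = FALSE)
  expect_equal(q, c(1, 3))
  capped <- pmin(pmax(v, q[1] - 1.5 * diff(q)), q[2] + 1.5 * diff(q))
  expect_equal(capped, c(0, 1, 2, 3, 6))
  # and the same fence arithmetic is what preprocess_counts applies:
  # craft counts whose log-CPM profile has one extreme outlier
  counts <- expression_tbl(
    tibble::tibble(gene_id = paste0("g", 1:6),
                   s1 = c(2^c(10, 11, 12, 13, 30), 5),
                   s2 = c(2^c(10, 11, 12, 13, 14), 5)),
    platform = "count")
  out <- expr_matrix(preprocess_counts(counts))
  # in s1 the outlier gene must sit exactly on its upper fence
  v1 <- out[, "s1"]
  q13 <- quantile(v1, c(0.25, 0.75), names = FALSE, type = 7)
  expect_equal(max(v1), q13[2] + 1.5 * diff(q13), tolerance = 1e-9)
})

test_that("all-zero genes are removed and CPM is library-size invariant", {
  counts <- make_expr(30, 4, seed = 42, platform = "count")
  counts$g0001 <- NULL  # keep shape predictable
  zero <- tibble::tibble(gene_id = "gzero", s01 = 0, s02 = 0, s03 = 0,
                         s04 = 0)
  counts2 <- expression_tbl(dplyr::bind_rows(counts, zero), "count")
  out <- preprocess_counts(counts2)
  expect_false("gzero" %in% out$gene_id)
  # doubling every count leaves the output unchanged
  doubled <- counts2
  for (s in c("s01", "s02", "s03", "s04")) doubled[[s]] <- 2 * doubled[[s]]
  expect_equal(expr_matrix(preprocess_counts(expression_tbl(doubled, "count"))),
               expr_matrix(out), tolerance = 1e-12)
})

test_that("signatures are the most expressed of the most variable genes", {
  # 6 genes x 4 samples, hand-checkable
  m <- tibble::tibble(
    gene_id = c("gA", "gB", "gC", "gD", "gE", "gF"),
    s1 = c(10, 0, 5, 1, 1, 1), s2 = c(-10, 0, 5, 1, 1, 1),
    s3 = c(10, 0, -5, 1, 1, 1), s4 = c(-10, 0, 5, 1, 1, 1))
  # variances: gA=133.3, gC=25, rest 0 -> pool of 3 is gA, gC, then gB
  # (lexicographic among the zero-variance ties: gB < gD < gE < gF)
  sigs <- build_signatures(m, rep("cond", 4), pool = 3, size = 2)
  # means: gA = 0, gC = 2.5, gB = 0; ties gA/gB broken lexicographically
  expect_identical(sigs$cond, c("gC", "gA"))
  # size = pool returns the whole pool reordered by expression
  all3 <- build_signatures(m, rep("cond", 4), pool = 3, size = 3)
  expect_setequal(all3$cond, c("gA", "gB", "gC"))
  # condition labels are symmetric: swapping names swaps signatures
  two <- build_signatures(m, c("x", "y", "x", "y"), pool = 3, size = 2)
  swapped <- build_signatures(m, c("y", "x", "y", "x"), pool = 3, size = 2)
  expect_identical(two$x, swapped$y)
  expect_identical(two$y, swapped$x)
  expect_error(build_signatures(m, rep("c", 4), pool = 10, size = 2),
               "exceeds gene count")
})

test_that("enrichment score reproduces the hand-computed four-gene walks", {
  v <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
  expect_equal(enrichment_score(v, "g1"), 2)
  expect_equal(enrichment_score(v, "g4"), -2)
  expect_error(enrichment_score(v, character(0)), "proper subset")
  expect_error(enrichment_score(v, names(v)), "proper subset")
  expect_error(enrichment_score(v, "nope"), "proper subset")
})

test_that("enrichment score matches the brute-force ECDF walk on small toys", {
  withr::with_seed(43, {
    for (rep in 1:5) {
      n <- sample(5:12, 1)
      v <- rlang::set_names(round(rnorm(n), 3), paste0("g", sample(100, n)))
      genes <- names(v)
      # every non-trivial subset up to size 3, plus some random larger ones
      subsets <- c(purrr::map(genes, identity),
                   utils::combn(genes, 2, simplify = FALSE),
                   purrr::map(1:5, ~ sample(genes, sample(n - 1, 1))))
      for (sig in subsets) {
        expect_equal(enrichment_score(v, sig), es_oracle(v, sig),
                     tolerance = 1e-12)
        expect_equal(enrichment_score(v, sig, tau = 0.5),
                     es_oracle(v, sig, tau = 0.5), tolerance = 1e-12)
      }
    }
  })
})

test_that("negating a symmetric profile flips the enrichment score", {
  # symmetric values, signature weights symmetric around zero
  v <- rlang::set_names(c(-3, -2, -1, 1, 2, 3), paste0("g", 1:6))
  sig <- c("g1", "g6")   # |values| symmetric within the signature
  expect_equal(enrichment_score(-v, sig), -enrichment_score(v, sig),
               tolerance = 1e-12)
  expect_equal(es_oracle(-v, sig), -es_oracle(v, sig), tolerance = 1e-12)
})

test_that("the score ignores non-signature gene labels and is tie-stable", {
  v <- rlang::set_names(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  base <- enrichment_score(v, c("g1", "g3"))
  relabeled <- rlang::set_names(v, c("g1", "x9", "g3", "x1", "x5"))
  expect_equal(enrichment_score(relabeled, c("g1", "g3")), base)
  # exact ties resolved lexicographically, hence reproducible
  tied <- rlang::set_names(rep(c(2, 1), c(3, 3)), paste0("g", 1:6))
  expect_equal(enrichment_score(tied, c("g2", "g5")),
               enrichment_score(tied, c("g2", "g5")))
  expect_equal(enrichment_score(tied, c("g2", "g5")),
               es_oracle(tied, c("g2", "g5")))
})

test_that("score_signatures crosses every condition with every sample", {
  counts <- make_expr(60, 4, seed = 44, platform = "count")
  processed <- preprocess_counts(counts)
  sigs <- build_signatures(processed, c("a", "a", "b", "b"),
                           pool = min(30, nrow(processed)), size = 10)
  es <- score_signatures(processed, sigs)
  expect_identical(nrow(es), 8L)
  m <- expr_matrix(processed)
  expect_equal(es$es[es$condition == "a" & es$sample_id == "s01"],
               es_oracle(m[, "s01"], sigs$a))
  # a condition's own samples should score higher on its signature
  mean_own <- mean(es$es[(es$condition == "a" & es$sample_id %in%
                            c("s01", "s02")) |
                           (es$condition == "b" & es$sample_id %in%
                              c("s03", "s04"))])
  mean_other <- mean(es$es[(es$condition == "a" & es$sample_id %in%
                              c("s03", "s04")) |
                             (es$condition == "b" & es$sample_id %in%
                                c("s01", "s02"))])
  expect_gt(mean_own, mean_other)
})
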