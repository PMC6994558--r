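# projection scoring, null calibration, significance calls

test_that("reference profiles score 1 with themselves and 0 with others", {
  ref <- simulate_reference(G = 300, K = 5, rho = 0.4, seed = 31)
  basis <- build_reference(ref$matrices)
  scores <- project_onto_basis(basis, as_ztbl(basis$B, n = basis$n)) |>
    tidyr::pivot_wider(names_from = "cell_type", values_from = "score")
  S <- as.matrix(scores[, -1])
  expect_equal(unname(S), diag(5), tolerance = 1e-8)
})

test_that("projection is linear: zero queries and hand-solved coordinates", {
  prof <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                         a = c(1, 0, 1), b = c(0, 1, 1))
  basis <- build_basis(prof)
  zero <- project_onto_basis(basis, as_ztbl(matrix(0, 3, 1,
                                                   dimnames = list(c("g1", "g2", "g3"), "q"))))
  expect_equal(zero$score, c(0, 0))
  # normal equations for q = (0,0,1): Gram [[2,1],[1,2]], B'q = (1,1)
  q <- as_ztbl(matrix(c(0, 0, 1), 3, 1,
                      dimnames = list(c("g1", "g2", "g3"), "q")))
  expect_equal(project_onto_basis(basis, q)$score, c(1 / 3, 1 / 3),
               tolerance = 1e-12)
})

test_that("z-space mixtures are recovered exactly at zero noise", {
  basis <- build_reference(
    simulate_reference(G = 500, K = 6, rho = 0.5, seed = 32)$matrices)
  w <- c(0.7, 0.3, 0, 0, 0, 0)
  sim <- simulate_query_mixture(basis, w, noise_sd = 0, seed = 0)
  got <- project_onto_basis(basis, sim$zspace)
  expect_equal(got$score, w, tolerance = 1e-8)
  # a unit-weight query is the identity contract again
  e3 <- simulate_query_mixture(basis, c(0, 0, 1, 0, 0, 0))
  expect_equal(project_onto_basis(basis, e3$zspace)$score,
               c(0, 0, 1, 0, 0, 0), tolerance = 1e-8)
})

test_that("scores are invariant to a simultaneous gene reordering", {
  withr::with_seed(33, {
    basis <- orthogonal_basis(120, 4)
    q <- matrix(rnorm(120), dimnames = list(basis$gene_ids, "q"))
    s1 <- project_onto_basis(basis, as_ztbl(q))
    perm <- sample.int(120)
    Bp <- basis$B[perm, , drop = FALSE]
    s2 <- project_onto_basis(build_basis(as_ztbl(Bp)),
                             as_ztbl(q[perm, , drop = FALSE]))
    expect_equal(s2$score, s1$score, tolerance = 1e-8)
  })
})

test_that("queries on the wrong gene universe are rejected with counts", {
  basis <- orthogonal_basis(50, 3)
  q <- matrix(rnorm(49), dimnames = list(basis$gene_ids[-1], "q"))
  expect_error(project_onto_basis(basis, as_ztbl(q)), "1 missing")
})

test_that("query normalization enforces basis-gene coverage", {
  ref <- simulate_reference(G = 300, K = 4, rho = 0.2, seed = 34)
  basis <- build_reference(ref$matrices)
  full <- simulate_query_mixture(basis, c(1, 0, 0, 0), seed = 1)$readout
  z <- normalize_query(basis, full)
  expect_identical(z$gene_id, basis$gene_ids)
  expect_equal(sum(z[[2]]^2), length(basis$gene_ids), tolerance = 1e-9)
  # drop 10% of basis genes: below the 95% coverage floor
  cut <- full[-seq_len(ceiling(0.10 * nrow(full))), ]
  expect_error(normalize_query(basis, cut), "covers only")
})

test_that("the null calibration is seeded, centered, and five sigma by default", {
  basis <- orthogonal_basis(200, 4, seed = 2)
  cal <- calibrate_null(basis, R = 2000, seed = 7)
  expect_equal(cal$threshold, 5 * cal$sd)
  expect_identical(cal$seed, 7L)
  # reproducible; different seed, different draw
  expect_equal(calibrate_null(basis, R = 2000, seed = 7)$sd, cal$sd)
  expect_false(isTRUE(all.equal(
    calibrate_null(basis, R = 2000, seed = 8)$sd, cal$sd)))
  # grand mean is zero up to Monte-Carlo error
  expect_lt(abs(cal$mean), 4 * cal$sd / sqrt(cal$R * 4))
  expect_error(calibrate_null(basis, R = 500), "at least 1000")
})

test_that("null means over repeated calibrations are centered at zero", {
  basis <- orthogonal_basis(150, 3, seed = 3)
  means <- vapply(1:20, function(s) calibrate_null(basis, R = 1000,
                                                   seed = s)$mean,
                  numeric(1))
  expect_gt(t.test(means)$p.value, 0.01)
})

test_that("significance calls use strict magnitude comparison", {
  cal <- structure(list(R = 10000L, mean = 0, sd = 0.04, multiplier = 5,
                        threshold = 0.2, seed = 0L),
                   class = "null_calibration")
  expect_identical(classify_significant(c(0.25, -0.25, 0.2, 0.1), cal),
                   c(TRUE, TRUE, FALSE, FALSE))
  scores <- tibble::tibble(sample_id = "s", cell_type = c("a", "b"),
                           score = c(0.21, -0.19))
  expect_identical(classify_significant(scores, cal)$significant,
                   c(TRUE, FALSE))
})
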