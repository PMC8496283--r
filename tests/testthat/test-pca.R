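test_that("Patterson normalization centres and scales by sqrt(p(1-p))", {
  mat <- cbind(c(0L, 0L, 1L, 1L),   # p = 0.5 -> (-1, -1, 1, 1)
               c(0L, 0L, 0L, 0L),   # fixed -> dropped
               c(1L, 1L, 1L, 1L),   # fixed -> dropped
               c(0L, 1L, 1L, 1L))   # p = 0.75
  norm <- patterson_normalize(mat)
  expect_equal(norm$n_dropped, 2)
  expect_equal(ncol(norm$matrix), 2)
  expect_equal(norm$matrix[, 1], c(-1, -1, 1, 1))
  expect_equal(norm$matrix[, 2],
               (c(0, 1, 1, 1) - 0.75) / sqrt(0.75 * 0.25))
  # every surviving column has mean exactly 0
  expect_equal(colMeans(norm$matrix), c(0, 0))
  expect_warning(patterson_normalize(matrix(1L, 3, 2)), "fixed")
})

test_that("principal components match a brute-force eigendecomposition", {
  x <- matrix(c(1.2, -0.4, 0.8, -1.6,
                0.3, 0.9, -1.1, -0.1), 4, 2)
  x <- sweep(x, 2, colMeans(x))
  res <- principal_components(x, k = 2)
  # oracle: dense eigen of the 4x4 row covariance
  ev <- eigen(x %*% t(x) / ncol(x), symmetric = TRUE)
  expect_equal(res$eigenvalues, ev$values[1:2])
  for (j in 1:2) {
    oracle_scores <- ev$vectors[, j] * sqrt(ev$values[j] * ncol(x))
    expect_equal(abs(res$scores[, j]), abs(oracle_scores))
  }
  # orthogonal score columns, non-increasing eigenvalues
  expect_lt(abs(sum(res$scores[, 1] * res$scores[, 2])), 1e-10)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
  # sign convention: largest-magnitude entry of each column is positive
  expect_true(all(apply(res$scores, 2,
                        function(s) s[which.max(abs(s))] > 0)))
  expect_error(principal_components(x, k = 5), "out of range")
})

test_that("eigenvalues of the centred covariance sum to its trace", {
  set.seed(14)
  mat <- rand_seg_matrix(8, 30)
  norm <- patterson_normalize(mat)
  res <- principal_components(norm, k = nrow(mat) - 1)
  cov_mat <- norm$matrix %*% t(norm$matrix) / ncol(norm$matrix)
  # column centring makes the all-ones direction null, so the top n-1
  # eigenvalues carry the whole trace
  expect_equal(sum(res$eigenvalues), sum(diag(cov_mat)))
})

test_that("two fixed-difference populations give rank-1 structure", {
  mat <- rbind(matrix(0L, 5, 6), matrix(1L, 5, 6))
  res <- principal_components(patterson_normalize(mat), k = 2)
  expect_length(unique(round(res$scores[, 1], 9)), 2)
  expect_lt(res$eigenvalues[2], 1e-10)
  # degenerate clusters: separation diverges with a warning
  res$pop <- rep(1:2, each = 5)
  expect_warning(sep <- cluster_separation(res, 1, 2), "spread")
  expect_identical(sep, Inf)
})

test_that("permuting haplotypes permutes their scores identically", {
  set.seed(15)
  mat <- rand_seg_matrix(10, 25)
  perm <- sample(10)
  r1 <- principal_components(patterson_normalize(mat), k = 3)
  r2 <- principal_components(patterson_normalize(mat[perm, ]), k = 3)
  expect_equal(r2$scores, r1$scores[perm, ], tolerance = 1e-8)
})

test_that("pca input pools candidate columns across replicates", {
  reps <- small_three_pop_reps()
  input <- build_pca_input(reps, scheme = "none")
  expect_equal(nrow(input$matrix), 30)  # 10 typing x 3 demes
  expect_equal(ncol(input$matrix),
               sum(vapply(reps, function(r) ncol(r$haplotypes),
                          integer(1))))
  expect_equal(nrow(input$provenance), ncol(input$matrix))
  asc <- build_pca_input(reps, scheme = "single_population",
                         maf_threshold = 0.05)
  # ascertained input only keeps the per-replicate candidate sets
  expect_true(ncol(asc$matrix) < ncol(input$matrix))
  for (r in seq_along(reps)) {
    cfg <- ascertainment_config("single_population", maf_threshold = 0.05)
    expect_equal(asc$provenance$site[asc$provenance$replicate_id ==
                                       reps[[r]]$replicate_id],
                 candidate_sites(reps[[r]], cfg))
  }
  expect_error(
    build_pca_input(list(reps[[1]],
                         simulate_replicate(island_model(2, 0.1),
                                            sampling_design(5, 5),
                                            seed = 1))),
    "sampling design")
})

test_that("cluster separation contrasts centroid distance with spread", {
  scores <- rbind(matrix(rnorm(40, mean = 0, sd = 0.5), 20, 2),
                  matrix(rnorm(40, mean = 10, sd = 0.5), 20, 2))
  res <- structure(list(scores = scores, eigenvalues = c(2, 1),
                        pop = rep(1:2, each = 20), n_sites_used = 2L,
                        n_dropped = 0L, sign_convention = ""),
                   class = "pca_result")
  expect_gt(cluster_separation(res, 1, 2), 5)
  # identical distributions -> small ratio
  set.seed(8)
  same <- res
  same$scores <- matrix(rnorm(80), 40, 2)
  expect_lt(cluster_separation(same, 1, 2), 1.5)
  seps <- pca_separations(res)
  expect_equal(nrow(seps), 1)
  expect_error(cluster_separation(res, 1, 2, pop = c(1, rep(2, 39))),
               ">= 2")
})
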