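test_that("pairwise-difference formulas reproduce hand-computed values", {
  ds <- hand_example_dataset()
  expect_equal(pi_within(ds, 1), 1)
  expect_equal(pi_within(ds, 2), 1)
  expect_equal(pi_between(ds, 1, 2), 1.5)  # distances 2, 1, 1, 2
  expect_equal(fst_hudson(ds, 1, 2), 1 / 3)
  # a population with no internal variation has pi_w = 0
  flat <- ds_from_matrix(rbind(c(0L, 0L), c(0L, 0L), c(1L, 0L), c(0L, 1L)),
                         pop = c(1, 1, 2, 2))
  expect_equal(pi_within(flat, 1), 0)
})

test_that("frequency formulas equal brute-force pair enumeration exactly", {
  set.seed(77)
  for (i in 1:30) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    s <- sample(1:20, 1)
    mat <- rand_seg_matrix(n1 + n2, s)
    ds <- ds_from_matrix(mat, rep(1:2, c(n1, n2)))
    expect_identical(pi_within(ds, 1), brute_pi_within(mat[1:n1, , drop = FALSE]))
    expect_identical(pi_within(ds, 2),
                     brute_pi_within(mat[(n1 + 1):(n1 + n2), , drop = FALSE]))
    expect_identical(pi_between(ds, 1, 2),
                     brute_pi_between(mat[1:n1, , drop = FALSE],
                                      mat[(n1 + 1):(n1 + n2), , drop = FALSE]))
  }
})

test_that("pi is invariant to duplicating every haplotype", {
  set.seed(11)
  mat <- rand_seg_matrix(8, 12)
  ds <- ds_from_matrix(mat, rep(1:2, each = 4))
  doubled <- ds_from_matrix(rbind(mat, mat), rep(rep(1:2, each = 4), 2))
  expect_equal(pi_between(ds, 1, 2), pi_between(doubled, 1, 2))
})

test_that("copied populations show only the self-pair correction", {
  set.seed(12)
  half <- rand_seg_matrix(5, 10)
  ds <- ds_from_matrix(rbind(half, half), rep(1:2, each = 5))
  # pi_b over two copies includes the n zero-distance self pairs that
  # pi_w excludes, so pi_w/pi_b = n/(n-1) exactly and FST = -1/(n-1);
  # the bias vanishes as n grows
  n <- 5
  expect_equal(pi_between(ds, 1, 2) * n / (n - 1), pi_within(ds, 1))
  expect_equal(fst_hudson(ds, 1, 2), -1 / (n - 1))
  # two invariant demes, all variation in a third -> pi_b(1,2) = 0
  mono <- ds_from_matrix(rbind(matrix(0L, 4, 3), rand_seg_matrix(2, 3)),
                         pop = c(1, 1, 2, 2, 3, 3))
  expect_true(is.na(fst_hudson(mono, 1, 2)))
  expect_equal(pi_between(mono, 1, 2), 0)
})

test_that("the 2D-SFS tabulates sites by joint derived counts", {
  # per-pop derived counts: site 1 -> (0, 2), site 2 -> (1, 1)
  ds <- ds_from_matrix(rbind(c(0L, 1L), c(0L, 0L), c(1L, 1L), c(1L, 0L)),
                       pop = c(1, 1, 2, 2))
  sfs <- sfs_2d(ds, 1, 2)
  expect_equal(dim(sfs$counts), c(3L, 3L))
  expect_equal(sfs$counts["0", "2"], 1L)
  expect_equal(sfs$counts["1", "1"], 1L)
  expect_equal(sum(sfs$counts), 2L)
  expect_equal(sfs$n_sites, 2L)
  # swapping the populations transposes the spectrum
  expect_equal(sfs_2d(ds, 2, 1)$counts, t(sfs$counts))
  expect_error(sfs_2d(ds, 1, 9), "present")
})

test_that("2D-SFS margins equal the per-population 1D spectra", {
  set.seed(21)
  mat <- rand_seg_matrix(12, 40)
  ds <- ds_from_matrix(mat, rep(1:2, each = 6))
  sfs <- sfs_2d(ds, 1, 2)
  d1 <- colSums(mat[1:6, ])
  d2 <- colSums(mat[7:12, ])
  expect_equal(rowSums(sfs$counts),
               as.numeric(table(factor(d1, levels = 0:6))),
               ignore_attr = TRUE)
  expect_equal(colSums(sfs$counts),
               as.numeric(table(factor(d2, levels = 0:6))),
               ignore_attr = TRUE)
  tl <- tidy(sfs)
  expect_equal(sum(tl$n_sites), sfs$n_sites)
})

test_that("typing data restricts to typing haplotypes at sorted markers", {
  reps <- small_three_pop_reps()
  ds <- reps[[1]]
  cfg <- ascertainment_config("merged_panel", maf_threshold = 0,
                              n_markers = 5, seed = 2)
  sel <- select_markers(candidate_sites(ds, cfg), cfg)
  td <- make_typing_data(ds, sel)
  expect_equal(dim(td$haplotypes), c(30L, 5L))  # 10 typing x 3 demes
  expect_equal(td$marker_sites, sort(sel$selected_markers))
  expect_false(is.unsorted(td$marker_sites))
  expect_equal(as.vector(table(td$pop)), c(10L, 10L, 10L))
  # pairwise_stats agrees with the individual statistics
  ps <- pairwise_stats(td)
  expect_equal(nrow(ps), 3)
  expect_equal(ps$fst[ps$pop_a == 1 & ps$pop_b == 2],
               fst_hudson(td, 1, 2))
  expect_equal(ps$pi_w_a[1], pi_within(td, 1))
})

test_that("markers monomorphic among typing haplotypes are retained", {
  # site 2 is carried only by discovery haplotypes: typing column all-zero
  mat <- rbind(c(1L, 1L), c(0L, 1L), c(0L, 0L), c(0L, 0L),
               c(1L, 0L), c(0L, 0L), c(1L, 0L), c(0L, 0L))
  ds <- ds_from_matrix(mat, pop = rep(1:2, each = 4),
                       role = rep(c("discovery", "discovery",
                                    "typing", "typing"), 2))
  sel <- random_marker_baseline(ds, n_markers = 2, seed = 1)
  td <- make_typing_data(ds, sel)
  expect_equal(ncol(td$haplotypes), 2)
  expect_true(all(td$haplotypes[, 2] == 0))
  expect_error(make_typing_data(ds, random_marker_baseline(ds, 10)),
               "excluded")
})

test_that("an excluded replicate refuses to produce typing data", {
  ds <- ds_from_matrix(rand_seg_matrix(8, 3), rep(1:2, each = 4))
  sel <- random_marker_baseline(ds, n_markers = 50)
  expect_true(sel$excluded)
  expect_error(make_typing_data(ds, sel), "replicate 0.*excluded|excluded")
})

test_that("reused discovery panels sharply truncate the typing spectrum", {
  reuse <- sampling_design(30, 30, reuse_discovery_as_typing = TRUE)
  ds <- simulate_replicate(island_model(2, 0.1), reuse, seed = 55)
  thr <- 0.1
  cfg <- ascertainment_config("single_population", maf_threshold = thr,
                              n_markers = 10, seed = 4)
  sel <- select_markers(candidate_sites(ds, cfg), cfg)
  td <- make_typing_data(ds, sel)
  # typing sample == discovery panel, so every marker's MAF in the
  # ascertained population stays at or above the threshold: no mass at
  # the truncated frequencies on either end of the spectrum
  d <- colSums(td$haplotypes[td$pop == 1, , drop = FALSE])
  n <- sum(td$pop == 1)
  expect_true(all(minor_allele_frequency(d, n) >= thr))
  sfs <- sfs_2d(td, 1, 2)
  below <- minor_allele_frequency(0:n, n) < thr
  expect_true(all(rowSums(sfs$counts)[below] == 0))
})

test_that("FST between two halves of a panmictic sample is near zero", {
  reps <- simulate_replicates(panmictic_model(), 100,
                              sampling_design(10, 10), seed = 71)
  fsts <- vapply(reps, function(ds) {
    halves <- haplotype_dataset(ds$haplotypes, ds$positions,
                                pop = rep(1:2, each = 10),
                                role = ds$role)
    fst_hudson(halves, 1, 2)
  }, numeric(1))
  se <- sd(fsts) / sqrt(length(fsts))
  expect_lt(abs(mean(fsts)), 3 * se + 0.01)
})
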