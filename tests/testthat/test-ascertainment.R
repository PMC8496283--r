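test_that("minor allele frequency folds the derived-allele frequency", {
  expect_equal(minor_allele_frequency(4, 100), 0.04)
  expect_equal(minor_allele_frequency(97, 100), 0.03)
  expect_equal(minor_allele_frequency(50, 100), 0.50)
  expect_equal(minor_allele_frequency(0, 100), 0)
  expect_equal(minor_allele_frequency(c(4, 97), 100), c(0.04, 0.03))
  expect_error(minor_allele_frequency(101, 100), "derived_count")
  expect_error(minor_allele_frequency(1, 0), "n_haplotypes")
})

test_that("single-population discovery filters on the panel's MAF only", {
  # panel MAFs in pop 1: 0.0, 0.04, 0.10, 0.50 (sites 1-4);
  # pop 2 keeps every site segregating overall
  ds <- panel_fixture(rbind(c(0L, 2L, 5L, 25L),
                            c(10L, 10L, 10L, 10L)), n = 50)
  cand <- function(thr, ...) {
    candidate_sites(ds, ascertainment_config("single_population",
                                             maf_threshold = thr, ...))
  }
  expect_equal(cand(0.05), c(3L, 4L))
  # ties are kept by default ("lower than" eliminates), dropped when strict
  expect_equal(cand(0.04), 2:4)
  expect_equal(candidate_sites(ds, ascertainment_config(
    "single_population", maf_threshold = 0.04, strict = TRUE)), c(3L, 4L))
  # threshold 0 disables the frequency filter but still requires the
  # site to segregate in the panel
  expect_equal(cand(0), 2:4)
  # panel from the other population sees different frequencies
  expect_equal(candidate_sites(ds, ascertainment_config(
    "single_population", discovery_population = 2L,
    maf_threshold = 0.15)), 1:4)
})

test_that("merged panel pools frequencies across populations", {
  # derived counts (0, 10) of (100, 100): pooled 10/200 = 0.05
  ds <- panel_fixture(rbind(c(0L), c(10L)), n = 100)
  merged <- ascertainment_config("merged_panel", maf_threshold = 0.04)
  expect_equal(candidate_sites(ds, merged), 1L)
  # the same site is invisible to pop 1's own panel
  single <- ascertainment_config("single_population", maf_threshold = 0)
  expect_equal(candidate_sites(ds, single), integer(0))
  # pooled MAF below threshold -> eliminated
  strict_thr <- ascertainment_config("merged_panel", maf_threshold = 0.06)
  expect_equal(candidate_sites(ds, strict_thr), integer(0))
})

test_that("independent panels eliminate sites rare in any population", {
  # per-panel MAFs (0.10, 0.20, 0.00): monomorphic in pop 3 -> eliminated
  ds <- panel_fixture(rbind(c(10L), c(20L), c(0L)), n = 100)
  cfg <- ascertainment_config("independent_panel", maf_threshold = 0.05)
  expect_equal(candidate_sites(ds, cfg), integer(0))
  # (0.10, 0.20, 0.06): passes everywhere
  ds2 <- panel_fixture(rbind(c(10L), c(20L), c(6L)), n = 100)
  expect_equal(candidate_sites(ds2, cfg), 1L)
  # (0.10, 0.20, 0.04): rare in pop 3 -> eliminated
  ds3 <- panel_fixture(rbind(c(10L), c(20L), c(4L)), n = 100)
  expect_equal(candidate_sites(ds3, cfg), integer(0))
})

test_that("candidate sets nest across thresholds and schemes", {
  set.seed(31)
  for (i in 1:20) {
    n <- 8
    mat <- rand_seg_matrix(3 * n, 15)
    ds <- ds_from_matrix(mat, rep(1:3, each = n),
                         role = rep("discovery", 3 * n))
    thresholds <- sort(runif(3, 0, 0.4))
    for (scheme in c("single_population", "merged_panel",
                     "independent_panel")) {
      sets <- lapply(thresholds, function(t) {
        candidate_sites(ds, ascertainment_config(scheme,
                                                 maf_threshold = t))
      })
      # monotone in threshold: higher cutoff keeps a subset
      expect_true(all(sets[[3]] %in% sets[[2]]))
      expect_true(all(sets[[2]] %in% sets[[1]]))
    }
    t0 <- thresholds[2]
    indep <- candidate_sites(ds, ascertainment_config(
      "independent_panel", maf_threshold = t0))
    merged <- candidate_sites(ds, ascertainment_config(
      "merged_panel", maf_threshold = t0))
    expect_true(all(indep %in% merged))
    for (p in 1:3) {
      single <- candidate_sites(ds, ascertainment_config(
        "single_population", discovery_population = p,
        maf_threshold = t0))
      expect_true(all(indep %in% single))
    }
  }
})

test_that("with one deme at threshold 0, single and merged panels agree", {
  ds <- ds_from_matrix(rand_seg_matrix(12, 10), rep(1, 12),
                       role = rep("discovery", 12))
  s <- candidate_sites(ds, ascertainment_config("single_population",
                                                maf_threshold = 0))
  m <- candidate_sites(ds, ascertainment_config("merged_panel",
                                                maf_threshold = 0))
  expect_identical(s, m)
})

test_that("marker selection samples exactly n_markers or excludes", {
  cfg <- ascertainment_config("merged_panel", n_markers = 50, seed = 7)
  sel <- select_markers(1:60, cfg)
  expect_false(sel$excluded)
  expect_length(sel$selected_markers, 50)
  expect_true(all(sel$selected_markers %in% 1:60))
  expect_false(is.unsorted(sel$selected_markers))
  expect_identical(select_markers(1:60, cfg)$selected_markers,
                   sel$selected_markers)
  # fewer candidates than markers -> exclusion state, not an error
  excl <- select_markers(1:49, cfg)
  expect_true(excl$excluded)
  expect_length(excl$selected_markers, 0)
  # exactly n_markers -> forced selection regardless of seed
  forced <- select_markers(1:50, cfg)
  expect_equal(forced$selected_markers, 1:50)
})

test_that("the random baseline draws from all segregating sites", {
  set.seed(5)
  ds <- ds_from_matrix(rand_seg_matrix(10, 140), rep(1:2, each = 5))
  sel <- random_marker_baseline(ds, n_markers = 50, seed = 3)
  expect_length(sel$selected_markers, 50)
  expect_length(sel$candidate_sites, 140)
  small <- ds_from_matrix(rand_seg_matrix(10, 30), rep(1:2, each = 5))
  expect_true(random_marker_baseline(small, 50)$excluded)
})
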