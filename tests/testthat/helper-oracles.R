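# Brute-force oracles and small-fixture builders shared across test files.

# Mean Hamming distance over all within-group haplotype pairs.
brute_pi_within <- function(mat) {
  n <- nrow(mat)
  pairs <- combn(n, 2)
  mean(vapply(seq_len(ncol(pairs)), function(k) {
    sum(mat[pairs[1, k], ] != mat[pairs[2, k], ])
  }, numeric(1)))
}

# Mean Hamming distance over all cross-group haplotype pairs.
brute_pi_between <- function(a, b) {
  mean(vapply(seq_len(nrow(a)), function(i) {
    vapply(seq_len(nrow(b)), function(j) {
      sum(a[i, ] != b[j, ])
    }, numeric(1))
  }, numeric(nrow(b))))
}

# Random 0/1 matrix with every column segregating.
rand_seg_matrix <- function(n, s) {
  mat <- matrix(rbinom(n * s, 1, runif(1, 0.2, 0.8)), n, s)
  for (j in seq_len(s)) {
    cs <- sum(mat[, j])
    if (cs == 0) mat[sample.int(n, 1), j] <- 1L
    if (cs == n) mat[sample.int(n, 1), j] <- 0L
  }
  mat
}

# Wrap a plain matrix as a haplotype_dataset with evenly spaced positions.
ds_from_matrix <- function(mat, pop, role = rep("typing", nrow(mat)), ...) {
  haplotype_dataset(mat, positions = seq(0.01, 0.98,
                                         length.out = max(1, ncol(mat))),
                    pop = pop, role = role, ...)
}

# The worked two-population example: pi_w = 1 in each deme, pi_b = 1.5,
# Hudson FST = 1/3.
hand_example_dataset <- function() {
  ds_from_matrix(rbind(c(0L, 0L), c(0L, 1L), c(1L, 1L), c(1L, 0L)),
                 pop = c(1, 1, 2, 2))
}

# Build a dataset whose per-population discovery panels have exact derived
# counts: `counts` is a pops x sites matrix, `n` the panel size per pop.
panel_fixture <- function(counts, n) {
  pops <- nrow(counts)
  mat <- do.call(rbind, lapply(seq_len(pops), function(p) {
    sapply(seq_len(ncol(counts)), function(j) {
      rep(c(1L, 0L), c(counts[p, j], n - counts[p, j]))
    })
  }))
  ds_from_matrix(matrix(mat, nrow = pops * n), rep(seq_len(pops), each = n),
                 role = rep("discovery", pops * n))
}
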