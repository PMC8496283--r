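# Resolve any supported data object to (matrix, pop) for statistics.
# For a haplotype_dataset, `role = "typing"` restricts to the typing
# sample (the re-sequencing baseline view); NULL uses all haplotypes.
stat_view <- function(data, role = NULL, sites = NULL) {
  if (inherits(data, "typing_data")) {
    mat <- data$haplotypes
    pop <- data$pop
  } else if (inherits(data, "haplotype_dataset")) {
    idx <- if (is.null(role)) seq_len(nrow(data$haplotypes))
           else if (role == "typing") typing_rows(data)
           else discovery_rows(data)
    mat <- data$haplotypes[idx, , drop = FALSE]
    pop <- data$pop[idx]
  } else {
    abort("`data` must be a haplotype_dataset or typing_data.")
  }
  if (!is.null(sites)) mat <- mat[, sites, drop = FALSE]
  list(mat = mat, pop = pop)
}

pi_within_counts <- function(d, n) {
  if (n < 2) abort("pi_within needs >= 2 haplotypes.")
  sum(d * (n - d)) / choose(n, 2)
}

pi_between_counts <- function(dA, nA, dB, nB) {
  if (nA < 1 || nB < 1) abort("pi_between needs non-empty populations.")
  sum(dA * (nB - dB) + dB * (nA - dA)) / (nA * nB)
}

#' Mean pairwise differences within a population
#'
#' The average number of sites at which two haplotypes drawn from the same
#' population differ, summed over the site set (a per-site-set total, not
#' per bp). Computed from derived-allele counts,
#' `sum(d * (n - d)) / choose(n, 2)`, which equals the mean Hamming
#' distance over all within-population haplotype pairs.
#'
#' @param data A [haplotype_dataset()] or `typing_data`.
#' @param pop 1-based population index.
#' @param sites Optional site (column) subset.
#' @param role For a `haplotype_dataset`: `NULL` (all haplotypes) or
#'   `"typing"`/`"discovery"` to restrict to one role.
#' @return A single non-negative number.
#' @export
pi_within <- function(data, pop, sites = NULL, role = NULL) {
  v <- stat_view(data, role, sites)
  rows <- v$pop == pop
  pi_within_counts(colSums(v$mat[rows, , drop = FALSE]), sum(rows))
}

#' Mean pairwise differences between two populations
#'
#' The average number of sites at which a haplotype from `popA` differs
#' from one of `popB`:
#' `sum(dA * (nB - dB) + dB * (nA - dA)) / (nA * nB)`.
#'
#' @inheritParams pi_within
#' @param popA,popB 1-based population indices.
#' @return A single non-negative number.
#' @export
pi_between <- function(data, popA, popB, sites = NULL, role = NULL) {
  v <- stat_view(data, role, sites)
  a <- v$pop == popA
  b <- v$pop == popB
  pi_between_counts(colSums(v$mat[a, , drop = FALSE]), sum(a),
                    colSums(v$mat[b, , drop = FALSE]), sum(b))
}

#' Hudson-style FST from pairwise differences
#'
#' `FST = 1 - pi_w / pi_b`, where `pi_w` is the unweighted mean of the two
#' within-population pairwise-difference values and `pi_b` the
#' between-population value. Returns `NA` (undefined) when `pi_b = 0`;
#' such replicates are dropped from aggregation with a logged count.
#'
#' @inheritParams pi_between
#' @return A single number `<= 1`, or `NA` when undefined.
#' @export
#' @examples
#' ds <- haplotype_dataset(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)),
#'                         c(0.1, 0.5), pop = c(1, 1, 2, 2),
#'                         role = rep("typing", 4))
#' fst_hudson(ds, 1, 2)  # 1 - 1/1.5 = 1/3
fst_hudson <- function(data, popA, popB, sites = NULL, role = NULL) {
  pw <- (pi_within(data, popA, sites, role) +
         pi_within(data, popB, sites, role)) / 2
  pb <- pi_between(data, popA, popB, sites, role)
  if (pb == 0) return(NA_real_)
  1 - pw / pb
}

#' Joint (2D) site frequency spectrum
#'
#' Tabulates sites by derived-allele count in two populations: cell
#' `(i, j)` (0-based counts) holds the number of sites with `i` derived
#' copies in `popA` and `j` in `popB`. All columns of the object are
#' tabulated, so cell totals equal the number of marker sites (typing
#' data) or segregating sites (re-sequencing data); corner cells `(0, 0)`
#' and `(nA, nB)` can be occupied when a site is monomorphic within the
#' pair.
#'
#' @inheritParams pi_between
#' @return An object of class `sfs_2d`: list with `counts`
#'   (`(nA+1) x (nB+1)` matrix, dimnames = derived counts), `pop_pair`,
#'   `n_sites`, `n_haplotypes`.
#' @export
sfs_2d <- function(data, popA, popB, role = NULL) {
  v <- stat_view(data, role)
  if (!all(c(popA, popB) %in% v$pop)) {
    abort("both populations must be present in the data.")
  }
  a <- v$pop == popA
  b <- v$pop == popB
  dA <- colSums(v$mat[a, , drop = FALSE])
  dB <- colSums(v$mat[b, , drop = FALSE])
  nA <- sum(a)
  nB <- sum(b)
  counts <- table(factor(dA, levels = 0:nA), factor(dB, levels = 0:nB))
  counts <- matrix(as.integer(counts), nA + 1, nB + 1,
                   dimnames = list(0:nA, 0:nB))
  structure(list(counts = counts, pop_pair = c(popA, popB),
                 n_sites = length(dA), n_haplotypes = c(nA, nB)),
            class = "sfs_2d")
}

#' @export
print.sfs_2d <- function(x, ...) {
  cat(sprintf("<sfs_2d> populations (%d, %d), %d sites, %d x %d haplotypes\n",
              x$pop_pair[1], x$pop_pair[2], x$n_sites,
              x$n_haplotypes[1], x$n_haplotypes[2]))
  invisible(x)
}

#' Tidy a 2D-SFS into a long tibble
#'
#' @param x An `sfs_2d` object.
#' @param ... Unused.
#' @return A tibble with columns `count_a`, `count_b`, `freq_a`, `freq_b`,
#'   `n_sites`.
#' @export
tidy.sfs_2d <- function(x, ...) {
  grid <- expand.grid(count_a = 0:x$n_haplotypes[1],
                      count_b = 0:x$n_haplotypes[2])
  tibble(count_a = grid$count_a, count_b = grid$count_b,
         freq_a = grid$count_a / x$n_haplotypes[1],
         freq_b = grid$count_b / x$n_haplotypes[2],
         n_sites = as.vector(x$counts))
}

#' Within/between diversity and FST for every population pair
#'
#' One-stop summary of a site set: per-pair within-population diversity,
#' between-population diversity and Hudson-style FST.
#'
#' @inheritParams pi_within
#' @return A tibble with one row per unordered population pair: `pop_a`,
#'   `pop_b`, `pi_w_a`, `pi_w_b`, `pi_w` (their mean), `pi_b`, `fst`
#'   (`NA` when `pi_b = 0`), `n_sites`.
#' @export
pairwise_stats <- function(data, sites = NULL, role = NULL) {
  v <- stat_view(data, role, sites)
  pops <- sort(unique(v$pop))
  if (length(pops) < 2) abort("need at least two populations.")
  per_pop <- lapply(pops, function(p) {
    rows <- v$pop == p
    list(d = colSums(v$mat[rows, , drop = FALSE]), n = sum(rows))
  })
  names(per_pop) <- pops
  pairs <- combn(pops, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    pa <- as.character(pairs[1, k])
    pb <- as.character(pairs[2, k])
    a <- per_pop[[pa]]
    b <- per_pop[[pb]]
    pwa <- pi_within_counts(a$d, a$n)
    pwb <- pi_within_counts(b$d, b$n)
    pib <- pi_between_counts(a$d, a$n, b$d, b$n)
    tibble(pop_a = pairs[1, k], pop_b = pairs[2, k],
           pi_w_a = pwa, pi_w_b = pwb, pi_w = (pwa + pwb) / 2,
           pi_b = pib,
           fst = if (pib == 0) NA_real_ else 1 - (pwa + pwb) / 2 / pib,
           n_sites = ncol(v$mat))
  })
}
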