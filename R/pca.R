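#' Pool typing genotypes across replicates for PCA
#'
#' Builds the multi-locus genotype matrix on which population structure is
#' inferred: per replicate, the candidate sites of the chosen scheme at
#' the given MAF threshold (all candidates — no marker subsampling), or
#' all segregating sites for the `"none"` (no-ascertainment) control;
#' typing-role haplotypes only; columns concatenated across replicates.
#' Replicates contributing zero candidate sites are skipped and counted.
#'
#' @param replicates List of [haplotype_dataset()]s sharing one sampling
#'   design.
#' @param scheme `"none"` or an ascertainment scheme name (see
#'   [ascertainment_config()]).
#' @param maf_threshold Panel MAF cutoff (default 0.05, the conventional
#'   array-design filter).
#' @param discovery_population Panel population for `single_population`.
#' @return An object of class `pca_input`: list with `matrix`
#'   (haplotypes x pooled sites), `pop`, `provenance` (tibble of
#'   `replicate_id`, `site`), `scheme`, `n_excluded`.
#' @export
build_pca_input <- function(replicates, scheme = "none",
                            maf_threshold = 0.05,
                            discovery_population = 1L) {
  stopifnot(length(replicates) >= 1)
  first <- replicates[[1]]
  rows0 <- typing_rows(first)
  pop <- first$pop[rows0]
  blocks <- list()
  prov <- list()
  n_excluded <- 0L
  for (ds in replicates) {
    rows <- typing_rows(ds)
    if (length(rows) != length(rows0) ||
        !identical(ds$pop[rows], pop)) {
      abort("all replicates must share the same sampling design.")
    }
    sites <- if (identical(scheme, "none")) {
      seq_len(ncol(ds$haplotypes))
    } else {
      cfg <- ascertainment_config(scheme, discovery_population,
                                  maf_threshold)
      candidate_sites(ds, cfg)
    }
    if (!length(sites)) {
      n_excluded <- n_excluded + 1L
      next
    }
    blocks[[length(blocks) + 1]] <- ds$haplotypes[rows, sites, drop = FALSE]
    prov[[length(prov) + 1]] <- tibble(replicate_id = ds$replicate_id,
                                       site = sites)
  }
  if (!length(blocks)) {
    warn("no replicate contributed any site; PCA input is empty.")
    mat <- matrix(integer(), nrow = length(rows0), ncol = 0)
    provenance <- tibble(replicate_id = integer(), site = integer())
  } else {
    mat <- do.call(cbind, blocks)
    provenance <- dplyr::bind_rows(prov)
  }
  structure(list(matrix = mat, pop = pop, provenance = provenance,
                 scheme = scheme, n_excluded = n_excluded),
            class = "pca_input")
}

#' @export
print.pca_input <- function(x, ...) {
  cat(sprintf("<pca_input: %s> %d haplotypes x %d sites (%d empty replicate(s))\n",
              x$scheme, nrow(x$matrix), ncol(x$matrix), x$n_excluded))
  invisible(x)
}

#' EIGENSTRAT-style normalization of a genotype matrix
#'
#' Per column: with `p` the allele frequency among the rows (haploid 0/1
#' genotypes), entries become `(g - p) / sqrt(p * (1 - p))` — centred and
#' scaled by the binomial standard deviation, so each site contributes
#' variance proportional to drift rather than to its frequency. Columns
#' fixed among the rows (`p` 0 or 1) carry no information and are
#' dropped, with the count reported: ascertained markers can be
#' monomorphic in the typing sample. Haplotypes are the analysis units,
#' so no diploid factor-of-2 rescaling is applied.
#'
#' @param input A `pca_input` or a plain 0/1 matrix.
#' @return List with `matrix` (normalized, possibly fewer columns),
#'   `pop` (when available), `n_dropped`.
#' @export
patterson_normalize <- function(input) {
  mat <- if (inherits(input, "pca_input")) input$matrix else input
  if (!nrow(mat)) abort("need at least 2 rows.")
  p <- colMeans(mat)
  keep <- p > 0 & p < 1
  n_dropped <- sum(!keep)
  mat <- mat[, keep, drop = FALSE]
  p <- p[keep]
  if (!ncol(mat)) {
    warn("all columns are fixed; normalized matrix is empty.")
    norm <- matrix(numeric(), nrow = nrow(mat), ncol = 0)
  } else {
    norm <- sweep(sweep(mat, 2, p, "-"), 2, sqrt(p * (1 - p)), "/")
  }
  list(matrix = norm,
       pop = if (inherits(input, "pca_input")) input$pop else NULL,
       n_dropped = n_dropped)
}

#' Principal components of a normalized genotype matrix
#'
#' Eigendecomposition of the sample-by-sample covariance
#' `X %*% t(X) / m` of the normalized matrix `X` (`m` sites). Scores are
#' the projections of haplotypes onto the top-`k` axes (eigenvector times
#' the singular value), so inter-sample distances in score space reflect
#' the covariance structure. Component signs are fixed deterministically
#' by making each score column's largest-magnitude entry positive.
#'
#' @param x Output of [patterson_normalize()], a `pca_input` (normalized
#'   on the fly) or a plain numeric matrix.
#' @param k Number of components, `<= min(rows - 1, columns)`.
#' @return An object of class `pca_result`: list with `scores`
#'   (haplotypes x k), `eigenvalues` (top k of the covariance), `pop`,
#'   `n_sites_used`, `n_dropped`, `sign_convention`.
#' @export
principal_components <- function(x, k = 10) {
  if (inherits(x, "pca_input")) x <- patterson_normalize(x)
  if (is.list(x)) {
    mat <- x$matrix
    pop <- x$pop
    n_dropped <- x$n_dropped %||% 0L
  } else {
    mat <- x
    pop <- NULL
    n_dropped <- 0L
  }
  n <- nrow(mat)
  m <- ncol(mat)
  if (k > min(n - 1, m)) {
    abort(sprintf("`k` = %d out of range (max %d).", k, min(n - 1, m)))
  }
  cov_mat <- tcrossprod(mat) / m
  eig <- eigen(cov_mat, symmetric = TRUE)
  vals <- pmax(eig$values[seq_len(k)], 0)
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals * m), k, k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(scores[, j]))
    if (scores[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  structure(list(scores = scores, eigenvalues = vals, pop = pop,
                 n_sites_used = m, n_dropped = n_dropped,
                 sign_convention = "largest-magnitude score positive"),
            class = "pca_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d haplotypes, %d components, %d sites\n",
              nrow(x$scores), ncol(x$scores), x$n_sites_used))
  cat("eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Tidy PCA scores into a tibble
#'
#' @param x A `pca_result`.
#' @param ... Unused.
#' @return Tibble with `haplotype`, `pop` (if known) and one `PCi` column
#'   per component.
#' @export
tidy.pca_result <- function(x, ...) {
  scores <- as.data.frame(x$scores)
  names(scores) <- paste0("PC", seq_len(ncol(scores)))
  out <- tibble(haplotype = seq_len(nrow(scores)))
  if (!is.null(x$pop)) out$pop <- factor(x$pop)
  dplyr::bind_cols(out, scores)
}

#' @export
glance.pca_result <- function(x, ...) {
  tibble(n_haplotypes = nrow(x$scores), n_components = ncol(x$scores),
         n_sites_used = x$n_sites_used, n_dropped = x$n_dropped,
         var_pc1 = x$eigenvalues[1] / sum(x$eigenvalues) *
           (sum(x$eigenvalues) > 0))
}

#' Centroid separation between two populations in PC space
#'
#' Distance between the two populations' centroids in the first `k_dims`
#' components, divided by the mean within-population root-mean-square
#' spread in those components. Ratios well above 1 mean the populations
#' form distinct clusters; ratios near or below 1 mean they overlap. When
#' both spreads are zero (two point clusters) the ratio diverges and
#' `Inf` is returned with a warning.
#'
#' @param result A `pca_result` with population labels (or supply
#'   `pop`).
#' @param popA,popB Population indices.
#' @param k_dims Number of leading components to use (default 2).
#' @param pop Optional label vector overriding `result$pop`.
#' @return A single non-negative number (possibly `Inf`).
#' @export
cluster_separation <- function(result, popA, popB, k_dims = 2, pop = NULL) {
  stopifnot(inherits(result, "pca_result"))
  labels <- pop %||% result$pop
  if (is.null(labels)) abort("no population labels available.")
  sc <- result$scores[, seq_len(k_dims), drop = FALSE]
  a <- sc[labels == popA, , drop = FALSE]
  b <- sc[labels == popB, , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) {
    abort("each population needs >= 2 members.")
  }
  ca <- colMeans(a)
  cb <- colMeans(b)
  dist_ab <- sqrt(sum((ca - cb)^2))
  rms <- function(m, centre) {
    sqrt(mean(rowSums(sweep(m, 2, centre, "-")^2)))
  }
  spread <- (rms(a, ca) + rms(b, cb)) / 2
  if (spread <= dist_ab * 1e-6) {
    if (dist_ab == 0) return(0)
    warn("near-zero within-population spread; separation is infinite.")
    return(Inf)
  }
  dist_ab / spread
}

#' All pairwise cluster separations of a PCA result
#'
#' @param result A `pca_result` with population labels.
#' @param k_dims Leading components to use.
#' @return Tibble with `pop_a`, `pop_b`, `separation`.
#' @export
pca_separations <- function(result, k_dims = 2) {
  pops <- sort(unique(result$pop))
  pairs <- combn(pops, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    tibble(pop_a = pairs[1, i], pop_b = pairs[2, i],
           separation = cluster_separation(result, pairs[1, i],
                                           pairs[2, i], k_dims))
  })
}
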