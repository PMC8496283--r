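#' One replicate of simulated haplotypes
#'
#' Container for a single coalescent replicate: a binary haplotype matrix
#' (rows = haplotypes, columns = segregating sites; 0 = ancestral,
#' 1 = derived under the infinite-sites convention), relative site
#' positions in `[0, 1)`, and per-haplotype population and role labels.
#' The full pre-ascertainment matrix is the "re-sequencing" view of the
#' replicate, the unbiased baseline every typing result is compared with.
#'
#' @param haplotypes Integer matrix of 0/1 values, haplotypes x sites.
#' @param positions Numeric vector of strictly increasing positions in
#'   `[0, 1)`, one per site.
#' @param pop Integer vector of 1-based population indices, one per
#'   haplotype.
#' @param role Character vector, `"discovery"` or `"typing"`, one per
#'   haplotype.
#' @param replicate_id Integer replicate index (0-based, following ms
#'   block order).
#' @param seed RNG seed that produced this replicate, or `NA`.
#' @param length Region length in bp (used for VCF export positions).
#' @param reuse_discovery_as_typing If `TRUE`, the discovery haplotypes
#'   double as the typing sample ([typing_rows()] then returns them).
#' @return An object of class `haplotype_dataset`.
#' @export
haplotype_dataset <- function(haplotypes, positions, pop, role,
                              replicate_id = 0L, seed = NA_integer_,
                              length = 50000L,
                              reuse_discovery_as_typing = FALSE) {
  x <- structure(list(haplotypes = haplotypes,
                      positions = as.numeric(positions),
                      pop = as.integer(pop),
                      role = as.character(role),
                      replicate_id = as.integer(replicate_id),
                      seed = seed,
                      length = as.integer(length),
                      reuse_discovery_as_typing =
                        isTRUE(reuse_discovery_as_typing)),
                 class = "haplotype_dataset")
  validate_haplotype_dataset(x)
}

validate_haplotype_dataset <- function(x) {
  h <- x$haplotypes
  if (!is.matrix(h)) abort("`haplotypes` must be a matrix.")
  if (length(h) && !all(h %in% c(0L, 1L))) {
    abort("haplotype entries must all be 0 or 1.")
  }
  if (length(x$positions) != ncol(h)) {
    abort("`positions` must have one entry per site.")
  }
  if (ncol(h) > 1 && any(diff(x$positions) <= 0)) {
    abort("`positions` must be strictly increasing.")
  }
  if (length(x$positions) && (any(x$positions < 0) || any(x$positions >= 1))) {
    abort("`positions` must lie in [0, 1).")
  }
  if (length(x$pop) != nrow(h) || length(x$role) != nrow(h)) {
    abort("`pop` and `role` must have one entry per haplotype.")
  }
  if (length(x$role) && !all(x$role %in% c("discovery", "typing"))) {
    abort("roles must be 'discovery' or 'typing'.")
  }
  if (ncol(h)) {
    cs <- colSums(h)
    if (any(cs == 0 | cs == nrow(h))) {
      abort("every site must be segregating in the full sample.")
    }
  }
  x
}

#' @export
print.haplotype_dataset <- function(x, ...) {
  cat(sprintf(
    "<haplotype_dataset> replicate %d: %d haplotypes x %d segregating sites\n",
    x$replicate_id, nrow(x$haplotypes), ncol(x$haplotypes)))
  tab <- table(pop = x$pop, role = x$role)
  print(tab)
  if (x$reuse_discovery_as_typing) {
    cat("discovery haplotypes are reused as the typing sample\n")
  }
  invisible(x)
}

#' @export
n_pops.haplotype_dataset <- function(x) {
  if (length(x$pop)) max(x$pop) else 0L
}

#' Row indices of discovery / typing haplotypes
#'
#' `typing_rows()` honours the `reuse_discovery_as_typing` flag: when set,
#' the discovery haplotypes are the typing sample.
#'
#' @param x A `haplotype_dataset`.
#' @param pop Optional population index to restrict to.
#' @return Integer vector of row indices.
#' @export
typing_rows <- function(x, pop = NULL) {
  role <- if (x$reuse_discovery_as_typing) "discovery" else "typing"
  idx <- which(x$role == role)
  if (!is.null(pop)) idx <- idx[x$pop[idx] == pop]
  idx
}

#' @rdname typing_rows
#' @export
discovery_rows <- function(x, pop = NULL) {
  idx <- which(x$role == "discovery")
  if (!is.null(pop)) idx <- idx[x$pop[idx] == pop]
  idx
}

#' Genotypes of selected markers in the typing sample
#'
#' Restricts a replicate to its typing-role haplotypes at the selected
#' marker sites, emulating the genotyping step of an array: marker state is
#' determined in every typing haplotype, and markers that turn out
#' monomorphic among the typing haplotypes are retained as constant
#' columns (there is no post-typing filtering).
#'
#' @param dataset A [haplotype_dataset()].
#' @param selection A `marker_selection` from [select_markers()] or
#'   [random_marker_baseline()].
#' @return An object of class `typing_data`: list with elements
#'   `haplotypes` (typing haplotypes x markers), `pop`, `marker_sites`
#'   (original site indices, ascending), `replicate_id`, `length`,
#'   `positions`.
#' @export
make_typing_data <- function(dataset, selection) {
  stopifnot(inherits(dataset, "haplotype_dataset"),
            inherits(selection, "marker_selection"))
  if (selection$excluded) {
    abort(sprintf(
      "replicate %d was excluded (%d candidate site(s) < %d markers).",
      dataset$replicate_id, length(selection$candidate_sites),
      selection$n_markers))
  }
  sites <- sort(selection$selected_markers)
  rows <- typing_rows(dataset)
  structure(list(haplotypes = dataset$haplotypes[rows, sites, drop = FALSE],
                 pop = dataset$pop[rows],
                 marker_sites = sites,
                 positions = dataset$positions[sites],
                 replicate_id = dataset$replicate_id,
                 length = dataset$length),
            class = "typing_data")
}

#' @export
print.typing_data <- function(x, ...) {
  cat(sprintf("<typing_data> replicate %d: %d haplotypes x %d markers\n",
              x$replicate_id, nrow(x$haplotypes), ncol(x$haplotypes)))
  invisible(x)
}

#' @export
n_pops.typing_data <- function(x) {
  if (length(x$pop)) max(x$pop) else 0L
}
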