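#' Minor allele frequency
#'
#' Folded allele frequency `min(d/n, 1 - d/n)` of a site with `d` derived
#' alleles among `n` haplotypes. Vectorized over `derived_count`.
#'
#' @param derived_count Derived-allele count(s), `0 <= d <= n`.
#' @param n_haplotypes Number of haplotypes, `>= 1`.
#' @return Numeric MAF in `[0, 0.5]`.
#' @export
#' @examples
#' minor_allele_frequency(c(4, 97, 50), 100)
minor_allele_frequency <- function(derived_count, n_haplotypes) {
  if (any(n_haplotypes < 1)) abort("`n_haplotypes` must be >= 1.")
  if (any(derived_count < 0) || any(derived_count > n_haplotypes)) {
    abort("`derived_count` must lie in [0, n_haplotypes].")
  }
  f <- derived_count / n_haplotypes
  pmin(f, 1 - f)
}

#' Ascertainment scheme configuration
#'
#' The three marker-discovery schemes compared by the package:
#'
#' * `single_population`: variable sites are discovered in the discovery
#'   panel of one population (`discovery_population`); sites whose MAF in
#'   that panel falls below `maf_threshold` are eliminated.
#' * `merged_panel`: all populations' discovery panels are pooled into one
#'   panel; discovery and the MAF filter apply to the pooled frequencies.
#' * `independent_panel`: each population keeps its own panel; a site is
#'   eliminated if its MAF falls below the threshold (or it is
#'   monomorphic) in any panel.
#'
#' In every scheme a site must be segregating in the panel(s) consulted —
#' a variant invisible to the panel cannot be discovered — so at threshold
#' 0 the frequency filter is disabled but the polymorphism requirement
#' remains.
#'
#' @param scheme One of `"single_population"`, `"merged_panel"`,
#'   `"independent_panel"`.
#' @param discovery_population 1-based population whose panel is used
#'   under `single_population`.
#' @param maf_threshold MAF cutoff in `[0, 0.5)`. Sites with panel MAF
#'   *below* the threshold are eliminated, i.e. ties are kept
#'   (`strict = FALSE`); `strict = TRUE` also drops ties, for sensitivity
#'   checks.
#' @param n_markers Number of SNP markers randomly selected from the
#'   candidates (default 50).
#' @param strict Drop sites whose MAF equals the threshold?
#' @param seed Seed for marker selection, or `NULL` to use the current
#'   RNG stream.
#' @return An object of class `ascertainment_config`.
#' @export
ascertainment_config <- function(scheme = c("single_population",
                                            "merged_panel",
                                            "independent_panel"),
                                 discovery_population = 1L,
                                 maf_threshold = 0.05,
                                 n_markers = 50L,
                                 strict = FALSE,
                                 seed = NULL) {
  scheme <- match.arg(scheme)
  if (!is.numeric(maf_threshold) || maf_threshold < 0 ||
      maf_threshold >= 0.5) {
    abort("`maf_threshold` must lie in [0, 0.5).")
  }
  if (!is.numeric(n_markers) || n_markers < 1) {
    abort("`n_markers` must be >= 1.")
  }
  structure(list(scheme = scheme,
                 discovery_population = as.integer(discovery_population),
                 maf_threshold = maf_threshold,
                 n_markers = as.integer(n_markers),
                 strict = isTRUE(strict),
                 seed = seed),
            class = "ascertainment_config")
}

panel_counts <- function(dataset, pop) {
  rows <- discovery_rows(dataset, pop)
  if (!length(rows)) {
    abort(sprintf("no discovery panel for population %d.", pop))
  }
  list(d = colSums(dataset$haplotypes[rows, , drop = FALSE]),
       n = length(rows))
}

passes_panel <- function(d, n, threshold, strict) {
  maf <- pmin(d / n, 1 - d / n)
  seg <- d > 0 & d < n
  if (strict) seg & maf > threshold else seg & maf >= threshold
}

#' Candidate marker sites under an ascertainment scheme
#'
#' Applies the scheme's discovery and MAF-filter rules (see
#' [ascertainment_config()]) to one replicate and returns the site
#' indices that survive.
#'
#' @param dataset A [haplotype_dataset()] with discovery-role haplotypes
#'   for every population the scheme consults.
#' @param config An [ascertainment_config()].
#' @return Sorted integer vector of candidate site indices.
#' @export
candidate_sites <- function(dataset, config) {
  stopifnot(inherits(dataset, "haplotype_dataset"),
            inherits(config, "ascertainment_config"))
  if (!ncol(dataset$haplotypes)) return(integer())
  thr <- config$maf_threshold
  strict <- config$strict
  keep <- switch(config$scheme,
    single_population = {
      pc <- panel_counts(dataset, config$discovery_population)
      passes_panel(pc$d, pc$n, thr, strict)
    },
    merged_panel = {
      pops <- sort(unique(dataset$pop))
      pcs <- lapply(pops, function(p) panel_counts(dataset, p))
      d <- Reduce(`+`, lapply(pcs, `[[`, "d"))
      n <- sum(vapply(pcs, `[[`, integer(1), "n"))
      passes_panel(d, n, thr, strict)
    },
    independent_panel = {
      pops <- sort(unique(dataset$pop))
      per_pop <- lapply(pops, function(p) {
        pc <- panel_counts(dataset, p)
        passes_panel(pc$d, pc$n, thr, strict)
      })
      Reduce(`&`, per_pop)
    })
  which(keep)
}

new_marker_selection <- function(candidates, selected, excluded, n_markers,
                                 scheme) {
  structure(list(candidate_sites = as.integer(candidates),
                 selected_markers = as.integer(selected),
                 excluded = excluded,
                 n_markers = as.integer(n_markers),
                 scheme = scheme),
            class = "marker_selection")
}

#' @export
print.marker_selection <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf(
      "<marker_selection: %s> EXCLUDED (%d candidates < %d markers)\n",
      x$scheme, length(x$candidate_sites), x$n_markers))
  } else {
    cat(sprintf("<marker_selection: %s> %d markers from %d candidates\n",
                x$scheme, length(x$selected_markers),
                length(x$candidate_sites)))
  }
  invisible(x)
}

#' Randomly select SNP markers from the candidate set
#'
#' Draws `n_markers` sites uniformly without replacement from the
#' candidates. A replicate whose candidate set is smaller than
#' `n_markers` is flagged excluded — exclusion is a result state, not an
#' error — and is dropped from downstream aggregation.
#'
#' @param candidates Integer vector of candidate site indices, e.g. from
#'   [candidate_sites()].
#' @param config An [ascertainment_config()]; its `n_markers` and `seed`
#'   are used.
#' @return A `marker_selection`: list with `candidate_sites`,
#'   `selected_markers` (sorted; empty when excluded), `excluded`,
#'   `n_markers`, `scheme`.
#' @export
select_markers <- function(candidates, config) {
  stopifnot(inherits(config, "ascertainment_config"))
  draw <- function() {
    if (length(candidates) == config$n_markers) {
      candidates
    } else {
      sample(candidates, config$n_markers)
    }
  }
  if (length(candidates) < config$n_markers) {
    return(new_marker_selection(candidates, integer(), TRUE,
                                config$n_markers, config$scheme))
  }
  sel <- if (is.null(config$seed)) draw() else with_seed(config$seed, draw())
  new_marker_selection(candidates, sort(sel), FALSE, config$n_markers,
                       config$scheme)
}

#' Random-marker baseline selection
#'
#' The no-ascertainment reference: `n_markers` sites drawn uniformly from
#' all sites segregating in the full replicate, with no panel conditioning
#' and no MAF filter. Uniform subsampling is unbiased for per-site
#' averages, so diversity computed on these markers estimates the
#' re-sequencing diversity; typing-scheme diversities are reported
#' relative to this baseline.
#'
#' @param dataset A [haplotype_dataset()].
#' @param n_markers Number of markers.
#' @param seed Seed for the draw, or `NULL` for the current RNG stream.
#' @return A `marker_selection` (excluded if the replicate has fewer than
#'   `n_markers` segregating sites).
#' @export
random_marker_baseline <- function(dataset, n_markers = 50L, seed = NULL) {
  stopifnot(inherits(dataset, "haplotype_dataset"))
  sites <- seq_len(ncol(dataset$haplotypes))
  if (length(sites) < n_markers) {
    return(new_marker_selection(sites, integer(), TRUE, n_markers,
                                "random_markers"))
  }
  draw <- function() sample(sites, n_markers)
  sel <- if (is.null(seed)) draw() else with_seed(seed, draw())
  new_marker_selection(sites, sort(sel), FALSE, n_markers, "random_markers")
}
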