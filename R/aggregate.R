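#' Per-replicate summary statistics for every ascertainment cell
#'
#' Runs the whole per-replicate pipeline once: for every requested
#' `(scheme, threshold)` cell it discovers candidate sites, selects
#' markers, builds typing data and computes pairwise diversity and FST;
#' it also computes the two baselines shared by all cells — the
#' re-sequencing statistics (typing haplotypes at all segregating sites)
#' and the random-marker baseline. Baseline rows carry scheme
#' `"resequencing"` / `"random_markers"` and threshold `NA`. Cells whose
#' candidate set is smaller than `n_markers` are flagged excluded and
#' their statistics are `NA`.
#'
#' @param dataset A [haplotype_dataset()].
#' @param schemes Character vector of scheme names (see
#'   [ascertainment_config()]).
#' @param thresholds Numeric vector of MAF thresholds.
#' @param n_markers Markers per cell (default 50).
#' @param seed Seed for all marker draws of this replicate; `NULL` uses
#'   the current RNG stream.
#' @param discovery_population Population index for the
#'   `single_population` scheme.
#' @param strict Passed to [ascertainment_config()].
#' @return A tibble with one row per (cell, population pair):
#'   `replicate_id`, `scheme`, `threshold`, `pop_a`, `pop_b`,
#'   `n_candidates`, `excluded`, `n_sites`, `pi_w_a`, `pi_w_b`, `pi_w`,
#'   `pi_b`, `fst`.
#' @export
replicate_stats <- function(dataset,
                            schemes = c("single_population", "merged_panel",
                                        "independent_panel"),
                            thresholds = 0.1,
                            n_markers = 50L,
                            seed = NULL,
                            discovery_population = 1L,
                            strict = FALSE) {
  stopifnot(inherits(dataset, "haplotype_dataset"))
  run <- function() {
    pops <- sort(unique(dataset$pop))
    pairs <- combn(pops, 2)
    na_pairs <- tibble(pop_a = pairs[1, ], pop_b = pairs[2, ],
                       pi_w_a = NA_real_, pi_w_b = NA_real_,
                       pi_w = NA_real_, pi_b = NA_real_, fst = NA_real_,
                       n_sites = NA_integer_)
    cell <- function(scheme, threshold, selection) {
      stats <- if (selection$excluded) {
        na_pairs
      } else if (inherits(selection, "marker_selection")) {
        pairwise_stats(make_typing_data(dataset, selection))
      }
      dplyr::mutate(stats,
                    replicate_id = dataset$replicate_id,
                    scheme = scheme, threshold = threshold,
                    n_candidates = length(selection$candidate_sites),
                    excluded = selection$excluded,
                    .before = 1)
    }

    n_seg <- ncol(dataset$haplotypes)
    reseq <- dplyr::mutate(
      if (n_seg) pairwise_stats(dataset, role = "typing") else na_pairs,
      replicate_id = dataset$replicate_id,
      scheme = "resequencing", threshold = NA_real_,
      n_candidates = n_seg, excluded = n_seg == 0L,
      .before = 1)
    baseline <- cell("random_markers", NA_real_,
                     random_marker_baseline(dataset, n_markers))

    cells <- purrr::map_dfr(schemes, function(sc) {
      purrr::map_dfr(thresholds, function(thr) {
        cfg <- ascertainment_config(sc, discovery_population, thr,
                                    n_markers, strict)
        cell(sc, thr, select_markers(candidate_sites(dataset, cfg), cfg))
      })
    })
    dplyr::bind_rows(reseq, baseline, cells)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Delta-method Monte-Carlo standard error of mean(x)/mean(y) over paired
# replicates.
ratio_se <- function(x, y) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  r <- mean(x) / mean(y)
  abs(r) * sqrt((var(x) / mean(x)^2 + var(y) / mean(y)^2 -
                   2 * stats::cov(x, y) / (mean(x) * mean(y))) / n)
}

#' Aggregate per-replicate statistics into deviation records
#'
#' Collapses the long tibble from [replicate_stats()] over replicates,
#' pairing every `(scheme, threshold, population pair)` cell with the same
#' replicates' re-sequencing and random-marker baselines. A replicate
#' contributes to a cell only if the cell was not excluded, its FST and
#' the re-sequencing FST are defined, and the random baseline exists; the
#' number dropped is reported per cell, making conditioning-induced bias
#' visible.
#'
#' The headline `fst_deviation` is the difference of replicate means
#' (mean typing FST minus mean re-sequencing FST);
#' `fst_deviation_paired`, the mean of per-replicate differences, is also
#' reported together with its paired Monte-Carlo standard error.
#' Relative diversities are ratios of replicate means against the
#' random-marker baseline, with delta-method standard errors.
#'
#' @param stats Tibble from [replicate_stats()] (rows from many
#'   replicates bound together).
#' @return A tibble with one row per (scheme, threshold, population
#'   pair) cell.
#' @export
aggregate_deviations <- function(stats) {
  base_schemes <- "resequencing"
  reseq <- stats %>%
    dplyr::filter(.data$scheme == "resequencing") %>%
    dplyr::select("replicate_id", "pop_a", "pop_b",
                  fst_reseq = "fst", reseq_excluded = "excluded")
  rand <- stats %>%
    dplyr::filter(.data$scheme == "random_markers") %>%
    dplyr::select("replicate_id", "pop_a", "pop_b",
                  pi_w_rand = "pi_w", pi_b_rand = "pi_b",
                  rand_excluded = "excluded")
  stats %>%
    dplyr::filter(!.data$scheme %in% base_schemes) %>%
    dplyr::left_join(reseq, by = c("replicate_id", "pop_a", "pop_b")) %>%
    dplyr::left_join(rand, by = c("replicate_id", "pop_a", "pop_b")) %>%
    dplyr::mutate(used = !.data$excluded & !.data$rand_excluded &
                    !is.na(.data$fst) & !is.na(.data$fst_reseq)) %>%
    dplyr::group_by(.data$scheme, .data$threshold, .data$pop_a,
                    .data$pop_b) %>%
    dplyr::summarise(
      n_replicates_used = sum(used),
      n_excluded = dplyr::n() - n_replicates_used,
      mean_fst_typing = mean(fst[used]),
      mean_fst_reseq = mean(fst_reseq[used]),
      fst_deviation = mean_fst_typing - mean_fst_reseq,
      fst_deviation_paired = mean(fst[used] - fst_reseq[used]),
      se_fst_deviation = stats::sd(fst[used] - fst_reseq[used]) /
        sqrt(max(1, n_replicates_used)),
      mean_pi_w_typing = mean(pi_w[used]),
      mean_pi_b_typing = mean(pi_b[used]),
      mean_pi_w_random = mean(pi_w_rand[used]),
      mean_pi_b_random = mean(pi_b_rand[used]),
      relative_pi_within = mean_pi_w_typing / mean_pi_w_random,
      relative_pi_between = mean_pi_b_typing / mean_pi_b_random,
      se_relative_pi_within = ratio_se(pi_w[used], pi_w_rand[used]),
      se_relative_pi_between = ratio_se(pi_b[used], pi_b_rand[used]),
      .groups = "drop")
}
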