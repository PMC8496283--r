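#' Full factorial experiment configuration
#'
#' Bundles everything one experiment run needs: the demographic model,
#' region parameters, sampling design, the schemes and MAF-threshold
#' sweep, replicate count and master seed. Defaults follow the study
#' conditions: 100 discovery + 100 typing haplotypes per deme,
#' `theta = rho = 20` over 50 kb, 50 markers per cell, and a
#' threshold sweep spanning 0 to 0.2.
#'
#' @param demography A [demography()] object.
#' @param params A [sim_params()].
#' @param design A [sampling_design()].
#' @param schemes Character vector of ascertainment schemes.
#' @param thresholds Ascending numeric MAF-threshold sweep.
#' @param n_replicates Number of coalescent replicates (the reference
#'   study uses 10,000; 1,000 is a practical desk-scale default).
#' @param n_markers Markers selected per cell.
#' @param master_seed Master seed; every random draw of the run derives
#'   from it.
#' @param discovery_population Panel population for `single_population`.
#' @param strict MAF-threshold strictness flag (see
#'   [ascertainment_config()]).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(demography,
                              params = sim_params(),
                              design = sampling_design(),
                              schemes = c("single_population",
                                          "merged_panel",
                                          "independent_panel"),
                              thresholds = c(0, 0.01, 0.025, 0.05, 0.075,
                                             0.1, 0.15, 0.2),
                              n_replicates = 1000,
                              n_markers = 50L,
                              master_seed = 1L,
                              discovery_population = 1L,
                              strict = FALSE) {
  stopifnot(inherits(demography, "demography"),
            inherits(params, "sim_params"),
            inherits(design, "sampling_design"))
  if (is.unsorted(thresholds)) abort("`thresholds` must be ascending.")
  if (discovery_population > n_pops(demography)) {
    abort("`discovery_population` does not exist in the demography.")
  }
  structure(list(demography = demography, params = params, design = design,
                 schemes = schemes, thresholds = thresholds,
                 n_replicates = as.integer(n_replicates),
                 n_markers = as.integer(n_markers),
                 master_seed = as.integer(master_seed),
                 discovery_population = as.integer(discovery_population),
                 strict = isTRUE(strict)),
            class = "experiment_config")
}

#' Run the factorial ascertainment experiment
#'
#' Simulates `n_replicates` coalescent replicates once and pushes each
#' through every `(scheme, threshold)` cell — candidate discovery, marker
#' selection, typing, diversity and FST — plus the shared re-sequencing
#' and random-marker baselines, then aggregates deviations over
#' replicates. Because a single simulation pass is shared by all cells,
#' scheme comparisons are paired and lower-variance than independent
#' simulation. The run is fully reproducible from `master_seed`.
#'
#' @param config An [experiment_config()].
#' @param replicates Optional pre-simulated list of
#'   [haplotype_dataset()]s (e.g. parsed from ms output); when supplied,
#'   simulation is skipped and marker-draw seeds still derive from
#'   `master_seed`.
#' @return An object of class `ascertainment_experiment`: list with
#'   `deviations` (the aggregated cell table), `replicate_stats` (the
#'   long per-replicate table) and `config`.
#' @export
run_experiment <- function(config, replicates = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(replicates)) {
    replicates <- simulate_replicates(config$demography,
                                      config$n_replicates,
                                      config$design, config$params,
                                      seed = config$master_seed)
  }
  stat_seeds <- replicate_seeds(config$master_seed + 1L,
                                length(replicates))
  stats <- purrr::map2_dfr(replicates, stat_seeds, function(ds, s) {
    replicate_stats(ds,
                    schemes = config$schemes,
                    thresholds = config$thresholds,
                    n_markers = config$n_markers,
                    seed = s,
                    discovery_population = config$discovery_population,
                    strict = config$strict)
  })
  structure(list(deviations = aggregate_deviations(stats),
                 replicate_stats = stats,
                 config = config),
            class = "ascertainment_experiment")
}

#' @export
print.ascertainment_experiment <- function(x, ...) {
  cat(sprintf(
    "<ascertainment_experiment: %s> %d replicates, %d cell rows\n",
    x$config$demography$name, x$config$n_replicates, nrow(x$deviations)))
  print(x$deviations)
  invisible(x)
}

#' Tidy an ascertainment experiment into its deviation table
#'
#' @param x An `ascertainment_experiment`.
#' @param ... Unused.
#' @return The per-cell deviation tibble (see [aggregate_deviations()]).
#' @export
tidy.ascertainment_experiment <- function(x, ...) x$deviations

#' @export
glance.ascertainment_experiment <- function(x, ...) {
  tibble(model = x$config$demography$name,
         n_replicates = x$config$n_replicates,
         n_schemes = length(x$config$schemes),
         n_thresholds = length(x$config$thresholds),
         n_cells = nrow(x$deviations),
         max_exclusion_fraction =
           max(x$deviations$n_excluded /
                 (x$deviations$n_excluded + x$deviations$n_replicates_used)),
         master_seed = x$config$master_seed)
}

#' Run the PCA structure-recovery experiment
#'
#' Simulates `n_replicates` replicates of a three-population demography
#' and, over the same replicates, runs EIGENSTRAT-style PCA for the
#' no-ascertainment control and each requested scheme: per replicate all
#' candidate sites at `maf_threshold` are kept (no marker subsampling),
#' typing haplotypes are pooled across replicates, the matrix is
#' normalized and decomposed, and pairwise cluster separations in the
#' first two components are tabulated.
#'
#' @param demography A three-population [demography()].
#' @param n_replicates Replicates pooled into the genotype matrix
#'   (default 100).
#' @param schemes Schemes to run besides the `"none"` control.
#' @param maf_threshold Panel MAF cutoff (default 0.05).
#' @param design A [sampling_design()].
#' @param params A [sim_params()].
#' @param master_seed Master seed.
#' @param k Components to extract.
#' @param discovery_population Panel population for `single_population`.
#' @param replicates Optional pre-simulated replicate list.
#' @return An object of class `pca_experiment`: list with `results`
#'   (named list of `pca_result`), `separations` (tibble with `scheme`,
#'   `pop_a`, `pop_b`, `separation`), `config` fields.
#' @export
run_pca_experiment <- function(demography,
                               n_replicates = 100,
                               schemes = c("none", "single_population",
                                           "merged_panel",
                                           "independent_panel"),
                               maf_threshold = 0.05,
                               design = sampling_design(),
                               params = sim_params(),
                               master_seed = 1L,
                               k = 10,
                               discovery_population = 1L,
                               replicates = NULL) {
  if (n_replicates == 1) {
    warn("PCA on a single replicate is valid but noisy.")
  }
  if (is.null(replicates)) {
    replicates <- simulate_replicates(demography, n_replicates, design,
                                      params, seed = master_seed)
  }
  results <- lapply(schemes, function(sc) {
    input <- build_pca_input(replicates, scheme = sc,
                             maf_threshold = maf_threshold,
                             discovery_population = discovery_population)
    principal_components(input, k = k)
  })
  names(results) <- schemes
  separations <- purrr::map_dfr(schemes, function(sc) {
    dplyr::mutate(pca_separations(results[[sc]]), scheme = sc,
                  .before = 1)
  })
  structure(list(results = results, separations = separations,
                 maf_threshold = maf_threshold,
                 n_replicates = length(replicates),
                 master_seed = master_seed),
            class = "pca_experiment")
}

#' @export
print.pca_experiment <- function(x, ...) {
  cat(sprintf("<pca_experiment> %d replicates pooled, schemes: %s\n",
              x$n_replicates, paste(names(x$results), collapse = ", ")))
  print(x$separations)
  invisible(x)
}

#' @export
tidy.pca_experiment <- function(x, ...) x$separations
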