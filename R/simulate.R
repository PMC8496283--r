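python_binary <- function() {
  getOption("ascbias.python", Sys.getenv("ASCBIAS_PYTHON", "python"))
}

demography_job <- function(demography, design, params, seeds) {
  per_pop <- if (design$reuse_discovery_as_typing) design$n_discovery
             else design$n_discovery + design$n_typing
  list(N0 = params$N0,
       theta = params$theta,
       rho = params$rho,
       length = params$length,
       deme_sizes = as.list(demography$deme_sizes),
       migration_matrix = apply(demography$migration_matrix, 1, as.list,
                                simplify = FALSE),
       events = if (nrow(demography$events)) {
         lapply(seq_len(nrow(demography$events)), function(i) {
           row <- as.list(demography$events[i, ])
           row[!vapply(row, is.na, logical(1))]
         })
       } else {
         list()
       },
       sample_sizes = as.list(rep(per_pop, n_pops(demography))),
       seeds = as.list(seeds))
}

#' Simulate coalescent replicates under a demographic model
#'
#' Generates independent neutral coalescent replicates with recombination
#' (infinite-sites mutation, derived-allele 0/1 coding) by driving the
#' msprime engine through a bundled Python helper that emits ms-format
#' text, which is then read back with [parse_ms_output()]. Per-replicate
#' seeds come from [replicate_seeds()], so the run is deterministic given
#' `seed` and each replicate is individually reproducible.
#'
#' Each deme contributes `n_discovery + n_typing` haplotypes (or just
#' `n_discovery` when the design reuses the discovery panel for typing).
#'
#' @param demography A [demography()] object.
#' @param n_replicates Number of replicates.
#' @param design A [sampling_design()].
#' @param params A [sim_params()].
#' @param seed Master seed (integer).
#' @return A list of [haplotype_dataset()] objects.
#' @seealso [parse_ms_output()] to use replicates from any ms-compatible
#'   simulator instead.
#' @export
#' @examplesIf nzchar(Sys.which("python"))
#' reps <- simulate_replicates(island_model(2, 0.1), n_replicates = 2,
#'                             seed = 1)
#' reps[[1]]
simulate_replicates <- function(demography, n_replicates = 1,
                                design = sampling_design(),
                                params = sim_params(), seed = 1) {
  stopifnot(inherits(demography, "demography"),
            inherits(design, "sampling_design"),
            inherits(params, "sim_params"))
  seeds <- replicate_seeds(seed, n_replicates)
  job <- demography_job(demography, design, params, seeds)

  job_file <- tempfile("ascbias_job_", fileext = ".json")
  out_file <- tempfile("ascbias_ms_", fileext = ".txt")
  on.exit(unlink(c(job_file, out_file)), add = TRUE)
  jsonlite::write_json(job, job_file, auto_unbox = TRUE, digits = NA)

  script <- system.file("python", "simulate_ms.py", package = "ascbias",
                        mustWork = TRUE)
  err_file <- tempfile("ascbias_err_")
  on.exit(unlink(err_file), add = TRUE)
  status <- system2(python_binary(), c(script, job_file, out_file),
                    stdout = FALSE, stderr = err_file)
  if (!identical(status, 0L)) {
    msg <- paste(readLines(err_file, warn = FALSE), collapse = "\n")
    abort(sprintf("coalescent engine failed (status %s) for model '%s':\n%s",
                  status, demography$name, msg))
  }

  per_pop <- if (design$reuse_discovery_as_typing) design$n_discovery
             else design$n_discovery + design$n_typing
  reps <- parse_ms_output(out_file, design = design,
                          pop_sizes = rep(per_pop, n_pops(demography)),
                          length = params$length)
  if (length(reps) != n_replicates) {
    abort(sprintf("engine returned %d replicates, expected %d.",
                  length(reps), n_replicates))
  }
  reps
}

#' @rdname simulate_replicates
#' @export
simulate_replicate <- function(demography, design = sampling_design(),
                               params = sim_params(), seed = 1) {
  simulate_replicates(demography, 1L, design, params, seed)[[1]]
}
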