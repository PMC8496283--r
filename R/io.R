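#' Export haplotypes as a minimal haploid VCF
#'
#' Writes a plain-text VCFv4.2 file with one haploid GT column per
#' haplotype. Alleles are placeholders (REF = A, ALT = T; the simulation
#' is infinite-sites binary), CHROM is `rep<replicate_id>` and POS is
#' `floor(position * length) + 1` (1-based; distinct relative positions
#' can collide on the same bp after flooring). The `##source` header
#' records the replicate seed.
#'
#' @param x A [haplotype_dataset()] or `typing_data`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  if (inherits(x, "haplotype_dataset")) {
    mat <- x$haplotypes
    pop <- x$pop
    role <- x$role
    seed <- x$seed
  } else if (inherits(x, "typing_data")) {
    mat <- x$haplotypes
    pop <- x$pop
    role <- rep("typing", nrow(mat))
    seed <- NA_integer_
  } else {
    abort("`x` must be a haplotype_dataset or typing_data.")
  }
  ids <- stats::ave(seq_along(pop), pop, FUN = seq_along)
  sample_names <- sprintf("pop%d_%s%d", pop, substr(role, 1, 3), ids)
  pos <- floor(x$positions * x$length) + 1
  chrom <- sprintf("rep%d", x$replicate_id)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=ascbias seed=%s",
            if (is.na(seed)) "NA" else as.character(seed)),
    sprintf("##contig=<ID=%s,length=%d>", chrom, x$length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t"))
  body <- vapply(seq_len(ncol(mat)), function(j) {
    paste(c(chrom, pos[j], ".", "A", "T", ".", "PASS", ".", "GT",
            mat[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a 2D-SFS as plain matrix text
#'
#' A comment header names the populations and sample sizes; rows are
#' derived-allele counts in population A (0-based), columns counts in
#' population B.
#'
#' @param sfs An `sfs_2d` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sfs_matrix <- function(sfs, path) {
  stopifnot(inherits(sfs, "sfs_2d"))
  header <- sprintf("# 2D-SFS popA=%d popB=%d nA=%d nB=%d n_sites=%d",
                    sfs$pop_pair[1], sfs$pop_pair[2],
                    sfs$n_haplotypes[1], sfs$n_haplotypes[2], sfs$n_sites)
  rows <- apply(sfs$counts, 1, paste, collapse = " ")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write or read a full experiment configuration
#'
#' YAML serialization of an [experiment_config()], demography included;
#' the round trip reproduces the configuration exactly.
#'
#' @param config An `experiment_config`.
#' @param path File path.
#' @return `write_experiment_config()` returns `path` invisibly;
#'   `read_experiment_config()` returns the `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  demo_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(demo_file))
  write_demography_config(config$demography, demo_file)
  demo_cfg <- yaml::read_yaml(demo_file)
  cfg <- c(demo_cfg,
           list(params = unclass(config$params),
                design = unclass(config$design),
                experiment = list(
                  schemes = config$schemes,
                  thresholds = config$thresholds,
                  n_replicates = config$n_replicates,
                  n_markers = config$n_markers,
                  master_seed = config$master_seed,
                  discovery_population = config$discovery_population,
                  strict = config$strict)))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  parsed <- read_demography_config(path)
  ex <- cfg$experiment
  experiment_config(demography = parsed$demography,
                    params = do.call(sim_params, cfg$params),
                    design = do.call(sampling_design, cfg$design),
                    schemes = unlist(ex$schemes),
                    thresholds = unlist(ex$thresholds),
                    n_replicates = ex$n_replicates,
                    n_markers = ex$n_markers,
                    master_seed = ex$master_seed,
                    discovery_population = ex$discovery_population,
                    strict = ex$strict)
}
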