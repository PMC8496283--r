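#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_hline geom_tile
#'   geom_errorbar facet_grid facet_wrap labs scale_fill_viridis_c
#'   theme_minimal
NULL

#' Plot FST deviations against the threshold sweep
#'
#' One panel per population pair; deviation of mean typing FST from the
#' re-sequencing mean, with +/- 2 Monte-Carlo-SE error bars, coloured by
#' ascertainment scheme. The dashed zero line is the unbiased reference.
#'
#' @param object An `ascertainment_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ascertainment_experiment <- function(object, ...) {
  dat <- dplyr::filter(object$deviations, !is.na(.data$threshold))
  ggplot(dat, aes(x = .data$threshold, y = .data$fst_deviation,
                  colour = .data$scheme)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    geom_line() +
    geom_point() +
    geom_errorbar(aes(ymin = .data$fst_deviation -
                        2 * .data$se_fst_deviation,
                      ymax = .data$fst_deviation +
                        2 * .data$se_fst_deviation),
                  width = 0.004) +
    facet_wrap(~ paste0("pops ", .data$pop_a, "-", .data$pop_b)) +
    labs(x = "MAF threshold of marker selection",
         y = "FST deviation from re-sequencing",
         colour = "scheme",
         title = object$config$demography$name) +
    theme_minimal()
}

#' Plot relative diversity against the threshold sweep
#'
#' Relative within- and between-population pairwise diversity (typing
#' over random-marker baseline) per scheme, the package's analogue of the
#' classic relative-variation panels.
#'
#' @param experiment An `ascertainment_experiment`.
#' @return A ggplot object.
#' @export
plot_relative_pi <- function(experiment) {
  dat <- experiment$deviations %>%
    dplyr::filter(!is.na(.data$threshold)) %>%
    tidyr::pivot_longer(c("relative_pi_within", "relative_pi_between"),
                        names_to = "statistic", values_to = "relative_pi")
  ggplot(dat, aes(x = .data$threshold, y = .data$relative_pi,
                  colour = .data$scheme, linetype = .data$statistic)) +
    geom_hline(yintercept = 1, colour = "grey40") +
    geom_line() +
    geom_point() +
    facet_wrap(~ paste0("pops ", .data$pop_a, "-", .data$pop_b)) +
    labs(x = "MAF threshold of marker selection",
         y = "diversity relative to random markers") +
    theme_minimal()
}

#' Scatter plot of the first two principal components
#'
#' @param object A `pca_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_result <- function(object, ...) {
  dat <- tidy(object)
  ggplot(dat, aes(x = .data$PC1, y = .data$PC2, colour = .data$pop)) +
    geom_point(alpha = 0.7) +
    labs(x = "PC1", y = "PC2", colour = "population") +
    theme_minimal()
}

#' Panelled PC1/PC2 plots for a PCA experiment
#'
#' @param object A `pca_experiment`.
#' @param ... Unused.
#' @return A ggplot object with one facet per scheme.
#' @export
autoplot.pca_experiment <- function(object, ...) {
  dat <- purrr::imap_dfr(object$results, function(res, sc) {
    dplyr::mutate(tidy(res), scheme = sc)
  })
  ggplot(dat, aes(x = .data$PC1, y = .data$PC2, colour = .data$pop)) +
    geom_point(alpha = 0.6, size = 0.8) +
    facet_wrap(~ scheme, scales = "free") +
    labs(x = "PC1", y = "PC2", colour = "population") +
    theme_minimal()
}

#' Heat map of a joint site-frequency spectrum
#'
#' Log-scaled site counts over derived-allele frequencies in the two
#' populations.
#'
#' @param object An `sfs_2d`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sfs_2d <- function(object, ...) {
  dat <- tidy(object)
  ggplot(dat, aes(x = .data$freq_a, y = .data$freq_b,
                  fill = log10(.data$n_sites + 1))) +
    geom_tile() +
    scale_fill_viridis_c(name = "log10(sites + 1)") +
    labs(x = sprintf("derived allele frequency, pop %d",
                     object$pop_pair[1]),
         y = sprintf("derived allele frequency, pop %d",
                     object$pop_pair[2])) +
    theme_minimal()
}
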