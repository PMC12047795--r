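#' @importFrom ggplot2 ggplot aes autoplot geom_col geom_histogram
#'   geom_vline geom_line geom_abline labs stat_ecdf facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a mutation spectrum
#' @param object spectrum tibble from [mutation_spectrum()].
#' @param ... ignored.
#' @return ggplot object.
#' @export
plot_spectrum <- function(object, ...) {
  ggplot(object, aes(x = .data$type, y = .data$proportion)) +
    geom_col(fill = "grey35") +
    labs(x = NULL, y = "Proportion of mutations")
}

#' @export
autoplot.fm_enrichment <- function(object, ...) {
  ggplot(tibble(null = object$null), aes(x = .data$null)) +
    geom_histogram(bins = 40, fill = "grey70") +
    geom_vline(xintercept = object$observed, colour = "red") +
    labs(x = "Overlap fraction (shuffled sets)", y = "Sets",
         title = sprintf("Observed %.1f%%, fold %.2f, p = %.3g",
                         100 * object$observed, object$fold, object$p))
}

#' @export
autoplot.fm_tract <- function(object, ...) {
  ggplot(object$loglik, aes(x = .data$mean_bp, y = .data$loglik)) +
    geom_line() +
    geom_vline(xintercept = object$mean_bp, colour = "red",
               linetype = "dashed") +
    labs(x = "Mean conversion tract length (bp)",
         y = "Composite log-likelihood")
}

#' @export
autoplot.fm_dist <- function(object, ...) {
  ggplot(object$positions, aes(x = .data$relpos, colour = .data$cls)) +
    stat_ecdf() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    labs(x = "Normalized chromosome position", y = "Cumulative fraction",
         colour = NULL)
}

#' Per-chromosome recombination-event densities against length
#' @param dsb tibble from [dsb_summaries()].
#' @return ggplot object.
#' @export
plot_dsb_density <- function(dsb) {
  ggplot(dsb, aes(x = .data$length / 1e6, y = .data$density * 1e6)) +
    ggplot2::geom_point() +
    labs(x = "Chromosome length (Mb)", y = "DSB density (per Mb)")
}
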