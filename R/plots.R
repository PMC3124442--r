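# ggplot2 graphics for tracks, strata, region sets, enrichment tests and
# intron profiles.

#' Plot pre-processing stages along the genome
#'
#' @param object A `meth_tracks` tibble from [preprocess_sample()].
#' @param chrom Chromosome to show (default: first).
#' @param xlim Optional coordinate window (bp).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.meth_tracks <- function(object, chrom = NULL, xlim = NULL, ...) {
  chrom <- chrom %||% object$chrom[1]
  df <- object |>
    dplyr::filter(.data$chrom == !!chrom) |>
    tidyr::pivot_longer(c("log_ratio", "adjusted", "smoothed", "z"),
                        names_to = "stage", values_to = "value") |>
    dplyr::mutate(stage = factor(.data$stage, levels = c("log_ratio", "adjusted",
                                                         "smoothed", "z")))
  if (!is.null(xlim)) df <- dplyr::filter(df, .data$start >= xlim[1],
                                          .data$start <= xlim[2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$stage), scales = "free_y") +
    ggplot2::labs(x = sprintf("%s position (bp)", chrom), y = NULL,
                  title = "Pre-processing stages") +
    ggplot2::theme_minimal()
}

#' Plot the GC-stratum baseline
#'
#' Shows the median log-ratio per GC stratum with a robust-scale ribbon —
#' the probe effect the adjustment subtracts.
#'
#' @param object A `gc_strata`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gc_strata <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$gc_mid <- (df$gc_min + df$gc_max) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gc_mid, y = .data$m)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$s,
                                      ymax = .data$m + .data$s),
                         alpha = 0.25) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "probe G+C count", y = "null-probe median log2 ratio",
                  title = "GC-stratified null baseline") +
    ggplot2::theme_minimal()
}

#' Plot region lengths against additive Z
#'
#' @param object A `region_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.region_set <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$additive_z)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "region length (bp)", y = "additive Z",
                  title = sprintf("%d called regions", nrow(df))) +
    ggplot2::theme_minimal()
}

#' Plot an enrichment permutation test
#'
#' Histogram of the matched-random statistics with the observed value
#' marked.
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "annotation statistic",
                  title = sprintf("Matched random sets (Q = %d), p = %.3g",
                                  object$q_total, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot an intron metagene profile
#'
#' @param object An `intron_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.intron_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$rel_pos, y = .data$mean_signal,
                               colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "relative intron position (%)",
                  y = "mean smoothed adjusted log2(M/T)",
                  colour = "intron class",
                  title = "Intron metagene profile") +
    ggplot2::theme_minimal()
}
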