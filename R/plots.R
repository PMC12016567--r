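#' Heatmap of one chromosome of a contact map
#'
#' @param map A `contact_map`.
#' @param chrom Chromosome to plot.
#' @param log_counts Plot `log10(count + 1)`.
#' @return A ggplot object.
#' @export
plot_contact_map <- function(map, chrom, log_counts = TRUE) {
  M <- cis_matrix(map, chrom)
  df <- tibble(i = as.vector(row(M)), j = as.vector(col(M)),
               count = as.vector(M))
  if (log_counts) df$count <- log10(df$count + 1)
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (log_counts) "log10(n+1)" else "n") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bin", y = "bin", title = chrom) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_directionality Autoplot method for DI tracks.
#' @export
autoplot.di_track <- function(object, ...) plot_directionality(object, ...)

#' Directionality-index track plot
#'
#' @param di,object A `di_track`.
#' @param chrom Optional chromosome subset.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_directionality <- function(di, chrom = NULL, ...) {
  if (!is.null(chrom)) di <- di[di$chrom %in% chrom, ]
  ggplot2::ggplot(di, ggplot2::aes(x = .data$start / 1e6, y = .data$di,
                                   fill = .data$di > 0)) +
    ggplot2::geom_col(width = attr(di, "resolution") / 1e6, show.legend = FALSE) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#D7301F", `FALSE` = "#2B8CBE")) +
    ggplot2::labs(x = "position (Mb)", y = "directionality index") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_tad_sizes Autoplot method for TAD sets.
#' @export
autoplot.tad_set <- function(object, ...) plot_tad_sizes(object, ...)

#' TAD size distribution plot
#'
#' @param tads,object A `tad_set`.
#' @param binwidth_kb Histogram bin width in kb.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_tad_sizes <- function(tads, binwidth_kb = 80, ...) {
  ggplot2::ggplot(tads, ggplot2::aes(.data$span_bp / 1e3)) +
    ggplot2::geom_histogram(binwidth = binwidth_kb, fill = "#2B8CBE",
                            color = "white") +
    ggplot2::labs(x = "TAD span (kb)", y = "TADs") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_compartments Autoplot method for compartment tracks.
#' @export
autoplot.compartment_track <- function(object, ...) plot_compartments(object, ...)

#' Compartment eigenvector track plot
#'
#' @param track,object A `compartment_track`.
#' @param chrom Optional chromosome subset.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_compartments <- function(track, chrom = NULL, ...) {
  if (!is.null(chrom)) track <- track[track$chrom %in% chrom, ]
  track <- track[!is.na(track$score), ]
  ggplot2::ggplot(track, ggplot2::aes(x = .data$start / 1e6, y = .data$score,
                                      fill = .data$label)) +
    ggplot2::geom_col(width = attr(track, "resolution") / 1e6) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(A = "#D7301F", B = "#2B8CBE"),
                               name = "compartment") +
    ggplot2::labs(x = "position (Mb)", y = "eigenvector score") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_expression_ma Autoplot method for expression results.
#' @export
autoplot.expression_result <- function(object, ...) plot_expression_ma(object, ...)

#' MA-style plot of a differential-expression result
#'
#' @param expr,object An `expression_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_expression_ma <- function(expr, ...) {
  rpkm_cols <- grep("^rpkm_", names(expr), value = TRUE)
  df <- as_tibble(expr)
  df$mean_rpkm <- rowMeans(df[rpkm_cols])
  df <- df[!df$low_abundance, ]
  ggplot2::ggplot(df, ggplot2::aes(log10(.data$mean_rpkm + 1e-3),
                                   .data$log2_fc,
                                   color = .data$deg_flag)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(up = "#D7301F", down = "#2B8CBE",
                                           none = "grey60"), name = NULL) +
    ggplot2::labs(x = "log10 mean RPKM", y = "log2 fold change") +
    ggplot2::theme_minimal()
}

#' Candidate-pair overview plot
#'
#' Peak-to-TSS distance by mechanism, colored by direction.
#'
#' @param pairs A candidate-pair tibble (or `pair_result`).
#' @return A ggplot object.
#' @export
plot_pairs <- function(pairs) {
  if (inherits(pairs, "pair_result")) pairs <- pairs$pairs
  ggplot2::ggplot(pairs,
                  ggplot2::aes(factor(.data$mechanism),
                               .data$distance_bp / 1e3,
                               color = .data$direction,
                               shape = .data$role)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 2) +
    ggplot2::labs(x = "mechanism", y = "peak-TSS distance (kb)") +
    ggplot2::theme_minimal()
}
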