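#' Plot a 96-channel mutation spectrum
#'
#' Bar chart of channel counts, faceted by substitution class in the
#' canonical order.
#'
#' @param object A `mutation_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mutation_spectrum
#' @export
autoplot.mutation_spectrum <- function(object, ...) {
  d <- tidy(object)
  d$channel <- factor(d$channel, levels = sbs_channels())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$context, y = .data$count,
                                  fill = .data$substitution)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(~substitution, scales = "free_x") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 5)) +
    ggplot2::labs(x = "trinucleotide context", y = "SNV count")
}

#' Plot fitted signature fractions
#'
#' @param object An `exposure_fit`.
#' @param ... Unused.
#' @return A ggplot object (bar chart of signature fractions).
#' @method autoplot exposure_fit
#' @export
autoplot.exposure_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$signature,
                                                     -.data$fraction),
                                  y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "fraction of mutations",
                  title = sprintf("%d mutations", object$n_mutations))
}

#' Plot a copy-number heterogeneity matrix
#'
#' @param object A `cnv_distance` matrix from [cnv_heterogeneity()].
#' @param ... Unused.
#' @return A ggplot heatmap of pairwise distances.
#' @method autoplot cnv_distance
#' @export
autoplot.cnv_distance <- function(object, ...) {
  m <- as.matrix(object)
  d <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(d) <- c("region_a", "region_b", "distance")
  ggplot2::ggplot(d, ggplot2::aes(.data$region_a, .data$region_b,
                                  fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "CN distance")
}
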