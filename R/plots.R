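#' Plot a presence/absence matrix as a tile map
#'
#' @param object A `pa_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pa_matrix <- function(object, ...) {
  df <- tidy.pa_matrix(object)
  df$taxon <- factor(df$taxon, levels = rev(rownames(object$states)))
  df$locus_id <- factor(df$locus_id, levels = colnames(object$states))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$locus_id, y = .data$taxon,
                                   fill = .data$state)) +
    ggplot2::geom_tile(colour = "grey85", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c("0" = "white", "1" = "grey20",
                                          "?" = "steelblue"),
                               name = "state") +
    ggplot2::labs(x = "locus", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Plot posterior node-age estimates with 95% HPD bars
#'
#' @param object A `flank_dating` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flank_dating <- function(object, ...) {
  df <- object$summaries
  df$label <- factor(df$label, levels = df$label[order(df$mean)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$label)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$hpd_lower,
                                          xmax = .data$hpd_upper)) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "age (Ma)", y = NULL,
                  title = if (object$prior_only) "Prior node ages"
                          else "Posterior node ages") +
    ggplot2::theme_minimal()
}

#' Plot candidate elements along their source sequences
#'
#' @param candidates Tibble from [scan_tsd_candidates()].
#' @return A ggplot with one horizontal track per source sequence.
#' @export
plot_candidates <- function(candidates) {
  ggplot2::ggplot(candidates,
                  ggplot2::aes(y = .data$source_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$element_start,
                                       xend = .data$element_end,
                                       yend = .data$source_id,
                                       colour = factor(.data$tsd_length)),
                          linewidth = 3) +
    ggplot2::labs(x = "position (nt)", y = NULL, colour = "TSD (nt)") +
    ggplot2::theme_minimal()
}
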