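#' Plot a PID matrix as a heatmap
#' @param object A `pid_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pid_matrix
#' @export
autoplot.pid_matrix <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object$values, rownames = "id_a"),
    cols = -"id_a", names_to = "id_b", values_to = "pid")
  ggplot2::ggplot(df, ggplot2::aes(.data$id_a, .data$id_b,
                                   fill = .data$pid)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(NA, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "PID") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a between-group identity distribution
#' @param object A `pni_distribution`.
#' @param ... Unused.
#' @return A ggplot object (violin + median line), the single-panel
#'   analogue of the classic multi-group PNI violin figure.
#' @method autoplot pni_distribution
#' @export
autoplot.pni_distribution <- function(object, ...) {
  df <- tidy(object)
  df$pair <- paste(df$group_a, "vs", df$group_b)
  ggplot2::ggplot(df, ggplot2::aes(.data$pair, .data$pni)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_point(alpha = 0.4, size = 0.6,
                        position = ggplot2::position_jitter(width = 0.05)) +
    ggplot2::geom_hline(yintercept = object$median, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = NULL, y = "proportion nucleotide identity") +
    ggplot2::theme_minimal()
}

#' Plot windowed and cumulative GC skew
#'
#' Draws the cumulative GC-skew curve; if a prediction is supplied the
#' origin and terminus are marked.
#'
#' @param object A `skew_profile`.
#' @param prediction Optional `ori_ter_prediction` to annotate.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot skew_profile
#' @export
autoplot.skew_profile <- function(object, prediction = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$midpoint,
                                            .data$cumulative)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "genome position (bp)", y = "cumulative GC skew") +
    ggplot2::theme_minimal()
  if (!is.null(prediction) && !prediction$no_signal) {
    marks <- tibble::tibble(
      position = c(prediction$ori_position, prediction$ter_position),
      what = c("ori", "ter"))
    p <- p + ggplot2::geom_vline(data = marks,
                                 ggplot2::aes(xintercept = .data$position,
                                              colour = .data$what),
                                 linetype = 2) +
      ggplot2::labs(colour = NULL)
  }
  p
}

#' Plot a gene presence/absence matrix
#' @param object A `presence_matrix`.
#' @param ... Unused.
#' @return A ggplot tile plot (genes x genomes).
#' @method autoplot presence_matrix
#' @export
autoplot.presence_matrix <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$gene_symbol <- factor(df$gene_symbol,
                           levels = rev(unique(df$gene_symbol)))
  ggplot2::ggplot(df, ggplot2::aes(.data$genome_id, .data$gene_symbol,
                                   fill = .data$present)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey25",
                                          `FALSE` = "grey90")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "present") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
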