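#' Heatmap of a cluster's aligned mean profile
#'
#' @param object An `epi_cluster`.
#' @param track_index Optional tensor track index (tibble with `sample_id`,
#'   `mark`) to label and order the tracks by mark.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.epi_cluster <- function(object, track_index = NULL, ...) {
  prof <- object$profile
  Tn <- nrow(prof); B <- ncol(prof)
  lab <- if (!is.null(track_index))
    paste(track_index$mark, track_index$sample_id, sep = ":")
  else paste0("track", seq_len(Tn))
  df <- tibble::tibble(track = factor(rep(lab, B), levels = rev(unique(lab))),
                       bin = rep(seq_len(B), each = Tn),
                       signal = as.vector(prof))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$track,
                                   fill = .data$signal)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(title = paste0("Cluster ", object$id, " (",
                                 nrow(object$members), " regions)"),
                  x = "window bin", y = NULL, fill = "signal") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Section occupancy of a fitted self-organizing map
#'
#' @param object A `section_map`.
#' @param ... Unused.
#' @return A ggplot showing how many clusters fall on each grid node.
#' @export
autoplot.section_map <- function(object, ...) {
  counts <- table(factor(object$assignment$section,
                         levels = seq_len(nrow(object$node_pos))))
  df <- tibble::tibble(row = object$node_pos[, "row"],
                       col = object$node_pos[, "col"],
                       n = as.integer(counts))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$n), color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(title = "Clusters per SOM node", x = NULL, y = NULL,
                  fill = "clusters") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Mark composition of DMER calls
#'
#' @param dmers Tibble from [call_dmers()].
#' @return A ggplot bar chart of DMER counts per mark.
#' @export
plot_dmer_marks <- function(dmers) {
  d <- dplyr::count(dplyr::filter(dmers, .data$is_dmer), .data$mark)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$mark, -.data$n),
                                  y = .data$n)) +
    ggplot2::geom_col(fill = "#3B6FB6") +
    ggplot2::labs(x = NULL, y = "DMERs") +
    ggplot2::theme_minimal(base_size = 9)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
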