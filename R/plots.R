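#' Plot per-residue pKa distributions
#'
#' Distribution strips per residue: pKa values binned along the x axis,
#' more frequent values darker, with the engine's model value marked by a
#' dotted line where known.
#'
#' @param table A `pka_table`.
#' @param bin_width Bin width in pKa units.
#' @return A ggplot object.
#' @export
plot_pka_distribution <- function(table, bin_width = 0.1) {
  counts <- pka_distribution(table, bin_width)
  p <- ggplot2::ggplot(
    counts,
    ggplot2::aes(x = .data$bin_left + bin_width / 2, y = .data$residue,
                 fill = .data$count)
  ) +
    ggplot2::geom_tile(height = 0.8, width = bin_width) +
    ggplot2::scale_fill_gradient(low = "#deebf7", high = "#08306b") +
    ggplot2::labs(x = "pKa", y = NULL, fill = "frames")
  mp <- model_pka(table)
  if (!is.null(mp)) {
    marks <- tibble::tibble(residue = names(mp), model = unname(mp))
    marks <- marks[marks$residue %in% counts$residue, ]
    p <- p + ggplot2::geom_point(
      data = marks,
      ggplot2::aes(x = .data$model, y = .data$residue),
      inherit.aes = FALSE, shape = 124, size = 4
    )
  }
  p
}

#' Plot pKa time evolutions
#'
#' Instantaneous per-frame values (light) overlaid with the centered
#' running average (dark), one panel per residue.
#'
#' @param table A `pka_table`.
#' @param residues Residue labels to show (default: all).
#' @param window Running-average window in frames (odd; see
#'   [window_frames()] to convert from a time span).
#' @return A ggplot object.
#' @export
plot_pka_timeseries <- function(table, residues = NULL, window = 1L) {
  long <- pka_long(table)
  if (!is.null(residues)) {
    long <- long[long$residue %in% residues, , drop = FALSE]
  }
  long <- long |>
    dplyr::group_by(.data$residue) |>
    dplyr::mutate(smooth = if (window > 1 && window <= dplyr::n()) {
      running_average(.data$pka, window)
    } else {
      .data$pka
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ps)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pka), colour = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smooth), colour = "#08306b") +
    ggplot2::facet_wrap(ggplot2::vars(.data$residue), scales = "free_y") +
    ggplot2::labs(x = "time (ps)", y = "pKa")
}

#' Plot a clustering in feature space
#'
#' Frames on the first two feature (or principal-component) axes, coloured
#' by cluster label, with representatives marked.
#'
#' @param object A `pka_clusters` result.
#' @param fm The `feature_matrix` that was clustered.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pka_clusters <- function(object, fm, ...) {
  vals <- feature_values(fm)
  axes <- colnames(vals)[1:2]
  d <- tibble::tibble(
    x = vals[, 1], y = vals[, 2],
    label = factor(object$labels$label)
  )
  reps <- d[object$representatives$row, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_point(data = reps, shape = 8, size = 4,
                        colour = "black") +
    ggplot2::labs(x = axes[1], y = axes[2], colour = "cluster")
}
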