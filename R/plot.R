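#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a seed geometry with its key lines
#'
#' Draws the traced contour with the longest chord `AB`, the perpendicular
#' bisector `CD`, the auxiliary chords `P1P2`/`P3P4`, the convex hull, and
#' the concavity apexes `K`/`L` — a visual audit of the feature extraction.
#'
#' @param object A `seed_geometry`.
#' @param ... Unused.
#' @return A ggplot object (y axis reversed to match image coordinates).
#' @export
autoplot.seed_geometry <- function(object, ...) {
  g <- object
  cont <- tibble::tibble(row = g$contour[, 1], col = g$contour[, 2])
  hull <- tibble::tibble(row = g$hull[, 1], col = g$hull[, 2])
  seg <- function(p, q, what) tibble::tibble(
    row = p[1], col = p[2], row_end = q[1], col_end = q[2], line = what)
  lines <- dplyr::bind_rows(
    seg(g$A, g$B, "AB"), seg(g$C, g$D, "CD"),
    seg(g$P1, g$P2, "P1P2"), seg(g$P3, g$P4, "P3P4"),
    seg(g$R_K$apex, g$R_L$apex, "LK"))
  apexes <- tibble::tibble(
    row = c(g$R_K$apex[1], g$R_L$apex[1], g$A[1]),
    col = c(g$R_K$apex[2], g$R_L$apex[2], g$A[2]),
    point = c("K", "L", "A (tip)"))
  ggplot2::ggplot(cont, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_path() +
    ggplot2::geom_polygon(data = hull, fill = NA, colour = "grey60",
                          linetype = "dashed") +
    ggplot2::geom_segment(
      data = lines,
      ggplot2::aes(xend = .data$col_end, yend = .data$row_end,
                   colour = .data$line)) +
    ggplot2::geom_point(data = apexes,
                        ggplot2::aes(shape = .data$point), size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (px)", y = "row (px)",
                  colour = "key line", shape = "key point")
}

#' Plot the BPNN training curve
#'
#' @param object A `bpnn` model.
#' @param ... Unused.
#' @return A ggplot object of epoch-mean MSE on a log scale, with the
#'   tolerance marked.
#' @export
autoplot.bpnn <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$epoch, y = .data$mse)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$config$tolerance,
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "mean squared error")
}

#' Plot a confusion matrix as a heat map
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot tile plot with counts annotated.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- as.data.frame.table(unclass(object), responseName = "count")
  names(df)[1:2] <- c("predicted", "true")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true, y = .data$predicted,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "true variety", y = "predicted variety")
}

#' @importFrom rlang .data
NULL
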