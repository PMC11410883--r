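# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a landmarks table
#'
#' Draws each specimen's semiperimeter as a path in mm coordinates, coloured
#' by species.
#'
#' @param landmarks A landmarks tibble (or [ref_db()]).
#' @param alpha Path transparency.
#' @return A ggplot.
#' @export
plot_landmarks <- function(landmarks, alpha = 0.6) {
  if (inherits(landmarks, "ref_db")) landmarks <- landmarks$landmarks
  ggplot2::ggplot(landmarks,
                  ggplot2::aes(.data$x_mm, .data$y_mm,
                               group = .data$specimen_id, colour = .data$species)) +
    ggplot2::geom_path(alpha = alpha) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = "species") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.molar_template <- function(object, ...) plot_molar_outline(object)

#' @export
autoplot.molar_specimen <- function(object, ...) plot_molar_outline(object)

plot_molar_outline <- function(object) {
  xy <- object$outline
  df <- tibble::tibble(x = xy[, 1], y = xy[, 2])
  lb <- tibble::tibble(name = names(object$labels),
                       x = xy[object$labels, 1], y = xy[object$labels, 2])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = lb, colour = "red", size = 1) +
    ggplot2::geom_text(data = lb, ggplot2::aes(label = .data$name),
                       size = 3, vjust = -0.6, colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$preset, x = "mm", y = "mm") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.procrustes_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(x = object$a[, 1], y = object$a[, 2], which = "reference"),
    tibble::tibble(x = object$b_aligned[, 1], y = object$b_aligned[, 2],
                   which = "superimposed"))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$which)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "mm", y = "mm", colour = NULL,
                  subtitle = sprintf("Procrustes dissimilarity %.4g",
                                     object$dissimilarity)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.loo_result <- function(object, ...) {
  ggplot2::ggplot(object$by_species,
                  ggplot2::aes(.data$method, .data$species, fill = .data$accuracy_pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f%%", .data$accuracy_pct)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "LOO accuracy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.vdm_measurements <- function(object, ...) {
  xy <- attr(object, "outline_mm")
  df <- tibble::tibble(x = xy[, 1], y = xy[, 2])
  seg <- tibble::as_tibble(object)
  seg <- seg[!is.na(seg$value_mm), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(colour = "grey40") +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x1, y = .data$y1,
                                       xend = .data$x2, yend = .data$y2,
                                       colour = .data$segment),
                          linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "mm", y = "mm", colour = "segment") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.exemplar_cluster <- function(object, ...) {
  hc <- stats::hclust(stats::as.dist(object$distances), method = object$linkage)
  dend <- stats::as.dendrogram(hc)
  seg <- dendro_segments(dend)
  lab <- tibble::tibble(x = seq_along(hc$labels),
                        label = hc$labels[hc$order])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg, ggplot2::aes(x = .data$x, y = .data$y,
                                                   xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_text(data = lab, ggplot2::aes(.data$x, 0, label = .data$label),
                       angle = 90, hjust = 1.05, size = 3) +
    ggplot2::scale_y_continuous("Procrustes dissimilarity at merge") +
    ggplot2::scale_x_continuous(NULL, breaks = NULL) +
    ggplot2::expand_limits(y = -max(hc$height) / 3) +
    ggplot2::labs(caption = object$disclaimer) +
    ggplot2::theme_minimal()
}

# segment table of a dendrogram (leaf positions 1..n in plotting order)
dendro_segments <- function(d) {
  segs <- list()
  walk <- function(node) {
    if (is.leaf(node)) return(c(attr(node, "x.pos"), 0))
    kids <- lapply(seq_along(node), function(i) walk(node[[i]]))
    h <- attr(node, "height")
    xs <- vapply(kids, `[`, numeric(1), 1)
    for (k in seq_along(kids))
      segs[[length(segs) + 1L]] <<- c(xs[k], kids[[k]][2], xs[k], h)
    segs[[length(segs) + 1L]] <<- c(min(xs), h, max(xs), h)
    c(mean(range(xs)), h)
  }
  # assign leaf x positions in dendrogram order
  x <- 0
  d <- stats::dendrapply(d, function(node) {
    if (is.leaf(node)) { x <<- x + 1; attr(node, "x.pos") <- x }
    node
  })
  walk(d)
  m <- do.call(rbind, segs)
  tibble::tibble(x = m[, 1], y = m[, 2], xend = m[, 3], yend = m[, 4])
}
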