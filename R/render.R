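# Rendering synthetic molars to rasters, in the two dialects the pipeline
# accepts: "filled" (a solid dark molar on white, emulating a cleaned
# photograph) and "stroke_cement" (a thin dark outline stroke with filled
# cement blobs inside the re-entrant folds, emulating a literature drawing).

#' Render a synthetic molar to a raster
#'
#' Maps the specimen outline (mm, y up) into pixel coordinates at the given
#' calibration and rasterizes it. The ground truth -- the outline polyline and
#' every feature label, in both px and mm of the rendered frame -- is attached
#' so the image-processing pipeline can be scored against it.
#'
#' @param specimen A `molar_specimen` or `molar_template`.
#' @param scale mm per pixel (> 0).
#' @param style `"filled"` (photo dialect) or `"stroke_cement"` (drawing
#'   dialect).
#' @param stroke_px Stroke width of the drawing dialect, px (odd; default 3).
#' @param cement Draw cement blobs inside the folds (drawing dialect only).
#' @param cement_radius_mm Radius of the cement blobs.
#' @param margin_px White margin around the foreground.
#' @return A `molar_render`: list with `grey` (matrix in [0,1], rows = y),
#'   `truth` (list: `outline_px`, `labels_px`, `labels_mm`, `area_px`,
#'   `sigma`, `seed`, `preset`), `scale`, `style`, `source_kind`.
#' @export
render_molar <- function(specimen, scale = 0.01,
                         style = c("filled", "stroke_cement"),
                         stroke_px = 3L, cement = TRUE,
                         cement_radius_mm = 0.06, margin_px = 10L) {
  style <- match.arg(style)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a single positive mm-per-pixel value")
  xy <- specimen$outline
  x0 <- min(xy[, 1]); y1 <- max(xy[, 2])
  to_px <- function(m) cbind((m[, 1] - x0) / scale + margin_px + 1,
                             (y1 - m[, 2]) / scale + margin_px + 1)
  px <- to_px(xy)
  nc <- ceiling(max(px[, 1])) + margin_px
  nr <- ceiling(max(px[, 2])) + margin_px

  if (style == "filled") {
    mask <- scanline_fill(px, nr, nc)
  } else {
    # Euclidean stroke: pixels within stroke_px/2 of the outline polyline
    dense <- resample_spacing(px, 0.25, closed = TRUE)
    ptmask <- matrix(FALSE, nr, nc)
    ij <- cbind(pmin(nr, pmax(1, round(dense[, 2]))),
                pmin(nc, pmax(1, round(dense[, 1]))))
    ptmask[ij] <- TRUE
    d_to_line <- unebi(EBImage::distmap(ebi((!ptmask) * 1)))
    mask <- d_to_line <= stroke_px / 2
    if (cement) {
      labs <- specimen$labels
      folds <- labs[grepl("^(BRA|LRA)", names(labs))]
      nout <- outward_normals(xy)
      tooth <- scanline_fill(px, nr, nc)  # cement never crosses the enamel line
      for (k in folds) {
        # blob centred a little outside the outline, inside the fold cavity,
        # overlapping the stroke so it stays attached (as drawn in figures);
        # clipped to the exterior of the tooth polygon
        ctr_mm <- xy[k, ] + nout[k, ] * (cement_radius_mm * 0.7)
        ang <- seq(0, 2 * pi, length.out = 40L)
        circ <- cbind(ctr_mm[1] + cement_radius_mm * cos(ang),
                      ctr_mm[2] + cement_radius_mm * sin(ang))
        mask <- mask | (scanline_fill(to_px(circ), nr, nc) & !tooth)
      }
    }
  }
  grey <- matrix(1, nr, nc)
  grey[mask] <- 0
  truth <- list(
    outline_px = px, labels_px = to_px(xy[specimen$labels, , drop = FALSE]),
    labels_mm = xy[specimen$labels, , drop = FALSE],
    label_names = names(specimen$labels),
    label_index = unname(specimen$labels),
    area_px = abs(shoelace_area(px)),
    sigma = specimen$sigma %||% 0, seed = specimen$seed %||% NA_integer_,
    preset = specimen$preset
  )
  structure(list(grey = grey, truth = truth, scale = scale, style = style,
                 source_kind = if (style == "filled") "photo" else "drawing"),
            class = "molar_render")
}

outward_normals <- function(xy) {
  n <- nrow(xy)
  sm <- smooth_closed(xy, 9L)
  tx <- sm[c(2:n, 1L), 1] - sm[c(n, 1:(n - 1L)), 1]
  ty <- sm[c(2:n, 1L), 2] - sm[c(n, 1:(n - 1L)), 2]
  nl <- sqrt(tx^2 + ty^2); nl[nl == 0] <- 1
  cbind(ty / nl, -tx / nl)   # CCW polygon: outward = right of travel
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.molar_render <- function(x, ...) {
  cat("<molar_render '", x$truth$preset, "'> ", ncol(x$grey), "x", nrow(x$grey),
      " px at ", x$scale, " mm/px, ", x$style, "\n", sep = "")
  invisible(x)
}

#' Write a rendered molar and its ground truth to disk
#'
#' Writes the raster as PNG and the truth sidecar (outline polyline, labels in
#' px and mm, generator parameters) as JSON.
#'
#' @param render A `molar_render`.
#' @param png_path,json_path Output paths; `json_path` defaults to the PNG
#'   path with extension `.truth.json`.
#' @return `png_path`, invisibly.
#' @export
write_render <- function(render, png_path,
                         json_path = sub("\\.png$", ".truth.json", png_path)) {
  stopifnot(inherits(render, "molar_render"))
  EBImage::writeImage(ebi(render$grey), png_path, type = "png")
  truth <- render$truth
  truth$outline_px <- round(truth$outline_px, 3)  # keep sidecars compact
  truth$scale <- render$scale
  truth$style <- render$style
  jsonlite::write_json(truth, json_path, auto_unbox = TRUE, digits = 9)
  invisible(png_path)
}

#' Convert a rendered molar to an occlusal image in memory
#'
#' Convenience wrapper equivalent to writing the render to PNG and loading it
#' back with [load_specimen_image()]; the render is already in canonical pose.
#'
#' @param render A `molar_render`.
#' @return An `occlusal_image` with `oriented = TRUE`.
#' @export
render_to_image <- function(render) {
  stopifnot(inherits(render, "molar_render"))
  as_occlusal_image(render$grey, render$scale,
                    source_kind = render$source_kind, oriented = TRUE)
}
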