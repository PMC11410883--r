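# Loading, calibration and canonical orientation of single-molar images.
# Raster I/O, thresholding, connected components and resampling-based
# rotation are delegated to EBImage; this module owns the calibration and
# pose conventions.
#
# Conventions: the grey image is a plain R matrix `grey[row = y, col = x]`
# with values in [0, 1] (0 = black), y increasing downwards, pixel centres at
# integer coordinates. Foreground is dark-on-light unless `invert = TRUE`.
# Canonical pose: anterior (cap) leftmost, posterior lobe rightmost, buccal
# (labial) side at the bottom of the screen.

ebi <- function(m) EBImage::Image(t(m))
unebi <- function(img) t(EBImage::imageData(img))

#' Construct an occlusal image from an in-memory grey matrix
#'
#' @param grey Numeric matrix in [0, 1], rows = y (down), cols = x.
#' @param scale Calibration in mm per pixel (> 0).
#' @param source_kind `"photo"` (continuous tone, Otsu threshold) or
#'   `"drawing"` (line art, fixed 50% threshold).
#' @param invert Foreground is light-on-dark instead of dark-on-light.
#' @param threshold Override the binarization threshold (in grey units).
#' @param oriented Mark the image as already being in canonical pose.
#' @return An `occlusal_image`: list with `grey`, logical `mask`, `scale`,
#'   `source_kind`, `threshold`, `oriented`.
#' @export
as_occlusal_image <- function(grey, scale, source_kind = c("photo", "drawing"),
                              invert = FALSE, threshold = NULL, oriented = FALSE) {
  source_kind <- match.arg(source_kind)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("scale must be a single positive mm-per-pixel value")
  grey <- pmin(pmax(grey, 0), 1)  # argument order preserves the dim attribute
  if (is.null(threshold)) {
    threshold <- if (source_kind == "photo")
      as.numeric(EBImage::otsu(ebi(grey), range = c(0, 1))) else 0.5
  }
  mask <- if (invert) grey > threshold else grey < threshold
  ncomp <- max(EBImage::bwlabel(ebi(mask * 1)))
  if (ncomp == 0L) stop("background not cleaned: no foreground component found")
  if (ncomp > 1L) stop("background not cleaned: ", ncomp,
                       " foreground components found (expected exactly 1)")
  structure(list(grey = grey, mask = mask, scale = scale,
                 source_kind = source_kind, threshold = threshold,
                 invert = invert, oriented = oriented),
            class = "occlusal_image")
}

#' Load and calibrate a single-molar image
#'
#' Reads a PNG/TIFF/JPEG raster whose background has already been cleaned
#' (uniform near-white or transparent), flattens any alpha channel against
#' white, converts to greyscale, binarizes (Otsu for photos, fixed 50% for
#' drawings) and verifies that exactly one foreground component remains.
#'
#' @param path Path to the image file.
#' @inheritParams as_occlusal_image
#' @return An `occlusal_image`.
#' @export
load_specimen_image <- function(path, scale, source_kind = c("photo", "drawing"),
                                invert = FALSE, threshold = NULL, oriented = FALSE) {
  source_kind <- match.arg(source_kind)
  if (!file.exists(path)) stop("cannot read image: no such file '", path, "'")
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("unreadable image '", path, "': ",
                                           conditionMessage(e)))
  a <- EBImage::imageData(img)
  grey <- if (length(dim(a)) == 2L) {
    t(a)
  } else {
    nc <- dim(a)[3]
    flat <- function(ch, alpha) ch * alpha + (1 - alpha)  # flatten on white
    if (nc == 2L) t(flat(a[, , 1], a[, , 2]))
    else {
      alpha <- if (nc >= 4L) a[, , 4] else 1
      lum <- 0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
      t(flat(lum, alpha))
    }
  }
  as_occlusal_image(grey, scale, source_kind, invert, threshold, oriented)
}

#' Rotate and flip an occlusal image into canonical pose
#'
#' Applies a rotation about the image centre followed by optional horizontal /
#' vertical flips, then re-binarizes. Positive angles rotate the foreground
#' counter-clockwise on screen. Photos are resampled bilinearly; drawings with
#' nearest-neighbour so strokes stay thin. The mm-per-pixel scale is
#' unchanged.
#'
#' @param img An `occlusal_image`.
#' @param rotation_deg Rotation in degrees (about the image centre).
#' @param flip_horizontal,flip_vertical Mirror after rotation.
#' @return The reoriented `occlusal_image`, with `oriented = TRUE`.
#' @export
normalize_orientation <- function(img, rotation_deg = 0,
                                  flip_horizontal = FALSE, flip_vertical = FALSE) {
  stopifnot(inherits(img, "occlusal_image"))
  g <- img$grey
  if (rotation_deg %% 360 != 0) {
    filt <- if (img$source_kind == "drawing") "none" else "bilinear"
    # EBImage rotates clockwise in its own frame; our transpose convention
    # makes a positive angle counter-clockwise on screen.
    rot <- EBImage::rotate(ebi(g), angle = rotation_deg, filter = filt,
                           bg.col = 1)
    g <- unebi(rot)
    g <- pmin(pmax(g, 0), 1)
  }
  if (flip_horizontal) g <- g[, rev(seq_len(ncol(g))), drop = FALSE]
  if (flip_vertical) g <- g[rev(seq_len(nrow(g))), , drop = FALSE]
  as_occlusal_image(g, img$scale, img$source_kind, img$invert,
                    threshold = img$threshold, oriented = TRUE)
}

#' Suggest an orientation for a molar image (advisory heuristic)
#'
#' Estimates the rotation that brings the principal axis of the foreground to
#' horizontal, then inspects the re-entrant folds of the tentative outline:
#' the anterior half carries the fold field (more deep folds than the smooth
#' posterior lobe half), and in arvicoline m1 topology the lingual side has
#' one fold more than the buccal side, which resolves the vertical flip.
#' Explicit user flags always win; this is a convenience for batch runs.
#'
#' @param img An `occlusal_image`.
#' @return List with `rotation_deg`, `flip_horizontal`, `flip_vertical`, and
#'   `confident` (FALSE when the fold analysis failed and only the principal
#'   axis was used).
#' @export
auto_orient <- function(img) {
  stopifnot(inherits(img, "occlusal_image"))
  yx <- which(img$mask, arr.ind = TRUE)
  P <- cbind(x = yx[, 2], y = yx[, 1])
  P <- sweep(P, 2, colMeans(P))
  v <- eigen(crossprod(P) / nrow(P), symmetric = TRUE)$vectors[, 1]
  if (v[1] < 0) v <- -v                  # canonical sign: rotation in (-90, 90]
  rot <- -atan2(-v[2], v[1]) * 180 / pi  # y-down frame -> screen angle
  cand <- normalize_orientation(img, rot)
  res <- list(rotation_deg = rot, flip_horizontal = FALSE,
              flip_vertical = FALSE, confident = FALSE)
  feats <- tryCatch({
    tr <- extract_outline(cand)
    detect_feature_points(tr, require_arvicoline = FALSE)
  }, error = function(e) NULL)
  if (is.null(feats)) return(res)
  xy <- trace_xy(tr)
  deep <- c(feats$buccal_reentrants, feats$lingual_reentrants)
  if (length(deep) >= 3L) {
    # anterior = the narrower end (the cap is slimmer than the posterior lobe)
    xr <- range(xy[, 1]); band <- 0.15 * diff(xr)
    width_at <- function(sel) if (any(sel)) diff(range(xy[sel, 2])) else Inf
    w_left <- width_at(xy[, 1] <= xr[1] + band)
    w_right <- width_at(xy[, 1] >= xr[2] - band)
    if (w_left > w_right) res$flip_horizontal <- TRUE
    # lingual side carries more folds and must end up at the top of the screen
    nb <- length(feats$buccal_reentrants); nl <- length(feats$lingual_reentrants)
    if (nb > nl) res$flip_vertical <- TRUE
    res$confident <- TRUE
  }
  res
}

#' @export
print.occlusal_image <- function(x, ...) {
  cat("<occlusal_image> ", ncol(x$grey), "x", nrow(x$grey), " px, ",
      x$scale, " mm/px, ", x$source_kind,
      if (x$oriented) ", oriented" else "",
      ", foreground ", sum(x$mask), " px\n", sep = "")
  invisible(x)
}
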