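# Outline extraction, anatomical feature detection, anterior semiperimeter
# isolation and 200-landmark resampling.
#
# An `outline_trace` is a closed chain of ~unit-spaced points in pixel
# coordinates (x right, y down, 1-based pixel centres), traversed
# counter-clockwise in the y-up mathematical frame, carrying the mm-per-pixel
# scale of its source image.

new_outline_trace <- function(xy, scale, source_kind) {
  structure(list(xy = xy, scale = scale, source_kind = source_kind),
            class = "outline_trace")
}

trace_xy <- function(trace) trace$xy

#' @export
print.outline_trace <- function(x, ...) {
  cat("<outline_trace> ", nrow(x$xy), " points, perimeter ",
      round(poly_perimeter(x$xy), 1), " px (",
      signif(poly_perimeter(x$xy) * x$scale, 4), " mm), ", x$source_kind, "\n", sep = "")
  invisible(x)
}

#' Extract the closed outline of the molar
#'
#' Photo mode traces the boundary of the (hole-filled) foreground mask, which
#' approximates the inner-enamel edge of a cleaned photograph. Drawing mode
#' recovers the midline of the drawn stroke: the enclosed interior region
#' (the hole bounded by the stroke's inner edge) is located, dilated by the
#' estimated stroke half-width, and its boundary traced. Cement areas drawn
#' inside the re-entrant folds never touch the interior hole, so they cannot
#' perturb the midline. The chain is resampled to unit (1 px) spacing and
#' oriented counter-clockwise in the y-up frame.
#'
#' @param img An `occlusal_image` in canonical pose.
#' @param enamel_offset_px Optional inward offset (morphological erosion of
#'   the photo mask) standing in for the interior-of-enamel edge; default 0.
#' @return An `outline_trace`.
#' @export
extract_outline <- function(img, enamel_offset_px = 0L) {
  stopifnot(inherits(img, "occlusal_image"))
  mask <- img$mask
  nr <- nrow(mask); nc <- ncol(mask)
  if (any(mask[1, ]) || any(mask[nr, ]) || any(mask[, 1]) || any(mask[, nc]))
    stop("clipped specimen: foreground touches the image border")

  if (img$source_kind == "photo") {
    m <- unebi(EBImage::fillHull(ebi(mask * 1)))
    if (enamel_offset_px > 0) {
      m <- unebi(EBImage::erode(ebi(m), EBImage::makeBrush(2L * enamel_offset_px + 1L, "disc")))
      if (sum(m) == 0) stop("enamel offset erased the foreground")
    }
    chain <- largest_contour(m)
  } else {
    bg <- EBImage::bwlabel(ebi((!mask) * 1))
    labs <- unebi(bg)
    border_labels <- unique(c(labs[1, ], labs[nr, ], labs[, 1], labs[, nc]))
    inner_labels <- setdiff(seq_len(max(labs)), c(0L, border_labels))
    if (!length(inner_labels))
      stop("outline not closed: the drawing stroke does not enclose an interior")
    sizes <- tabulate(labs[labs %in% inner_labels], nbins = max(labs))
    interior <- labs == which.max(sizes)
    # stroke width: exterior distance at the interior-adjacent edge of the
    # stroke (pockets sealed off by cement count as non-exterior)
    non_ext <- mask | interior
    for (lab in setdiff(inner_labels, which.max(sizes))) non_ext <- non_ext | (labs == lab)
    d_ext <- unebi(EBImage::distmap(ebi(non_ext * 1)))
    inner_edge <- mask & unebi(EBImage::dilate(ebi(interior * 1),
                                               EBImage::makeBrush(3L, "box"))) > 0
    if (!any(inner_edge)) stop("outline not closed: no stroke adjacent to the interior")
    w_est <- stats::median(d_ext[inner_edge])
    r <- max(1L, round((w_est - 1) / 2))
    mid <- unebi(EBImage::dilate(ebi(interior * 1),
                                 EBImage::makeBrush(2L * r + 1L, "disc")))
    chain <- largest_contour(mid)
  }

  # one corner-cutting pass removes most of the staircase length inflation of
  # the integer pixel chain (moves points by <= 0.25 px); the point count is
  # then set from the arc length of a smoothed copy, whose length is free of
  # the residual half-pixel oscillation, giving a ~1 px spaced chain whose
  # count matches the true curve length. Canonical traversal is
  # counter-clockwise in the y-up frame (negative shoelace in pixel coords).
  chain <- chaikin_once(chain)
  chain <- resample_spacing(chain, 1, closed = TRUE)
  n_tr <- max(8L, round(poly_perimeter(smooth_closed(chain, 7L))))
  chain <- resample_polyline(chain, n_tr, closed = TRUE)
  if (shoelace_area(chain) > 0) chain <- chain[rev(seq_len(nrow(chain))), , drop = FALSE]

  if (img$source_kind == "photo") {
    # boundary pixel centres lie half a pixel inside the continuous edge
    yup <- cbind(chain[, 1], -chain[, 2])
    nrm <- outward_normals(yup)
    chain <- chain + 0.5 * cbind(nrm[, 1], -nrm[, 2])
  }
  if (img$source_kind == "drawing") {
    # bias correction: the integer dilation radius leaves the traced boundary
    # inside the true stroke midline, where the across-stroke distance should
    # be (w+1)/2; at sharp convex corners the deficit grows like
    # 1/sin(theta/2). Measure it per point from the across-stroke distance
    # map (cement cores count as "beyond the stroke" so blobs cannot inflate
    # it), smooth along the chain, clamp, and shift outward along the normals.
    dm_fg <- unebi(EBImage::distmap(ebi(mask * 1)))
    stroke_only <- mask & (dm_fg <= (w_est + 1) / 2 + 0.51)
    d_cross <- unebi(EBImage::distmap(ebi((stroke_only | (non_ext & !mask)) * 1)))
    ij <- cbind(pmin(nrow(mask), pmax(1, round(chain[, 2]))),
                pmin(ncol(mask), pmax(1, round(chain[, 1]))))
    bias <- stats::median(d_cross[ij]) - (w_est + 1) / 2
    if (is.finite(bias) && abs(bias) > 0.2) {
      yup <- cbind(chain[, 1], -chain[, 2])
      nrm <- outward_normals(yup)
      chain <- chain + bias * cbind(nrm[, 1], -nrm[, 2])
    }
  }
  new_outline_trace(chain, img$scale, img$source_kind)
}

# one iteration of Chaikin corner cutting on a closed chain
chaikin_once <- function(xy) {
  n <- nrow(xy)
  nxt <- c(2:n, 1L)
  out <- matrix(0, 2L * n, 2L)
  out[seq(1L, 2L * n, 2L), ] <- 0.75 * xy + 0.25 * xy[nxt, , drop = FALSE]
  out[seq(2L, 2L * n, 2L), ] <- 0.25 * xy + 0.75 * xy[nxt, , drop = FALSE]
  out
}

# circular moving average of a numeric vector
smooth_circular <- function(v, window = 9L) {
  k <- (as.integer(window) - 1L) %/% 2L
  n <- length(v)
  idx <- outer(seq_len(n), (-k):k, `+`)
  idx <- ((idx - 1L) %% n) + 1L
  rowMeans(matrix(v[idx], n))
}

# ordered boundary chain (1-based pixel coords) of the largest object in a
# binary matrix, via EBImage's contour follower (returns 0-based coordinates)
largest_contour <- function(m) {
  oc <- EBImage::ocontour(EBImage::bwlabel(ebi(m * 1)))
  if (!length(oc)) stop("no contour found")
  chain <- oc[[which.max(vapply(oc, nrow, 1L))]]
  cbind(chain[, 1] + 1, chain[, 2] + 1)
}

#' Detect anatomical feature points on a closed outline
#'
#' Works in canonical pose. The trace is smoothed with a circular moving
#' average, and re-entrant folds are found as maximal runs of convexity-defect
#' depth (distance to the bracketing convex-hull chord) exceeding a threshold;
#' the deepest point of each run is the re-entrant's deep point. Folds are
#' numbered 1, 2, ... from the posterior (max-x) end separately on the buccal
#' (lower) and lingual (upper) chains. Salients (triangle apices) are the
#' vertical extrema between consecutive same-side folds. The segment-'a'
#' anchors are the deep points of BRA3 and LRA4.
#'
#' @param trace An `outline_trace` in canonical pose.
#' @param smooth_window Circular moving-average window (samples; default 7).
#' @param min_depth_frac Minimum fold depth as a fraction of the outline
#'   length. The default 0.02 sits well below the anatomical fold depth of a
#'   deeply folded arvicoline m1 (whose perimeter grows with its folds, so
#'   fold depth is only ~3% of outline length) while rejecting noise dents.
#' @param require_arvicoline Error when fewer than 3 buccal or 4 lingual folds
#'   are found (the counts needed to anchor segment 'a').
#' @return An `outline_features` object: indices into the trace for `apex`,
#'   `posterior`, `buccal_reentrants`, `lingual_reentrants`,
#'   `buccal_salients`, `lingual_salients`, `a_endpoint_buccal`,
#'   `a_endpoint_lingual`, plus the per-point `depth` profile used.
#' @export
detect_feature_points <- function(trace, smooth_window = 7L,
                                  min_depth_frac = 0.02,
                                  require_arvicoline = TRUE) {
  stopifnot(inherits(trace, "outline_trace"))
  raw <- trace_xy(trace)
  n <- nrow(raw)
  yup <- cbind(raw[, 1], -raw[, 2])
  sm <- smooth_closed(yup, smooth_window)

  perim <- poly_perimeter(sm)
  thr <- min_depth_frac * perim
  depth <- defect_depth(sm)

  deep_runs <- circular_runs(depth > thr)
  if (!length(deep_runs)) {
    if (require_arvicoline) stop("insufficient re-entrants; cannot anchor segment a ",
                                 "(no folds deeper than ", signif(thr, 3), " px found)")
    deep_idx <- integer(0)
  } else {
    # deep point: centre of the near-maximum plateau of the depth profile,
    # which is stable on rounded fold tips where the raw argmax wanders
    deep_idx <- vapply(deep_runs, function(run) {
      top <- run[depth[run] >= max(depth[run]) - 0.75]
      top[ceiling(length(top) / 2)]
    }, 1L)
  }

  apex <- which.min(sm[, 1])
  posterior <- which.max(sm[, 1])

  # the two open chains between posterior and apex; buccal = lower (smaller y-up)
  fwd <- if (posterior <= apex) posterior:apex else c(posterior:n, 1:apex)
  bwd <- setdiff(seq_len(n), fwd)
  side_of <- integer(n)          # 1 = chain A, 2 = chain B
  side_of[fwd] <- 1L; side_of[bwd] <- 2L
  meany <- c(mean(sm[fwd, 2]), if (length(bwd)) mean(sm[bwd, 2]) else Inf)
  buccal_side <- which.min(meany)

  # order each side's folds by arc distance from the posterior point
  pos_along <- arc_positions(sm)
  from_post <- (pos_along - pos_along[posterior]) %% perim
  dist_post <- pmin(from_post, perim - from_post)
  split_folds <- function(side) {
    k <- deep_idx[side_of[deep_idx] == side & deep_idx != apex & deep_idx != posterior]
    k[order(dist_post[k])]
  }
  bra <- split_folds(buccal_side)
  lra <- split_folds(if (buccal_side == 1L) 2L else 1L)

  if (require_arvicoline && (length(bra) < 3L || length(lra) < 4L))
    stop("insufficient re-entrants; cannot anchor segment a (found ",
         length(bra), " buccal and ", length(lra), " lingual, need >= 3 and >= 4)")

  # salients: y extrema of the chain segment between consecutive same-side folds
  salients_between <- function(folds, lower) {
    if (length(folds) < 2L) return(integer(0))
    out <- integer(length(folds) - 1L)
    for (k in seq_len(length(folds) - 1L)) {
      i <- folds[k]; j <- folds[k + 1L]
      seg <- if (i <= j) i:j else c(i:n, 1:j)
      # take the branch not running around the far side of the tooth
      if (length(seg) > n / 2) seg <- rev(setdiff(seq_len(n), seg[-c(1, length(seg))]))
      out[k] <- if (lower) seg[which.min(sm[seg, 2])] else seg[which.max(sm[seg, 2])]
    }
    out
  }
  b_sal <- salients_between(bra, lower = TRUE)
  l_sal <- salients_between(lra, lower = FALSE)

  structure(list(
    apex = apex, posterior = posterior,
    buccal_reentrants = bra, lingual_reentrants = lra,
    buccal_salients = b_sal, lingual_salients = l_sal,
    a_endpoint_buccal = if (length(bra) >= 3L) bra[3L] else NA_integer_,
    a_endpoint_lingual = if (length(lra) >= 4L) lra[4L] else NA_integer_,
    depth = depth, depth_threshold = thr,
    smooth_window = smooth_window, min_depth_frac = min_depth_frac
  ), class = "outline_features")
}

# convexity-defect depth: distance of each point to the convex-hull chord
# bracketing it along the chain
defect_depth <- function(xy) {
  n <- nrow(xy)
  h <- sort(grDevices::chull(xy))
  depth <- numeric(n)
  hh <- c(h, h[1] + n)  # wrap
  for (k in seq_len(length(h))) {
    i <- hh[k]; j <- hh[k + 1L]
    if (j - i <= 1L) next
    seg <- ((i:(j)) - 1L) %% n + 1L
    A <- xy[((i - 1L) %% n) + 1L, ]; B <- xy[((j - 1L) %% n) + 1L, ]
    ab <- B - A; len2 <- sum(ab^2)
    if (len2 == 0) next
    dx <- xy[seg, 1] - A[1]; dy <- xy[seg, 2] - A[2]
    t <- pmin(1, pmax(0, (dx * ab[1] + dy * ab[2]) / len2))
    depth[seg] <- sqrt((dx - t * ab[1])^2 + (dy - t * ab[2])^2)
  }
  depth
}

# maximal runs of TRUE in a circular logical vector, as lists of indices
circular_runs <- function(flag) {
  n <- length(flag)
  if (all(flag)) return(list(seq_len(n)))
  if (!any(flag)) return(list())
  # rotate so the vector starts on a FALSE, then use rle
  start <- which(!flag)[1]
  rot <- c(start:n, seq_len(start - 1L))
  f <- flag[rot]
  r <- rle(f)
  ends <- cumsum(r$lengths); begins <- ends - r$lengths + 1L
  runs <- Map(function(b, e) rot[b:e], begins[r$values], ends[r$values])
  unname(runs)
}

#' @export
print.outline_features <- function(x, ...) {
  cat("<outline_features> ", length(x$buccal_reentrants), " BRA / ",
      length(x$lingual_reentrants), " LRA, ",
      length(x$buccal_salients), "+", length(x$lingual_salients), " salients",
      if (!is.na(x$a_endpoint_buccal)) ", segment-a anchored" else "", "\n", sep = "")
  invisible(x)
}

#' Manually anchor the segment-'a' endpoints
#'
#' Builds a minimal feature annotation from user-supplied endpoint
#' coordinates (px), for specimens where automatic fold detection fails.
#'
#' @param trace An `outline_trace`.
#' @param p_buccal,p_lingual Numeric length-2 vectors (x, y in pixel
#'   coordinates) near the intended deep points; snapped to the nearest trace
#'   point.
#' @return An `outline_features` with the anchors and apex set; fold and
#'   salient lists are empty.
#' @export
manual_a_endpoints <- function(trace, p_buccal, p_lingual) {
  xy <- trace_xy(trace)
  snap <- function(p) which.min((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2)
  structure(list(
    apex = which.min(xy[, 1]), posterior = which.max(xy[, 1]),
    buccal_reentrants = integer(0), lingual_reentrants = integer(0),
    buccal_salients = integer(0), lingual_salients = integer(0),
    a_endpoint_buccal = snap(p_buccal), a_endpoint_lingual = snap(p_lingual),
    depth = NULL, depth_threshold = NA_real_,
    smooth_window = NA_integer_, min_depth_frac = NA_real_
  ), class = "outline_features")
}

#' Isolate the anterior semiperimeter
#'
#' Returns the open sub-chain of the closed trace running from the buccal
#' segment-'a' endpoint, through the anterior apex, to the lingual endpoint
#' (the branch that carries T4..T7 and the anterior cap); the posterior part
#' of the molar is discarded. A warning attribute is set when the selected
#' branch is suspiciously short or long (< 20% or > 80% of the perimeter).
#'
#' @param trace An `outline_trace` in canonical pose.
#' @param ann An `outline_features` for the same trace.
#' @return n x 2 matrix of pixel coordinates, buccal endpoint first, with
#'   attributes `scale` and `suspicious`.
#' @export
anterior_semiperimeter <- function(trace, ann) {
  stopifnot(inherits(trace, "outline_trace"), inherits(ann, "outline_features"))
  if (is.na(ann$a_endpoint_buccal) || is.na(ann$a_endpoint_lingual))
    stop("annotation lacks segment-a endpoints")
  xy <- trace_xy(trace)
  poly <- tryCatch(
    chain_between(xy, ann$a_endpoint_buccal, ann$a_endpoint_lingual, ann$apex),
    error = function(e) stop("internal consistency error: apex not on either branch"))
  # canonical orientation: buccal endpoint first
  if (!all(poly[1, ] == xy[ann$a_endpoint_buccal, ]))
    poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  frac <- poly_perimeter(poly, closed = FALSE) / poly_perimeter(xy)
  suspicious <- frac < 0.20 || frac > 0.80
  if (suspicious)
    warning("suspicious split: anterior semiperimeter is ",
            round(100 * frac, 1), "% of the outline")
  attr(poly, "scale") <- trace$scale
  attr(poly, "suspicious") <- suspicious
  poly
}

#' Resample a semiperimeter to equally spaced landmarks
#'
#' Places `n` points at equal arc-length spacing along the open polyline
#' (endpoints preserved exactly), converts pixel coordinates to mm with the
#' calibration scale, and flips the y axis into the y-up mathematical frame.
#'
#' @param poly Open polyline in pixel coordinates (e.g. from
#'   [anterior_semiperimeter()]).
#' @param n Number of landmarks (200 by convention).
#' @param scale mm per pixel; defaults to the polyline's `scale` attribute.
#' @param specimen_id,species,source_kind Metadata columns of the output.
#' @return A landmarks tibble: `specimen_id`, `species`, `source_kind`,
#'   `point_index`, `x_mm`, `y_mm` (n rows).
#' @export
resample_landmarks <- function(poly, n = 200L, scale = attr(poly, "scale"),
                               specimen_id = "", species = "",
                               source_kind = "") {
  stopifnot(is.matrix(poly), ncol(poly) == 2, n >= 2L)
  if (is.null(scale)) stop("scale (mm per pixel) is required")
  if (nrow(poly) < n)
    stop("semiperimeter too short: ", nrow(poly), " points for ", n, " landmarks")
  # spacing is measured on a lightly smoothed copy of the chain, which is free
  # of pixel-staircase length noise; the emitted points stay on the raw chain.
  # The chain is first brought to unit spacing so the smoothing scale (px) is
  # the same regardless of how densely the input was sampled.
  first <- poly[1, ]; last <- poly[nrow(poly), ]
  poly <- resample_spacing(poly, 1, closed = FALSE)
  poly[1, ] <- first; poly[nrow(poly), ] <- last
  sm <- smooth_open(poly, 7L)
  s_sm <- c(0, cumsum(seg_lengths(sm, closed = FALSE)))
  total <- s_sm[length(s_sm)]
  target <- seq(0, total, length.out = n)
  keep <- c(TRUE, diff(s_sm) > 0)
  lm <- cbind(stats::approx(s_sm[keep], poly[keep, 1], xout = target, rule = 2)$y,
              stats::approx(s_sm[keep], poly[keep, 2], xout = target, rule = 2)$y)
  lm[1, ] <- poly[1, ]
  lm[n, ] <- poly[nrow(poly), ]
  tibble::tibble(specimen_id = specimen_id, species = species,
                 source_kind = source_kind, point_index = seq_len(n),
                 x_mm = lm[, 1] * scale, y_mm = -lm[, 2] * scale)
}
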