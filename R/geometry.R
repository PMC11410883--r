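# Low-level polyline / polygon geometry shared by the generator, the outline
# extractor and the index measurements. All functions take plain n x 2
# matrices; frames (pixel y-down vs mm y-up) are the caller's business.

seg_lengths <- function(xy, closed = FALSE) {
  n <- nrow(xy)
  nxt <- if (closed) c(2:n, 1L) else 2:n
  cur <- if (closed) 1:n else 1:(n - 1L)
  sqrt((xy[nxt, 1] - xy[cur, 1])^2 + (xy[nxt, 2] - xy[cur, 2])^2)
}

poly_perimeter <- function(xy, closed = TRUE) sum(seg_lengths(xy, closed))

shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

#' @keywords internal
#' @noRd
resample_polyline <- function(xy, n, closed = FALSE) {
  stopifnot(n >= 2L, nrow(xy) >= 2L)
  if (closed && !all(xy[1, ] == xy[nrow(xy), ])) xy <- rbind(xy, xy[1, ])
  s <- c(0, cumsum(seg_lengths(xy, closed = FALSE)))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate polyline: zero length")
  target <- if (closed) seq(0, total, length.out = n + 1L)[1:n]
            else seq(0, total, length.out = n)
  # drop duplicated vertices so approx() sees strictly increasing s
  keep <- c(TRUE, diff(s) > 0)
  out <- cbind(
    stats::approx(s[keep], xy[keep, 1], xout = target, rule = 2)$y,
    stats::approx(s[keep], xy[keep, 2], xout = target, rule = 2)$y
  )
  if (!closed) { # endpoints exact
    out[1, ] <- xy[1, ]
    out[n, ] <- xy[nrow(xy), ]
  }
  out
}

# resample a chain to (approximately) unit spacing `h`
resample_spacing <- function(xy, h, closed = FALSE) {
  total <- poly_perimeter(xy, closed)
  n <- max(if (closed) 8L else 2L, round(total / h))
  resample_polyline(xy, n, closed)
}

# moving-average smoothing of an open chain; the window shrinks symmetrically
# near the ends so the endpoints stay fixed
smooth_open <- function(xy, window = 7L) {
  n <- nrow(xy)
  k <- (as.integer(window) - 1L) %/% 2L
  if (k < 1L || n < 3L) return(xy)
  cs <- rbind(c(0, 0), apply(xy, 2, cumsum))
  out <- xy
  i <- seq_len(n)
  kk <- pmin(k, i - 1L, n - i)
  lo <- i - kk; hi <- i + kk
  out[, 1] <- (cs[hi + 1L, 1] - cs[lo, 1]) / (hi - lo + 1L)
  out[, 2] <- (cs[hi + 1L, 2] - cs[lo, 2]) / (hi - lo + 1L)
  out
}

# circular moving average smoothing of a closed chain
smooth_closed <- function(xy, window = 7L) {
  window <- as.integer(window)
  if (window <= 1L) return(xy)
  n <- nrow(xy)
  k <- (window - 1L) %/% 2L
  idx <- outer(seq_len(n), (-k):k, `+`)
  idx <- ((idx - 1L) %% n) + 1L
  cbind(rowMeans(matrix(xy[idx, 1], n)), rowMeans(matrix(xy[idx, 2], n)))
}

# squared euclidean cross-distance matrix between two n x 2 / m x 2 sets
cross_dist2 <- function(A, B) {
  outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
}

# directed min distances from each point of A to the point set B
min_dist_to_set <- function(A, B) {
  d2 <- cross_dist2(A, B)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Symmetric point-set Hausdorff distance
#'
#' The classical Hausdorff distance between two finite 2-D point sets:
#' the largest distance from any point of one set to the nearest point of the
#' other, symmetrized by taking the maximum over both directions. Used
#' throughout the test suite to compare extracted outlines with ground truth.
#'
#' @param a,b Numeric matrices with two columns (x, y).
#' @return A single non-negative number in the units of the inputs.
#' @export
hausdorff_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 2, ncol(b) == 2, nrow(a) > 0, nrow(b) > 0)
  max(max(min_dist_to_set(a, b)), max(min_dist_to_set(b, a)))
}

# distance from points P to a polygon boundary given as closed vertex matrix
dist_to_polygon <- function(P, V) {
  n <- nrow(V)
  A <- V
  B <- V[c(2:n, 1L), , drop = FALSE]
  ab <- B - A
  len2 <- rowSums(ab^2)
  len2[len2 == 0] <- 1e-300
  # t = clamp(((p - a) . ab) / |ab|^2)
  out <- rep(Inf, nrow(P))
  for (j in seq_len(n)) {
    dx <- P[, 1] - A[j, 1]; dy <- P[, 2] - A[j, 2]
    t <- pmin(1, pmax(0, (dx * ab[j, 1] + dy * ab[j, 2]) / len2[j]))
    ex <- dx - t * ab[j, 1]; ey <- dy - t * ab[j, 2]
    out <- pmin(out, ex * ex + ey * ey)
  }
  sqrt(out)
}

# depth of every vertex of a closed chain below its own convex hull boundary
hull_depth <- function(xy) {
  h <- grDevices::chull(xy)
  dist_to_polygon(xy, xy[h, , drop = FALSE])
}

# do any two non-adjacent edges of the closed polygon intersect?
# checked on a decimated copy (speed); exact segment-intersection predicate.
is_simple_polygon <- function(xy, max_vertices = 400L) {
  if (nrow(xy) > max_vertices) xy <- resample_polyline(xy, max_vertices, closed = TRUE)
  n <- nrow(xy)
  A <- xy
  B <- xy[c(2:n, 1L), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]  # skip edges adjacent to edge 1
    if (!length(js)) next
    d1 <- cross(A[i, 1], A[i, 2], B[i, 1], B[i, 2], A[js, 1], A[js, 2])
    d2 <- cross(A[i, 1], A[i, 2], B[i, 1], B[i, 2], B[js, 1], B[js, 2])
    d3 <- cross(A[js, 1], A[js, 2], B[js, 1], B[js, 2], rep(A[i, 1], length(js)), rep(A[i, 2], length(js)))
    d4 <- cross(A[js, 1], A[js, 2], B[js, 1], B[js, 2], rep(B[i, 1], length(js)), rep(B[i, 2], length(js)))
    hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(hit)) return(FALSE)
  }
  TRUE
}

# even-odd scanline rasterization of a closed polygon given in pixel
# coordinates (x right, y down, pixel centres at integers). Returns a logical
# nrow x ncol matrix (rows = y). Hand-rolled: no installed package rasterizes
# polygons to a matrix.
scanline_fill <- function(poly_px, nrow_px, ncol_px) {
  V <- poly_px
  if (all(V[1, ] == V[nrow(V), ])) V <- V[-nrow(V), , drop = FALSE]
  n <- nrow(V)
  x1 <- V[, 1]; y1 <- V[, 2]
  x2 <- V[c(2:n, 1L), 1]; y2 <- V[c(2:n, 1L), 2]
  mask <- matrix(FALSE, nrow_px, ncol_px)
  for (r in seq_len(nrow_px)) {
    y0 <- r
    crosses <- (y1 <= y0 & y2 > y0) | (y2 <= y0 & y1 > y0)
    if (!any(crosses)) next
    t <- (y0 - y1[crosses]) / (y2[crosses] - y1[crosses])
    xs <- sort(x1[crosses] + t * (x2[crosses] - x1[crosses]))
    for (k in seq(1, length(xs) - 1, by = 2)) {
      lo <- ceiling(xs[k]); hi <- floor(xs[k + 1])
      if (hi >= lo) {
        lo <- max(1L, lo); hi <- min(ncol_px, hi)
        if (hi >= lo) mask[r, lo:hi] <- TRUE
      }
    }
  }
  mask
}

# arc-length positions of every vertex (closed chain), starting at vertex 1
arc_positions <- function(xy) c(0, cumsum(seg_lengths(xy, closed = TRUE)))[seq_len(nrow(xy))]

# circular index distance (number of steps along the chain)
circ_steps <- function(i, j, n) {
  d <- abs(i - j)
  pmin(d, n - d)
}
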