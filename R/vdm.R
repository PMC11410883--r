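# Automatic measurement of the Van der Meulen linear indices (L, W, a, b, c,
# e) and the La/Li asymmetry of the molar, with per-segment manual override
# and dependent recomputation. All measurements are taken on the full closed
# outline in canonical pose, in mm with the y axis up:
#
#   L  total anteroposterior length (x extent of the outline)
#   a  x distance from the segment-'a' line (through the BRA3 and LRA4 deep
#      points) to the anterior-most point
#   W  maximal width (y extent) of the part posterior to the 'a' line
#   b  maximal width of the T4/T5 region, between the 'a' line and the line
#      through the most anterior re-entrants (which bound the anterior cap)
#   c  maximal width of the anterior cap (anterior to that second line)
#   e  distance from the lowest point of T6 to the highest point of T7
#   La/Li  distances from the anterior apex to the buccal / lingual ends of
#      the 'a' line (molar asymmetry); chord by default, arc optional
#
# Segments whose defining features were not detected are reported absent with
# a reason -- never silently guessed.

vdm_segment_names <- c("L", "W", "a", "b", "c", "e", "La", "Li")

#' Measure the Van der Meulen indices and La/Li asymmetry
#'
#' @param trace An `outline_trace` of the full closed outline (canonical
#'   pose), or an n x 2 matrix of mm coordinates (y up) if `ann` carries mm
#'   anchors.
#' @param ann An `outline_features` annotation of the same trace.
#' @param scale mm per pixel; defaults to the trace's own calibration.
#' @param asymmetry `"chord"` (straight distance) or `"arc"` (along-outline
#'   length) definition of La/Li.
#' @return A `vdm_measurements` object: tibble with one row per segment
#'   (`segment`, `value_mm`, endpoint coordinates, `provenance`, `reason`),
#'   with the outline, apex and 'a'-line anchors stored as attributes. Derived
#'   ratios are always recomputed from the current segments via
#'   [vdm_ratios()].
#' @export
measure_indices <- function(trace, ann, scale = NULL,
                            asymmetry = c("chord", "arc")) {
  asymmetry <- match.arg(asymmetry)
  stopifnot(inherits(trace, "outline_trace"), inherits(ann, "outline_features"))
  scale <- scale %||% trace$scale
  pxy <- trace_xy(trace)
  xy <- cbind(pxy[, 1] * scale, -pxy[, 2] * scale)   # mm, y up

  idx_or_null <- function(i) if (is.null(i) || length(i) == 0L || is.na(i)) NULL else xy[i, ]
  n_b <- length(ann$buccal_reentrants); n_l <- length(ann$lingual_reentrants)
  anchors <- list(
    a_b = idx_or_null(ann$a_endpoint_buccal),
    a_l = idx_or_null(ann$a_endpoint_lingual),
    ac_b = if (n_b >= 1L) xy[ann$buccal_reentrants[n_b], ] else NULL,
    ac_l = if (n_l >= 1L) xy[ann$lingual_reentrants[n_l], ] else NULL,
    ac_is_a = (n_b > 0L && n_b == 3L) || (n_l > 0L && n_l == 4L),
    # T4/T6 are the 1st/2nd buccal salients anterior of BRA3; T5/T7 the
    # 1st/2nd lingual salients anterior of LRA4. Salient k sits between
    # fold k and fold k+1, so these are salients 3:4 (buccal) and 4:5 (lingual).
    t6 = if (length(ann$buccal_salients) >= 4L) xy[ann$buccal_salients[4L], ] else NULL,
    t7 = if (length(ann$lingual_salients) >= 5L) xy[ann$lingual_salients[5L], ] else NULL,
    arc_idx = list(a_b = ann$a_endpoint_buccal, a_l = ann$a_endpoint_lingual,
                   apex = ann$apex)
  )
  measure_vdm_points(xy, anchors, asymmetry = asymmetry, scale = scale)
}

# the measurement engine, shared with the generator's ground-truth path
measure_vdm_points <- function(xy, anchors, asymmetry = "chord", scale = NA_real_) {
  apex <- xy[which.min(xy[, 1]), ]
  rows <- list()
  seg_row <- function(segment, p1, p2, reason = NA_character_, value = NULL) {
    if (is.null(p1) || is.null(p2)) {
      tibble::tibble(segment = segment, value_mm = NA_real_,
                     x1 = NA_real_, y1 = NA_real_, x2 = NA_real_, y2 = NA_real_,
                     provenance = "absent", reason = reason)
    } else {
      v <- if (is.null(value)) sqrt(sum((p1 - p2)^2)) else value
      tibble::tibble(segment = segment, value_mm = v,
                     x1 = p1[1], y1 = p1[2], x2 = p2[1], y2 = p2[2],
                     provenance = "automatic", reason = NA_character_)
    }
  }

  # L: x extent
  pmin_x <- xy[which.min(xy[, 1]), ]; pmax_x <- xy[which.max(xy[, 1]), ]
  rows$L <- seg_row("L", c(pmin_x[1], pmin_x[2]), c(pmax_x[1], pmin_x[2]),
                    value = pmax_x[1] - pmin_x[1])

  a_b <- anchors$a_b; a_l <- anchors$a_l
  have_a <- !is.null(a_b) && !is.null(a_l)
  x_at <- function(p, q, y) x_at_vec(p, q, y)[1]
  if (have_a) {
    xa <- x_at(a_b, a_l, apex[2])
    rows$a <- seg_row("a", apex, c(xa, apex[2]))
  } else {
    rows$a <- seg_row("a", NULL, NULL, "segment-a anchors (BRA3/LRA4) not detected")
  }

  # W: y extent posterior to the 'a' line
  if (have_a) {
    sel <- xy[, 1] >= x_at_vec(a_b, a_l, xy[, 2])
    if (any(sel)) {
      sub <- xy[sel, , drop = FALSE]
      ptop <- sub[which.max(sub[, 2]), ]; pbot <- sub[which.min(sub[, 2]), ]
      rows$W <- seg_row("W", ptop, pbot, value = ptop[2] - pbot[2])
    } else rows$W <- seg_row("W", NULL, NULL, "no outline posterior to the 'a' line")
  } else rows$W <- seg_row("W", NULL, NULL, "segment-a anchors not detected")

  # b and c need the anterior-cap bounding line (most anterior re-entrants)
  ac_b <- anchors$ac_b; ac_l <- anchors$ac_l
  have_ac <- !is.null(ac_b) && !is.null(ac_l) && !isTRUE(anchors$ac_is_a)
  if (have_a && have_ac) {
    in_mid <- xy[, 1] < x_at_vec(a_b, a_l, xy[, 2]) &
              xy[, 1] >= x_at_vec(ac_b, ac_l, xy[, 2])
    if (any(in_mid)) {
      sub <- xy[in_mid, , drop = FALSE]
      ptop <- sub[which.max(sub[, 2]), ]; pbot <- sub[which.min(sub[, 2]), ]
      rows$b <- seg_row("b", ptop, pbot, value = ptop[2] - pbot[2])
    } else rows$b <- seg_row("b", NULL, NULL, "empty T4/T5 region")
    in_cap <- xy[, 1] < x_at_vec(ac_b, ac_l, xy[, 2])
    if (any(in_cap)) {
      sub <- xy[in_cap, , drop = FALSE]
      ptop <- sub[which.max(sub[, 2]), ]; pbot <- sub[which.min(sub[, 2]), ]
      rows$c <- seg_row("c", ptop, pbot, value = ptop[2] - pbot[2])
    } else rows$c <- seg_row("c", NULL, NULL, "empty anterior-cap region")
  } else if (have_a) {
    rows$b <- seg_row("b", NULL, NULL, "no re-entrant folds anterior of segment a")
    in_cap <- xy[, 1] < x_at_vec(a_b, a_l, xy[, 2])
    sub <- xy[in_cap, , drop = FALSE]
    if (nrow(sub)) {
      ptop <- sub[which.max(sub[, 2]), ]; pbot <- sub[which.min(sub[, 2]), ]
      rows$c <- seg_row("c", ptop, pbot, value = ptop[2] - pbot[2])
    } else rows$c <- seg_row("c", NULL, NULL, "empty anterior region")
  } else {
    rows$b <- seg_row("b", NULL, NULL, "segment-a anchors not detected")
    rows$c <- seg_row("c", NULL, NULL, "segment-a anchors not detected")
  }

  # e: lowest point of T6 to highest point of T7
  if (is.null(anchors$t6)) rows$e <- seg_row("e", NULL, NULL, "T6 not detected")
  else if (is.null(anchors$t7)) rows$e <- seg_row("e", NULL, NULL, "T7 not detected")
  else rows$e <- seg_row("e", anchors$t6, anchors$t7)

  # La / Li asymmetry
  if (have_a) {
    if (asymmetry == "arc" && !is.null(anchors$arc_idx)) {
      ai <- anchors$arc_idx
      la <- arc_between(xy, ai$apex, ai$a_b)
      li <- arc_between(xy, ai$apex, ai$a_l)
      rows$La <- seg_row("La", apex, a_b, value = la)
      rows$Li <- seg_row("Li", apex, a_l, value = li)
    } else {
      rows$La <- seg_row("La", apex, a_b)
      rows$Li <- seg_row("Li", apex, a_l)
    }
  } else {
    rows$La <- seg_row("La", NULL, NULL, "segment-a anchors not detected")
    rows$Li <- seg_row("Li", NULL, NULL, "segment-a anchors not detected")
  }

  out <- dplyr::bind_rows(rows[vdm_segment_names])
  structure(out, class = c("vdm_measurements", class(out)),
            apex = apex, anchors = list(a_b = a_b, a_l = a_l),
            outline_mm = xy, scale_mm_per_px = scale, asymmetry = asymmetry)
}

# x coordinate of the 'a' line at height y, clamped to the anchor segment so
# that a nearly level line (anchors barely crossing the midline) cannot
# extrapolate; beyond the anchors the boundary continues vertically
x_at_vec <- function(p, q, y) {
  if (abs(q[2] - p[2]) < 1e-12) return(rep((p[1] + q[1]) / 2, length(y)))
  t <- pmin(1, pmax(0, (y - p[2]) / (q[2] - p[2])))
  p[1] + t * (q[1] - p[1])
}

# shortest along-outline length between two vertex indices of a closed chain
arc_between <- function(xy, i, j) {
  pos <- arc_positions(xy)
  P <- poly_perimeter(xy)
  d <- abs(pos[i] - pos[j])
  min(d, P - d)
}

#' Ground-truth index measurements of a synthetic specimen
#'
#' Runs the same measurement engine as [measure_indices()], but anchored on
#' the generator's own labels instead of detected features -- the oracle for
#' testing the automatic pipeline.
#'
#' @param specimen A `molar_specimen` or `molar_template`.
#' @inheritParams measure_indices
#' @return A `vdm_measurements`.
#' @export
measure_indices_truth <- function(specimen, asymmetry = c("chord", "arc")) {
  asymmetry <- match.arg(asymmetry)
  xy <- specimen$outline
  lb <- specimen$labels
  pt <- function(nm) if (nm %in% names(lb)) xy[lb[[nm]], ] else NULL
  bra <- sort(names(lb)[grepl("^BRA", names(lb))])
  lra <- sort(names(lb)[grepl("^LRA", names(lb))])
  last_bra <- if (length(bra)) bra[length(bra)] else NA
  last_lra <- if (length(lra)) lra[length(lra)] else NA
  anchors <- list(
    a_b = pt("BRA3"), a_l = pt("LRA4"),
    ac_b = if (!is.na(last_bra)) pt(last_bra) else NULL,
    ac_l = if (!is.na(last_lra)) pt(last_lra) else NULL,
    ac_is_a = identical(last_bra, "BRA3") || identical(last_lra, "LRA4"),
    t6 = pt("T6"), t7 = pt("T7"),
    arc_idx = list(a_b = lb[["BRA3"]], a_l = lb[["LRA4"]],
                   apex = which.min(xy[, 1]))
  )
  measure_vdm_points(xy, anchors, asymmetry = asymmetry)
}

#' Derived Van der Meulen ratios
#'
#' `A_L = 100 a / L`, `B_W = 100 b / W`, `C_W = 100 c / W`, always recomputed
#' from the current segment values (never stale after an override).
#'
#' @param m A `vdm_measurements`.
#' @return Tibble `ratio`, `value`.
#' @export
vdm_ratios <- function(m) {
  v <- stats::setNames(m$value_mm, m$segment)
  tibble::tibble(
    ratio = c("A_L", "B_W", "C_W"),
    value = c(100 * v[["a"]] / v[["L"]],
              100 * v[["b"]] / v[["W"]],
              100 * v[["c"]] / v[["W"]]))
}

#' Manually override one measured segment
#'
#' Replaces a segment with a manually measured one and recomputes everything
#' that depends on it. For the simple spans (L, W, b, c, e, La, Li) the new
#' value is the distance between the two supplied endpoints. For `"a"`, the
#' endpoints are interpreted as the new segment-'a' line anchors (the manual
#' equivalents of the BRA3/LRA4 deep points): `a`, `La` and `Li` are then
#' recomputed from them by the automatic formulas, `a` flagged `manual` and
#' `La`/`Li` flagged `derived-from-manual`. Ratios follow automatically since
#' [vdm_ratios()] always reads the current segments.
#'
#' @param m A `vdm_measurements`.
#' @param segment One of `"L"`, `"W"`, `"a"`, `"b"`, `"c"`, `"e"`, `"La"`,
#'   `"Li"`.
#' @param p1,p2 Numeric length-2 endpoints in mm (canonical frame, y up).
#' @return The updated `vdm_measurements`.
#' @export
override_segment <- function(m, segment, p1, p2) {
  stopifnot(inherits(m, "vdm_measurements"),
            is.numeric(p1), length(p1) == 2L, is.numeric(p2), length(p2) == 2L)
  if (!segment %in% vdm_segment_names)
    stop("unknown segment '", segment, "'; expected one of: ",
         paste(vdm_segment_names, collapse = ", "))
  apex <- attr(m, "apex")
  set_row <- function(m, seg, value, p1, p2, prov) {
    i <- which(m$segment == seg)
    m$value_mm[i] <- value
    m$x1[i] <- p1[1]; m$y1[i] <- p1[2]; m$x2[i] <- p2[1]; m$y2[i] <- p2[2]
    m$provenance[i] <- prov
    m$reason[i] <- NA_character_
    m
  }
  if (segment == "a") {
    xa <- x_at_vec(p1, p2, apex[2])[1]
    m <- set_row(m, "a", xa - apex[1], apex, c(xa, apex[2]), "manual")
    m <- set_row(m, "La", sqrt(sum((apex - p1)^2)), apex, p1, "derived-from-manual")
    m <- set_row(m, "Li", sqrt(sum((apex - p2)^2)), apex, p2, "derived-from-manual")
    anc <- attr(m, "anchors"); anc$a_b <- p1; anc$a_l <- p2
    attr(m, "anchors") <- anc
  } else {
    m <- set_row(m, segment, sqrt(sum((p1 - p2)^2)), p1, p2, "manual")
  }
  m
}

#' Compare automatic against manual measurements
#'
#' @param auto,manual A `vdm_measurements` each, or lists of them (a batch;
#'   matched by position). Indices absent on either side are excluded from the
#'   summary and counted.
#' @return A `vdm_comparison`: list with `per_index` (one row per specimen and
#'   segment: both values and the absolute difference, mm) and `summary`
#'   (per segment: mean and max absolute discrepancy, n compared, n missing).
#' @export
compare_auto_manual <- function(auto, manual) {
  as_list <- function(x) if (inherits(x, "vdm_measurements")) list(x) else x
  la <- as_list(auto); lm <- as_list(manual)
  if (length(la) != length(lm)) stop("auto and manual batches differ in length")
  per <- dplyr::bind_rows(lapply(seq_along(la), function(i) {
    a <- la[[i]]; b <- lm[[i]]
    tibble::tibble(item = i, segment = a$segment,
                   value_auto = a$value_mm,
                   value_manual = b$value_mm[match(a$segment, b$segment)])
  }))
  per$abs_diff_mm <- abs(per$value_auto - per$value_manual)
  summ <- dplyr::summarise(
    dplyr::group_by(per, .data$segment),
    mean_abs_diff_mm = mean(.data$abs_diff_mm, na.rm = TRUE),
    max_abs_diff_mm = if (all(is.na(.data$abs_diff_mm))) NA_real_
                      else max(.data$abs_diff_mm, na.rm = TRUE),
    n_compared = sum(!is.na(.data$abs_diff_mm)),
    n_missing = sum(is.na(.data$abs_diff_mm)),
    .groups = "drop")
  summ <- summ[match(vdm_segment_names, summ$segment), ]
  structure(list(per_index = per, summary = summ), class = "vdm_comparison")
}

#' @export
print.vdm_comparison <- function(x, ...) {
  cat("<vdm_comparison> ", length(unique(x$per_index$item)), " specimen(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
print.vdm_measurements <- function(x, ...) {
  cat("<vdm_measurements> (mm)\n")
  print(tibble::as_tibble(x)[, c("segment", "value_mm", "provenance", "reason")])
  r <- vdm_ratios(x)
  ok <- !is.na(r$value)
  if (any(ok)) cat("ratios:", paste(sprintf("%s = %.2f", r$ratio[ok], r$value[ok]),
                                    collapse = ", "), "\n")
  invisible(x)
}
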