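# Parametric generator of vole-m1-like occlusal outlines with labelled ground
# truth. The outline is built from an explicit vertex plan around a medial
# spine (posterior lobe - alternating triangles - anterior cap), corners are
# rounded with quadratic Bezier arcs, and every anatomical feature point
# (T-apices, BRA/LRA deep points, AC apex, PL tip) is a labelled vertex that
# lies exactly on the generated curve. Coordinates are mm in canonical pose:
# anterior left, posterior right, buccal at the bottom, y axis up.

#' Build a synthetic molar template
#'
#' Constructs a deterministic, labelled, closed outline that emulates the
#' occlusal topology of an arvicoline first lower molar: an elongate body with
#' alternating buccal/lingual enamel triangles separated by deep re-entrant
#' folds (BRA/LRA), a rounded posterior lobe and an anterior cap. Presets are
#' schematic -- they reproduce the topology (fold counts, interdigitation,
#' T-point layout) rather than any measured species outline.
#'
#' @param species_preset One of `names(molar_presets())`, or `"custom"` to use
#'   the remaining arguments as given.
#' @param length_mm Total anteroposterior length (x extent) in mm.
#' @param n_bra,n_lra Number of buccal / lingual re-entrant folds. At least 3
#'   buccal and 4 lingual folds are required unless `allow_few = TRUE`.
#' @param half_width_mm Half of the maximal width: |y| of triangle apices.
#' @param fold_overshoot_mm How far fold deep points cross past the midline
#'   (positive values interdigitate the two sides, as in real arvicolines).
#' @param pl_len_mm,pl_half_width_mm Posterior lobe length and half width.
#' @param ac_len_mm,ac_half_width_mm Anterior cap length and half width.
#' @param ac_asym_mm Vertical offset of the anterior apex (cap asymmetry).
#' @param fold_mouth_frac Fold mouth width as a fraction of the fold period.
#' @param fold_phase Phase shift of the fold field along the tooth axis, as a
#'   fraction of one fold slot (0 to 1); distinguishes presets with equal fold
#'   counts.
#' @param t6 Is the T6 triangle present? When `FALSE` the buccal side carries
#'   one fold less and no T6 label (the *Alexandromys oeconomus* morphotype).
#' @param step_mm Densification step of the returned polyline.
#' @param allow_few Permit fewer folds than the arvicoline minimum (used to
#'   build degenerate shapes in tests).
#' @return An object of class `molar_template`: a list with the dense closed
#'   `outline` (n x 2 matrix, mm, counter-clockwise), a named integer vector
#'   `labels` of vertex indices (`T1`..`T7`, `BRA1`.., `LRA1`.., `AC`, `PL`),
#'   the fold counts and the parameter set.
#' @examples
#' tpl <- make_template("microtus-like")
#' tpl$n_bra
#' @export
make_template <- function(species_preset = "microtus-like",
                          length_mm = 2.8, n_bra = 5L, n_lra = 6L,
                          half_width_mm = 0.60, fold_overshoot_mm = 0.15,
                          pl_len_mm = 0.45, pl_half_width_mm = 0.52,
                          ac_len_mm = 0.55, ac_half_width_mm = 0.40,
                          ac_asym_mm = 0.03, fold_mouth_frac = 0.30,
                          fold_phase = 0, t6 = TRUE, step_mm = 0.004,
                          allow_few = FALSE) {
  if (!identical(species_preset, "custom")) {
    p <- molar_presets()[[species_preset]]
    if (is.null(p)) stop("unknown preset '", species_preset, "'; see molar_presets()")
    p$step_mm <- step_mm
    return(do.call(make_template, c(list(species_preset = "custom"), p)))
  }
  stopifnot(length_mm > 0, half_width_mm > 0, pl_len_mm > 0, ac_len_mm > 0)
  if (fold_overshoot_mm < -half_width_mm) stop("invalid fold depth: deep point outside the outline")
  if (fold_overshoot_mm >= half_width_mm) stop("invalid fold depth: folds would cross the far side")
  n_bra <- as.integer(n_bra); n_lra <- as.integer(n_lra)
  if (!allow_few && (n_bra < 3L || n_lra < 4L))
    stop("arvicoline m1 topology needs >= 3 buccal and >= 4 lingual re-entrants")

  L <- length_mm; hw <- half_width_mm
  x_post <- L - pl_len_mm      # posterior end of the fold field
  x_ant  <- ac_len_mm          # anterior end of the fold field
  if (x_post <= x_ant) stop("posterior lobe and anterior cap leave no room for triangles")

  # folds of the two sides are assigned jointly to alternating "slots" along
  # the tooth axis, so buccal and lingual folds interdigitate and the deep
  # points can cross the midline without the walls ever intersecting
  m_slots <- n_bra + n_lra
  field <- x_post - x_ant
  # the phased slot grid stays clear of both ends of the fold field
  period <- field / (m_slots + 0.4 * abs(fold_phase))
  slot_x <- x_post - (seq_len(m_slots) - 0.5 + 0.4 * fold_phase) * period
  b_slots <- pmin(m_slots, floor((seq_len(n_bra) - 0.5) * m_slots / n_bra) + 1L)
  # fold mouth and throat keep a minimum absolute width so the gap between the
  # fold walls stays resolvable when rasterized at typical calibrations
  mouth <- min(0.45 * period, max(0.035, fold_mouth_frac * period / 2))

  side_plan <- function(n_folds, sgn, xf) {
    # sgn = -1 buccal (y < 0), +1 lingual; xf = fold x positions, posterior
    # first. Folds are U-shaped (near-parallel walls, rounded tip) so the
    # narrow gap stays resolvable when rasterized.
    y_sal <- sgn * hw
    y_tip <- -sgn * fold_overshoot_mm    # may cross the midline
    y_mouth <- y_sal * 0.93   # keeps triangle apices blunt enough to ink
    y_wall <- y_tip + 0.18 * (y_mouth - y_tip)
    w_tip <- max(0.028, min(0.035, mouth * 0.8))  # half-width of the fold throat
    vx <- c(); vy <- c(); vl <- c(); vr <- c()
    add <- function(x, y, lab, r) { vx <<- c(vx, x); vy <<- c(vy, y); vl <<- c(vl, lab); vr <<- c(vr, r) }
    add(x_post + pl_len_mm * 0.25, sgn * pl_half_width_mm, "", 0.10)  # posterior shoulder
    for (i in seq_len(n_folds)) {
      add(xf[i] + mouth, y_mouth, "", 0.05)
      add(xf[i] + w_tip, y_wall, "", 0.04)
      add(xf[i], y_tip, sprintf("%s%d", if (sgn < 0) "BRA" else "LRA", i), 0.025)
      add(xf[i] - w_tip, y_wall, "", 0.04)
      # the anterior wall of the last fold exits lower, flowing into the cap
      # shoulder without an acute spike
      y_exit <- if (i == n_folds) (y_mouth + sgn * ac_half_width_mm) / 2 else y_mouth
      add(xf[i] - mouth, y_exit, "", if (i == n_folds) 0.06 else 0.05)
      if (i < n_folds)   # salient between fold i and i+1
        add((xf[i] + xf[i + 1L]) / 2, y_sal, salient_label(i, sgn < 0, n_folds, t6), 0.08)
    }
    add(x_ant - ac_len_mm * 0.15, sgn * ac_half_width_mm, "", 0.10)  # cap shoulder
    list(x = vx, y = vy, lab = vl, r = vr)
  }

  buc <- side_plan(n_bra, -1, slot_x[b_slots])
  lin <- side_plan(n_lra, +1, slot_x[setdiff(seq_len(m_slots), b_slots)])

  # assemble counter-clockwise: apex -> buccal (anterior->posterior) ->
  # posterior tip -> lingual (posterior->anterior) -> back to apex
  nb <- length(buc$x); nl <- length(lin$x)
  vx <- c(0, rev(buc$x), L, lin$x)
  vy <- c(ac_asym_mm, rev(buc$y), 0, lin$y)
  vl <- c("AC", rev(buc$lab), "PL", lin$lab)
  vr <- c(0.22, rev(buc$r), 0.30, lin$r)

  dens <- round_and_densify(cbind(vx, vy), vl, vr, step_mm)
  outline <- dens$xy
  # corner rounding pulls the apex and posterior tip slightly inwards; rescale
  # x so the outline's anteroposterior extent is exactly length_mm
  xr <- range(outline[, 1])
  outline[, 1] <- (outline[, 1] - xr[1]) / diff(xr) * length_mm
  labels <- dens$labels
  if (!t6) labels <- labels[names(labels) != "T6"]

  if (!is_simple_polygon(outline)) stop("template parameters produce a self-intersecting outline")
  if (shoelace_area(outline) < 0) stop("internal error: outline not counter-clockwise")

  structure(list(
    outline = outline, labels = labels, n_bra = n_bra, n_lra = n_lra,
    preset = species_preset,
    params = list(length_mm = length_mm, n_bra = n_bra, n_lra = n_lra,
                  half_width_mm = half_width_mm, fold_overshoot_mm = fold_overshoot_mm,
                  pl_len_mm = pl_len_mm, pl_half_width_mm = pl_half_width_mm,
                  ac_len_mm = ac_len_mm, ac_half_width_mm = ac_half_width_mm,
                  ac_asym_mm = ac_asym_mm, fold_mouth_frac = fold_mouth_frac,
                  fold_phase = fold_phase, t6 = t6)
  ), class = "molar_template")
}

# Label of the salient between fold i and i+1, counted from the posterior.
# Lingual triangles are odd (T1, T3, [unlabelled], T5, T7), buccal even
# (T2, [unlabelled], T4, T6); one unlabelled salient per side sits just
# posterior of the segment-'a' anchors (BRA3 / LRA4) so that T4..T7 lie on the
# anterior semiperimeter.
salient_label <- function(i, buccal, n_folds, t6) {
  if (buccal) {
    lab <- switch(as.character(i), "1" = "T2", "2" = "", "3" = "T4", "4" = "T6", "")
    if (identical(lab, "T6") && !t6) lab <- ""
    lab
  } else {
    switch(as.character(i), "1" = "T1", "2" = "T3", "3" = "", "4" = "T5", "5" = "T7", "")
  }
}

# Round the corners of a closed control polygon with quadratic Bezier arcs and
# densify to `step`. Labelled corners keep their label at the arc midpoint
# (t = 0.5), which lies exactly on the final curve.
round_and_densify <- function(V, labs, radii, step) {
  m <- nrow(V)
  pieces <- vector("list", 2L * m)
  lab_pos <- list()  # label -> function of current total length
  total_rows <- 0L
  lab_idx <- integer(0); lab_nm <- character(0)
  for (k in seq_len(m)) {
    prv <- V[if (k == 1L) m else k - 1L, ]
    cur <- V[k, ]
    nxt <- V[if (k == m) 1L else k + 1L, ]
    d1 <- sqrt(sum((cur - prv)^2)); d2 <- sqrt(sum((nxt - cur)^2))
    r <- min(radii[k], 0.42 * d1, 0.42 * d2)
    p_in <- cur + (prv - cur) * (r / d1)
    p_out <- cur + (nxt - cur) * (r / d2)
    arc_n <- max(5L, ceiling((2 * r) / step))
    t <- seq(0, 1, length.out = arc_n)
    bez <- outer((1 - t)^2, p_in) + outer(2 * t * (1 - t), cur) + outer(t^2, p_out)
    # straight run from this arc's end to the next arc's start is added on the
    # next iteration via the chord between consecutive pieces
    pieces[[2L * k - 1L]] <- bez
    if (nzchar(labs[k])) {
      lab_nm <- c(lab_nm, labs[k])
      lab_idx <- c(lab_idx, total_rows + (arc_n + 1L) %/% 2L)
    }
    total_rows <- total_rows + arc_n
    pieces[[2L * k]] <- matrix(numeric(0), 0, 2)
  }
  path <- do.call(rbind, pieces)
  # densify the straight chords between consecutive arc pieces
  out <- list(); idx_map <- integer(nrow(path)); n_out <- 0L
  n <- nrow(path)
  for (k in seq_len(n)) {
    nk <- if (k == n) 1L else k + 1L
    d <- sqrt(sum((path[nk, ] - path[k, ])^2))
    n_out <- n_out + 1L
    idx_map[k] <- n_out
    out[[length(out) + 1L]] <- path[k, , drop = FALSE]
    if (d > step) {
      n_mid <- floor(d / step)
      tt <- seq_len(n_mid) / (n_mid + 1L)
      mid <- outer(1 - tt, path[k, ]) + outer(tt, path[nk, ])
      out[[length(out) + 1L]] <- mid
      n_out <- n_out + n_mid
    }
  }
  xy <- do.call(rbind, out)
  labels <- stats::setNames(idx_map[lab_idx], lab_nm)
  list(xy = xy, labels = labels)
}

#' Species parameter presets for the synthetic generator
#'
#' Five schematic parameter sets named after arvicoline taxa. They differ in
#' size, fold counts and cap proportions so that their centred 200-landmark
#' semiperimeters are mutually well separated (pairwise modified Hausdorff
#' distance >= 0.1 mm; asserted by the test suite). `oeconomus-like` lacks T6;
#' `allophaiomys-like` has the archaic 3 + 4 fold count with a confluent
#' anteroconid (no T4..T7 labels).
#'
#' @return Named list of argument lists for [make_template()].
#' @export
molar_presets <- function() {
  list(
    "microtus-like" = list(length_mm = 2.90, n_bra = 5L, n_lra = 6L,
                           half_width_mm = 0.68, fold_overshoot_mm = 0.17,
                           pl_len_mm = 0.45, pl_half_width_mm = 0.58,
                           ac_len_mm = 0.52, ac_half_width_mm = 0.46,
                           ac_asym_mm = 0.03, fold_mouth_frac = 0.30,
                           fold_phase = 0, t6 = TRUE),
    "arvalis-like" = list(length_mm = 2.40, n_bra = 5L, n_lra = 6L,
                          half_width_mm = 0.40, fold_overshoot_mm = 0.10,
                          pl_len_mm = 0.34, pl_half_width_mm = 0.36,
                          ac_len_mm = 0.34, ac_half_width_mm = 0.25,
                          ac_asym_mm = -0.03, fold_mouth_frac = 0.26,
                          fold_phase = 1, t6 = TRUE),
    "agrestis-like" = list(length_mm = 3.55, n_bra = 6L, n_lra = 7L,
                           half_width_mm = 0.74, fold_overshoot_mm = 0.12,
                           pl_len_mm = 0.55, pl_half_width_mm = 0.66,
                           ac_len_mm = 0.70, ac_half_width_mm = 0.56,
                           ac_asym_mm = 0.05, fold_mouth_frac = 0.33,
                           fold_phase = 0, t6 = TRUE),
    "oeconomus-like" = list(length_mm = 3.50, n_bra = 4L, n_lra = 6L,
                            half_width_mm = 0.50, fold_overshoot_mm = 0.04,
                            pl_len_mm = 0.48, pl_half_width_mm = 0.46,
                            ac_len_mm = 1.10, ac_half_width_mm = 0.30,
                            ac_asym_mm = 0.04, fold_mouth_frac = 0.30,
                            fold_phase = 0.7, t6 = FALSE),
    "allophaiomys-like" = list(length_mm = 1.35, n_bra = 3L, n_lra = 4L,
                               half_width_mm = 0.50, fold_overshoot_mm = -0.02,
                               pl_len_mm = 0.34, pl_half_width_mm = 0.45,
                               ac_len_mm = 0.46, ac_half_width_mm = 0.43,
                               ac_asym_mm = 0.00, fold_mouth_frac = 0.34,
                               fold_phase = 0, t6 = FALSE)
  )
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a noisy specimen from a template
#'
#' Perturbs the template outline with a smooth random 2-D deformation field:
#' a low-order spatial Fourier series over the tooth's bounding box, with
#' Gaussian coefficients normalized so the pointwise displacement of each
#' coordinate has standard deviation `noise_sigma_mm`. Because the field is
#' smooth in *space* (not along the outline), the two walls of a re-entrant
#' fold — spatially adjacent, but far apart along the perimeter — move
#' together, so folds deform without pinching shut. Feature labels are
#' transported with their vertices. If the perturbed outline nevertheless
#' self-intersects, the field is deterministically damped by factors of 0.8
#' until it is simple again; the number of damping steps is recorded.
#'
#' @param template A [make_template()] object.
#' @param noise_sigma_mm Pointwise standard deviation of each displacement
#'   component, mm.
#' @param seed Integer seed; specimens are deterministic given (template,
#'   sigma, seed).
#' @param freq_order Maximum spatial frequency order of the field (default 2;
#'   higher orders shorten the correlation length of the deformation).
#' @return A `molar_specimen`: list with `outline`, `labels`, `sigma`, `seed`,
#'   `damping_steps`, `preset`.
#' @export
generate_specimen <- function(template, noise_sigma_mm = 0.02, seed = 1L,
                              freq_order = 2L) {
  stopifnot(inherits(template, "molar_template"), noise_sigma_mm >= 0)
  xy <- template$outline
  if (noise_sigma_mm == 0) {
    return(structure(list(outline = xy, labels = template$labels,
                          sigma = 0, seed = as.integer(seed), damping_steps = 0L,
                          preset = template$preset, n_bra = template$n_bra,
                          n_lra = template$n_lra),
                     class = "molar_specimen"))
  }
  # normalized coordinates over the bounding box
  xr <- range(xy[, 1]); yr <- range(xy[, 2])
  u <- (xy[, 1] - mean(xr)) / (diff(xr) / 2)
  v <- (xy[, 2] - mean(yr)) / (diff(yr) / 2)
  ij <- expand.grid(i = 0:freq_order, j = 0:freq_order)
  ij <- ij[ij$i + ij$j > 0 & ij$i + ij$j <= freq_order, , drop = FALSE]
  theta <- pi * (outer(u, ij$i) + outer(v, ij$j))   # n x K phase matrix
  K <- nrow(ij)
  # cos/sin pairs per frequency make the pointwise variance position-free
  co <- with_seed(seed, matrix(stats::rnorm(4L * K, sd = noise_sigma_mm / sqrt(K)),
                               ncol = 4))
  dx <- cos(theta) %*% co[, 1] + sin(theta) %*% co[, 2]
  dy <- cos(theta) %*% co[, 3] + sin(theta) %*% co[, 4]
  damp <- 1; steps <- 0L
  repeat {
    out <- xy + damp * cbind(drop(dx), drop(dy))
    if (is_simple_polygon(out, 1000L) || steps >= 24L) break
    damp <- damp * 0.8; steps <- steps + 1L
  }
  if (!is_simple_polygon(out, 1000L))
    stop("could not keep the perturbed outline simple; lower noise_sigma_mm")
  structure(list(outline = out, labels = template$labels, sigma = noise_sigma_mm,
                 seed = as.integer(seed), damping_steps = steps,
                 preset = template$preset, n_bra = template$n_bra,
                 n_lra = template$n_lra),
            class = "molar_specimen")
}

#' @export
print.molar_template <- function(x, ...) {
  cat("<molar_template '", x$preset, "'>  L=", x$params$length_mm, " mm, ",
      x$n_bra, " BRA / ", x$n_lra, " LRA, ", nrow(x$outline), " vertices, labels: ",
      paste(names(x$labels), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
print.molar_specimen <- function(x, ...) {
  cat("<molar_specimen '", x$preset, "'>  sigma=", x$sigma, " mm, seed=", x$seed,
      if (x$damping_steps > 0) paste0(", damped x", x$damping_steps) else "", "\n", sep = "")
  invisible(x)
}

# ---- ground-truth accessors ------------------------------------------------

# open sub-chain of a closed outline from index i to index j, passing through
# index `through`
chain_between <- function(xy, i, j, through) {
  n <- nrow(xy)
  fwd <- if (i <= j) i:j else c(i:n, 1:j)
  if (through %in% fwd) return(xy[fwd, , drop = FALSE])
  bwd <- if (j <= i) j:i else c(j:n, 1:i)
  if (!(through %in% bwd)) stop("anchor not on either branch")
  xy[rev(bwd), , drop = FALSE]
}

#' Ground-truth anterior semiperimeter of a synthetic specimen
#'
#' Returns the open polyline from the buccal segment-'a' endpoint (BRA3 deep
#' point) through the anterior apex to the lingual endpoint (LRA4), taken from
#' the generator's own labels -- the oracle against which the image pipeline
#' is checked.
#'
#' @param specimen A `molar_specimen` or `molar_template`.
#' @return n x 2 matrix (mm, y up), buccal endpoint first.
#' @export
truth_semiperimeter <- function(specimen) {
  lb <- specimen$labels
  need <- c("BRA3", "LRA4", "AC")
  if (!all(need %in% names(lb))) stop("specimen lacks BRA3/LRA4/AC labels")
  chain_between(specimen$outline, lb[["BRA3"]], lb[["LRA4"]], lb[["AC"]])
}

#' Build a labelled landmark database from synthetic specimens
#'
#' Generates `n_per_species` noisy specimens per preset, extracts the
#' ground-truth anterior semiperimeter of each and resamples it to
#' `n_landmarks` equally spaced points. This is the reference database used by
#' the package's own evaluation studies.
#'
#' @param presets Character vector of preset names (>= 2).
#' @param n_per_species Specimens per preset.
#' @param sigma_mm Radial noise standard deviation (mm).
#' @param seed Integer master seed; per-specimen seeds are derived from it.
#' @param n_landmarks Landmarks per specimen (200 by convention).
#' @param source_kind Recorded source dialect for each specimen.
#' @return A landmarks tibble with columns `specimen_id`, `species`,
#'   `source_kind`, `point_index`, `x_mm`, `y_mm`.
#' @export
synth_landmarks <- function(presets = names(molar_presets()), n_per_species = 30L,
                            sigma_mm = 0.02, seed = 1L, n_landmarks = 200L,
                            source_kind = "drawing") {
  stopifnot(length(presets) >= 1L, n_per_species >= 1L)
  tpls <- lapply(presets, make_template)
  names(tpls) <- presets
  n_tot <- length(presets) * n_per_species
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_tot))
  src <- rep_len(source_kind, n_tot)
  k <- 0L
  rows <- vector("list", n_tot)
  for (sp in presets) {
    for (i in seq_len(n_per_species)) {
      k <- k + 1L
      spec <- generate_specimen(tpls[[sp]], sigma_mm, seed = sub_seeds[k])
      lm <- resample_polyline(truth_semiperimeter(spec), n_landmarks)
      rows[[k]] <- tibble::tibble(
        specimen_id = sprintf("%s_%03d", gsub("-like$", "", sp), i),
        species = sp, source_kind = src[k],
        point_index = seq_len(n_landmarks), x_mm = lm[, 1], y_mm = lm[, 2])
    }
  }
  dplyr::bind_rows(rows)
}
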