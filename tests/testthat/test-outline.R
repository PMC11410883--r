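# Outline extraction, feature detection, semiperimeter, landmark resampling.

test_that("a filled disc traces to a unit-spaced circle of the right length and area", {
  n <- 256; r <- 100
  xs <- matrix(rep(1:n, n), n); ys <- t(xs)
  grey <- matrix(1, n, n)
  grey[(xs - 128)^2 + (ys - 128)^2 <= r^2] <- 0
  img <- as_occlusal_image(grey, 0.01, "photo", oriented = TRUE)
  tr <- extract_outline(img)
  expect_equal(nrow(tr$xy), 2 * pi * r, tolerance = 6 / (2 * pi * r))
  expect_equal(abs(shoelace_area(tr$xy)), pi * r^2, tolerance = 0.02)
})

test_that("clipped specimens are refused", {
  grey <- matrix(1, 40, 40); grey[1:20, 10:30] <- 0  # touches the top border
  img <- structure(list(grey = grey, mask = grey < 0.5, scale = 0.01,
                        source_kind = "photo", threshold = 0.5, invert = FALSE,
                        oriented = TRUE), class = "occlusal_image")
  expect_error(extract_outline(img), "clipped specimen")
})

test_that("an open drawing stroke is rejected as not closed", {
  grey <- matrix(1, 60, 60)
  grey[30:32, 10:50] <- 0   # a bar: no enclosed interior
  img <- as_occlusal_image(grey, 0.01, "drawing", oriented = TRUE)
  expect_error(extract_outline(img), "outline not closed")
})

test_that("photo and drawing dialects both recover the outline within 2 px", {
  for (style in c("filled", "stroke_cement")) {
    rnd <- fx_render("microtus-like", style)
    tr <- fx_trace("microtus-like", style)
    expect_lt(hausdorff_distance(tr$xy, rnd$truth$outline_px), 2.5)
    # trace is closed, ~unit-spaced, counter-clockwise in the y-up frame
    steps <- seg_lengths(tr$xy, closed = TRUE)
    expect_lt(max(steps), 2)
    expect_lt(abs(mean(steps) - 1), 0.1)
    expect_lt(shoelace_area(tr$xy), 0)  # y-down frame: negative = CCW in y-up
  }
})

test_that("feature detection finds the generator's folds and anchors", {
  for (style in c("filled", "stroke_cement")) {
    rnd <- fx_render("microtus-like", style)
    tr <- fx_trace("microtus-like", style)
    ann <- fx_features("microtus-like", style)
    expect_length(ann$buccal_reentrants, 5L)
    expect_length(ann$lingual_reentrants, 6L)
    labs <- truth_labels(rnd)
    xy <- tr$xy
    err <- function(det_idx, lab)
      sqrt(sum((xy[det_idx, ] - rnd$truth$outline_px[labs[[lab]], ])^2))
    for (k in 1:5) expect_lt(err(ann$buccal_reentrants[k], paste0("BRA", k)), 3)
    for (k in 1:6) expect_lt(err(ann$lingual_reentrants[k], paste0("LRA", k)), 3)
    expect_lt(err(ann$a_endpoint_buccal, "BRA3"), 3)
    expect_lt(err(ann$a_endpoint_lingual, "LRA4"), 3)
    # salient apices land on the labelled triangles
    expect_lt(err(ann$buccal_salients[3], "T4"), 5)
    expect_lt(err(ann$buccal_salients[4], "T6"), 5)
    expect_lt(err(ann$lingual_salients[4], "T5"), 5)
    expect_lt(err(ann$lingual_salients[5], "T7"), 5)
  }
})

test_that("a featureless ellipse has insufficient re-entrants", {
  th <- seq(0, 2 * pi, length.out = 400)[-400]
  poly <- cbind(150 + 100 * cos(th), 80 + 50 * sin(th))
  grey <- matrix(1, 160, 300)
  grey[scanline_fill(poly, 160, 300)] <- 0
  img <- as_occlusal_image(grey, 0.01, "photo", oriented = TRUE)
  tr <- extract_outline(img)
  expect_error(detect_feature_points(tr), "insufficient re-entrants")
  ann <- detect_feature_points(tr, require_arvicoline = FALSE)
  expect_length(ann$buccal_reentrants, 0L)
})

test_that("the anterior semiperimeter contains T4..T7 + AC and excludes T1..T3 + PL", {
  rnd <- fx_render("microtus-like", "filled")
  tr <- fx_trace("microtus-like", "filled")
  ann <- fx_features("microtus-like", "filled")
  semi <- anterior_semiperimeter(tr, ann)
  labs <- truth_labels(rnd)
  on_semi <- function(lab) {
    p <- rnd$truth$outline_px[labs[[lab]], ]
    min(sqrt((semi[, 1] - p[1])^2 + (semi[, 2] - p[2])^2))
  }
  for (lab in c("T4", "T5", "T6", "T7", "AC")) expect_lt(on_semi(lab), 4)
  for (lab in c("T1", "T2", "T3", "PL")) expect_gt(on_semi(lab), 10)
  # canonical orientation: buccal endpoint first
  expect_equal(semi[1, ], tr$xy[ann$a_endpoint_buccal, ])
  expect_equal(semi[nrow(semi), ], tr$xy[ann$a_endpoint_lingual, ])
})

test_that("manually anchored endpoints reproduce the automatic split", {
  rnd <- fx_render("arvalis-like", "filled")
  tr <- fx_trace("arvalis-like", "filled")
  ann <- fx_features("arvalis-like", "filled")
  man <- manual_a_endpoints(tr, tr$xy[ann$a_endpoint_buccal, ],
                            tr$xy[ann$a_endpoint_lingual, ])
  expect_equal(anterior_semiperimeter(tr, man),
               anterior_semiperimeter(tr, ann), ignore_attr = TRUE)
})

test_that("a suspicious split (tiny anterior branch) raises a warning", {
  tr <- fx_trace("microtus-like", "filled")
  ann <- fx_features("microtus-like", "filled")
  # fabricate endpoints straddling the apex closely
  xy <- tr$xy
  man <- manual_a_endpoints(tr, xy[ann$apex, ] + c(3, 8), xy[ann$apex, ] - c(-3, 8))
  expect_warning(anterior_semiperimeter(tr, man), "suspicious split")
})

test_that("landmark resampling has exact spacing, endpoints and mm conversion", {
  # straight 200-px segment: closed form
  poly <- cbind(0:199, rep(0, 200))
  lm <- resample_landmarks(poly, 200, scale = 0.01)
  expect_equal(lm$x_mm, 0.01 * (0:199), tolerance = 1e-12)
  expect_equal(lm$y_mm, rep(0, 200), tolerance = 1e-12)

  # endpoints are preserved exactly on a crooked chain
  set.seed(3)
  steps <- cbind(runif(999, 0.5, 1.5), runif(999, -0.5, 0.5))
  poly2 <- apply(rbind(c(10, 400), steps), 2, cumsum)
  lm2 <- resample_landmarks(poly2, 200, scale = 0.01)
  expect_equal(c(lm2$x_mm[1], lm2$y_mm[1]),
               c(poly2[1, 1] * 0.01, -poly2[1, 2] * 0.01), tolerance = 1e-12)
  expect_equal(c(lm2$x_mm[200], lm2$y_mm[200]),
               c(poly2[1000, 1] * 0.01, -poly2[1000, 2] * 0.01), tolerance = 1e-12)
  # equal arc-length spacing: coefficient of variation of gaps < 5%
  gaps <- sqrt(diff(lm2$x_mm)^2 + diff(lm2$y_mm)^2)
  expect_lt(stats::sd(gaps) / mean(gaps), 0.05)
  # spacing agrees with a brute-force cumulative arc-length computation up to
  # the smoothing of the staircase noise in the parameterization
  s <- c(0, cumsum(sqrt(rowSums(diff(poly2)^2))))
  expect_equal(mean(gaps), s[1000] / 199 * 0.01, tolerance = 0.05)

  expect_error(resample_landmarks(poly2[1:50, ], 200, scale = 0.01),
               "semiperimeter too short")
})

test_that("rendering the same shape at twice the resolution changes mm landmarks little", {
  tpl <- fx_template("allophaiomys-like")
  lms <- lapply(c(0.01, 0.005), function(sc) {
    rnd <- render_molar(tpl, scale = sc, style = "filled")
    tr <- extract_outline(render_to_image(rnd))
    ann <- detect_feature_points(tr)
    lm <- resample_landmarks(anterior_semiperimeter(tr, ann), scale = sc)
    m <- lm_mat(lm)
    sweep(m, 2, colMeans(m))
  })
  expect_lt(hausdorff_distance(lms[[1]], lms[[2]]), 0.01)  # < 1 px at 0.01 mm/px
})
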