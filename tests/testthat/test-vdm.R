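# Van der Meulen indices and La/Li asymmetry.

test_that("a 3 x 1 mm rectangle measures L = 3 and W = 1 exactly", {
  # closed rectangle outline in pixel coordinates at 0.01 mm/px
  xs <- c(seq(10, 310, 1), rep(310, 99), seq(310, 10, -1), rep(10, 99))
  ys <- c(rep(50, 301), seq(51, 149, 1), rep(150, 301), seq(149, 51, -1))
  tr <- structure(list(xy = cbind(xs, ys), scale = 0.01, source_kind = "photo"),
                  class = "outline_trace")
  ann <- manual_a_endpoints(tr, c(60, 150), c(60, 50))  # 'a' line at x = 60 px
  m <- measure_indices(tr, ann)
  v <- stats::setNames(m$value_mm, m$segment)
  expect_equal(v[["L"]], 3, tolerance = 1e-12)
  expect_equal(v[["W"]], 1, tolerance = 1e-12)
  expect_equal(v[["a"]], 0.5, tolerance = 1e-12)  # x = 60 px -> 0.5 mm from x = 10
  expect_true(all(is.na(v[c("b", "e")])))          # no folds anterior of 'a', no T6
})

test_that("automatic measurements match generator truth within 2 px-equivalents", {
  for (preset in c("microtus-like", "agrestis-like")) {
    tr <- fx_trace(preset, "filled")
    ann <- fx_features(preset, "filled")
    auto <- measure_indices(tr, ann)
    truth <- measure_indices_truth(fx_template(preset))
    cmp <- compare_auto_manual(auto, truth)
    s <- cmp$summary
    for (seg in c("L", "a", "e"))
      expect_lt(s$mean_abs_diff_mm[s$segment == seg], 0.01)  # 2 px at 0.005 mm/px
    # A_L ratio within 1 unit of truth
    expect_lt(abs(vdm_ratios(auto)$value[1] - vdm_ratios(truth)$value[1]), 1)
    # a never exceeds L
    v <- stats::setNames(auto$value_mm, auto$segment)
    expect_lte(v[["a"]], v[["L"]])
  }
})

test_that("a T6-suppressed morphotype reports e absent with a reason", {
  tr <- fx_trace("oeconomus-like", "filled")
  ann <- fx_features("oeconomus-like", "filled")
  m <- measure_indices(tr, ann)
  erow <- m[m$segment == "e", ]
  expect_true(is.na(erow$value_mm))
  expect_equal(erow$provenance, "absent")
  expect_match(erow$reason, "T6 not detected")
  # the remaining indices are still measured
  expect_true(all(!is.na(m$value_mm[m$segment %in% c("L", "W", "a", "La", "Li")])))
})

test_that("override_segment recomputes values, dependants and ratios", {
  tr <- fx_trace("microtus-like", "filled")
  ann <- fx_features("microtus-like", "filled")
  m <- measure_indices(tr, ann)
  v0 <- stats::setNames(m$value_mm, m$segment)

  m2 <- override_segment(m, "L", c(0, 0), c(3, 0))
  expect_equal(m2$value_mm[m2$segment == "L"], 3)
  expect_equal(m2$provenance[m2$segment == "L"], "manual")
  expect_equal(vdm_ratios(m2)$value[1], 100 * v0[["a"]] / 3, tolerance = 1e-12)

  # overriding back with the stored endpoints restores everything to 1e-12
  Lrow <- m[m$segment == "L", ]
  m3 <- override_segment(m2, "L", c(Lrow$x1, Lrow$y1), c(Lrow$x2, Lrow$y2))
  expect_equal(m3$value_mm, m$value_mm, tolerance = 1e-12)

  expect_error(override_segment(m, "Z", c(0, 0), c(1, 1)), "unknown segment")
})

test_that("overriding the 'a' anchors recomputes a, La, Li consistently", {
  tr <- fx_trace("microtus-like", "filled")
  ann <- fx_features("microtus-like", "filled")
  m <- measure_indices(tr, ann)
  anc <- attr(m, "anchors")

  # override with the original anchors: a, La, Li unchanged to 1e-12
  m2 <- override_segment(m, "a", anc$a_b, anc$a_l)
  for (seg in c("a", "La", "Li"))
    expect_equal(m2$value_mm[m2$segment == seg], m$value_mm[m$segment == seg],
                 tolerance = 1e-12)
  expect_equal(m2$provenance[m2$segment == "a"], "manual")
  expect_equal(m2$provenance[m2$segment == "La"], "derived-from-manual")
  expect_equal(m2$provenance[m2$segment == "Li"], "derived-from-manual")

  # override with shifted anchors: La/Li equal apex-to-anchor distances
  p1 <- anc$a_b + c(0.05, 0); p2 <- anc$a_l - c(0.05, 0)
  m3 <- override_segment(m, "a", p1, p2)
  apex <- attr(m, "apex")
  expect_equal(m3$value_mm[m3$segment == "La"], sqrt(sum((apex - p1)^2)),
               tolerance = 1e-12)
  expect_equal(m3$value_mm[m3$segment == "Li"], sqrt(sum((apex - p2)^2)),
               tolerance = 1e-12)
})

test_that("compare_auto_manual reports per-index differences and missing counts", {
  tr <- fx_trace("microtus-like", "filled")
  ann <- fx_features("microtus-like", "filled")
  m <- measure_indices(tr, ann)
  same <- compare_auto_manual(m, m)
  expect_true(all(same$summary$mean_abs_diff_mm[!is.na(same$summary$mean_abs_diff_mm)] == 0))

  # absent on one side -> excluded from the mean, counted as missing
  oe <- measure_indices(fx_trace("oeconomus-like", "filled"),
                        fx_features("oeconomus-like", "filled"))
  cmp <- compare_auto_manual(oe, oe)
  erow <- cmp$summary[cmp$summary$segment == "e", ]
  expect_equal(erow$n_compared, 0L)
  expect_equal(erow$n_missing, 1L)
})

test_that("indices scale linearly with the calibration", {
  tr <- fx_trace("arvalis-like", "filled")
  ann <- fx_features("arvalis-like", "filled")
  m1 <- measure_indices(tr, ann, scale = 0.01)
  m2 <- measure_indices(tr, ann, scale = 0.02)
  expect_equal(m2$value_mm, 2 * m1$value_mm, tolerance = 1e-12)
  # ratios are scale-free
  expect_equal(vdm_ratios(m2)$value, vdm_ratios(m1)$value, tolerance = 1e-12)
})

test_that("La/Li support chord and arc definitions", {
  tr <- fx_trace("microtus-like", "filled")
  ann <- fx_features("microtus-like", "filled")
  ch <- measure_indices(tr, ann, asymmetry = "chord")
  ar <- measure_indices(tr, ann, asymmetry = "arc")
  for (seg in c("La", "Li"))
    expect_gt(ar$value_mm[ar$segment == seg], ch$value_mm[ch$segment == seg])
})
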