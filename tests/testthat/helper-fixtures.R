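# Shared fixtures, built once per test run and cached. Everything is
# generated in code: no data files ship with the package.

.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

fx_template <- function(preset = "microtus-like")
  fx(paste0("tpl_", preset), function() make_template(preset))

# reference calibrations of the two dialects: microscope photographs are
# fine-grained (0.005 mm/px for a ~3 mm tooth), scanned literature drawings
# coarser (0.01 mm/px)
fx_render <- function(preset = "microtus-like", style = "filled",
                      scale = if (style == "filled") 0.005 else 0.01)
  fx(paste0("rnd_", preset, "_", style), function()
    render_molar(fx_template(preset), scale = scale, style = style))

fx_trace <- function(preset = "microtus-like", style = "filled")
  fx(paste0("tr_", preset, "_", style), function()
    extract_outline(render_to_image(fx_render(preset, style))))

fx_features <- function(preset = "microtus-like", style = "filled")
  fx(paste0("ann_", preset, "_", style), function()
    detect_feature_points(fx_trace(preset, style)))

# small, well-separated synthetic database: 3 presets x 8 specimens
fx_small_db <- function()
  fx("small_db", function()
    ref_db(synth_landmarks(presets = c("microtus-like", "arvalis-like",
                                       "allophaiomys-like"),
                           n_per_species = 8, sigma_mm = 0.01, seed = 101)))

# ground-truth labels of a render, as a named index vector
truth_labels <- function(rnd) {
  stats::setNames(rnd$truth$label_index, rnd$truth$label_names)
}

# truth semiperimeter of a render, in its pixel frame
truth_semi_px <- function(rnd) {
  truth_semiperimeter(list(outline = rnd$truth$outline_px,
                           labels = truth_labels(rnd)))
}

# landmark tibble -> 200 x 2 matrix
lm_mat <- function(lm) cbind(lm$x_mm, lm$y_mm)

# brute-force double-loop modified Hausdorff oracle
mhd_bruteforce <- function(A, B) {
  dmin <- function(P, Q) {
    vapply(seq_len(nrow(P)), function(i)
      min(sqrt((Q[, 1] - P[i, 1])^2 + (Q[, 2] - P[i, 2])^2)), numeric(1))
  }
  max(mean(dmin(A, B)), mean(dmin(B, A)))
}

# grid-search + refinement oracle for the Procrustes dissimilarity
procrustes_gridsearch <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A)); A0 <- A0 / sqrt(sum(A0^2))
  B0 <- sweep(B, 2, colMeans(B)); B0 <- B0 / sqrt(sum(B0^2))
  obj <- function(theta, refl) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    if (refl) R <- R %*% diag(c(-1, 1))
    BR <- B0 %*% R
    s <- sum(A0 * BR)               # optimal scale in closed form
    sum((A0 - s * BR)^2)
  }
  best <- Inf
  for (refl in c(FALSE, TRUE)) {
    grid <- seq(0, 2 * pi, length.out = 721)
    v <- vapply(grid, obj, numeric(1), refl = refl)
    k <- which.min(v)
    lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
    best <- min(best, stats::optimize(obj, c(lo, hi), refl = refl,
                                      tol = 1e-12)$objective)
  }
  best
}
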