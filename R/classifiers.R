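# The four affinity-estimation methods: modified Hausdorff distance (against
# specimens, HDV, or species centroids, HDC), Procrustes nearest neighbour,
# Fisher canonical discriminant with Mahalanobis assignment, and one-vs-one
# linear SVMs under an error-correcting output-code scheme. All methods
# operate on per-specimen-centred landmark coordinates; absolute size is kept
# (images are calibrated, so size carries signal), absolute position is not.

# ---- modified Hausdorff distance --------------------------------------------

#' Modified Hausdorff distance between two point sets
#'
#' `mhd(A, B) = max(d(A, B), d(B, A))` where the directed distance
#' `d(A, B)` is the *mean* over points of A of the distance to the nearest
#' point of B. Replacing the classical maximum by the mean makes the measure
#' robust to single outlying points, which is why it outperforms the plain
#' Hausdorff distance for shape matching.
#'
#' @param a,b Numeric matrices with two columns (x, y), in mm.
#' @return A single non-negative distance (mm).
#' @examples
#' mhd(cbind(0, 0), cbind(3, 4))  # 5
#' @export
mhd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("mhd: empty point set")
  stopifnot(ncol(a) == 2, ncol(b) == 2, all(is.finite(a)), all(is.finite(b)))
  d2 <- cross_dist2(a, b)
  max(mean(sqrt(pmax(apply(d2, 1, min), 0))),
      mean(sqrt(pmax(apply(d2, 2, min), 0))))
}

#' Classify a specimen by modified Hausdorff distance
#'
#' Centres the query and every reference on their own centroids and assigns
#' the species of the nearest reference: either the nearest individual
#' specimen (`mode = "specimens"`, the HDV analysis) or the nearest species
#' centroid shape (`mode = "centroids"`, HDC). Ties break to the first
#' occurrence in database order (databases are sorted by species then
#' specimen id).
#'
#' @param query Landmarks tibble of one specimen, or an n x 2 matrix (mm).
#' @param db A [ref_db()].
#' @param mode `"specimens"` (HDV) or `"centroids"` (HDC).
#' @param exclude Specimen ids to leave out (for leave-one-out runs).
#' @return One-row tibble: `method`, `species`, `distance`,
#'   `nearest_specimen_id` (NA in centroid mode).
#' @export
classify_mhd <- function(query, db, mode = c("specimens", "centroids"),
                         exclude = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "ref_db"))
  q <- query_matrix(query)
  q <- sweep(q, 2, colMeans(q))
  if (mode == "specimens") {
    shapes <- db_shapes(db)
    keep <- !(names(shapes) %in% exclude)
    if (!any(keep)) stop("empty database after exclusions")
    d <- vapply(shapes[keep], function(m) mhd(q, m), numeric(1))
    i <- which.min(d)
    tibble::tibble(method = "mhd_v",
                   species = db$specimens$species[keep][i],
                   distance = unname(d[i]),
                   nearest_specimen_id = names(shapes)[keep][i])
  } else {
    lm <- db$landmarks
    if (!is.null(exclude)) lm <- lm[!(lm$specimen_id %in% exclude), ]
    if (nrow(lm) == 0L) stop("empty database after exclusions")
    cen <- species_centroids(lm)
    sp <- unique(cen$species)
    d <- vapply(sp, function(s) {
      m <- landmarks_matrix(cen[cen$species == s, ])
      m <- sweep(m, 2, colMeans(m))
      mhd(q, m)
    }, numeric(1))
    i <- which.min(d)
    tibble::tibble(method = "mhd_c", species = sp[i], distance = unname(d[i]),
                   nearest_specimen_id = NA_character_)
  }
}

# ---- Procrustes --------------------------------------------------------------

#' Procrustes dissimilarity between two landmark configurations
#'
#' Centres both configurations at the origin, scales each to unit centroid
#' size (trace of the cross-product matrix equal to 1), and applies to the
#' second the similarity transform -- rotation, reflection and scale -- that
#' minimizes the sum of squared pointwise differences. The dissimilarity is
#' that minimized residual, `1 - (sum of singular values)^2`, a number in
#' [0, 1]; the aligned copy of `b` (back in `a`'s original frame) is returned
#' for overlay plots.
#'
#' @param a,b Landmarks tibbles or n x 2 matrices with equal, index-matched
#'   point counts.
#' @return A `procrustes_fit`: list with `dissimilarity`, `a` (centred
#'   original), `b_aligned`, `rotation`, `scale`.
#' @export
procrustes_dist <- function(a, b) {
  A <- query_matrix(a); B <- query_matrix(b)
  if (nrow(A) != nrow(B)) stop("configurations must have the same point count")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  na <- sqrt(sum(A0^2)); nb <- sqrt(sum(B0^2))
  if (na < 1e-12 || nb < 1e-12) stop("degenerate configuration: all points coincident")
  A0 <- A0 / na; B0 <- B0 / nb
  sv <- svd(crossprod(B0, A0))          # B0' A0 = U S V'
  R <- sv$u %*% t(sv$v)                 # reflection permitted (no det correction)
  s <- sum(sv$d)
  d <- max(0, 1 - s^2)
  b_aligned <- s * B0 %*% R * na
  b_aligned <- sweep(b_aligned, 2, ca, `+`)
  structure(list(dissimilarity = d, a = A, b_aligned = b_aligned,
                 rotation = R, scale = s * na / nb),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat("<procrustes_fit> dissimilarity =", signif(x$dissimilarity, 6),
      if (det(x$rotation) < 0) "(reflected)" else "", "\n")
  invisible(x)
}

#' Classify a specimen by Procrustes nearest neighbour
#'
#' Finds the database specimen with the smallest Procrustes dissimilarity to
#' the query (the "closest morphology" report). Ties break to database order.
#'
#' @inheritParams classify_mhd
#' @return One-row tibble: `method`, `species`, `distance`,
#'   `nearest_specimen_id`.
#' @export
classify_procrustes <- function(query, db, exclude = NULL) {
  stopifnot(inherits(db, "ref_db"))
  q <- query_matrix(query)
  shapes <- db_shapes(db, centre = FALSE)
  keep <- !(names(shapes) %in% exclude)
  if (!any(keep)) stop("empty database after exclusions")
  d <- vapply(shapes[keep], function(m) procrustes_dist(q, m)$dissimilarity, numeric(1))
  i <- which.min(d)
  tibble::tibble(method = "procrustes",
                 species = db$specimens$species[keep][i], distance = unname(d[i]),
                 nearest_specimen_id = names(shapes)[keep][i])
}

# ---- Fisher canonical discriminant ------------------------------------------

#' Fit a Fisher canonical discriminant (LDC) model
#'
#' Features are the flattened centred landmark coordinates. Because the
#' feature dimension (2 x 200) exceeds the per-class sample sizes, the
#' features are first reduced by principal components to
#' `p' = min(n - N, #PCs retaining >= variance_retained)` dimensions, where
#' the pooled within-class scatter is invertible. The canonical variates --
#' the `q = min(N - 1, p')` directions with the highest discriminant power --
#' come from the generalized eigenproblem of between- versus within-class
#' scatter; they are scaled so the pooled within-class covariance in
#' canonical space is the identity, making Mahalanobis distance Euclidean
#' there. A query is assigned to the class with the smallest Mahalanobis
#' distance to its canonical-space mean.
#'
#' @param db A [ref_db()], or a numeric feature matrix (rows = specimens).
#' @param labels Class labels (required when `db` is a matrix).
#' @param variance_retained PCA variance fraction to keep (default 0.99).
#' @param exclude Specimen ids to leave out before fitting.
#' @return An `ldc_model`.
#' @export
fit_fisher_ldc <- function(db, labels = NULL, variance_retained = 0.99,
                           exclude = NULL) {
  if (inherits(db, "ref_db")) {
    X <- db_features(db)
    y <- attr(X, "species")
    if (!is.null(exclude)) {
      keep <- !(rownames(X) %in% exclude)
      X <- X[keep, , drop = FALSE]; y <- y[keep]
    }
  } else {
    X <- as.matrix(db); y <- labels
    if (is.null(y)) stop("labels required when fitting from a matrix")
  }
  y <- factor(y)
  N <- nlevels(y); n <- nrow(X)
  if (N < 2L) stop("need at least 2 species to fit a discriminant")
  if (max(table(y)) < 2L) stop("need at least one species with >= 2 specimens")

  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  k99 <- which(cum >= variance_retained)[1]
  p_prime <- max(1L, min(n - N, k99, ncol(X)))
  rot <- pca$rotation[, seq_len(p_prime), drop = FALSE]
  Z <- sweep(X, 2, pca$center) %*% rot

  means <- do.call(rbind, lapply(levels(y), function(lv)
    colMeans(Z[y == lv, , drop = FALSE])))
  rownames(means) <- levels(y)
  gm <- colMeans(Z)
  W <- matrix(0, p_prime, p_prime)
  for (lv in levels(y)) {
    Zi <- sweep(Z[y == lv, , drop = FALSE], 2, means[lv, ])
    W <- W + crossprod(Zi)
  }
  Bm <- crossprod(sweep(means, 2, gm) * sqrt(as.vector(table(y))))
  ridge_used <- FALSE
  R <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(R)) {
    ridge_used <- TRUE
    W <- W + diag(1e-8 * sum(diag(W)) / p_prime, p_prime)
    R <- chol(W)
    message("within-class scatter singular after reduction; ridge 1e-8*trace added")
  }
  Rinv <- backsolve(R, diag(p_prime))
  S <- t(Rinv) %*% Bm %*% Rinv
  eig <- eigen((S + t(S)) / 2, symmetric = TRUE)
  q <- min(N - 1L, p_prime)
  A <- Rinv %*% eig$vectors[, seq_len(q), drop = FALSE]
  A <- A * sqrt(n - N)   # unit pooled within-class covariance in canonical space
  canon_means <- means %*% A
  structure(list(center = pca$center, rotation = rot, canon = A,
                 class_means = canon_means, levels = levels(y),
                 q = q, p_prime = p_prime,
                 eigenvalues = pmax(eig$values[seq_len(q)], 0),
                 within_cov_canon = diag(q),  # by construction
                 ridge_used = ridge_used, n = n, N = N),
            class = "ldc_model")
}

#' @export
print.ldc_model <- function(x, ...) {
  cat("<ldc_model> ", x$N, " classes, n = ", x$n, ", PCA dims p' = ", x$p_prime,
      ", canonical variates q = ", x$q,
      if (x$ridge_used) " (ridged)" else "", "\n", sep = "")
  invisible(x)
}

#' Classify a specimen with a fitted LDC model
#'
#' @param model An `ldc_model`.
#' @param query Landmarks tibble / n x 2 matrix, or a raw feature vector of
#'   the dimensionality the model was fitted on.
#' @return One-row tibble: `method`, `species`, `distance` (Mahalanobis in
#'   canonical space).
#' @export
predict_ldc <- function(model, query) {
  f <- query_to_features(query, length(model$center))
  z <- drop((f - model$center) %*% model$rotation %*% model$canon)
  d <- sqrt(colSums((t(model$class_means) - z)^2))
  i <- which.min(d)
  tibble::tibble(method = "ldc", species = model$levels[i], distance = unname(d[i]),
                 nearest_specimen_id = NA_character_)
}

query_to_features <- function(query, p) {
  if (is.numeric(query) && is.null(dim(query)) && length(query) == p) return(query)
  query_features(query, n_landmarks = p / 2L)
}

# ---- ECOC-SVM ----------------------------------------------------------------

#' Fit an error-correcting output-code SVM
#'
#' Trains one binary linear SVM per class pair (one-vs-one coding:
#' N(N-1)/2 learners) on per-feature standardized landmark features, with
#' uniform class priors and the default 0/1 misclassification cost. Decoding
#' assigns the class with the smallest aggregate binary hinge loss over the
#' learners that involve it.
#'
#' @inheritParams fit_fisher_ldc
#' @param cost Soft-margin cost of the binary learners.
#' @return An `ecoc_svm` model.
#' @export
fit_ecoc_svm <- function(db, labels = NULL, cost = 1, exclude = NULL) {
  if (inherits(db, "ref_db")) {
    X <- db_features(db)
    y <- attr(X, "species")
    if (!is.null(exclude)) {
      keep <- !(rownames(X) %in% exclude)
      X <- X[keep, , drop = FALSE]; y <- y[keep]
    }
  } else {
    X <- as.matrix(db); y <- labels
    if (is.null(y)) stop("labels required when fitting from a matrix")
  }
  y <- factor(y)
  N <- nlevels(y)
  if (N < 2L) stop("need at least 2 species to fit an SVM")
  singletons <- names(which(table(y) < 2L))
  if (length(singletons))
    warning("species with a single specimen (model trained but flagged): ",
            paste(singletons, collapse = ", "))
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  pairs <- utils::combn(levels(y), 2L)
  learners <- vector("list", ncol(pairs))
  for (l in seq_len(ncol(pairs))) {
    ci <- pairs[1, l]; cj <- pairs[2, l]
    sel <- y %in% c(ci, cj)
    yl <- factor(as.character(y[sel]), levels = c(ci, cj))  # positive = ci
    learners[[l]] <- e1071::svm(Xs[sel, , drop = FALSE], yl, kernel = "linear",
                                cost = cost, scale = FALSE)
  }
  structure(list(learners = learners, pairs = pairs, mu = mu, sd = sdv,
                 levels = levels(y), cost = cost, flagged = singletons,
                 n = nrow(X), N = N),
            class = "ecoc_svm")
}

#' @export
print.ecoc_svm <- function(x, ...) {
  cat("<ecoc_svm> ", x$N, " classes, ", length(x$learners),
      " binary linear learners (one-vs-one), n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Classify a specimen with a fitted ECOC-SVM
#'
#' @param model An `ecoc_svm`.
#' @param query Landmarks tibble / matrix / feature vector.
#' @return One-row tibble: `method`, `species`, `margin` (aggregate-loss gap
#'   to the runner-up class; larger is more confident).
#' @export
predict_svm <- function(model, query) {
  f <- query_to_features(query, length(model$mu))
  fs <- (f - model$mu) / model$sd
  L <- length(model$learners)
  dv <- numeric(L)
  for (l in seq_len(L)) {
    p <- stats::predict(model$learners[[l]], matrix(fs, nrow = 1), decision.values = TRUE)
    dv[l] <- as.numeric(attr(p, "decision.values"))  # positive = first class of pair
  }
  loss <- vapply(model$levels, function(cl) {
    inv <- which(model$pairs[1, ] == cl | model$pairs[2, ] == cl)
    m <- ifelse(model$pairs[1, inv] == cl, 1, -1)
    mean(pmax(0, 1 - m * dv[inv]))
  }, numeric(1))
  ord <- order(loss)
  margin <- if (length(loss) > 1L) loss[ord[2L]] - loss[ord[1L]] else Inf
  tibble::tibble(method = "svm", species = model$levels[ord[1L]],
                 distance = margin, nearest_specimen_id = NA_character_)
}

# ---- combined call -----------------------------------------------------------

#' Run all classification methods on one specimen
#'
#' Runs the five analyses (MHD against specimens and centroids, Procrustes
#' nearest neighbour, Fisher LDC, ECOC-SVM) and assembles one result table.
#' Methods that fail are reported with their error message instead of a
#' prediction; an error is raised only if every method fails.
#'
#' @param query Landmarks tibble of one specimen, or an n x 2 matrix.
#' @param db A [ref_db()].
#' @param methods Subset of `c("mhd_v", "mhd_c", "procrustes", "ldc", "svm")`.
#' @param exclude Specimen ids to leave out (leave-one-out mode).
#' @param models Optional list with prefitted `ldc` / `svm` models (to avoid
#'   refitting in batch runs).
#' @param specimen_id Id recorded in the result.
#' @return A `classification_result` tibble: one row per method with
#'   `specimen_id`, `method`, `species`, `distance` (distance or decision
#'   margin), `nearest_specimen_id`, `error`.
#' @export
classify_all <- function(query, db, methods = c("mhd_v", "mhd_c", "procrustes",
                                                "ldc", "svm"),
                         exclude = NULL, models = NULL, specimen_id = "") {
  stopifnot(inherits(db, "ref_db"))
  methods <- match.arg(methods, several.ok = TRUE)
  if (nrow(db$specimens) == 0L) stop("empty database")
  run <- function(m) {
    tryCatch(switch(m,
      mhd_v = classify_mhd(query, db, "specimens", exclude = exclude),
      mhd_c = classify_mhd(query, db, "centroids", exclude = exclude),
      procrustes = classify_procrustes(query, db, exclude = exclude),
      ldc = {
        mod <- if (!is.null(models$ldc)) models$ldc else
          fit_fisher_ldc(db, exclude = exclude)
        predict_ldc(mod, query)
      },
      svm = {
        mod <- if (!is.null(models$svm)) models$svm else
          suppressWarnings(fit_ecoc_svm(db, exclude = exclude))
        predict_svm(mod, query)
      }),
      error = function(e) tibble::tibble(method = m, species = NA_character_,
                                         distance = NA_real_,
                                         nearest_specimen_id = NA_character_,
                                         error = conditionMessage(e)))
  }
  out <- dplyr::bind_rows(lapply(methods, run))
  if (!"error" %in% names(out)) out$error <- NA_character_
  if (all(!is.na(out$error))) stop("all classification methods failed; first error: ",
                                   out$error[1])
  out <- tibble::add_column(out, specimen_id = specimen_id, .before = 1)
  class(out) <- c("classification_result", class(out))
  out
}

#' Classify a batch of specimens
#'
#' Splits a landmarks tibble by specimen and runs [classify_all()] on each,
#' fitting the LDC and SVM models once for the whole batch.
#'
#' @param landmarks Landmarks tibble with one or more specimens.
#' @param db A [ref_db()].
#' @inheritParams classify_all
#' @return A `classification_result` tibble with one row per specimen and
#'   method.
#' @export
classify_batch <- function(landmarks, db, methods = c("mhd_v", "mhd_c",
                                                      "procrustes", "ldc", "svm")) {
  methods <- match.arg(methods, several.ok = TRUE)
  models <- list(
    ldc = if ("ldc" %in% methods) fit_fisher_ldc(db) else NULL,
    svm = if ("svm" %in% methods) suppressWarnings(fit_ecoc_svm(db)) else NULL)
  out <- landmarks |>
    dplyr::group_split(.data$specimen_id) |>
    purrr::map(~ classify_all(.x, db, methods = methods, models = models,
                              specimen_id = .x$specimen_id[1])) |>
    dplyr::bind_rows()
  class(out) <- c("classification_result", class(out))
  out
}

#' Serialize a classification result to JSON
#'
#' One JSON object per specimen with one field per method (species, score,
#' nearest specimen where applicable).
#'
#' @param result A `classification_result` from [classify_all()].
#' @return A JSON string.
#' @export
classification_json <- function(result) {
  obj <- list(specimen_id = result$specimen_id[1])
  for (i in seq_len(nrow(result))) {
    r <- result[i, ]
    obj[[r$method]] <- if (!is.na(r$error)) list(error = r$error) else {
      x <- list(species = r$species, score = r$distance)
      if (!is.na(r$nearest_specimen_id)) x$nearest_specimen_id <- r$nearest_specimen_id
      x
    }
  }
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 9)
}
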