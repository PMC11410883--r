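# The four affinity measures and the combined call.

test_that("mhd reproduces hand values and the brute-force oracle", {
  expect_equal(mhd(rbind(c(0, 0), c(1, 0)), rbind(c(0, 0), c(1, 0))), 0)
  expect_equal(mhd(cbind(0, 0), cbind(3, 4)), 5)
  expect_error(mhd(matrix(numeric(0), 0, 2), cbind(1, 1)), "empty")

  set.seed(11)
  for (k in 1:40) {
    A <- matrix(runif(2 * sample(60, 1), -1, 1), ncol = 2)
    B <- matrix(runif(2 * sample(60, 1), -1, 1), ncol = 2)
    expect_lt(abs(mhd(A, B) - mhd_bruteforce(A, B)), 1e-12)
    expect_equal(mhd(A, B), mhd(B, A))      # symmetric
    expect_gte(mhd(A, B), 0)
    expect_equal(mhd(A, A), 0)
  }
})

test_that("classify_mhd assigns the nearest specimen or centroid deterministically", {
  db <- fx_small_db()
  id1 <- db$specimens$specimen_id[1]
  q <- db$landmarks[db$landmarks$specimen_id == id1, ]
  hit <- classify_mhd(q, db, "specimens")
  expect_equal(hit$species, db$specimens$species[1])
  expect_equal(hit$distance, 0)
  expect_equal(hit$nearest_specimen_id, id1)

  # noisy query near its own template classifies home (margin >> noise)
  tpl <- fx_template("microtus-like")
  spec <- generate_specimen(tpl, 0.02, seed = 77)
  qm <- resample_polyline(truth_semiperimeter(spec), 200)
  expect_equal(classify_mhd(qm, db, "specimens")$species, "microtus-like")
  expect_equal(classify_mhd(qm, db, "centroids")$species, "microtus-like")

  # single-member species: centroid mode equals specimen mode
  one <- ref_db(db$landmarks[db$landmarks$specimen_id %in%
                               db$specimens$specimen_id[!duplicated(db$specimens$species)], ])
  expect_equal(classify_mhd(qm, one, "centroids")$species,
               classify_mhd(qm, one, "specimens")$species)
  expect_error(classify_mhd(qm, db, "specimens",
                            exclude = db$specimens$specimen_id), "empty database")
})

test_that("procrustes dissimilarity is invariant under similarity transforms", {
  set.seed(21)
  A <- matrix(rnorm(100), ncol = 2)
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  B <- 2.5 * A %*% R
  B <- sweep(B, 2, c(5, 5), `+`)
  expect_lt(procrustes_dist(A, B)$dissimilarity, 1e-9)
  expect_lt(procrustes_dist(A, A %*% diag(c(-1, 1)))$dissimilarity, 1e-9)  # reflection
  expect_error(procrustes_dist(A, matrix(1, 50, 2)), "degenerate")
  expect_error(procrustes_dist(A, A[1:10, ]), "same point count")

  # the aligned copy really is superimposed on A
  fit <- procrustes_dist(A, B)
  expect_lt(max(abs(fit$b_aligned - A)), 1e-9)
})

test_that("procrustes matches the grid-search oracle on triangles and random shapes", {
  A <- rbind(c(0, 0), c(1, 0), c(0, 1))
  B <- rbind(c(0, 0), c(2, 0), c(0, 1))
  expect_lt(abs(procrustes_dist(A, B)$dissimilarity - procrustes_gridsearch(A, B)),
            1e-6)
  set.seed(31)
  for (k in 1:10) {
    A <- matrix(rnorm(2 * sample(3:30, 1)), ncol = 2)
    B <- matrix(rnorm(2 * nrow(A)), ncol = 2)
    expect_lt(abs(procrustes_dist(A, B)$dissimilarity - procrustes_gridsearch(A, B)),
              1e-6)
  }
})

test_that("procrustes agrees with vegan's symmetric superimposition", {
  set.seed(41)
  A <- matrix(rnorm(80), ncol = 2)
  B <- matrix(rnorm(80), ncol = 2)
  v <- vegan::procrustes(A, B, symmetric = TRUE)
  expect_equal(procrustes_dist(A, B)$dissimilarity, v$ss, tolerance = 1e-10)
})

test_that("classify_procrustes finds itself and breaks ties by database order", {
  db <- fx_small_db()
  id1 <- db$specimens$specimen_id[5]
  q <- db$landmarks[db$landmarks$specimen_id == id1, ]
  hit <- classify_procrustes(q, db)
  expect_equal(hit$nearest_specimen_id, id1)
  expect_lt(hit$distance, 1e-12)

  # all-identical db: first record wins
  th <- seq(0, pi, length.out = 200)
  rows <- lapply(1:4, function(i)
    tibble::tibble(specimen_id = paste0("s", i), species = c("a", "a", "b", "b")[i],
                   source_kind = "photo", point_index = 1:200,
                   x_mm = cos(th), y_mm = sin(th)))
  same <- ref_db(dplyr::bind_rows(rows))
  hit2 <- classify_procrustes(cbind(cos(th), sin(th)), same)
  expect_equal(hit2$nearest_specimen_id, "s1")
})

test_that("the Fisher LDC respects q = min(N-1, p') and separates clear classes", {
  # dimensionality contract across N
  set.seed(51)
  for (N in c(2L, 5L, 10L)) {
    X <- do.call(rbind, lapply(seq_len(N), function(c)
      matrix(rnorm(12 * 20, mean = 3 * c), ncol = 20)))
    y <- rep(paste0("c", seq_len(N)), each = 12)
    m <- fit_fisher_ldc(X, y)
    expect_equal(m$q, min(N - 1L, m$p_prime))
    expect_lte(m$q, N - 1L)
    # between-class scatter in canonical space is diagonal and decreasing
    expect_true(all(diff(m$eigenvalues) <= 1e-8))
  }

  # two spherical Gaussians 10 sigma apart: 100% leave-one-out accuracy
  set.seed(52)
  X2 <- rbind(matrix(rnorm(40 * 2, 0), ncol = 2), matrix(rnorm(40 * 2, 10), ncol = 2))
  y2 <- rep(c("a", "b"), each = 40)
  pred <- vapply(seq_len(80), function(i)
    predict_ldc(fit_fisher_ldc(X2[-i, ], y2[-i]), X2[i, ])$species, character(1))
  expect_equal(mean(pred == y2), 1)

  # a query at a class's canonical mean is assigned to that class
  m2 <- fit_fisher_ldc(X2, y2)
  mu_b <- colMeans(X2[y2 == "b", ])
  expect_equal(predict_ldc(m2, mu_b)$species, "b")
})

test_that("LDC predictions agree with MASS::lda on a well-posed problem", {
  set.seed(53)
  X <- rbind(matrix(rnorm(40 * 4, 0), ncol = 4),
             matrix(rnorm(40 * 4, 2), ncol = 4),
             matrix(rnorm(40 * 4, -2), ncol = 4))
  y <- rep(c("a", "b", "c"), each = 40)
  mine <- fit_fisher_ldc(X, y)
  ref <- MASS::lda(X, grouping = y)
  p_mine <- vapply(seq_len(nrow(X)), function(i) predict_ldc(mine, X[i, ])$species,
                   character(1))
  p_ref <- as.character(predict(ref, X)$class)
  expect_equal(p_mine, p_ref)
})

test_that("the ECOC-SVM has N(N-1)/2 linear learners and separates separable data", {
  db <- fx_small_db()   # 3 species
  m <- fit_ecoc_svm(db)
  expect_equal(length(m$learners), 3L)      # 3*2/2
  expect_s3_class(tidy(m), "tbl_df")

  set.seed(61)
  X5 <- do.call(rbind, lapply(1:5, function(c) matrix(rnorm(10 * 8, 6 * c), ncol = 8)))
  y5 <- rep(paste0("c", 1:5), each = 10)
  m5 <- fit_ecoc_svm(X5, y5)
  expect_equal(length(m5$learners), 10L)    # 5*4/2

  # linearly separable two-class problem: 100% training accuracy
  X2 <- rbind(matrix(rnorm(30 * 2, 0), ncol = 2), matrix(rnorm(30 * 2, 8), ncol = 2))
  y2 <- rep(c("a", "b"), each = 30)
  m2 <- fit_ecoc_svm(X2, y2)
  pred <- vapply(seq_len(60), function(i) predict_svm(m2, X2[i, ])$species,
                 character(1))
  expect_equal(mean(pred == y2), 1)

  # single-specimen class is trained but flagged
  X1 <- rbind(X2, c(20, 20))
  expect_warning(m1 <- fit_ecoc_svm(X1, c(y2, "lonely")), "single specimen")
  expect_equal(m1$flagged, "lonely")
})

test_that("classify_all runs every method and serializes to one JSON object", {
  db <- fx_small_db()
  tpl <- fx_template("arvalis-like")
  q <- resample_polyline(truth_semiperimeter(generate_specimen(tpl, 0.01, seed = 9)), 200)
  res <- classify_all(q, db, specimen_id = "query1")
  expect_s3_class(res, "classification_result")
  expect_setequal(res$method, c("mhd_v", "mhd_c", "procrustes", "ldc", "svm"))
  expect_true(all(res$species == "arvalis-like"))
  expect_true(all(res$distance[res$method != "svm"] >= 0))
  expect_true(!is.na(res$nearest_specimen_id[res$method == "procrustes"]))

  js <- jsonlite::fromJSON(classification_json(res))
  expect_setequal(names(js), c("specimen_id", "mhd_v", "mhd_c", "procrustes",
                               "ldc", "svm"))

  # LOO mode: excluding a db member still classifies it correctly
  id <- db$specimens$specimen_id[1]
  qs <- db$landmarks[db$landmarks$specimen_id == id, ]
  loo <- classify_all(qs, db, exclude = id, specimen_id = id)
  expect_false(any(loo$nearest_specimen_id == id, na.rm = TRUE))

  expect_error(classify_all(q, ref_db(db$landmarks[0, ])), "empty")
})

test_that("classify_batch classifies several specimens with shared models", {
  db <- fx_small_db()
  ids <- db$specimens$specimen_id[c(1, 9, 17)]
  q <- db$landmarks[db$landmarks$specimen_id %in% ids, ]
  res <- classify_batch(q, db, methods = c("mhd_v", "svm"))
  expect_equal(nrow(res), 6L)
  expect_setequal(unique(res$specimen_id), ids)
  truth <- db$specimens$species[match(res$specimen_id, db$specimens$specimen_id)]
  expect_true(all(res$species == truth))
})

test_that("classifiers are deterministic functions of database and query", {
  db <- fx_small_db()
  tpl <- fx_template("microtus-like")
  q <- resample_polyline(truth_semiperimeter(generate_specimen(tpl, 0.02, seed = 13)), 200)
  r1 <- classify_all(q, db)
  r2 <- classify_all(q, db)
  expect_identical(r1, r2)
})
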