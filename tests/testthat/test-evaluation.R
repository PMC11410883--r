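# Leave-one-out evaluation and the exemplar cluster.

test_that("LOO on a separable synthetic database is perfect for every method", {
  db <- fx_small_db()   # separation ~10x the noise level
  res <- leave_one_out(db, seed = 1)
  expect_true(all(res$totals$accuracy_pct == 100))
  # aggregation identity: per-method totals = sums over species
  for (m in res$methods) {
    sp <- res$by_species[res$by_species$method == m, ]
    tot <- res$totals[res$totals$method == m, ]
    expect_equal(sum(sp$correct), tot$correct)
    expect_equal(sum(sp$total), tot$total)
    expect_equal(tot$accuracy_pct, 100 * tot$correct / tot$total)
  }
  # the held-out specimen never scores against itself
  expect_false(any(res$predictions$score == 0 &
                     res$predictions$method %in% c("mhd_v", "procrustes")))
})

test_that("twin specimens guarantee a perfect MHD nearest-neighbour LOO", {
  th <- seq(0, pi, length.out = 200)
  mk <- function(id, sp, d) tibble::tibble(specimen_id = id, species = sp,
                                           source_kind = "photo", point_index = 1:200,
                                           x_mm = cos(th) * d, y_mm = sin(th) * d)
  db <- ref_db(dplyr::bind_rows(mk("a1", "a", 1), mk("a2", "a", 1),
                                mk("b1", "b", 2), mk("b2", "b", 2)))
  res <- leave_one_out(db, methods = "mhd_v", seed = 1)
  expect_equal(res$totals$accuracy_pct, 100)
})

test_that("LOO excludes single-specimen species and reports them", {
  db <- fx_small_db()
  keep <- db$landmarks$specimen_id != db$specimens$specimen_id[1] |
    db$landmarks$specimen_id == db$specimens$specimen_id[1]
  lone <- dplyr::mutate(db$landmarks,
                        species = ifelse(.data$specimen_id == db$specimens$specimen_id[1],
                                         "lonely", .data$species))
  db2 <- ref_db(lone)
  expect_message(res <- leave_one_out(db2, methods = "mhd_v", seed = 1), "excluded")
  expect_false("lonely" %in% res$by_species$species)
})

test_that("LOO reports are reproducible under a repeated run", {
  db <- fx_small_db()
  r1 <- leave_one_out(db, methods = c("mhd_v", "svm"), seed = 3)
  r2 <- leave_one_out(db, methods = c("mhd_v", "svm"), seed = 3)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$by_species, r2$by_species)
})

test_that("the accuracy table splits by source dialect", {
  db <- fx_small_db()
  mixed <- db$landmarks
  half <- unique(mixed$specimen_id)[seq(1, 24, 2)]
  mixed$source_kind <- ifelse(mixed$specimen_id %in% half, "drawing", "photo")
  res <- leave_one_out(ref_db(mixed), methods = "mhd_v", seed = 1)
  expect_setequal(unique(res$by_source$source_kind), c("photo", "drawing"))
  # pooled counts equal the by-source sums
  m <- merge(stats::aggregate(correct ~ species, data = res$by_source, sum),
             res$by_species[, c("species", "correct")], by = "species")
  expect_equal(m$correct.x, m$correct.y)
})

test_that("UPGMA reproduces the hand-computed topology and heights", {
  D <- matrix(c(0, .1, .4, .1, 0, .4, .4, .4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma_tree(D)
  expect_s3_class(tree, "phylo")
  # topology ((A,B),C)
  expect_true(ape::is.monophyletic(tree, c("A", "B")))
  # ultrametric heights: A and B join at 0.1/2
  expect_equal(max(ape::node.depth.edgelength(tree)), 0.4 / 2, tolerance = 1e-12)

  # two species join at half their distance
  D2 <- matrix(c(0, .3, .3, 0), 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  t2 <- upgma_tree(D2)
  expect_equal(t2$edge.length, c(0.15, 0.15))
})

test_that("exemplar_cluster picks centroid-nearest all-correct exemplars deterministically", {
  db <- fx_small_db()
  loo <- leave_one_out(db, seed = 1)
  cl1 <- exemplar_cluster(db, loo = loo)
  cl2 <- exemplar_cluster(db, loo = loo)
  expect_identical(cl1$newick, cl2$newick)
  expect_equal(nrow(cl1$exemplars), 3L)
  expect_match(cl1$disclaimer, "no biological or phylogenetic significance")
  # newick labels are the species
  expect_setequal(cl1$tree$tip.label, unique(db$specimens$species))
  # exemplar is the all-correct specimen closest to its species centroid
  sp <- cl1$exemplars$species[1]
  cen <- landmarks_matrix(db$centroids[db$centroids$species == sp, ])
  cand <- db$specimens$specimen_id[db$specimens$species == sp]
  d <- vapply(cand, function(id)
    procrustes_dist(landmarks_matrix(db$landmarks, id), cen)$dissimilarity,
    numeric(1))
  expect_equal(cl1$exemplars$specimen_id[1], cand[which.min(d)])

  f <- tempfile(fileext = ".nwk")
  write_cluster(cl1, f)
  lines <- readLines(f)
  expect_match(lines[1], "no biological")
  expect_silent(ape::read.tree(text = lines[2]))
  unlink(f)
})

test_that("tidy and glance summarize evaluation objects", {
  db <- fx_small_db()
  res <- leave_one_out(db, methods = c("mhd_v", "ldc"), seed = 2)
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(nrow(g), 1L)
  expect_true(all(c("accuracy_mhd_v", "accuracy_ldc") %in% names(g)))

  m <- fit_fisher_ldc(db)
  expect_equal(nrow(tidy(m)), m$q)
  expect_equal(glance(m)$q, m$q)
})
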