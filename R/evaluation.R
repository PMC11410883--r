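# Batch evaluation: leave-one-out accuracy tables (by species, method and
# source dialect) and the species-exemplar similarity cluster.

#' Leave-one-out accuracy of the classification methods
#'
#' Classifies every database specimen against the database minus itself.
#' Model-based methods (LDC, SVM) are refitted for every fold with the
#' held-out specimen excluded; the distance-based methods use precomputed
#' pairwise distance matrices with the held-out row masked, so the held-out
#' specimen never influences the model it is scored against. Species with a
#' single specimen are excluded from their own row (there is nothing to
#' compare them against) and reported.
#'
#' @param db A [ref_db()].
#' @param methods Subset of `c("mhd_v", "mhd_c", "procrustes", "ldc", "svm")`.
#' @param seed Integer seed, recorded in the result (all methods are
#'   deterministic; the seed makes the report reproducible byte for byte).
#' @return A `loo_result`: list with `predictions` (one row per specimen and
#'   method), `by_species`, `by_source`, `totals` accuracy tibbles, `excluded`
#'   ids, `seed`.
#' @export
leave_one_out <- function(db, methods = c("mhd_v", "mhd_c", "procrustes",
                                          "ldc", "svm"), seed = 1L) {
  stopifnot(inherits(db, "ref_db"))
  methods <- match.arg(methods, several.ok = TRUE)
  set.seed(as.integer(seed))
  ids <- db$specimens$specimen_id
  spp <- db$specimens$species
  n <- length(ids)
  counts <- table(spp)
  excluded <- ids[spp %in% names(counts)[counts < 2L]]
  if (length(excluded))
    message("excluded from LOO (single specimen of their species): ",
            paste(excluded, collapse = ", "))
  eval_ids <- setdiff(ids, excluded)

  shapes_c <- db_shapes(db, centre = TRUE)
  shapes_r <- db_shapes(db, centre = FALSE)

  D_mhd <- if (any(c("mhd_v") %in% methods)) pairwise_matrix(shapes_c, mhd) else NULL
  D_pro <- if ("procrustes" %in% methods)
    pairwise_matrix(shapes_r, function(a, b) procrustes_dist(a, b)$dissimilarity) else NULL

  # per-species landmark sums for fast leave-one-out centroids
  if ("mhd_c" %in% methods) {
    sums <- lapply(split(seq_len(n), spp), function(is)
      Reduce(`+`, shapes_r[is]))
    nsp <- table(spp)
  }

  preds <- vector("list", n)
  for (i in seq_len(n)) {
    if (!(ids[i] %in% eval_ids)) next
    rows <- list()
    if ("mhd_v" %in% methods) {
      d <- D_mhd[i, ]; d[i] <- Inf
      j <- which.min(d)
      rows$mhd_v <- tibble::tibble(method = "mhd_v", predicted = spp[j], score = d[j])
    }
    if ("mhd_c" %in% methods) {
      q <- shapes_c[[i]]
      dsp <- vapply(names(sums), function(s) {
        cen <- if (s == spp[i]) (sums[[s]] - shapes_r[[i]]) / (nsp[[s]] - 1L)
               else sums[[s]] / nsp[[s]]
        mhd(q, sweep(cen, 2, colMeans(cen)))
      }, numeric(1))
      j <- which.min(dsp)
      rows$mhd_c <- tibble::tibble(method = "mhd_c", predicted = names(sums)[j],
                                   score = dsp[j])
    }
    if ("procrustes" %in% methods) {
      d <- D_pro[i, ]; d[i] <- Inf
      j <- which.min(d)
      rows$procrustes <- tibble::tibble(method = "procrustes", predicted = spp[j],
                                        score = d[j])
    }
    if ("ldc" %in% methods) {
      fit <- fit_fisher_ldc(db, exclude = ids[i])
      p <- predict_ldc(fit, c(shapes_c[[i]][, 1], shapes_c[[i]][, 2]))
      rows$ldc <- tibble::tibble(method = "ldc", predicted = p$species, score = p$distance)
    }
    if ("svm" %in% methods) {
      fit <- suppressWarnings(fit_ecoc_svm(db, exclude = ids[i]))
      p <- predict_svm(fit, c(shapes_c[[i]][, 1], shapes_c[[i]][, 2]))
      rows$svm <- tibble::tibble(method = "svm", predicted = p$species, score = p$distance)
    }
    preds[[i]] <- dplyr::bind_rows(rows)
    preds[[i]]$specimen_id <- ids[i]
    preds[[i]]$species <- spp[i]
    preds[[i]]$source_kind <- db$specimens$source_kind[i]
  }
  predictions <- dplyr::bind_rows(preds)
  predictions$correct <- predictions$predicted == predictions$species
  predictions <- predictions[, c("specimen_id", "species", "source_kind",
                                 "method", "predicted", "score", "correct")]

  acc <- function(g) {
    out <- dplyr::summarise(g, accuracy_pct = 100 * mean(.data$correct),
                            correct = sum(.data$correct), total = dplyr::n(),
                            .groups = "drop")
    dplyr::relocate(out, "accuracy_pct", .after = "total")
  }
  by_species <- acc(dplyr::group_by(predictions, .data$species, .data$method))
  by_source <- acc(dplyr::group_by(predictions, .data$species, .data$source_kind,
                                   .data$method))
  totals <- acc(dplyr::group_by(predictions, .data$method))

  structure(list(predictions = predictions, by_species = by_species,
                 by_source = by_source, totals = totals,
                 excluded = excluded, seed = as.integer(seed),
                 methods = methods),
            class = "loo_result")
}

pairwise_matrix <- function(shapes, f) {
  n <- length(shapes)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- f(shapes[[i]], shapes[[j]])
  }
  D
}

#' @export
print.loo_result <- function(x, ...) {
  cat("<loo_result> ", length(unique(x$predictions$specimen_id)), " specimens, methods: ",
      paste(x$methods, collapse = ", "), ", seed ", x$seed, "\n", sep = "")
  wide <- tidyr::pivot_wider(x$by_species[, c("species", "method", "accuracy_pct")],
                             names_from = "method", values_from = "accuracy_pct")
  print(wide)
  cat("totals:\n"); print(x$totals)
  invisible(x)
}

#' Species-exemplar similarity cluster
#'
#' Picks one exemplar per species -- among the specimens correctly classified
#' by *all* evaluated methods in the leave-one-out run, the one closest
#' (Procrustes) to its species centroid -- computes the pairwise Procrustes
#' dissimilarity matrix between exemplars and joins them by UPGMA (average
#' linkage). The cluster summarizes geometric similarity among the database
#' species only; it has no biological or phylogenetic meaning, and the newick
#' output carries that disclaimer.
#'
#' @param db A [ref_db()].
#' @param loo Optional precomputed [leave_one_out()] result for `db`.
#' @param linkage `"average"` (UPGMA), `"complete"` or `"single"`.
#' @param seed Seed forwarded to [leave_one_out()] when it must be run.
#' @return An `exemplar_cluster`: list with `tree` (ape phylo), `newick`
#'   string, `exemplars` tibble, `distances` matrix, `disclaimer`.
#' @export
exemplar_cluster <- function(db, loo = NULL,
                             linkage = c("average", "complete", "single"),
                             seed = 1L) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(db, "ref_db"))
  if (is.null(loo)) loo <- leave_one_out(db, seed = seed)
  all_ok <- dplyr::summarise(dplyr::group_by(loo$predictions, .data$specimen_id,
                                             .data$species),
                             ok = all(.data$correct), .groups = "drop")
  cen <- db$centroids
  pick <- list()
  for (sp in unique(db$specimens$species)) {
    cand <- all_ok$specimen_id[all_ok$species == sp & all_ok$ok]
    if (!length(cand)) {
      warning("species '", sp, "' has no specimen correctly classified by all ",
              "methods; dropped from the cluster")
      next
    }
    cm <- landmarks_matrix(cen[cen$species == sp, ])
    d <- vapply(cand, function(id)
      procrustes_dist(landmarks_matrix(db$landmarks, id), cm)$dissimilarity,
      numeric(1))
    pick[[sp]] <- cand[which.min(d)]
  }
  if (length(pick) < 2L) stop("fewer than 2 species with all-methods-correct exemplars")
  exemplars <- tibble::tibble(species = names(pick),
                              specimen_id = unlist(pick, use.names = FALSE))
  shapes <- lapply(exemplars$specimen_id, function(id) landmarks_matrix(db$landmarks, id))
  D <- pairwise_matrix(shapes, function(a, b) procrustes_dist(a, b)$dissimilarity)
  dimnames(D) <- list(exemplars$species, exemplars$species)
  tree <- upgma_tree(D, method = linkage)
  structure(list(tree = tree, newick = ape::write.tree(tree),
                 exemplars = exemplars, distances = D, linkage = linkage,
                 disclaimer = paste("geometric similarity of database exemplars;",
                                    "no biological or phylogenetic significance")),
            class = "exemplar_cluster")
}

#' UPGMA (or other agglomerative) tree from a distance matrix
#'
#' Thin wrapper over `hclust` + `ape::as.phylo` producing an ultrametric tree
#' whose node heights are half the merge distances.
#'
#' @param D Symmetric distance matrix (or `dist`) with labels.
#' @param method `hclust` linkage method; `"average"` is UPGMA.
#' @return An `ape::phylo` tree.
#' @export
upgma_tree <- function(D, method = "average") {
  ape::as.phylo(stats::hclust(stats::as.dist(D), method = method))
}

#' @export
print.exemplar_cluster <- function(x, ...) {
  cat("<exemplar_cluster> ", nrow(x$exemplars), " species, ", x$linkage,
      " linkage\n  ", x$newick, "\n  note: ", x$disclaimer, "\n", sep = "")
  invisible(x)
}

#' Write an exemplar cluster to a newick file
#'
#' The disclaimer travels as a comment line above the tree.
#'
#' @param cluster An `exemplar_cluster`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cluster <- function(cluster, path) {
  writeLines(c(paste0("[", cluster$disclaimer, "]"), cluster$newick), path)
  invisible(path)
}
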