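# The reference database: labelled 200-landmark specimens plus per-species
# centroid shapes, persisted as plain CSV with a JSON metadata sidecar (the
# open-format replacement for the original per-study .mat files).

#' Build a reference database from a landmarks table
#'
#' Validates the landmark records (non-empty species, the exact landmark
#' count per specimen, unique specimen ids), sorts them by (species,
#' specimen_id) for reproducible tie-breaking, and computes per-species
#' centroid shapes as the pointwise arithmetic mean of raw (calibrated,
#' oriented) coordinates. No superimposition is applied before averaging
#' unless `align = TRUE`, which centres each specimen on its own centroid
#' first.
#'
#' @param landmarks Tibble with columns `specimen_id`, `species`,
#'   `source_kind`, `point_index`, `x_mm`, `y_mm`.
#' @param provenance Optional tibble (`specimen_id`, `provenance`) of free-text
#'   origin notes.
#' @param n_landmarks Required landmarks per specimen (default 200).
#' @param align Centre specimens before centroid averaging (off by default).
#' @return A `ref_db` object: list with `landmarks`, `specimens`, `centroids`
#'   tibbles and `n_landmarks`.
#' @export
ref_db <- function(landmarks, provenance = NULL, n_landmarks = 200L, align = FALSE) {
  req <- c("specimen_id", "species", "source_kind", "point_index", "x_mm", "y_mm")
  miss <- setdiff(req, names(landmarks))
  if (length(miss)) stop("landmarks table lacks columns: ", paste(miss, collapse = ", "))
  landmarks <- tibble::as_tibble(landmarks)[req]
  if (nrow(landmarks) == 0L) stop("empty landmarks table")

  bad_sp <- unique(landmarks$specimen_id[is.na(landmarks$species) | landmarks$species == ""])
  if (length(bad_sp))
    stop("records with empty species label: ", paste(bad_sp, collapse = ", "))

  meta <- dplyr::distinct(landmarks, .data$specimen_id, .data$species, .data$source_kind)
  dup <- meta$specimen_id[duplicated(meta$specimen_id)]
  if (length(dup))
    stop("duplicate specimen_id with conflicting metadata: ", paste(unique(dup), collapse = ", "))

  counts <- dplyr::count(landmarks, .data$specimen_id)
  wrong <- counts$specimen_id[counts$n != n_landmarks]
  chk <- dplyr::summarise(dplyr::group_by(landmarks, .data$specimen_id),
                          ok = length(.data$point_index) == n_landmarks &&
                            all(sort(as.integer(.data$point_index)) == seq_len(n_landmarks)),
                          .groups = "drop")
  wrong <- union(wrong, chk$specimen_id[!chk$ok])
  if (length(wrong))
    stop("records without exactly ", n_landmarks, " landmarks (point_index 1..",
         n_landmarks, "): ", paste(wrong, collapse = ", "))
  if (any(!is.finite(landmarks$x_mm)) || any(!is.finite(landmarks$y_mm)))
    stop("non-finite landmark coordinates")

  landmarks <- dplyr::arrange(landmarks, .data$species, .data$specimen_id, .data$point_index)
  specimens <- dplyr::distinct(landmarks, .data$specimen_id, .data$species, .data$source_kind)
  if (!is.null(provenance))
    specimens <- dplyr::left_join(specimens, provenance, by = "specimen_id")

  structure(list(landmarks = landmarks, specimens = specimens,
                 centroids = species_centroids(landmarks, align = align),
                 n_landmarks = as.integer(n_landmarks), align = align),
            class = "ref_db")
}

#' Per-species centroid shapes
#'
#' The k-th centroid point of a species is the arithmetic mean of the k-th
#' landmark over that species' records.
#'
#' @param x A `ref_db` or a landmarks tibble.
#' @param align Centre each specimen on its own centroid before averaging.
#' @return Tibble `species`, `point_index`, `x_mm`, `y_mm`.
#' @export
species_centroids <- function(x, align = FALSE) {
  landmarks <- if (inherits(x, "ref_db")) x$landmarks else tibble::as_tibble(x)
  if (nrow(landmarks) == 0L) stop("empty database: no centroids to compute")
  if (align) {
    landmarks <- dplyr::mutate(dplyr::group_by(landmarks, .data$specimen_id),
                               x_mm = .data$x_mm - mean(.data$x_mm),
                               y_mm = .data$y_mm - mean(.data$y_mm))
    landmarks <- dplyr::ungroup(landmarks)
  }
  out <- dplyr::summarise(dplyr::group_by(landmarks, .data$species, .data$point_index),
                          x_mm = mean(.data$x_mm), y_mm = mean(.data$y_mm),
                          .groups = "drop")
  dplyr::arrange(out, .data$species, .data$point_index)
}

#' @export
print.ref_db <- function(x, ...) {
  tab <- dplyr::count(x$specimens, .data$species)
  cat("<ref_db> ", nrow(x$specimens), " specimens, ", nrow(tab), " species, ",
      x$n_landmarks, " landmarks each\n", sep = "")
  for (i in seq_len(nrow(tab))) cat("  ", tab$species[i], ": ", tab$n[i], "\n", sep = "")
  invisible(x)
}

#' Save / load a reference database
#'
#' `write_ref_db()` writes `landmarks.csv`, `centroids.csv` and `meta.json`
#' into a directory; `read_ref_db()` reads them back, revalidates the records,
#' recomputes the centroids and errors if they differ from the stored ones by
#' more than 1e-9 mm. The round trip is lossless (full-precision CSV).
#'
#' @param db A `ref_db`.
#' @param dir Directory to write to / read from.
#' @return `write_ref_db()` the directory, invisibly; `read_ref_db()` a
#'   `ref_db`.
#' @export
write_ref_db <- function(db, dir) {
  stopifnot(inherits(db, "ref_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(db$landmarks, file.path(dir, "landmarks.csv"))
  readr::write_csv(db$centroids, file.path(dir, "centroids.csv"))
  meta <- list(
    n_landmarks = db$n_landmarks, align = isTRUE(db$align),
    n_specimens = nrow(db$specimens),
    species = as.list(table(db$specimens$species)),
    specimens = db$specimens
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_ref_db
#' @export
read_ref_db <- function(dir) {
  lm_path <- file.path(dir, "landmarks.csv")
  if (!file.exists(lm_path)) stop("not a reference database directory: ", dir)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  landmarks <- readr::read_csv(lm_path, show_col_types = FALSE,
                               col_types = readr::cols(
                                 specimen_id = "c", species = "c",
                                 source_kind = "c", point_index = "i",
                                 x_mm = "d", y_mm = "d"))
  db <- ref_db(landmarks, n_landmarks = meta$n_landmarks,
               align = isTRUE(meta$align))
  stored <- readr::read_csv(file.path(dir, "centroids.csv"), show_col_types = FALSE)
  stored <- dplyr::arrange(stored, .data$species, .data$point_index)
  if (!identical(stored$species, db$centroids$species) ||
      max(abs(stored$x_mm - db$centroids$x_mm),
          abs(stored$y_mm - db$centroids$y_mm)) > 1e-9)
    stop("stored centroids disagree with recomputed centroids (> 1e-9 mm); ",
         "database is corrupt")
  db
}

# ---- internal matrix accessors ----------------------------------------------

# 200 x 2 coordinate matrix of one specimen (rows in point_index order)
landmarks_matrix <- function(landmarks, id = NULL) {
  lm <- if (is.null(id)) landmarks else landmarks[landmarks$specimen_id == id, ]
  lm <- lm[order(lm$point_index), ]
  cbind(lm$x_mm, lm$y_mm)
}

# coerce a query (landmarks tibble of one specimen, or a plain matrix) to a
# coordinate matrix
query_matrix <- function(query) {
  if (is.matrix(query)) return(query)
  q <- tibble::as_tibble(query)
  ids <- unique(q$specimen_id)
  if (length(ids) > 1L) stop("query contains ", length(ids),
                             " specimens; classify them one at a time or use purrr::map")
  landmarks_matrix(q)
}

# list of per-specimen centred coordinate matrices, in db order
db_shapes <- function(db, centre = TRUE) {
  ids <- db$specimens$specimen_id
  out <- lapply(ids, function(id) {
    m <- landmarks_matrix(db$landmarks, id)
    if (centre) sweep(m, 2, colMeans(m)) else m
  })
  names(out) <- ids
  out
}

# n x 2p feature matrix (x1..xp, y1..yp), each specimen centred on its own
# centroid; scale deliberately NOT normalized (absolute size is diagnostic)
db_features <- function(db) {
  shapes <- db_shapes(db, centre = TRUE)
  X <- t(vapply(shapes, function(m) c(m[, 1], m[, 2]),
                numeric(2L * db$n_landmarks)))
  rownames(X) <- db$specimens$specimen_id
  attr(X, "species") <- db$specimens$species
  X
}

query_features <- function(query, n_landmarks = 200L) {
  m <- query_matrix(query)
  if (nrow(m) != n_landmarks)
    stop("query has ", nrow(m), " landmarks; database uses ", n_landmarks)
  m <- sweep(m, 2, colMeans(m))
  c(m[, 1], m[, 2])
}
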