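# broom-style tidiers for the fitted objects and result containers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidy.loo_result
#' @export
tidy.ldc_model <- function(x, ...) {
  tibble::tibble(canonical_axis = seq_len(x$q),
                 eigenvalue = x$eigenvalues,
                 discriminant_power = x$eigenvalues / sum(x$eigenvalues))
}

#' @rdname tidy.loo_result
#' @export
glance.ldc_model <- function(x, ...) {
  tibble::tibble(n = x$n, n_species = x$N, p_prime = x$p_prime, q = x$q,
                 ridge_used = x$ridge_used)
}

#' @rdname tidy.loo_result
#' @export
tidy.ecoc_svm <- function(x, ...) {
  tibble::tibble(learner = seq_along(x$learners),
                 class_pos = x$pairs[1, ], class_neg = x$pairs[2, ],
                 n_support_vectors = vapply(x$learners, function(m) m$tot.nSV, 1L))
}

#' @rdname tidy.loo_result
#' @export
glance.ecoc_svm <- function(x, ...) {
  tibble::tibble(n = x$n, n_species = x$N, n_learners = length(x$learners),
                 cost = x$cost, n_flagged_species = length(x$flagged))
}

#' Tidy and summarize evaluation results
#'
#' `tidy()` on a [leave_one_out()] result returns the per-species accuracy
#' table; `glance()` one row of per-method totals. `tidy()` on the fitted
#' classifier models returns their per-component summaries
#' (canonical axes for the LDC, binary learners for the ECOC-SVM).
#'
#' @param x The object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.loo_result <- function(x, ...) x$by_species

#' @rdname tidy.loo_result
#' @export
glance.loo_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$totals[, c("method", "accuracy_pct")],
                             names_from = "method", values_from = "accuracy_pct",
                             names_prefix = "accuracy_")
  dplyr::bind_cols(tibble::tibble(n_specimens = length(unique(x$predictions$specimen_id)),
                                  n_species = length(unique(x$predictions$species)),
                                  seed = x$seed), wide)
}

#' @rdname tidy.loo_result
#' @export
tidy.vdm_measurements <- function(x, ...) {
  out <- tibble::as_tibble(x)
  ratios <- vdm_ratios(x)
  attr(out, "ratios") <- ratios
  out
}

#' @rdname tidy.loo_result
#' @export
tidy.vdm_comparison <- function(x, ...) x$summary
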