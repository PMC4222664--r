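#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a category-cluster fit
#'
#' @param x A `category_fit` from [fit_category_model()].
#' @param ... Unused.
#' @return Tibble with one row per design column: `term`, `estimate`.
#' @exportS3Method generics::tidy
tidy.category_fit <- function(x, ...) {
  tibble::tibble(term = names(x$betas), estimate = unname(x$betas))
}

#' One-row summary of a category-cluster fit
#'
#' @param x A `category_fit`.
#' @param ... Unused.
#' @return Tibble with `cci`, `n_cells`, `rank_deficient`.
#' @exportS3Method generics::glance
glance.category_fit <- function(x, ...) {
  tibble::tibble(cci = x$cci, n_cells = x$n_cells,
                 rank_deficient = x$rank_deficient)
}

#' Tidy an RDM into its pair list
#'
#' @param x An [rdm()].
#' @param ... Unused.
#' @return The [vectorize()] tibble.
#' @exportS3Method generics::tidy
tidy.rdm <- function(x, ...) vectorize(x)

#' One-row summary of an RDM
#'
#' @param x An [rdm()].
#' @param ... Unused.
#' @return Tibble with `n_stimuli`, `n_pairs`, `n_missing`, `metric`.
#' @exportS3Method generics::glance
glance.rdm <- function(x, ...) {
  v <- utv(x)
  tibble::tibble(
    n_stimuli = nrow(x), n_pairs = length(v), n_missing = sum(is.na(v)),
    metric = rdm_metric(x)
  )
}
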