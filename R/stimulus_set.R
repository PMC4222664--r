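#' The ten hierarchical object categories
#'
#' Category labels used throughout the package, ordered from the top of the
#' animacy hierarchy down: animate/inanimate, faces and bodies, their
#' human/non-human subdivisions, and the natural/artificial split of the
#' inanimates.
#'
#' @return Character vector of the ten category names.
#' @export
category_names <- function() {
  c(
    "animate", "inanimate",
    "face", "human_face", "nonhuman_face",
    "body", "human_body", "nonhuman_body",
    "natural_inanimate", "artificial_inanimate"
  )
}

leaf_categories <- function() {
  c(
    "human_face", "nonhuman_face", "human_body", "nonhuman_body",
    "natural_inanimate", "artificial_inanimate"
  )
}

#' Build a stimulus set from leaf-category assignments
#'
#' Each stimulus belongs to exactly one leaf of the category tree
#' (human face, non-human face, human body, non-human body, natural
#' inanimate, artificial inanimate); membership in the ten hierarchical
#' categories is derived from the leaf.
#'
#' @param id Character vector of unique stimulus identifiers.
#' @param leaf Character vector (same length) of leaf-category names, one of
#'   `leaf_categories()`.
#' @return A tibble of class `stimulus_set` with an `id` column, a `leaf`
#'   column, and one logical membership column per category in
#'   [category_names()].
#' @examples
#' ss <- stimulus_set(c("s1", "s2", "s3"),
#'                    c("human_face", "nonhuman_body", "natural_inanimate"))
#' @export
stimulus_set <- function(id, leaf) {
  id <- as.character(id)
  leaf <- as.character(leaf)
  stopifnot(length(id) == length(leaf))
  if (anyDuplicated(id)) stop("stimulus ids must be unique")
  bad <- setdiff(unique(leaf), leaf_categories())
  if (length(bad)) {
    stop("unknown leaf categories: ", paste(bad, collapse = ", "))
  }
  out <- tibble::tibble(
    id = id,
    leaf = leaf,
    face = leaf %in% c("human_face", "nonhuman_face"),
    body = leaf %in% c("human_body", "nonhuman_body"),
    human_face = leaf == "human_face",
    nonhuman_face = leaf == "nonhuman_face",
    human_body = leaf == "human_body",
    nonhuman_body = leaf == "nonhuman_body",
    natural_inanimate = leaf == "natural_inanimate",
    artificial_inanimate = leaf == "artificial_inanimate"
  )
  out$animate <- out$face | out$body
  out$inanimate <- !out$animate
  out <- out[, c("id", "leaf", category_names())]
  class(out) <- c("stimulus_set", class(out))
  validate_stimulus_set(out)
  out
}

#' @keywords internal
validate_stimulus_set <- function(x) {
  stopifnot(is.data.frame(x), all(c("id", category_names()) %in% names(x)))
  if (anyDuplicated(x$id)) stop("stimulus ids must be unique")
  if (!all(xor(x$animate, x$inanimate))) {
    stop("animate and inanimate must be complementary")
  }
  if (any(x$face & !x$animate)) stop("every face must be animate")
  if (!all((x$human_face | x$nonhuman_face) == x$face)) {
    stop("face must be the union of human_face and nonhuman_face")
  }
  if (!all((x$human_body | x$nonhuman_body) == x$body)) {
    stop("body must be the union of human_body and nonhuman_body")
  }
  if (!all((x$natural_inanimate | x$artificial_inanimate) == x$inanimate)) {
    stop("inanimate must be the union of natural and artificial inanimates")
  }
  if (any(x$face & x$body)) stop("face and body must be disjoint")
  invisible(x)
}

#' Default stimulus set mirroring a balanced object-vision study
#'
#' `n_stimuli` stimuli, half animate: the animates split evenly into faces
#' and bodies, each split evenly into human and non-human; the inanimates
#' split evenly into natural and artificial. `n_stimuli` must be divisible
#' by 8 so that every subdivision is exact (the default, 96, gives the
#' familiar 48/48, 24/24/24/24, 12-per-leaf layout).
#'
#' @param n_stimuli Total number of stimuli (default 96).
#' @return A `stimulus_set` tibble.
#' @export
default_stimulus_set <- function(n_stimuli = 96) {
  if (n_stimuli %% 8 != 0) stop("n_stimuli must be divisible by 8")
  k <- n_stimuli / 8L
  leaf <- rep(
    c(
      "human_face", "nonhuman_face", "human_body", "nonhuman_body",
      "natural_inanimate", "natural_inanimate",
      "artificial_inanimate", "artificial_inanimate"
    ),
    each = k
  )
  stimulus_set(sprintf("stim%03d", seq_len(n_stimuli)), leaf)
}

#' Randomly permute the category labels of a stimulus set
#'
#' Reassigns the full hierarchical label tuple (the leaf, hence all ten
#' derived memberships) across stimuli, preserving the category sizes and
#' every containment invariant. Used to build category-label randomization
#' nulls.
#'
#' @param stimuli A `stimulus_set`.
#' @return A `stimulus_set` with permuted labels on the same ids.
#' @export
permute_labels <- function(stimuli) {
  stimulus_set(stimuli$id, sample(stimuli$leaf))
}
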