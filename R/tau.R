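as_dissim_vector <- function(x) {
  if (inherits(x, "rdm")) return(utv(x))
  if (is.data.frame(x)) {
    stopifnot("value" %in% names(x))
    return(x$value)
  }
  as.numeric(x)
}

#' Kendall tau-a rank correlation
#'
#' The proportion of pairs of values that are consistently ordered in both
#' variables: `(n_concordant - n_discordant) / (m(m-1)/2)` over the `m`
#' jointly valid entries. Because the denominator counts all pairs, pairs
#' tied in either variable count as neither concordant nor discordant, so
#' tau-a penalizes tied predictions; this makes it the statistic of choice
#' when comparing candidate RDMs that predict tied ranks (e.g. category
#' models) against data RDMs. Missing entries in either input are excluded
#' pairwise. Counting is O(m log m).
#'
#' @param a,b Aligned dissimilarity vectors: [rdm()] objects over the same
#'   stimuli, tibbles from [vectorize()], or plain numeric vectors (`NA` =
#'   missing).
#' @return The tau-a coefficient, in \[-1, 1\].
#' @examples
#' kendall_tau_a(c(1, 2, 3, 4), c(2, 3, 5, 9))
#' @export
kendall_tau_a <- function(a, b) {
  x <- as_dissim_vector(a)
  y <- as_dissim_vector(b)
  if (length(x) != length(y)) stop("vectors must be aligned on the same pair list")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) stop("need at least 2 jointly valid entries")
  .tau_a_cpp(x[ok], y[ok])
}
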