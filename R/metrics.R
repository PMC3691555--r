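# Pattern statistics: sparseness, overlap, separation, completion quality.
# These are the measures used by every other stage of the model.

#' Population sparseness of a firing-rate pattern
#'
#' Computes the population sparseness
#' \deqn{a = \left(\sum_i r_i / N\right)^2 / \left(\sum_i r_i^2 / N\right)}
#' of a nonnegative rate vector. For a binary pattern this equals the
#' fraction of active neurons; it ranges from `1/N` (a single responsive
#' neuron, a "grandmother cell" code) to 1 (all neurons responding equally).
#' Sparse codes (small `a`) are what give the autoassociative store its high
#' capacity, so this quantity appears in every capacity expression.
#'
#' @param p nonnegative numeric vector of firing rates (any rate unit).
#' @return scalar sparseness in `[1/N, 1]`.
#' @seealso [autoassoc_capacity()] which consumes this quantity.
#' @export
#' @examples
#' population_sparseness(c(1, 0, 0, 0))   # 0.25: binary, 1 of 4 active
#' population_sparseness(c(5, 5, 5))      # 1: all units firing equally
population_sparseness <- function(p) {
  check_rates(p)
  if (all(p == 0)) {
    stop("sparseness is undefined for the all-zero pattern")
  }
  N <- length(p)
  (sum(p) / N)^2 / (sum(p^2) / N)
}

#' Overlap (correlation) between two rate patterns
#'
#' Pearson correlation of two rate vectors over the same population, the
#' retrieval-quality measure used throughout: 1 means identical patterns up
#' to affine scaling, 0 chance-level similarity. Pearson (rather than cosine)
#' is the default because it is insensitive to a common baseline shift such
#' as one produced by global inhibition; cosine similarity is available via
#' `method = "cosine"`.
#'
#' @param p,q numeric vectors of equal length.
#' @param method `"pearson"` (default) or `"cosine"`.
#' @return scalar in `[-1, 1]`.
#' @export
#' @examples
#' pattern_overlap(c(1, 0, 1, 0), c(1, 0, 1, 0))
#' pattern_overlap(c(1, 1, 0, 0), c(0, 0, 1, 1))  # -1, complementary
pattern_overlap <- function(p, q, method = c("pearson", "cosine")) {
  method <- match.arg(method)
  if (length(p) != length(q)) stop("patterns must have equal length")
  if (method == "pearson") {
    if (stats::sd(p) == 0 || stats::sd(q) == 0) {
      stop("overlap is undefined for a zero-variance pattern")
    }
    stats::cor(p, q)
  } else {
    np <- sqrt(sum(p^2)); nq <- sqrt(sum(q^2))
    if (np == 0 || nq == 0) stop("overlap is undefined for an all-zero pattern")
    sum(p * q) / (np * nq)
  }
}

#' Pattern-separation index
#'
#' Difference between the correlation of a pair of input patterns and the
#' correlation of the corresponding output pair. Positive values mean the
#' transformation (e.g. the dentate competitive net or the mossy-fiber
#' projection) has made similar inputs less similar — pattern separation, or
#' orthogonalization.
#'
#' @param in_corr,out_corr correlations in `[-1, 1]`.
#' @return `in_corr - out_corr`.
#' @export
separation_index <- function(in_corr, out_corr) {
  stopifnot(abs(in_corr) <= 1, abs(out_corr) <= 1)
  in_corr - out_corr
}

#' Completion score of a recalled pattern
#'
#' Overlap between a recalled and a stored pattern restricted to the units
#' that were NOT part of the retrieval cue. Credit is given only for units
#' the attractor dynamics actually completed, not for units handed to the
#' network in the cue, so a network that merely echoes its cue scores at or
#' below zero.
#'
#' @param recalled,stored numeric vectors of equal length.
#' @param cue_support integer indices of the units supplied in the cue.
#' @return scalar in `[-1, 1]`.
#' @export
completion_score <- function(recalled, stored, cue_support) {
  if (length(recalled) != length(stored)) stop("patterns must have equal length")
  keep <- setdiff(seq_along(stored), cue_support)
  if (length(keep) < 2L) {
    stop("cue_support leaves no units on which to score completion")
  }
  if (stats::sd(recalled[keep]) == 0) {
    # nothing was completed beyond the cue (e.g. the network echoed it)
    return(0)
  }
  pattern_overlap(recalled[keep], stored[keep])
}
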