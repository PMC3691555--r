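# Diluted recurrent connectivity for the CA3 autoassociator.

#' Build a diluted recurrent contact mask
#'
#' Each postsynaptic neuron receives exactly `C` presynaptic contacts drawn
#' uniformly from the other `N - 1` neurons (no self-contacts). With
#' `allow_multiple = FALSE` (the anatomically motivated default) contacts are
#' drawn without replacement so no neuron pair is connected by more than one
#' synapse — the regime that diluted cortical connectivity is argued to
#' secure. With `allow_multiple = TRUE` contacts are drawn with replacement
#' and a pair may carry a multiplicity > 1; all contacts of a pair transmit,
#' so the pair's effective weight scales with its multiplicity.
#'
#' @param N population size.
#' @param C contacts per postsynaptic neuron, `C < N`.
#' @param allow_multiple logical, permit multiplicity > 1.
#' @param seed integer seed.
#' @return object of class `diluted_connectivity`: list with `N`, `C`,
#'   `mask` (dense `N` x `N` multiplicity matrix, rows = postsynaptic),
#'   `allow_multiple`, `seed`.
#' @export
#' @examples
#' con <- build_diluted_connectivity(50, 10, seed = 1)
#' rowSums(con$mask)  # exactly 10 contacts per neuron
build_diluted_connectivity <- function(N, C, allow_multiple = FALSE,
                                       seed = NULL) {
  stopifnot(N >= 2, C >= 1)
  if (C >= N && !allow_multiple) {
    stop("need C < N for distinct off-diagonal contacts without multiplicity")
  }
  mask <- with_seed(seed, {
    m <- matrix(0L, N, N)
    for (i in seq_len(N)) {
      pre <- sample(seq_len(N)[-i], C, replace = allow_multiple)
      tab <- tabulate(pre, nbins = N)
      m[i, ] <- tab
    }
    m
  })
  structure(
    list(N = N, C = C, mask = mask, allow_multiple = allow_multiple,
         seed = seed),
    class = "diluted_connectivity"
  )
}

#' Build connectivity with a controlled fraction of duplicated contacts
#'
#' At matched total contacts per neuron `C`, a fraction `duplicate_fraction`
#' of a neuron's contact slots is spent on duplicated pairs: each duplicated
#' presynaptic partner occupies two slots and carries multiplicity 2, so its
#' effective synaptic weight is doubled relative to singly contacted
#' partners. This is the manipulation used to show that multiple contacts
#' between neuron pairs distort the attractor landscape and cut storage
#' capacity.
#'
#' @param N,C,seed as in [build_diluted_connectivity()].
#' @param duplicate_fraction fraction of contact slots in duplicated pairs,
#'   in `[0, 1]`.
#' @return a `diluted_connectivity` object (with multiplicities 1 and 2).
#' @export
build_duplicated_connectivity <- function(N, C, duplicate_fraction,
                                          seed = NULL) {
  stopifnot(duplicate_fraction >= 0, duplicate_fraction <= 1, C < N)
  n_dup <- floor(C * duplicate_fraction / 2)   # pairs using two slots each
  n_single <- C - 2L * n_dup
  mask <- with_seed(seed, {
    m <- matrix(0L, N, N)
    for (i in seq_len(N)) {
      pre <- sample(seq_len(N)[-i], n_dup + n_single)
      if (n_dup > 0) m[i, pre[seq_len(n_dup)]] <- 2L
      if (n_single > 0) m[i, pre[n_dup + seq_len(n_single)]] <- 1L
    }
    m
  })
  structure(
    list(N = N, C = C, mask = mask, allow_multiple = TRUE, seed = seed,
         duplicate_fraction = duplicate_fraction),
    class = "diluted_connectivity"
  )
}

#' @export
print.diluted_connectivity <- function(x, ...) {
  cat(sprintf(
    "Diluted connectivity: N = %d, C = %d (dilution %.4g), %s\n",
    x$N, x$C, x$C / x$N,
    if (x$allow_multiple) "multiple contacts allowed" else "single contacts"
  ))
  invisible(x)
}

#' Empirical dilution of a connectivity object
#'
#' Fraction of realized (distinct) neuron pairs among possible off-diagonal
#' pairs, per postsynaptic neuron.
#'
#' @param con a `diluted_connectivity`.
#' @return scalar dilution fraction.
#' @export
empirical_dilution <- function(con) {
  mean(rowSums(con$mask > 0)) / (con$N - 1)
}
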