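# Closed-form storage-capacity formulas and connectivity arithmetic.
# These are the analytic counterparts of the simulations in ca3.R.

#' Analytic capacity of a sparse autoassociative (attractor) network
#'
#' Maximum number of patterns that can be stored and individually retrieved
#' by a recurrent autoassociator with `C` associatively modifiable synapses
#' per neuron and population sparseness `a`:
#' \deqn{p_{max} \approx \frac{C}{a \ln(1/a)} k}
#' with natural logarithm. `k` depends weakly on the firing-rate distribution
#' and connectivity structure and is roughly 0.2-0.3 for biologically
#' plausible codes; the default 0.235 reproduces the standard rat CA3 worked
#' example (`C = 12000`, `a = 0.02` giving about 36,000 memories). Capacity
#' grows linearly in the synapses per neuron and, for sparse codes, roughly
#' with the inverse of the sparseness — the quantitative argument for sparse
#' hippocampal representations.
#'
#' @param C synapses per neuron (recurrent collaterals), positive integer.
#' @param a population sparseness, strictly in (0, 1).
#' @param k proportionality factor, `>= 0`; default 0.235.
#' @return capacity in memory patterns (real; round for reporting).
#' @seealso [pattern_assoc_capacity()], [measure_capacity()] for the
#'   empirical, simulation-based estimate.
#' @export
#' @examples
#' autoassoc_capacity(12000, 0.02)            # ~36,000
#' autoassoc_capacity(12000, 0.02) / 1000     # in thousands
autoassoc_capacity <- function(C, a, k = 0.235) {
  stopifnot(C >= 1, k >= 0)
  if (a <= 0 || a >= 1) stop("sparseness `a` must lie strictly in (0, 1)")
  k * C / (a * log(1 / a))
}

#' Analytic capacity of a feedforward pattern associator
#'
#' \deqn{p_{max} \approx \frac{C^{PA}}{a_0 \ln(1/a_0)}}
#' where `C` is the number of feedforward associatively modifiable synapses
#' per output neuron and `a0` the sparseness of the output representation.
#' Because CA3 receives only ~3600 perforant-path synapses against 12,000
#' recurrent ones, a feedforward account of CA3 storage has roughly
#' 3600/12000 = 0.3 of the recurrent capacity — one of the quantitative
#' arguments that CA3 operates as an attractor, not a feedforward associator.
#'
#' @param C feedforward synapses per output neuron.
#' @param a0 output sparseness, strictly in (0, 1).
#' @return capacity in memory patterns.
#' @export
#' @examples
#' pattern_assoc_capacity(3600, 0.02)
pattern_assoc_capacity <- function(C, a0) {
  stopifnot(C >= 1)
  if (a0 <= 0 || a0 >= 1) stop("sparseness `a0` must lie strictly in (0, 1)")
  C / (a0 * log(1 / a0))
}

#' Connectivity dilution
#'
#' Fraction of possible presynaptic partners actually contacted: `C/N`.
#' For rat CA3, 12,000 recurrent synapses among 300,000 neurons gives 0.04
#' (or ~2% counting both hemispheres' 600,000 neurons as one bilateral
#' network); the 46 mossy-fiber contacts among 10^6 granule cells give
#' 0.005%.
#'
#' @param C synapses per neuron.
#' @param N number of potential presynaptic neurons.
#' @return dilution fraction in (0, 1].
#' @export
#' @examples
#' connectivity_dilution(12000, 300000)  # 0.04
#' connectivity_dilution(46, 1e6) * 100  # 0.0046 -> prints as 0.005 %
connectivity_dilution <- function(C, N) {
  stopifnot(C >= 1, N >= 1)
  if (C > N) stop("`C` cannot exceed the population size `N`")
  C / N
}
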