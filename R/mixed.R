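# Mixed continuous + discrete memories: a continuous attractor sub-population
# coding physical space as a Gaussian bump, combined with a discrete binary
# object/event code, stored together in one attractor. This is how a single
# CA3-like network can hold an object-place association: cueing with the
# object retrieves the bump (the place), and cueing with the place retrieves
# the object units.

#' Specify a mixed continuous + discrete memory
#'
#' @param center bump center, in unit-index coordinates inside
#'   `spatial_range` (1-based; space is non-periodic).
#' @param sigma Gaussian tuning width in index units (default 50).
#' @param spatial_range integer range (length-2 vector) of the continuous
#'   sub-population, default `c(1, 1000)`.
#' @param discrete_indices indices of the active binary units of the
#'   discrete (object/event) component; must lie outside `spatial_range`.
#' @param spatial_amplitude,discrete_amplitude peak rates of the two
#'   components.
#' @return object of class `mixed_memory_spec`.
#' @export
mixed_memory_spec <- function(center, sigma = 50,
                              spatial_range = c(1, 1000),
                              discrete_indices = integer(0),
                              spatial_amplitude = 1,
                              discrete_amplitude = 1) {
  stopifnot(length(spatial_range) == 2, spatial_range[1] < spatial_range[2],
            sigma >= 0, spatial_amplitude > 0, discrete_amplitude > 0)
  if (center < spatial_range[1] || center > spatial_range[2]) {
    stop("`center` must lie inside `spatial_range`")
  }
  if (length(discrete_indices) &&
      any(discrete_indices >= spatial_range[1] &
          discrete_indices <= spatial_range[2])) {
    stop("`discrete_indices` must be disjoint from `spatial_range`")
  }
  structure(
    list(center = center, sigma = sigma, spatial_range = spatial_range,
         discrete_indices = as.integer(discrete_indices),
         spatial_amplitude = spatial_amplitude,
         discrete_amplitude = discrete_amplitude),
    class = "mixed_memory_spec"
  )
}

#' Encode a mixed memory as a rate pattern
#'
#' The continuous component is a Gaussian bump
#' `A * exp(-(i - center)^2 / (2 sigma^2))` over the spatial sub-population
#' (each neuron's firing falls off with distance from its preferred
#' location, and neighbouring neurons have overlapping tuning — the
#' signature of a continuous attractor code); the discrete component sets
#' its binary units to their amplitude; all other units are silent. In the
#' `sigma = 0` limit only the unit at `center` fires.
#'
#' @param spec a [mixed_memory_spec()].
#' @param N total population size (`>= max(spatial_range, discrete)`).
#' @return numeric rate vector of length `N`.
#' @export
encode_mixed_memory <- function(spec, N) {
  stopifnot(inherits(spec, "mixed_memory_spec"))
  hi <- max(spec$spatial_range[2],
            if (length(spec$discrete_indices)) max(spec$discrete_indices) else 0)
  if (N < hi) stop("`N` too small for the spec's index ranges")
  r <- numeric(N)
  idx <- seq(spec$spatial_range[1], spec$spatial_range[2])
  if (spec$sigma == 0) {
    r[round(spec$center)] <- spec$spatial_amplitude
  } else {
    r[idx] <- spec$spatial_amplitude *
      exp(-(idx - spec$center)^2 / (2 * spec$sigma^2))
  }
  r[spec$discrete_indices] <- spec$discrete_amplitude
  r
}

#' Decode the bump center by population vector
#'
#' Rate-weighted center of mass of the unit indices within the spatial
#' sub-population (no wraparound; space is treated as a bounded segment).
#'
#' @param pattern rate vector.
#' @param spatial_range length-2 integer range of the continuous units.
#' @param threshold fraction of the peak rate below which units are ignored
#'   (default 0). A small threshold (e.g. 0.1) makes the decoder robust to
#'   a rectified background-noise floor, which would otherwise bias the
#'   center of mass toward the middle of the range.
#' @return decoded location in index units.
#' @export
decode_bump_center <- function(pattern, spatial_range = c(1, 1000),
                               threshold = 0) {
  idx <- seq(spatial_range[1], spatial_range[2])
  r <- pattern[idx]
  if (all(r <= 0)) stop("no activity in the spatial sub-population to decode")
  if (threshold > 0) r[r < threshold * max(r)] <- 0
  sum(idx * r) / sum(r)
}

#' Store mixed memories and recall one from a single component
#'
#' Convenience wrapper reproducing the object-place attractor demonstration:
#' the supplied mixed memories are stored with the covariance rule, then the
#' network is cued with only one component (the discrete object units, or
#' the continuous bump) of one memory, and the attractor dynamics complete
#' the other component. Cueing with the object retrieves the place bump;
#' cueing with the place retrieves the object units.
#'
#' @param net a [ca3_network()]; its `a_target` sets the recalled active
#'   fraction.
#' @param specs list of [mixed_memory_spec()] objects (all stored).
#' @param cue_memory index into `specs` of the memory to cue.
#' @param cue_component `"discrete"` or `"continuous"`.
#' @param alpha learning rate for storage.
#' @param cue_gain persistent cue field strength during recall; default 0
#'   here (plain `h = W r` dynamics): the cue is a complete component of
#'   the memory, not a degraded fragment, so the attractor is left to
#'   settle freely once started.
#' @return list with `pattern` (recalled rates), `decoded_center`,
#'   `recalled_discrete` (indices of active units outside the spatial
#'   range), `result` (full [recall()] value), and `stored` (the encoded
#'   memory matrix).
#' @export
recall_mixed <- function(net, specs, cue_memory = 1,
                         cue_component = c("discrete", "continuous"),
                         alpha = 1, cue_gain = 0) {
  cue_component <- match.arg(cue_component)
  net$cue_gain <- cue_gain
  stored <- t(vapply(specs, encode_mixed_memory, numeric(net$N), N = net$N))
  W <- store_patterns(net, stored, rule = "covariance", alpha = alpha)
  spec <- specs[[cue_memory]]
  cue <- numeric(net$N)
  if (cue_component == "discrete") {
    if (!length(spec$discrete_indices)) stop("memory has no discrete component")
    cue[spec$discrete_indices] <- spec$discrete_amplitude
  } else {
    full <- encode_mixed_memory(spec, net$N)
    idx <- seq(spec$spatial_range[1], spec$spatial_range[2])
    cue[idx] <- full[idx]
  }
  res <- recall(net, W, cue, target = stored[cue_memory, ])
  sr <- spec$spatial_range
  outside <- setdiff(seq_len(net$N), seq(sr[1], sr[2]))
  list(
    pattern = res$pattern,
    decoded_center = decode_bump_center(res$pattern, sr),
    recalled_discrete = outside[res$pattern[outside] > 0],
    result = res,
    stored = stored
  )
}
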