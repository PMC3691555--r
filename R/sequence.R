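# Temporal-order memory from time-encoding attractor pools: several
# attractor populations with firing-rate adaptation, global inhibition, and
# (optionally) slightly stronger forward than reverse weights between
# successive pools. As an active attractor dies from adaptation, the next
# pool ignites — with forward bias, in fixed order; without it, the least
# recently active (least adapted) pool tends to win. Items associated with
# the pools are then recalled in presentation order by replaying the cycle.

#' Parameters for a sequence (time-encoding) network
#'
#' Units are grouped into `n_pools` pools of `pool_size` rate units coupled
#' through pool means: within-pool weight `w_intra` (the attractor),
#' `forward_bias` added from pool i to pool i+1, global subtractive
#' inhibition `w_inh`, a background drive `b` that lets a new attractor
#' ignite once the active one has died, subtractive adaptation with gain
#' `adaptation_strength` and time constant `adaptation_tau`, and independent
#' Gaussian input noise per unit. Rates are threshold-linear, saturating
#' at 1. Defaults put the network in the slow-transition regime: an active
#' pool is a fixed point without adaptation, and dies after roughly
#' `adaptation_tau` time units with it.
#'
#' @param n_pools number of attractor pools.
#' @param pool_size units per pool.
#' @param w_intra within-pool excitatory weight.
#' @param forward_bias extra weight from pool i to pool i+1 (must be
#'   `< w_intra`; 0 disables the forward-order mechanism).
#' @param w_inh global inhibition weight.
#' @param b background drive.
#' @param adaptation_strength asymptotic adaptation current of a unit firing
#'   at rate 1 (must exceed `w_intra - w_inh + b` for transitions to occur).
#' @param adaptation_tau adaptation time constant; scalar, or one value per
#'   pool (the multiple-time-constant variant).
#' @param noise_sd s.d. of the independent Gaussian input noise added to
#'   each unit at each integration step.
#' @param tau_r rate time constant.
#' @param dt Euler step.
#' @param duration simulated time.
#' @return object of class `sequence_net_params`.
#' @export
sequence_net_params <- function(n_pools = 4, pool_size = 20,
                                w_intra = 2, forward_bias = 0.3,
                                w_inh = 1.2, b = 0.3,
                                adaptation_strength = 1.2,
                                adaptation_tau = 2,
                                noise_sd = 0.05,
                                tau_r = 0.1, dt = 0.01, duration = 30) {
  stopifnot(n_pools >= 1, pool_size >= 1, forward_bias >= 0,
            forward_bias < w_intra, adaptation_tau > 0, tau_r > 0, dt > 0,
            duration > dt, noise_sd >= 0)
  structure(
    list(n_pools = n_pools, pool_size = pool_size, w_intra = w_intra,
         forward_bias = forward_bias, w_inh = w_inh, b = b,
         adaptation_strength = adaptation_strength,
         adaptation_tau = rep_len(adaptation_tau, n_pools),
         noise_sd = noise_sd, tau_r = tau_r, dt = dt, duration = duration),
    class = "sequence_net_params"
  )
}

#' Run the sequence network
#'
#' Euler-integrates the rate and adaptation dynamics from an initial state
#' in which `initial_pool` is fully active. Returns the dominant pool per
#' time step (`0` when no pool exceeds the activity threshold) and the dwell
#' episodes.
#'
#' @param params a [sequence_net_params()].
#' @param initial_pool index of the initially active pool.
#' @param seed integer seed for the noise.
#' @return list with `dominant` (integer vector per step), `times`, `rates`
#'   (pool-mean rate matrix, steps x pools), `episodes` (data frame: pool,
#'   onset, offset, dwell) and `order` (sequence of distinct active pools).
#' @export
run_sequence <- function(params, initial_pool = 1, seed = NULL) {
  p <- params
  stopifnot(initial_pool >= 1, initial_pool <= p$n_pools)
  n <- p$n_pools * p$pool_size
  pool_of <- rep(seq_len(p$n_pools), each = p$pool_size)
  steps <- floor(p$duration / p$dt)
  with_seed(seed, {
    r <- numeric(n)
    r[pool_of == initial_pool] <- 1
    a <- numeric(n)
    dominant <- integer(steps)
    rates <- matrix(0, steps, p$n_pools)
    for (s in seq_len(steps)) {
      m <- vapply(seq_len(p$n_pools), function(q) mean(r[pool_of == q]),
                  numeric(1))
      drive_pool <- p$w_intra * m + p$b - p$w_inh * sum(m)
      if (p$forward_bias > 0 && p$n_pools > 1) {
        drive_pool <- drive_pool +
          p$forward_bias * c(0, m[-p$n_pools])
      }
      input <- drive_pool[pool_of] - a
      if (p$noise_sd > 0) {
        # Per-step input noise (the rate time constant low-passes it).
        input <- input + stats::rnorm(n, sd = p$noise_sd)
      }
      phi <- pmin(pmax(input, 0), 1)
      r <- r + p$dt * (phi - r) / p$tau_r
      if (any(!is.finite(r))) {
        stop("sequence integration diverged; reduce dt or weights")
      }
      a <- a + p$dt * (p$adaptation_strength * r - a) /
        p$adaptation_tau[pool_of]
      mq <- vapply(seq_len(p$n_pools), function(q) mean(r[pool_of == q]),
                   numeric(1))
      rates[s, ] <- mq
      dominant[s] <- if (max(mq) > 0.3) which.max(mq) else 0L
    }
    times <- seq_len(steps) * p$dt
    act <- rle(dominant)
    keep <- act$values != 0L
    offs <- cumsum(act$lengths)
    ons <- offs - act$lengths + 1L
    episodes <- data.frame(
      pool = act$values[keep],
      onset = times[ons[keep]],
      offset = times[offs[keep]],
      dwell = act$lengths[keep] * p$dt
    )
    list(dominant = dominant, times = times, rates = rates,
         episodes = episodes,
         order = episodes$pool[c(TRUE, diff(episodes$pool) != 0)])
  })
}

#' Associate items with time-encoding pools
#'
#' Hebbian pool-to-item weights: item `j`'s pattern is associated with the
#' pool active in slot `pool_schedule[j]`, modelling the recurrent-collateral
#' association between object-coding neurons and time-encoding neurons.
#'
#' @param item_patterns matrix, one item rate pattern per row.
#' @param pool_schedule integer vector, pool index per item (one item per
#'   slot).
#' @param n_pools total pools in the sequence network.
#' @return object of class `time_item_association` (weights: pools x item
#'   units).
#' @export
associate_items <- function(item_patterns, pool_schedule, n_pools) {
  item_patterns <- as_pattern_matrix(item_patterns)
  stopifnot(length(pool_schedule) == nrow(item_patterns),
            all(pool_schedule >= 1), all(pool_schedule <= n_pools))
  if (anyDuplicated(item_patterns, MARGIN = 1L)) {
    warning("duplicate item patterns make order readout ambiguous")
  }
  A <- matrix(0, n_pools, ncol(item_patterns))
  for (j in seq_len(nrow(item_patterns))) {
    A[pool_schedule[j], ] <- A[pool_schedule[j], ] + item_patterns[j, ]
  }
  structure(list(weights = A, item_patterns = item_patterns,
                 pool_schedule = pool_schedule, n_pools = n_pools),
            class = "time_item_association")
}

#' Recall items in temporal order
#'
#' Replays the time-encoding cycle with [run_sequence()] and, for each dwell
#' episode, reads out the item whose pattern best matches the active pool's
#' association weights. If the pools cycle in their normal order, the items
#' come out in presentation order.
#'
#' @param assoc a [associate_items()] object.
#' @param params a [sequence_net_params()] (must have `n_pools` matching).
#' @param initial_pool starting pool for the replay.
#' @param seed integer seed.
#' @return list with `item_order` (indices into the item set, one per dwell
#'   episode, deduplicated consecutively), `episodes`, and the `run`.
#' @export
recall_order <- function(assoc, params, initial_pool = 1, seed = NULL) {
  stopifnot(inherits(assoc, "time_item_association"),
            params$n_pools == assoc$n_pools)
  run <- run_sequence(params, initial_pool = initial_pool, seed = seed)
  eps <- run$episodes
  items <- integer(0)
  for (i in seq_len(nrow(eps))) {
    scores <- as.numeric(assoc$item_patterns %*% assoc$weights[eps$pool[i], ])
    best <- which.max(scores)
    if (scores[best] > 0 &&
        (length(items) == 0L || items[length(items)] != best)) {
      items <- c(items, best)
    }
  }
  list(item_order = items, episodes = eps, run = run)
}
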