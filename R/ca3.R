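# The CA3 autoassociative attractor: Hebbian/covariance storage on a diluted
# recurrent contact mask, k-WTA (or threshold-linear) recall dynamics,
# empirical capacity measurement, and the duplicated-contact experiment.

#' Construct a CA3 attractor network
#'
#' Bundles the diluted recurrent connectivity with the recall parameters.
#' Recall dynamics are synchronous: activations h = W r / C are recomputed
#' for all neurons, then global inhibition is emulated by k-winners-take-all
#' at the target sparseness `a_target` (default), or by a graded
#' threshold-linear transfer (`dynamics = "threshold-linear"`) that keeps the
#' same number of units above threshold but preserves graded rates.
#'
#' @param connectivity a [build_diluted_connectivity()] object.
#' @param a_target sparseness of the recalled representation in (0, 1).
#' @param dynamics `"kwta"` or `"threshold-linear"`.
#' @param max_steps maximum synchronous update steps during recall.
#' @param noise_sd s.d. of Gaussian activation noise added at each step.
#' @param cue_gain strength of the external cue field during recall: the
#'   retrieval cue is not a mere initial condition but a weak input that
#'   stays present while the recurrent collaterals complete the pattern
#'   (the cue pathway keeps firing during retrieval). The default,
#'   `a_target`, puts the cue field at the order of the mean recurrent
#'   activation — weak relative to the recurrent signal, as the cue pathway
#'   is relative to the collaterals. Set to 0 for pure
#'   initial-condition dynamics.
#' @return object of class `ca3_net`.
#' @export
ca3_network <- function(connectivity, a_target,
                        dynamics = c("kwta", "threshold-linear"),
                        max_steps = 25, noise_sd = 0, cue_gain = NULL) {
  dynamics <- match.arg(dynamics)
  stopifnot(inherits(connectivity, "diluted_connectivity"),
            a_target > 0, a_target < 1, max_steps >= 1, noise_sd >= 0)
  if (is.null(cue_gain)) cue_gain <- a_target
  stopifnot(cue_gain >= 0)
  structure(
    list(connectivity = connectivity, N = connectivity$N,
         C = connectivity$C, a_target = a_target, dynamics = dynamics,
         max_steps = max_steps, noise_sd = noise_sd, cue_gain = cue_gain),
    class = "ca3_net"
  )
}

#' Store patterns in the recurrent synapses
#'
#' Applies the associative update on every existing contact, for each
#' pattern:
#' \describe{
#'   \item{`hebb`}{`dw_ij = alpha * r_i * r_j` — pure associative LTP, the
#'     textbook rule. It saturates early with sparse patterns because
#'     weights only grow.}
#'   \item{`covariance` (default)}{`dw_ij = alpha * (r_i - a_post) *
#'     (r_j - a_pre)` — adds the heterosynaptic long-term depression that
#'     efficient storage of sparse patterns requires: a synapse from an
#'     active presynaptic neuron onto a silent postsynaptic neuron is
#'     weakened.}
#' }
#' The total update is a sum over patterns, hence independent of
#' presentation order. Contact multiplicity scales the effective weight
#' (every contact of a pair learns and transmits).
#'
#' @param net a `ca3_net`.
#' @param patterns matrix, one pattern per row (or a single vector).
#' @param rule `"covariance"` or `"hebb"`.
#' @param alpha learning-rate constant (> 0).
#' @param a_pre,a_post sparseness offsets for the covariance rule; default
#'   to the mean rate of each stored pattern.
#' @param weights optional existing weight matrix to add to.
#' @return `N` x `N` weight matrix supported on the contact mask
#'   (rows = postsynaptic).
#' @export
store_patterns <- function(net, patterns, rule = c("covariance", "hebb"),
                           alpha = 1, a_pre = NULL, a_post = NULL,
                           weights = NULL) {
  rule <- match.arg(rule)
  stopifnot(alpha > 0)
  patterns <- as_pattern_matrix(patterns, net$N)
  W <- if (is.null(weights)) matrix(0, net$N, net$N) else weights
  if (nrow(patterns) == 0L) return(W)
  if (rule == "covariance") {
    offs_post <- if (is.null(a_post)) rowMeans(patterns) else
      rep_len(a_post, nrow(patterns))
    offs_pre <- if (is.null(a_pre)) rowMeans(patterns) else
      rep_len(a_pre, nrow(patterns))
    Rpost <- patterns - offs_post
    Rpre <- patterns - offs_pre
  } else {
    Rpost <- patterns
    Rpre <- patterns
  }
  # Sum over patterns of outer(r_post, r_pre), masked to existing contacts;
  # multiplicity multiplies the effective weight.
  dW <- crossprod(Rpost, Rpre)   # t(Rpost) %*% Rpre, N x N
  W + alpha * dW * net$connectivity$mask
}

#' Cued recall by attractor dynamics
#'
#' Starting from the cue, iterates synchronous updates
#' `h = W r / C + cue_gain * cue` followed by the network's rate
#' nonlinearity (k-WTA at `a_target`, or threshold-linear) until the active
#' set stops changing or `max_steps` is reached. The drive is computed from
#' the average of the last two states: the fixed points are unchanged, but
#' the period-2 limit cycles that parallel binary updates can fall into are
#' suppressed. This is pattern
#' completion: the weak persistent cue field holds the network near the
#' cued units while the recurrent collaterals reinstate the missing ones,
#' and the state falls into the basin of attraction of the stored memory.
#'
#' @param net a `ca3_net`.
#' @param W weight matrix from [store_patterns()].
#' @param cue numeric cue vector of length `N` (e.g. a degraded pattern).
#' @param target optional stored pattern; if given, the per-step overlap
#'   with it is recorded in the trajectory.
#' @param seed optional seed (only relevant when `noise_sd > 0`).
#' @return list with `pattern` (final rates), `converged` (logical; a
#'   non-converged run is flagged, not an error), `steps`, and `trajectory`
#'   (per-step overlap with `target` if given, else with the previous
#'   state).
#' @export
recall <- function(net, W, cue, target = NULL, seed = NULL) {
  stopifnot(length(cue) == net$N)
  k <- n_active(net$a_target, net$N)
  with_seed(seed, {
    r <- as.numeric(cue)
    traj <- numeric(0)
    converged <- FALSE
    steps <- 0L
    prev_active <- which(r > 0)
    cue_field <- net$cue_gain * as.numeric(cue)
    r_prev <- r
    for (s in seq_len(net$max_steps)) {
      # drive from the mean of the last two states: same fixed points as
      # the undamped map, but the period-2 limit cycles that parallel
      # binary updates are prone to are no longer stable
      h <- as.numeric(W %*% ((r + r_prev) / 2)) / net$C + cue_field
      if (net$noise_sd > 0) h <- h + stats::rnorm(net$N, sd = net$noise_sd)
      r_new <- kwta(h, k, binary = (net$dynamics == "kwta"))
      active <- which(r_new > 0)
      traj <- c(traj, if (!is.null(target)) {
        pattern_overlap(r_new, target)
      } else if (stats::sd(r_new) > 0 && stats::sd(r) > 0) {
        pattern_overlap(r_new, r)
      } else NA_real_)
      steps <- s
      same <- identical(active, prev_active) &&
        (net$dynamics == "kwta" || isTRUE(all.equal(r_new, r)))
      r_prev <- r
      r <- r_new
      prev_active <- active
      if (same) { converged <- TRUE; break }
    }
    list(pattern = r, converged = converged, steps = steps, trajectory = traj)
  })
}

# Recall many cues at once (columns of `cues`); returns final rate matrix.
# Same dynamics as recall(), vectorized over cues for the capacity sweeps.
recall_batch <- function(net, W, cues, steps = net$max_steps) {
  k <- n_active(net$a_target, net$N)
  R <- cues
  R_prev <- cues
  cue_field <- net$cue_gain * cues
  for (s in seq_len(steps)) {
    H <- (W %*% ((R + R_prev) / 2)) / net$C + cue_field
    R_new <- apply(H, 2L, function(h) kwta(h, k,
                                           binary = (net$dynamics == "kwta")))
    if (identical(R_new > 0, R > 0)) { R <- R_new; break }
    R_prev <- R
    R <- R_new
  }
  R
}

# Degrade a pattern to a partial cue: keep a random fraction of its active
# units, silence the rest.
make_partial_cue <- function(pattern, cue_fraction) {
  active <- which(pattern > 0)
  keep <- sample(active, max(1L, round(cue_fraction * length(active))))
  cue <- numeric(length(pattern))
  cue[keep] <- pattern[keep]
  cue
}

#' Measure storage capacity empirically
#'
#' For each load `p` in `p_grid`, stores `p` random binary patterns at
#' sparseness `a_target` and attempts recall of up to `n_test` of them from
#' partial cues (`cue_fraction` of the active units). A pattern counts as
#' retrieved when the overlap between the recalled and stored pattern is at
#' least `overlap_criterion`. The capacity `p_max` is the largest load at
#' which at least `retrieved_criterion` of the probed patterns are
#' retrieved, and the proportionality factor of the analytic capacity
#' formula is recovered as `k = p_max * a * ln(1/a) / C`.
#'
#' @param N,C network size and contacts per neuron.
#' @param a_target pattern and recall sparseness.
#' @param p_grid increasing vector of loads to test.
#' @param cue_fraction fraction of active units in the retrieval cue.
#' @param overlap_criterion per-pattern retrieval threshold (default 0.7).
#' @param retrieved_criterion fraction of patterns that must be retrieved
#'   (default 0.9).
#' @param seeds integer vector; the protocol is repeated per seed.
#' @param n_test maximum number of recall probes per load (sampling keeps
#'   large sweeps affordable; the retrieved fraction is estimated from this
#'   probe set).
#' @param recall_steps synchronous steps per recall probe.
#' @return list with `sweep` (data frame: seed, p, fraction_retrieved),
#'   `p_max` (per seed), `k_fit` (per seed), `k_mean`.
#' @export
measure_capacity <- function(N, C, a_target, p_grid, cue_fraction = 0.5,
                             overlap_criterion = 0.7,
                             retrieved_criterion = 0.9,
                             seeds = 1L, n_test = 40L, recall_steps = 12L) {
  if (length(p_grid) == 0L) stop("empty p_grid")
  stopifnot(all(diff(p_grid) > 0), cue_fraction > 0, cue_fraction <= 1)
  rows <- list()
  p_max <- numeric(length(seeds))
  for (si in seq_along(seeds)) {
    seed <- seeds[si]
    con <- build_diluted_connectivity(N, C, seed = seed)
    net <- ca3_network(con, a_target = a_target, max_steps = recall_steps)
    fr <- with_seed(seed + 10000L, {
      vapply(p_grid, function(p) {
        pats <- generate_patterns(N, p, a_target)
        W <- store_patterns(net, pats, rule = "covariance",
                            a_pre = a_target, a_post = a_target)
        probe <- if (p > n_test) sort(sample.int(p, n_test)) else seq_len(p)
        cues <- vapply(probe, function(i) make_partial_cue(pats[i, ],
                                                           cue_fraction),
                       numeric(N))
        R <- recall_batch(net, W, cues, steps = recall_steps)
        ok <- vapply(seq_along(probe), function(j) {
          pattern_overlap(R[, j], pats[probe[j], ]) >= overlap_criterion
        }, logical(1))
        mean(ok)
      }, numeric(1))
    })
    rows[[si]] <- data.frame(seed = seed, p = p_grid, fraction_retrieved = fr)
    ok_p <- p_grid[fr >= retrieved_criterion]
    p_max[si] <- if (length(ok_p)) max(ok_p) else 0
  }
  k_fit <- p_max * a_target * log(1 / a_target) / C
  list(sweep = do.call(rbind, rows), p_max = p_max, k_fit = k_fit,
       k_mean = mean(k_fit))
}

#' Duplicated-contact capacity experiment
#'
#' Compares the empirical capacity of a network whose contacts are all
#' between distinct neuron pairs against one where a fraction of contact
#' slots is spent on duplicated pairs (doubled effective weight), at matched
#' total contacts per neuron. Duplicated contacts distort the attractor
#' landscape — the doubled weights dominate which states are stable — and
#' reduce capacity, the argument for why recurrent cortical connectivity is
#' diluted.
#'
#' @param N,C,a_target,p_grid,seeds,cue_fraction,overlap_criterion,retrieved_criterion,n_test,recall_steps
#'   as in [measure_capacity()].
#' @param duplicate_fraction fraction of contact slots in duplicated pairs.
#' @return list with `p_max_baseline`, `p_max_duplicated` (per seed), and
#'   the two sweeps.
#' @export
duplicate_contact_experiment <- function(N, C, a_target, duplicate_fraction,
                                         p_grid, seeds = 1L,
                                         cue_fraction = 0.5,
                                         overlap_criterion = 0.7,
                                         retrieved_criterion = 0.9,
                                         n_test = 40L, recall_steps = 12L) {
  run <- function(make_con) {
    p_max <- numeric(length(seeds))
    sweeps <- list()
    for (si in seq_along(seeds)) {
      seed <- seeds[si]
      con <- make_con(seed)
      net <- ca3_network(con, a_target = a_target, max_steps = recall_steps)
      fr <- with_seed(seed + 10000L, {
        vapply(p_grid, function(p) {
          pats <- generate_patterns(N, p, a_target)
          W <- store_patterns(net, pats, rule = "covariance",
                              a_pre = a_target, a_post = a_target)
          probe <- if (p > n_test) sort(sample.int(p, n_test)) else seq_len(p)
          cues <- vapply(probe, function(i) make_partial_cue(pats[i, ],
                                                             cue_fraction),
                         numeric(N))
          R <- recall_batch(net, W, cues, steps = recall_steps)
          mean(vapply(seq_along(probe), function(j) {
            pattern_overlap(R[, j], pats[probe[j], ]) >= overlap_criterion
          }, logical(1)))
        }, numeric(1))
      })
      sweeps[[si]] <- data.frame(seed = seed, p = p_grid,
                                 fraction_retrieved = fr)
      ok_p <- p_grid[fr >= retrieved_criterion]
      p_max[si] <- if (length(ok_p)) max(ok_p) else 0
    }
    list(p_max = p_max, sweep = do.call(rbind, sweeps))
  }
  base <- run(function(seed) build_diluted_connectivity(N, C, seed = seed))
  dup <- run(function(seed) build_duplicated_connectivity(
    N, C, duplicate_fraction, seed = seed))
  list(p_max_baseline = base$p_max, p_max_duplicated = dup$p_max,
       sweep_baseline = base$sweep, sweep_duplicated = dup$sweep)
}
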