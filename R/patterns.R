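# Seeded generators for the synthetic firing-rate patterns and object-place
# events consumed by the network modules. These realize the statistical
# structure the theory assumes: sparse binary or graded (exponential-tailed)
# codes, optionally with a controlled pairwise correlation.

#' Generate an ensemble of sparse firing-rate patterns
#'
#' Binary patterns have exactly `ceiling(a * N)` units active at unit rate,
#' chosen uniformly. Graded patterns draw exponential rates (the firing-rate
#' distribution typically observed across stimuli in cortex), truncated at 5
#' times the mean to keep weight updates bounded, on a support thinned so the
#' measured population sparseness is close to `a`. An optional pairwise
#' correlation between consecutive pattern pairs is produced by a shared-core
#' construction: a fraction of active units is common to both members of a
#' pair.
#'
#' @param N population size.
#' @param p number of patterns.
#' @param a target sparseness in (0, 1).
#' @param rate_distribution `"binary"` or `"exponential"`.
#' @param pairwise_target_corr optional target Pearson correlation in `[0, 1)`
#'   between patterns `2m-1` and `2m` (binary patterns only).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @return matrix with one pattern per row (`p` x `N`).
#' @export
#' @examples
#' x <- generate_patterns(100, 5, a = 0.05, seed = 1)
#' rowSums(x > 0)  # exactly 5 active units each
generate_patterns <- function(N, p, a,
                              rate_distribution = c("binary", "exponential"),
                              pairwise_target_corr = NULL,
                              seed = NULL) {
  rate_distribution <- match.arg(rate_distribution)
  stopifnot(N >= 1, p >= 1, a > 0, a < 1)
  n_act <- as.integer(ceiling(a * N))
  with_seed(seed, {
    out <- matrix(0, nrow = p, ncol = N)
    if (!is.null(pairwise_target_corr)) {
      if (rate_distribution != "binary") {
        stop("correlated ensembles are only supported for binary patterns")
      }
      rho <- pairwise_target_corr
      if (rho < 0 || rho >= 1) stop("pairwise_target_corr must be in [0, 1)")
      # For binary patterns at sparseness f with n_shared common active
      # units, Pearson corr = (s/f - f) / (1 - f) where s = P(both active).
      f <- n_act / N
      s_target <- f * (rho * (1 - f) + f)
      n_shared <- round(s_target * N)
      if (n_shared > n_act) stop("infeasible correlation target")
      n_free <- n_act - n_shared
      if (N - n_shared < 2L * n_free) stop("infeasible correlation target")
      for (m in seq_len(ceiling(p / 2))) {
        core <- sample.int(N, n_shared)
        rest <- setdiff(seq_len(N), core)
        free <- sample(rest, 2L * n_free)  # disjoint private units per member
        i <- 2L * m - 1L
        out[i, c(core, free[seq_len(n_free)])] <- 1
        if (2L * m <= p) {
          out[2L * m, c(core, free[n_free + seq_len(n_free)])] <- 1
        }
      }
    } else {
      for (i in seq_len(p)) {
        active <- sample.int(N, n_act)
        if (rate_distribution == "binary") {
          out[i, active] <- 1
        } else {
          r <- stats::rexp(n_act)
          out[i, active] <- pmin(r, 5)
        }
      }
      if (rate_distribution == "exponential") {
        # Exponential rates on a fraction f of units give population
        # sparseness ~ f * E[r]^2 / E[r^2] ~ f/2; widen the support so the
        # measured Eq.-2 sparseness lands on the target a.
        meas <- mean(apply(out, 1L, population_sparseness))
        if (meas < a) {
          scale_up <- min(a / meas, N / n_act)
          n_act2 <- as.integer(min(N, ceiling(n_act * scale_up)))
          out[] <- 0
          for (i in seq_len(p)) {
            active <- sample.int(N, n_act2)
            out[i, active] <- pmin(stats::rexp(n_act2), 5)
          }
        }
      }
    }
    out
  })
}

#' Generate object-place events
#'
#' Events pair a discrete object with a place in a small discrete space, the
#' minimal structure of an episodic memory ("an object in a particular
#' place"). Each event gets a distinct, randomly drawn binary object pattern
#' and a distinct place; the place code is a binary pattern per location.
#'
#' @param n_events number of events (each a distinct object at a distinct
#'   place).
#' @param n_places number of available places (`>= n_events`).
#' @param n_object_units,n_place_units sizes of the object and place
#'   sub-populations.
#' @param object_sparseness fraction of object units active per object.
#' @param place_sparseness fraction of place units active per place.
#' @param seed integer seed.
#' @return list with `events` (data frame: object_id, place_id), `objects`
#'   (matrix, one object pattern per row), `places` (matrix, one place
#'   pattern per row, row i = place i), and `patterns`: the concatenated
#'   object+place rate pattern per event (object units first).
#' @export
generate_events <- function(n_events, n_places = n_events,
                            n_object_units = 200, n_place_units = 200,
                            object_sparseness = 0.1, place_sparseness = 0.1,
                            seed = NULL) {
  stopifnot(n_events >= 1)
  if (n_events > n_places) {
    stop("more events than distinct places")
  }
  with_seed(seed, {
    objects <- generate_patterns(n_object_units, n_events, object_sparseness)
    places_all <- generate_patterns(n_place_units, n_places, place_sparseness)
    place_id <- sample.int(n_places, n_events)
    patterns <- cbind(objects, places_all[place_id, , drop = FALSE])
    list(
      events = data.frame(object_id = seq_len(n_events), place_id = place_id),
      objects = objects,
      places = places_all,
      patterns = patterns
    )
  })
}
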