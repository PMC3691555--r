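# Entorhinal grid-cell input, dentate competitive learning (grid-to-place
# transformation and pattern separation), the sparse mossy-fiber projection
# that randomizes CA3 representations during storage, and the perforant-path
# pathway that delivers the retrieval cue.

#' Grid-cell firing map
#'
#' Standard interference construction: the rate at position `x` is the
#' rectified mean of three cosine plane waves with wave vectors at 60 degree
#' separations, giving a triangular lattice of firing fields with period
#' `spacing`, rotated by `orientation` and translated by `phase`, scaled so
#' the lattice vertices fire at `peak_rate`.
#'
#' @param positions numeric matrix of 2-D positions (n x 2, cm), or a
#'   vector of 1-D positions (treated as points on the x axis).
#' @param spacing grid period (cm), > 0.
#' @param orientation lattice orientation (radians).
#' @param phase length-2 spatial offset (cm).
#' @param peak_rate firing rate at a lattice vertex.
#' @return numeric vector of nonnegative rates, one per position.
#' @export
#' @examples
#' grid_firing_map(cbind(0, 0), spacing = 30)  # phase origin: peak rate
grid_firing_map <- function(positions, spacing, orientation = 0,
                            phase = c(0, 0), peak_rate = 1) {
  stopifnot(spacing > 0, peak_rate > 0)
  if (is.null(dim(positions))) positions <- cbind(positions, 0)
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2, all(is.finite(positions)))
  # Wave vectors of magnitude 4*pi/(sqrt(3)*spacing) at 60 deg separations
  # give peak-to-peak lattice spacing equal to `spacing`.
  kmag <- 4 * pi / (sqrt(3) * spacing)
  theta <- orientation + c(0, pi / 3, 2 * pi / 3)
  d <- sweep(positions, 2L, phase)
  waves <- vapply(theta, function(th) {
    cos(kmag * (d[, 1] * cos(th) + d[, 2] * sin(th)))
  }, numeric(nrow(d)))
  s <- rowMeans(matrix(waves, nrow = nrow(d)))
  peak_rate * pmax(s, 0)
}

#' Build a population of grid cells over a set of positions
#'
#' Convenience fixture: `n_cells` grid cells with spacings cycled over
#' `spacings`, random orientations and phases, evaluated at `positions`.
#'
#' @param n_cells number of grid cells.
#' @param positions matrix or vector of positions (see
#'   [grid_firing_map()]).
#' @param spacings vector of grid periods to cycle over (cm).
#' @param peak_rate vertex firing rate.
#' @param seed integer seed.
#' @return matrix of rates, one row per position, one column per cell.
#' @export
grid_population <- function(n_cells, positions,
                            spacings = c(30, 50, 70), peak_rate = 1,
                            seed = NULL) {
  if (is.null(dim(positions))) positions <- cbind(positions, 0)
  with_seed(seed, {
    sp <- rep_len(spacings, n_cells)
    vapply(seq_len(n_cells), function(i) {
      grid_firing_map(positions, spacing = sp[i],
                      orientation = stats::runif(1, 0, pi / 3),
                      phase = stats::runif(2, 0, sp[i]),
                      peak_rate = peak_rate)
    }, numeric(nrow(positions)))
  })
}

#' Train a competitive network (grid-to-place transformation)
#'
#' One-layer competitive learning with k-winners-take-all output at
#' sparseness `a_out` and divisive (unit-norm) weight normalization: for
#' each input presentation the winners' weight rows move toward the input
#' and are renormalized to unit length, so each output unit learns to
#' respond to a particular combination of input cells. Applied to entorhinal
#' grid-cell input, each learned combination effectively specifies a place,
#' turning periodic multi-peaked grid input into sparse place-like output —
#' while the mutual inhibition (k-WTA) keeps the code sparse and performs
#' pattern separation.
#'
#' @param input_patterns matrix, one input pattern per row.
#' @param n_out number of output (granule-like) units.
#' @param a_out output sparseness target in (0, 1).
#' @param learn_rate weight step per presentation (> 0).
#' @param epochs passes over the input set.
#' @param seed integer seed (weight initialization and presentation order).
#' @return list with `weights` (`n_out` x `n_in`, unit-norm rows) and
#'   `outputs` (matrix, output pattern per input row after training).
#' @export
train_competitive <- function(input_patterns, n_out, a_out = 0.05,
                              learn_rate = 0.1, epochs = 10, seed = NULL) {
  input_patterns <- as_pattern_matrix(input_patterns)
  stopifnot(a_out > 0, a_out < 1, learn_rate > 0, epochs >= 1)
  n_in <- ncol(input_patterns)
  k <- n_active(a_out, n_out)
  with_seed(seed, {
    W <- matrix(stats::runif(n_out * n_in, 0.5, 1), n_out, n_in)
    W <- W / sqrt(rowSums(W^2))
    for (e in seq_len(epochs)) {
      for (i in sample.int(nrow(input_patterns))) {
        x <- input_patterns[i, ]
        if (all(x == 0)) {
          warning("skipping all-zero input pattern")
          next
        }
        h <- as.numeric(W %*% x)
        winners <- order(h, decreasing = TRUE)[seq_len(k)]
        W[winners, ] <- W[winners, , drop = FALSE] +
          learn_rate * matrix(x, k, n_in, byrow = TRUE)
        W[winners, ] <- W[winners, , drop = FALSE] /
          sqrt(rowSums(W[winners, , drop = FALSE]^2))
      }
    }
    outputs <- t(apply(input_patterns, 1L, function(x) {
      if (all(x == 0)) return(numeric(n_out))
      kwta(as.numeric(W %*% x), k)
    }))
    list(weights = W, outputs = outputs)
  })
}

#' Place-field statistics of a response map
#'
#' For each unit, counts contiguous runs of positions where the response
#' exceeds half its maximum, and reports their widths. Grid input has
#' multiple fields per traversal (periodicity); trained granule-like units
#' should mostly have a single field.
#'
#' @param response_map matrix, one row per position along a contiguous
#'   track, one column per unit.
#' @param position_step distance between consecutive positions (for widths).
#' @return data frame with `unit`, `n_fields`, `mean_width` (NA for silent
#'   units, which have 0 fields).
#' @export
place_field_stats <- function(response_map, position_step = 1) {
  response_map <- as.matrix(response_map)
  out <- lapply(seq_len(ncol(response_map)), function(j) {
    r <- response_map[, j]
    if (max(r) <= 0) {
      return(data.frame(unit = j, n_fields = 0L, mean_width = NA_real_))
    }
    above <- r > max(r) / 2
    runs <- rle(above)
    widths <- runs$lengths[runs$values] * position_step
    data.frame(unit = j, n_fields = length(widths),
               mean_width = mean(widths))
  })
  do.call(rbind, out)
}

#' Build a sparse mossy-fiber projection
#'
#' Each CA3 unit samples a small fixed set of `n_contacts` granule cells
#' (default 46, the anatomical count per CA3 cell). Because each CA3 cell
#' listens to so few, effectively random, granule cells, the CA3 patterns
#' assigned to different events are close to random — the randomizing
#' pattern-separation effect that keeps stored memories maximally distinct.
#'
#' @param n_dg number of granule cells.
#' @param n_ca3 number of CA3 units.
#' @param n_contacts mossy-fiber contacts per CA3 unit (default 46).
#' @param seed integer seed.
#' @return object of class `mossy_projection`: list with `contacts`
#'   (`n_ca3` x `n_contacts` index matrix), sizes, and seed.
#' @export
mossy_projection <- function(n_dg, n_ca3, n_contacts = 46, seed = NULL) {
  if (n_contacts > n_dg) stop("`n_contacts` cannot exceed `n_dg`")
  built <- with_seed(seed, {
    contacts <- t(vapply(seq_len(n_ca3), function(i) sample.int(n_dg, n_contacts),
                         integer(n_contacts)))
    # Fixed per-unit jitter for tie-breaking among equal integer drives,
    # part of the projection so the DG -> CA3 map stays deterministic.
    list(contacts = contacts, jitter = stats::runif(n_ca3, 0, 1e-9))
  })
  structure(list(contacts = built$contacts, jitter = built$jitter,
                 n_dg = n_dg, n_ca3 = n_ca3,
                 n_contacts = n_contacts, seed = seed),
            class = "mossy_projection")
}

#' Drive CA3 through the mossy fibers
#'
#' Each CA3 unit's drive is the summed rate of its sampled granule cells;
#' the CA3 pattern is the k-winners-take-all binarization at sparseness
#' `a_ca3`. Deterministic given the projection, so a granule-cell pattern
#' always maps to the same CA3 pattern.
#'
#' @param dg_pattern granule-cell rate vector (length `n_dg`).
#' @param proj a [mossy_projection()].
#' @param a_ca3 CA3 sparseness target.
#' @return binary CA3 rate vector of length `n_ca3`.
#' @export
apply_mossy <- function(dg_pattern, proj, a_ca3 = 0.05) {
  stopifnot(inherits(proj, "mossy_projection"),
            length(dg_pattern) == proj$n_dg)
  drive <- rowSums(matrix(dg_pattern[proj$contacts], nrow = proj$n_ca3))
  kwta(drive + proj$jitter, n_active(a_ca3, proj$n_ca3))
}

#' Train the perforant-path cue pathway
#'
#' Associative Hebbian weights from entorhinal cortex to CA3, trained at
#' storage time on (EC pattern, CA3 pattern) pairs. At recall, applying an
#' EC cue returns the k-WTA of the weighted sum: a possibly imperfect CA3
#' cue that the CA3 recurrent attractor then completes. This pathway carries
#' the retrieval cue; it is the mossy fibers that set the CA3 patterns
#' during storage.
#'
#' @param ec_patterns,ca3_patterns matrices with one paired pattern per row.
#' @param learn_rate Hebbian step.
#' @return weight matrix (`n_ca3` x `n_ec`).
#' @export
train_pp_cue <- function(ec_patterns, ca3_patterns, learn_rate = 1) {
  ec_patterns <- as_pattern_matrix(ec_patterns)
  ca3_patterns <- as_pattern_matrix(ca3_patterns)
  if (nrow(ec_patterns) != nrow(ca3_patterns)) {
    stop("EC and CA3 pattern counts differ")
  }
  learn_rate * crossprod(ca3_patterns, ec_patterns)
}

#' Apply the perforant-path cue pathway
#'
#' @param W_pp weights from [train_pp_cue()].
#' @param ec_pattern EC rate vector.
#' @param a_ca3 CA3 sparseness target.
#' @return binary CA3 cue vector.
#' @export
apply_pp_cue <- function(W_pp, ec_pattern, a_ca3 = 0.05) {
  stopifnot(ncol(W_pp) == length(ec_pattern))
  h <- as.numeric(W_pp %*% ec_pattern)
  kwta(h, n_active(a_ca3, nrow(W_pp)))
}
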