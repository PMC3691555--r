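# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All exported stochastic entry points
# funnel their randomness through this so results are reproducible and do not
# perturb the user's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' k-winners-take-all rectification
#'
#' Keeps the `k` largest entries of an activation vector and silences the
#' rest. This is the standard surrogate for fast feedback inhibition that
#' clamps the fraction of simultaneously active neurons: the interneuron
#' network is not modelled explicitly, only its effect of fixing the active
#' fraction. Ties at the cut are broken by index order (deterministic).
#'
#' @param h numeric activation vector.
#' @param k integer, number of winners (`1 <= k <= length(h)`).
#' @param binary logical; if `TRUE` (default) winners fire at unit rate, if
#'   `FALSE` winners keep their activation values shifted so the largest
#'   loser sits at zero (a graded, threshold-linear output).
#' @return numeric vector of the same length as `h`.
#' @export
#' @examples
#' kwta(c(0.2, 1.5, -1, 0.9), 2)
kwta <- function(h, k, binary = TRUE) {
  n <- length(h)
  stopifnot(k >= 1, k <= n)
  ord <- order(h, decreasing = TRUE)
  winners <- ord[seq_len(k)]
  r <- numeric(n)
  if (binary) {
    r[winners] <- 1
  } else {
    theta <- if (k < n) h[ord[k + 1L]] else min(h)
    r[winners] <- pmax(h[winners] - theta, 0)
  }
  r
}

# Number of active units implied by a sparseness target.
n_active <- function(a, N) {
  k <- round(a * N)
  max(1L, min(as.integer(k), N))
}

check_rates <- function(p, arg = "pattern") {
  if (!is.numeric(p) || length(p) < 1L) {
    stop(sprintf("`%s` must be a numeric vector of length >= 1", arg))
  }
  if (any(!is.finite(p))) stop(sprintf("`%s` contains non-finite rates", arg))
  if (any(p < 0)) stop(sprintf("`%s` contains negative rates", arg))
  invisible(p)
}

# Patterns are stored one per row throughout the package.
as_pattern_matrix <- function(patterns, N = NULL) {
  if (is.numeric(patterns) && is.null(dim(patterns))) {
    patterns <- matrix(patterns, nrow = 1L)
  }
  patterns <- as.matrix(patterns)
  if (!is.null(N) && ncol(patterns) != N) {
    stop(sprintf("pattern length %d does not match population size %d",
                 ncol(patterns), N))
  }
  patterns
}
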